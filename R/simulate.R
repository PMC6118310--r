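# Seeded synthetic-genome generator: two related genotypes with planted
# tandem duplicate clusters of controlled divergence/age, interleaved
# cassettes, intervening genes, TE features in contains/captured/partial
# configurations, subgenome blocks, a homology map, and a truth ledger so
# every downstream stage can be scored against known answers.

SENSE_CODONS <- {
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

#' Simulation configuration
#'
#' Defaults describe the study conditions emulated throughout the package:
#' two 5-Mb chromosomes, 200 shared background genes, 30 planted tandem
#' duplicate clusters with a bimodal (recent/ancient) age mixture, three
#' interleaved cassette pairs, and a grass-like nuclear substitution rate.
#'
#' @param seed Integer seed fixing all randomness end-to-end.
#' @param n_chromosomes Number of chromosomes per genotype.
#' @param chromosome_length Chromosome length in bp.
#' @param n_background_genes Non-duplicate genes, shared by both genotypes.
#' @param n_planted_clusters Planted tandem duplicate clusters (ignored when
#'   `planted_clusters` is supplied).
#' @param planted_clusters Optional data.frame overriding the generated
#'   plan: columns `size`, `age_my`, `intervening`, `cassette_pair`
#'   (integer id or `NA`), `single_exon`.
#' @param n_cassette_pairs Cassette pairs among the planted clusters; each
#'   pair consumes two equal-size clusters laid out interleaved.
#' @param te_density_per_class Named proportions of chromosome bases covered
#'   by background (intergenic) TEs per class.
#' @param shared_fraction Proportion of planted clusters present in both
#'   genotypes; the rest are split between A-private and B-private.
#' @param substitution_rate Substitutions/site/MY on each lineage.
#' @param calibration_my Outgroup (maize/Sorghum-like) divergence in MY.
#' @param cds_codon_range Range of CDS lengths in codons (uniform draw).
#' @param single_exon_fraction Fraction of planted clusters whose genes are
#'   single-exon.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chromosomes = 2,
                       chromosome_length = 5e6,
                       n_background_genes = 200,
                       n_planted_clusters = 30,
                       planted_clusters = NULL,
                       n_cassette_pairs = 3,
                       te_density_per_class = c(LTR = 0.25, LINE = 0.03,
                                                SINE = 0.01, TIR = 0.08),
                       shared_fraction = 0.38,
                       substitution_rate = 0.0065,
                       calibration_my = 12,
                       cds_codon_range = c(100, 200),
                       single_exon_fraction = 0.25) {
  stopifnot(seed == as.integer(seed), n_chromosomes >= 1,
            shared_fraction >= 0, shared_fraction <= 1,
            all(te_density_per_class >= 0), all(te_density_per_class <= 1),
            substitution_rate > 0, calibration_my > 0)
  structure(as.list(environment()), class = "sim_config")
}

# Apply Jukes-Cantor evolution for an expected d substitutions/site.
#' @noRd
mutate_jc <- function(seq, d) {
  if (d <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  p <- 0.75 * (1 - exp(-4 * d / 3))
  hit <- which(runif(length(ch)) < p)
  if (length(hit) > 0) {
    bases <- c("A", "C", "G", "T")
    for (i in hit) {
      ch[i] <- sample(setdiff(bases, ch[i]), 1)
    }
  }
  paste(ch, collapse = "")
}

#' @noRd
random_cds <- function(n_codons) {
  paste0("ATG",
         paste(sample(SENSE_CODONS, n_codons - 2L, replace = TRUE),
               collapse = ""),
         "TAA")
}

# Generate the planted-cluster plan from the seeded RNG.
#' @noRd
default_planted_plan <- function(config) {
  n <- config$n_planted_clusters
  n_cas <- min(config$n_cassette_pairs, n %/% 2)
  # bimodal age mixture mirroring a recent/ancient duplication history,
  # capped so expected CDS divergence 2*r*t stays at or below 20%
  age_cap <- 0.20 / (2 * config$substitution_rate)
  draw_age <- function(k) {
    cls <- sample(c("recent", "intermediate", "ancient"), k, replace = TRUE,
                  prob = c(0.4, 0.2, 0.4))
    a <- numeric(k)
    a[cls == "recent"] <- runif(sum(cls == "recent"), 0.3, 2)
    a[cls == "intermediate"] <- runif(sum(cls == "intermediate"), 3, 8)
    a[cls == "ancient"] <- runif(sum(cls == "ancient"), 10,
                                 min(13, age_cap))
    a
  }
  size <- sample(2:4, n, replace = TRUE, prob = c(0.7, 0.2, 0.1))
  cassette_pair <- rep(NA_integer_, n)
  if (n_cas > 0) {
    idx <- seq_len(2 * n_cas)
    cassette_pair[idx] <- rep(seq_len(n_cas), each = 2)
    # cassette partners share a size so their spans stagger, not nest
    size[idx] <- rep(sample(2:3, n_cas, replace = TRUE,
                            prob = c(0.7, 0.3)), each = 2)
  }
  data.frame(
    size = size,
    age_my = round(draw_age(n), 3),
    intervening = ifelse(is.na(cassette_pair),
                         sample(0:5, n, replace = TRUE,
                                prob = c(0.6, 0.15, 0.08, 0.07, 0.06, 0.04)),
                         0L),
    cassette_pair = cassette_pair,
    single_exon = runif(n) < config$single_exon_fraction
  )
}

#' Simulate two related genotypes with planted tandem duplicates
#'
#' Builds in-memory genome bundles for two genotypes (A and B) plus a truth
#' ledger. Duplicate copies descend from a common ancestral CDS by
#' independent Jukes-Cantor substitution so the expected pairwise divergence
#' of a cluster planted at age `t` is `2 * substitution_rate * t`
#' substitutions/site. Each planted cluster also gets an outgroup CDS that
#' diverged from the cluster's ancestor `calibration_my` ago, for clock
#' calibration. Shared clusters appear in both genotypes with homology-
#' linked gene ids; background genes are shared 1:1. Background TEs are
#' placed strictly intergenically; gene-overlapping TE configurations are
#' planted separately (see [plant_te_configurations()]) and tagged in the
#' truth ledger. All randomness derives from `config$seed`: the same seed
#' reproduces identical bundles.
#'
#' @param config A `sim_config`.
#' @param te_placements Optional TE configuration request forwarded to
#'   [plant_te_configurations()]; `NULL` plants a default set spanning every
#'   class/relation/gene-group combination.
#' @return list with `genotype_a`, `genotype_b` (each a `genome_bundle`:
#'   `gene_set`, `tes`, `blocks`, `outgroup_cds`, `outgroup_map`,
#'   `genotype`), `homology`, and `truth` (ledger with `$clusters`,
#'   `$genes`, `$te_placements`).
#' @export
simulate_genotypes <- function(config, te_placements = NULL) {
  stopifnot(is(config, "sim_config"))
  set.seed(config$seed)
  plan <- config$planted_clusters %||% default_planted_plan(config)
  n_clu <- nrow(plan)
  plan$truth_id <- sprintf("PC%03d", seq_len(n_clu))
  # presence: shared first, then alternate private A / private B
  n_shared <- round(config$shared_fraction * n_clu)
  presence <- rep(c("A", "B"), length.out = n_clu)
  presence[sample(n_clu, n_shared)] <- "both"
  # cassette pairs must co-occur: force partner presence to match
  if (any(!is.na(plan$cassette_pair))) {
    for (cp in unique(stats::na.omit(plan$cassette_pair))) {
      idx <- which(plan$cassette_pair == cp)
      presence[idx] <- presence[idx[1]]
    }
  }
  plan$presence <- presence

  # sequences: ancestor -> maize parent -> copies; outgroup from ancestor
  r <- config$substitution_rate
  cal <- config$calibration_my
  n_codons <- sample(seq(config$cds_codon_range[1],
                         config$cds_codon_range[2]),
                     n_clu, replace = TRUE)
  cluster_seqs <- vector("list", n_clu)
  outgroup_seqs <- character(n_clu)
  for (i in seq_len(n_clu)) {
    anc <- random_cds(n_codons[i])
    t_dup <- min(plan$age_my[i], cal)
    parent <- mutate_jc(anc, r * (cal - t_dup))
    cluster_seqs[[i]] <- vapply(seq_len(plan$size[i]), function(k) {
      mutate_jc(parent, r * t_dup)
    }, character(1))
    outgroup_seqs[i] <- mutate_jc(anc, r * cal)
  }
  names(outgroup_seqs) <- paste0("OG_", plan$truth_id)

  # background gene sequences, shared between genotypes
  bg_n <- config$n_background_genes
  bg_codons <- sample(seq(config$cds_codon_range[1],
                          config$cds_codon_range[2]), bg_n, replace = TRUE)
  bg_seqs <- vapply(bg_codons, random_cds, character(1))
  bg_exons <- sample(2:10, bg_n, replace = TRUE)

  blocks <- default_subgenome_blocks(config)

  bundle_a <- layout_genotype("A", config, plan, cluster_seqs, bg_seqs,
                              bg_exons, outgroup_seqs, blocks)
  bundle_b <- layout_genotype("B", config, plan, cluster_seqs, bg_seqs,
                              bg_exons, outgroup_seqs, blocks)

  homology <- build_homology(bundle_a, bundle_b)

  truth_clusters <- rbind(truth_rows(bundle_a, plan),
                          truth_rows(bundle_b, plan))
  truth <- list(clusters = truth_clusters,
                genes = rbind(bundle_a$gene_truth, bundle_b$gene_truth),
                te_placements = data.frame(
                  genotype = character(), te_id = character(),
                  gene_id = character(), te_class = character(),
                  config = character(), stringsAsFactors = FALSE))
  bundle_a$gene_truth <- NULL
  bundle_b$gene_truth <- NULL

  res <- list(genotype_a = bundle_a, genotype_b = bundle_b,
              homology = homology, truth = truth)
  placed <- plant_te_configurations(res$genotype_a, res$truth, te_placements)
  res$genotype_a <- placed$bundle
  res$truth <- placed$truth
  placed <- plant_te_configurations(res$genotype_b, res$truth, te_placements)
  res$genotype_b <- placed$bundle
  res$truth <- placed$truth
  res
}

#' @noRd
default_subgenome_blocks <- function(config) {
  do.call(rbind, lapply(seq_len(config$n_chromosomes), function(ci) {
    len <- config$chromosome_length
    cuts <- round(len * c(0.38, 0.62))
    labs <- if (ci %% 2 == 1) c("maize1", "maize2", "nonsyntenic") else
      c("maize2", "nonsyntenic", "maize1")
    data.frame(chrom = paste0("chr", ci),
               start = c(1, cuts[1] + 1, cuts[2] + 1),
               end = c(cuts[1], cuts[2], len),
               label = labs, stringsAsFactors = FALSE)
  }))
}

# Lay one genotype out along its chromosomes. Returns a genome_bundle plus
# a per-gene truth table (gene_id, truth_id or NA, copy index).
#' @noRd
layout_genotype <- function(genotype, config, plan, cluster_seqs, bg_seqs,
                            bg_exons, outgroup_seqs, blocks) {
  present <- which(plan$presence %in% c("both", genotype))
  bg_n <- length(bg_seqs)

  # assemble layout units: cassette pairs (interleaved), single clusters,
  # single background genes
  units <- list()
  used_cas <- character()
  for (i in present) {
    cp <- plan$cassette_pair[i]
    if (!is.na(cp)) {
      key <- as.character(cp)
      if (key %in% used_cas) next
      used_cas <- c(used_cas, key)
      pair <- intersect(which(plan$cassette_pair == cp), present)
      units[[length(units) + 1]] <- list(type = "cassette", members = pair)
    } else {
      units[[length(units) + 1]] <- list(type = "cluster", members = i)
    }
  }
  n_cluster_units <- length(units)
  for (b in seq_len(bg_n)) {
    units[[length(units) + 1]] <- list(type = "background", members = b)
  }
  # intervening genes are drawn from the background pool at layout time;
  # keep a queue of background unit indices to consume
  unit_order <- sample(length(units))

  genes <- list(); tx <- list(); cds <- list(); gene_truth <- list()
  gid <- 0
  consumed_bg <- logical(bg_n)

  emit_gene <- function(chrom, pos, cds_seq, exon_count, truth_id, copy,
                        is_bg, bg_index) {
    gid <<- gid + 1
    gene_id <- sprintf("G%s%04d", genotype, gid)
    span <- nchar(cds_seq) + sample(200:1500, 1)  # UTR/intron margin
    genes[[length(genes) + 1]] <<- data.frame(
      gene_id = gene_id, chrom = chrom, start = pos, end = pos + span - 1,
      strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
    tx_id <- paste0(gene_id, "_T01")
    tx[[length(tx) + 1]] <<- data.frame(
      tx_id = tx_id, gene_id = gene_id, exon_count = exon_count,
      cds_len = nchar(cds_seq), stringsAsFactors = FALSE)
    cds[[tx_id]] <<- cds_seq
    gene_truth[[length(gene_truth) + 1]] <<- data.frame(
      genotype = genotype, gene_id = gene_id,
      truth_id = truth_id, copy = copy,
      bg_index = if (is_bg) bg_index else NA_integer_,
      stringsAsFactors = FALSE)
    pos + span - 1
  }

  next_bg <- function() {
    free <- which(!consumed_bg)
    if (length(free) == 0) return(NA_integer_)
    pick <- free[1]
    consumed_bg[pick] <<- TRUE
    pick
  }

  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  chrom_of_unit <- sample(rep(chroms, length.out = length(units)))
  pos_by_chrom <- setNames(rep(1, length(chroms)), chroms)
  # intergenic gaps sized per chromosome so its genes spread over ~80% of
  # its length rather than packing at the head
  unit_genes <- vapply(units, function(u) {
    as.numeric(switch(u$type,
                      background = 1,
                      cluster = plan$size[u$members] +
                        plan$intervening[u$members],
                      cassette = sum(plan$size[u$members])))
  }, numeric(1))
  est_gene_bp <- 1500 + 3 * mean(seq(config$cds_codon_range[1],
                                     config$cds_codon_range[2]))
  genes_by_chrom <- vapply(chroms, function(ch) {
    sum(unit_genes[chrom_of_unit == ch])
  }, numeric(1))
  mean_gap_by_chrom <- setNames(
    pmax(2000, (0.80 * config$chromosome_length -
                  genes_by_chrom * est_gene_bp) / (genes_by_chrom + 1)),
    chroms)
  gap_for <- function(ch) {
    m <- mean_gap_by_chrom[[ch]]
    sample(round(0.5 * m):round(1.5 * m), 1)
  }

  cluster_exons <- function(i, k) {
    if (plan$single_exon[i]) 1L else sample(2:10, 1)
  }

  for (u in unit_order) {
    unit <- units[[u]]
    ch <- chrom_of_unit[u]
    end <- pos_by_chrom[[ch]]
    if (unit$type == "background") {
      b <- unit$members
      if (consumed_bg[b]) next
      consumed_bg[b] <- TRUE
      end <- emit_gene(ch, end + gap_for(ch), bg_seqs[b], bg_exons[b],
                       NA_character_, NA_integer_, TRUE, b)
    } else if (unit$type == "cluster") {
      i <- unit$members
      seqs <- cluster_seqs[[i]]
      for (k in seq_along(seqs)) {
        end <- emit_gene(ch, end + gap_for(ch), seqs[k], cluster_exons(i, k),
                         plan$truth_id[i], k, FALSE, NA_integer_)
        if (k == 1 && plan$intervening[i] > 0) {
          for (z in seq_len(plan$intervening[i])) {
            b <- next_bg()
            if (is.na(b)) break
            end <- emit_gene(ch, end + gap_for(ch), bg_seqs[b], bg_exons[b],
                             NA_character_, NA_integer_, TRUE, b)
          }
        }
      }
    } else {  # cassette: alternate copies of the two member clusters
      ii <- unit$members
      if (length(ii) == 1) {
        # partner absent from this genotype: lay out as plain cluster
        i <- ii
        seqs <- cluster_seqs[[i]]
        for (k in seq_along(seqs)) {
          end <- emit_gene(ch, end + gap_for(ch), seqs[k], cluster_exons(i, k),
                           plan$truth_id[i], k, FALSE, NA_integer_)
        }
      } else {
        s1 <- cluster_seqs[[ii[1]]]; s2 <- cluster_seqs[[ii[2]]]
        for (k in seq_len(max(length(s1), length(s2)))) {
          if (k <= length(s1)) {
            end <- emit_gene(ch, end + gap_for(ch), s1[k],
                             cluster_exons(ii[1], k),
                             plan$truth_id[ii[1]], k, FALSE, NA_integer_)
          }
          if (k <= length(s2)) {
            end <- emit_gene(ch, end + gap_for(ch), s2[k],
                             cluster_exons(ii[2], k),
                             plan$truth_id[ii[2]], k, FALSE, NA_integer_)
          }
        }
      }
    }
    if (end > config$chromosome_length) {
      stop("infeasible packing: genes exceed chromosome length on ", ch)
    }
    pos_by_chrom[[ch]] <- end
  }

  genes <- do.call(rbind, genes)
  tx <- do.call(rbind, tx)
  gene_truth <- do.call(rbind, gene_truth)
  gs <- as_gene_set(genes, tx, DNAStringSet(unlist(cds)))

  tes <- background_tes(config, genes)

  present_ids <- plan$truth_id[present]
  og_names <- if (length(present_ids) > 0) paste0("OG_", present_ids) else
    character(0)  # paste0 would recycle zero-length to "OG_"
  structure(list(
    genotype = genotype,
    gene_set = gs,
    tes = tes,
    blocks = blocks,
    outgroup_cds = DNAStringSet(outgroup_seqs[og_names]),
    outgroup_map = setNames(og_names, present_ids),
    gene_truth = gene_truth
  ), class = "genome_bundle")
}

#' @export
print.genome_bundle <- function(x, ...) {
  cat("genome_bundle (genotype ", x$genotype, "): ",
      nrow(x$gene_set$genes), " genes, ", nrow(x$tes), " TEs\n", sep = "")
  invisible(x)
}

# Background TEs: random intergenic intervals per class up to the target
# density; strictly gene-free so planted TE configurations stay the only
# gene-overlapping ones.
#' @noRd
background_tes <- function(config, genes) {
  te_len <- c(LTR = 8000, LINE = 3000, SINE = 300, TIR = 1500)
  chrom <- character(); start <- integer(); te_class <- character()
  for (ci in seq_len(config$n_chromosomes)) {
    ch <- paste0("chr", ci)
    gch <- genes[genes$chrom == ch, , drop = FALSE]
    occupied <- IRanges::reduce(IRanges::IRanges(gch$start, gch$end))
    free <- IRanges::setdiff(IRanges::IRanges(1, config$chromosome_length),
                             occupied + 100L)
    free <- free[IRanges::width(free) > 2 * max(te_len)]
    if (length(free) == 0) next
    fs <- IRanges::start(free)
    fw <- IRanges::width(free)
    for (cl in names(config$te_density_per_class)) {
      len <- te_len[[cl]]
      n_te <- ceiling(config$te_density_per_class[[cl]] *
                        config$chromosome_length / len)
      if (n_te == 0) next
      seg <- sample(length(free), n_te, replace = TRUE, prob = fw)
      off <- floor(runif(n_te) * (fw[seg] - len))
      chrom <- c(chrom, rep(ch, n_te))
      start <- c(start, as.integer(fs[seg] + off))
      te_class <- c(te_class, rep(cl, n_te))
    }
  }
  if (length(chrom) == 0) {
    return(data.frame(te_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      te_class = character(), stringsAsFactors = FALSE))
  }
  data.frame(te_id = sprintf("TE%05d", seq_along(chrom)), chrom = chrom,
             start = start,
             end = start + as.integer(te_len[te_class]) - 1L,
             te_class = te_class, stringsAsFactors = FALSE)
}

#' @noRd
build_homology <- function(bundle_a, bundle_b) {
  ta <- bundle_a$gene_truth
  tb <- bundle_b$gene_truth
  # background genes: matched by shared background index
  bg <- merge(ta[!is.na(ta$bg_index), c("gene_id", "bg_index")],
              tb[!is.na(tb$bg_index), c("gene_id", "bg_index")],
              by = "bg_index", suffixes = c("_a", "_b"))
  # planted genes: matched by (truth cluster, copy index)
  pl <- merge(ta[!is.na(ta$truth_id), c("gene_id", "truth_id", "copy")],
              tb[!is.na(tb$truth_id), c("gene_id", "truth_id", "copy")],
              by = c("truth_id", "copy"), suffixes = c("_a", "_b"))
  out <- rbind(
    data.frame(gene_a = bg$gene_id_a, gene_b = bg$gene_id_b,
               stringsAsFactors = FALSE),
    data.frame(gene_a = pl$gene_id_a, gene_b = pl$gene_id_b,
               stringsAsFactors = FALSE))
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @noRd
truth_rows <- function(bundle, plan) {
  gt <- bundle$gene_truth
  gt <- gt[!is.na(gt$truth_id), , drop = FALSE]
  do.call(rbind, lapply(split(gt, gt$truth_id), function(d) {
    i <- match(d$truth_id[1], plan$truth_id)
    g <- bundle$gene_set$genes
    chrom <- g$chrom[match(d$gene_id[1], g$gene_id)]
    data.frame(
      genotype = bundle$genotype, truth_id = d$truth_id[1],
      chrom = chrom, size = nrow(d),
      gene_ids = paste(sort(d$gene_id), collapse = ","),
      age_my = plan$age_my[i], intervening = plan$intervening[i],
      cassette_pair = plan$cassette_pair[i],
      single_exon = plan$single_exon[i],
      shared = plan$presence[i] == "both",
      stringsAsFactors = FALSE)
  }))
}

#' Plant TE configurations over genes
#'
#' Adds TE features in controlled relationships to genes: `contains` (TE
#' strictly inside a gene), `captured` (gene strictly inside a TE), and
#' `partial` (TE overlapping half the gene and extending into intergenic
#' space). Each placement targets a distinct gene and is recorded in the
#' truth ledger. The default request plants, for every TE class, two
#' `contains`, two `captured` and one `partial` case on tandem genes and
#' the same on background genes (as far as distinct genes are available).
#'
#' @param bundle A `genome_bundle`.
#' @param truth The truth ledger to extend.
#' @param request Optional data.frame with columns `te_class`, `config`
#'   (`contains`/`captured`/`partial`), `gene_group` (`tandem`/
#'   `background`), `n`.
#' @return list with updated `bundle` and `truth`.
#' @export
plant_te_configurations <- function(bundle, truth, request = NULL) {
  if (is.null(request)) {
    request <- expand.grid(te_class = TE_CLASSES,
                           config = c("contains", "captured", "partial"),
                           gene_group = c("tandem", "background"),
                           stringsAsFactors = FALSE)
    request$n <- ifelse(request$config == "partial", 1L, 2L)
  }
  g <- bundle$gene_set$genes
  planted_ids <- truth$clusters$gene_ids[truth$clusters$genotype ==
                                           bundle$genotype]
  tandem_ids <- unlist(strsplit(planted_ids, ","))
  pool <- list(tandem = g[g$gene_id %in% tandem_ids, , drop = FALSE],
               background = g[!(g$gene_id %in% tandem_ids), , drop = FALSE])
  used <- character()
  tid <- nrow(bundle$tes)
  new_tes <- list(); new_truth <- list()
  for (i in seq_len(nrow(request))) {
    cand <- pool[[request$gene_group[i]]]
    cand <- cand[!(cand$gene_id %in% used), , drop = FALSE]
    n_take <- min(request$n[i], nrow(cand))
    if (n_take == 0) next
    take <- cand[sample(nrow(cand), n_take), , drop = FALSE]
    used <- c(used, take$gene_id)
    for (k in seq_len(n_take)) {
      gk <- take[k, ]
      len <- gk$end - gk$start + 1
      cfg <- request$config[i]
      if (cfg == "contains") {
        s <- gk$start + max(1, len %/% 4)
        e <- s + max(10, len %/% 4)
      } else if (cfg == "captured") {
        s <- gk$start - 400
        e <- gk$end + 400
      } else {  # partial: cover the downstream half plus margin
        s <- gk$start + len %/% 2
        e <- gk$end + 800
      }
      tid <- tid + 1
      new_tes[[length(new_tes) + 1]] <- data.frame(
        te_id = sprintf("TEP%04d_%s", tid, bundle$genotype),
        chrom = gk$chrom, start = as.integer(max(1, s)),
        end = as.integer(e), te_class = request$te_class[i],
        stringsAsFactors = FALSE)
      new_truth[[length(new_truth) + 1]] <- data.frame(
        genotype = bundle$genotype,
        te_id = sprintf("TEP%04d_%s", tid, bundle$genotype),
        gene_id = gk$gene_id, te_class = request$te_class[i],
        config = cfg, stringsAsFactors = FALSE)
    }
  }
  if (length(new_tes) > 0) {
    bundle$tes <- rbind(bundle$tes, do.call(rbind, new_tes))
    truth$te_placements <- rbind(truth$te_placements,
                                 do.call(rbind, new_truth))
  }
  list(bundle = bundle, truth = truth)
}

#' Match detected clusters to planted truth
#'
#' @param clusters Detected `tandem_clusters`.
#' @param truth Truth ledger from [simulate_genotypes()].
#' @param genotype `"A"` or `"B"`.
#' @return data.frame with one row per planted cluster of that genotype:
#'   `truth_id`, `cluster_id` (detected cluster holding its genes, or
#'   `NA`), `exact` (membership recovered exactly).
#' @export
match_clusters_to_truth <- function(clusters, truth, genotype) {
  tc <- truth$clusters[truth$clusters$genotype == genotype, , drop = FALSE]
  m <- clusters$members
  do.call(rbind, lapply(seq_len(nrow(tc)), function(i) {
    planted <- sort(strsplit(tc$gene_ids[i], ",")[[1]])
    hit <- unique(m$cluster_id[m$gene_id %in% planted])
    if (length(hit) == 1) {
      detected <- sort(m$gene_id[m$cluster_id == hit])
      data.frame(truth_id = tc$truth_id[i], cluster_id = hit,
                 exact = identical(detected, planted),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(truth_id = tc$truth_id[i], cluster_id = NA_character_,
                 exact = FALSE, stringsAsFactors = FALSE)
    }
  }))
}

#' Write a genome bundle to standard files
#'
#' Emits `genes.gff3`, `cds.fa`, `tes.gff3`, `blocks.bed` (0-based
#' half-open), and `outgroup.fa` under `dir`.
#'
#' @param bundle A `genome_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_genome_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- bundle$gene_set$genes
  tx <- bundle$gene_set$transcripts
  lines <- c("##gff-version 3")
  for (i in order(g$chrom, g$start, g$end, g$gene_id)) {
    lines <- c(lines, paste(g$chrom[i], "sim", "gene", g$start[i], g$end[i],
                            ".", g$strand[i], ".",
                            paste0("ID=", g$gene_id[i]), sep = "\t"))
    txi <- tx[tx$gene_id == g$gene_id[i], , drop = FALSE]
    for (j in seq_len(nrow(txi))) {
      lines <- c(lines,
                 paste(g$chrom[i], "sim", "mRNA", g$start[i], g$end[i], ".",
                       g$strand[i], ".",
                       paste0("ID=", txi$tx_id[j], ";Parent=", g$gene_id[i]),
                       sep = "\t"))
      # exon_count CDS segments; internal structure is metadata only, so
      # segments partition the CDS length across the gene span
      n_ex <- txi$exon_count[j]
      len <- txi$cds_len[j]
      bnd <- floor(seq(0, len, length.out = n_ex + 1))
      off <- floor(seq(g$start[i], g$end[i] - 2, length.out = n_ex + 1))
      for (e in seq_len(n_ex)) {
        w <- bnd[e + 1] - bnd[e]
        if (w <= 0) next
        lines <- c(lines,
                   paste(g$chrom[i], "sim", "CDS", off[e],
                         off[e] + w - 1, ".", g$strand[i], "0",
                         paste0("ID=cds_", txi$tx_id[j], ";Parent=",
                                txi$tx_id[j]),
                         sep = "\t"))
      }
    }
  }
  writeLines(lines, file.path(dir, "genes.gff3"))
  writeXStringSet(bundle$gene_set$cds, file.path(dir, "cds.fa"))
  te <- bundle$tes
  type_of <- c(LTR = "LTR_retrotransposon", LINE = "LINE_element",
               SINE = "SINE_element",
               TIR = "terminal_inverted_repeat_element")
  te_lines <- c("##gff-version 3",
                paste(te$chrom, "sim", type_of[te$te_class], te$start,
                      te$end, ".", "+", ".", paste0("ID=", te$te_id),
                      sep = "\t"))
  writeLines(te_lines, file.path(dir, "tes.gff3"))
  b <- bundle$blocks
  writeLines(paste(b$chrom, b$start - 1L, b$end, b$label, sep = "\t"),
             file.path(dir, "blocks.bed"))
  writeXStringSet(bundle$outgroup_cds, file.path(dir, "outgroup.fa"))
  invisible(dir)
}
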