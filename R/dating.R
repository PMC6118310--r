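# Duplication age estimation: TMRCA extraction from dated trees, molecular
# clock calibration of pairwise distances against the maize/Sorghum
# outgroup divergence, cross-genotype event deduplication, age classes, and
# GC content.

#' @noRd
AGE_ANCIENT_MY <- 10
#' @noRd
AGE_RECENT_MY <- 2

#' Subgenome divergence prior
#'
#' The normal prior (mean 11.9 MY, sd 1) conventionally placed on the
#' divergence date of the two maize subgenomes when trees are dated by
#' MCMC. Recorded here as metadata for provenance; this package performs
#' no MCMC and uses the fixed 12-MY outgroup calibration instead.
#'
#' @format Named numeric vector with elements `mean` and `sd` (MY).
#' @export
subgenome_divergence_prior <- c(mean = 11.9, sd = 1)

#' Classify a duplication age
#'
#' Ancient at or above 10 MY, recent at or below 2 MY, intermediate
#' otherwise.
#'
#' @param tmrca_my Numeric vector of ages in MY.
#' @return Character vector in `{ancient, recent, intermediate}`.
#' @export
age_class <- function(tmrca_my) {
  ifelse(tmrca_my >= AGE_ANCIENT_MY, "ancient",
         ifelse(tmrca_my <= AGE_RECENT_MY, "recent", "intermediate"))
}

#' TMRCA of two tips in a dated tree
#'
#' Reads the age (in MY) of the most recent common ancestor of two tips in
#' an ultrametric, time-calibrated tree (node heights are ages; tips sit at
#' age 0).
#'
#' @param tree An [ape::phylo] tree with ages as branch lengths (ultrametric).
#' @param tip_a,tip_b Tip labels.
#' @return Age of the MRCA node in MY.
#' @export
tmrca_from_dated_tree <- function(tree, tip_a, tip_b) {
  miss <- setdiff(c(tip_a, tip_b), tree$tip.label)
  if (length(miss) > 0) stop("tip(s) not in tree: ",
                             paste(miss, collapse = ", "))
  depths <- ape::node.depth.edgelength(tree)  # distance from root
  ages <- max(depths[seq_along(tree$tip.label)]) - depths
  node <- ape::getMRCA(tree, c(tip_a, tip_b))
  unname(ages[node])
}

#' Molecular-clock age from calibrated distances
#'
#' Converts a pairwise substitution distance into an age by scaling against
#' the distance to the outgroup, itself pinned to the maize/Sorghum
#' divergence: `age = calibration_my * d_pair / d_outgroup`, clamped to be
#' nonnegative. Scale-invariant in the distances.
#'
#' @param d_pair Substitutions/site between the duplicate copies.
#' @param d_outgroup Substitutions/site between a copy and the outgroup
#'   (must be > 0).
#' @param calibration_my Outgroup divergence in MY (default 12).
#' @return Estimated age in MY.
#' @export
clock_calibrated_age <- function(d_pair, d_outgroup, calibration_my = 12) {
  if (any(d_outgroup <= 0)) stop("outgroup distance must be positive")
  pmax(0, calibration_my * d_pair / d_outgroup)
}

#' Jukes-Cantor distance between two aligned coding sequences
#'
#' Proportion of differing sites over ungapped, unambiguous columns,
#' corrected for multiple hits: `d = -3/4 log(1 - 4p/3)`. Saturated inputs
#' (`p >= 3/4`) return `Inf`.
#'
#' @param a,b Equal-length aligned nucleotide strings (gaps `-` allowed).
#' @return Estimated substitutions per site.
#' @export
jc_distance <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  if (length(ca) != length(cb)) stop("aligned sequences differ in length")
  ok <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  n <- sum(ok)
  if (n == 0) stop("no comparable sites")
  p <- sum(ca[ok] != cb[ok]) / n
  if (p >= 0.75) return(Inf)
  -0.75 * log(1 - 4 * p / 3)
}

#' Clock-calibrate ages for tandem clusters against planted outgroups
#'
#' For each cluster, aligns member coding sequences codon-wise (they must be
#' in frame), computes the mean pairwise Jukes-Cantor distance among members
#' (`d_pair`) and the mean member-to-outgroup distance (`d_outgroup`), and
#' applies [clock_calibrated_age()]. Members whose CDS lengths differ are
#' aligned at the protein level first and back-translated.
#'
#' @param gene_set A `gene_set` that also carries outgroup CDS records in
#'   `$cds`.
#' @param clusters A `tandem_clusters` object.
#' @param outgroup_map Named character vector: cluster_id -> outgroup CDS id
#'   present in `gene_set$cds`.
#' @param calibration_my Calibration in MY (default 12).
#' @return data.frame: `cluster_id`, `d_pair`, `d_outgroup`, `tmrca_my`,
#'   `age_class`.
#' @export
cluster_clock_ages <- function(gene_set, clusters, outgroup_map,
                               calibration_my = 12) {
  m <- clusters$members
  ids <- unique(m$cluster_id)
  rows <- lapply(ids, function(cid) {
    og_id <- outgroup_map[[cid]]
    if (is.null(og_id) || is.na(og_id)) return(NULL)
    genes <- m$gene_id[m$cluster_id == cid]
    seqs <- vapply(genes, function(g) {
      longest_transcript_protein(gene_set, g)$cds
    }, character(1))
    seqs <- seqs[!is.na(seqs)]
    if (length(seqs) < 2) return(NULL)
    og <- as.character(gene_set$cds[[og_id]])
    d_pair <- mean(apply(utils::combn(length(seqs), 2), 2, function(ij) {
      aligned_jc(seqs[ij[1]], seqs[ij[2]])
    }))
    d_out <- mean(vapply(seqs, function(s) aligned_jc(s, og), numeric(1)))
    data.frame(cluster_id = cid, d_pair = d_pair, d_outgroup = d_out,
               tmrca_my = clock_calibrated_age(d_pair, d_out, calibration_my),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(cluster_id = character(), d_pair = numeric(),
                      d_outgroup = numeric(), tmrca_my = numeric(),
                      stringsAsFactors = FALSE)
  }
  out$age_class <- age_class(out$tmrca_my)
  rownames(out) <- NULL
  out
}

# JC distance of two in-frame CDS; codon alignment via protein alignment
# when lengths differ, direct pairing otherwise.
#' @noRd
aligned_jc <- function(cds_a, cds_b) {
  if (nchar(cds_a) == nchar(cds_b)) return(jc_distance(cds_a, cds_b))
  pa <- translate_cds(cds_a)
  pb <- translate_cds(cds_b)
  aln <- align_pair(pa$protein, pb$protein)
  bt <- back_translate(aln, pa$cds, pb$cds)
  jc_distance(paste(bt$codon_a, collapse = ""),
              paste(bt$codon_b, collapse = ""))
}

#' Deduplicate duplication events across two genotypes
#'
#' Homologous clusters that are duplicated in both genotypes (each has at
#' least two members — copy-number differences do not break sharing) are one
#' shared event whose TMRCA is the mean of the two genotype estimates.
#' Clusters with no duplicated homologous partner are private events. The
#' operation is idempotent: deduplicating its own output changes nothing.
#'
#' @param clusters_a,clusters_b `tandem_clusters` for genotypes A and B.
#' @param ages_a,ages_b Age tables from [cluster_clock_ages()] (or any
#'   data.frame with `cluster_id`, `tmrca_my`); may be `NULL` for undated
#'   events.
#' @param homology Homology map ([read_homology()]).
#' @return data.frame of events: `event_id`, `cluster_a`, `cluster_b`,
#'   `shared`, `tmrca_my`, `age_class`, `subgenome`.
#' @export
deduplicate_events <- function(clusters_a, clusters_b, homology,
                               ages_a = NULL, ages_b = NULL) {
  links <- link_clusters(clusters_a, clusters_b, homology)$links
  age_of <- function(ages, cid) {
    if (is.null(ages)) return(NA_real_)
    i <- match(cid, ages$cluster_id)
    if (is.na(i)) NA_real_ else ages$tmrca_my[i]
  }
  sub_of <- function(clusters, cid) {
    m <- clusters$members
    m$subgenome[match(cid, m$cluster_id)]
  }
  shared_a <- unique(links$cluster_a)
  shared_b <- unique(links$cluster_b)
  rows <- list()
  for (i in seq_len(nrow(links))) {
    ca <- links$cluster_a[i]; cb <- links$cluster_b[i]
    tm <- mean(c(age_of(ages_a, ca), age_of(ages_b, cb)), na.rm = TRUE)
    rows[[length(rows) + 1]] <- data.frame(
      cluster_a = ca, cluster_b = cb, shared = TRUE,
      tmrca_my = if (is.nan(tm)) NA_real_ else tm,
      subgenome = sub_of(clusters_a, ca), stringsAsFactors = FALSE)
  }
  for (ca in setdiff(cluster_ids(clusters_a), shared_a)) {
    rows[[length(rows) + 1]] <- data.frame(
      cluster_a = ca, cluster_b = NA_character_, shared = FALSE,
      tmrca_my = age_of(ages_a, ca), subgenome = sub_of(clusters_a, ca),
      stringsAsFactors = FALSE)
  }
  for (cb in setdiff(cluster_ids(clusters_b), shared_b)) {
    rows[[length(rows) + 1]] <- data.frame(
      cluster_a = NA_character_, cluster_b = cb, shared = FALSE,
      tmrca_my = age_of(ages_b, cb), subgenome = sub_of(clusters_b, cb),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(event_id = character(), cluster_a = character(),
                      cluster_b = character(), shared = logical(),
                      tmrca_my = numeric(), age_class = character(),
                      subgenome = character(), stringsAsFactors = FALSE))
  }
  ev <- do.call(rbind, rows)
  ev <- ev[order(!ev$shared, ev$cluster_a, ev$cluster_b, na.last = TRUE), ,
           drop = FALSE]
  ev$event_id <- sprintf("EVT%04d", seq_len(nrow(ev)))
  ev$age_class <- ifelse(is.na(ev$tmrca_my), NA_character_,
                         age_class(ev$tmrca_my))
  rownames(ev) <- NULL
  ev[c("event_id", "cluster_a", "cluster_b", "shared", "tmrca_my",
       "age_class", "subgenome")]
}

#' GC content of a nucleotide sequence
#'
#' `(G + C) / (A + C + G + T)`; `N` and other ambiguity codes are excluded
#' from the denominator. A sequence with no unambiguous base returns `NA`.
#'
#' @param sequence Nucleotide string (or vector of strings).
#' @return Numeric fraction(s) in `[0, 1]`, `NA` where undefined.
#' @export
gc_content <- function(sequence) {
  vapply(sequence, function(s) {
    if (!nzchar(s)) stop("empty sequence")
    ch <- strsplit(toupper(s), "")[[1]]
    n <- sum(ch %in% c("A", "C", "G", "T"))
    if (n == 0) return(NA_real_)
    sum(ch %in% c("G", "C")) / n
  }, numeric(1), USE.NAMES = FALSE)
}

#' Binned age distribution and cross-tabulated event counts
#'
#' @param events Event table from [deduplicate_events()] (dated rows only
#'   are binned).
#' @param bin_width Histogram bin width in MY (default 1).
#' @return list with `histogram` (data.frame `bin_start`, `bin_end`,
#'   `count`) and `counts` (data.frame by shared status, subgenome and age
#'   class).
#' @export
age_distribution <- function(events, bin_width = 1) {
  ages <- events$tmrca_my[!is.na(events$tmrca_my)]
  if (length(ages) == 0) {
    hist_df <- data.frame(bin_start = numeric(), bin_end = numeric(),
                          count = integer())
  } else {
    top <- ceiling(max(ages) / bin_width) * bin_width
    breaks <- seq(0, max(top, bin_width), by = bin_width)
    cnt <- table(cut(ages, breaks = breaks, include.lowest = TRUE,
                     right = FALSE))
    hist_df <- data.frame(bin_start = breaks[-length(breaks)],
                          bin_end = breaks[-1],
                          count = as.integer(cnt))
  }
  dated <- events[!is.na(events$tmrca_my), , drop = FALSE]
  if (nrow(dated) > 0) {
    counts <- as.data.frame(table(
      shared = ifelse(dated$shared, "shared", "private"),
      subgenome = dated$subgenome,
      age_class = dated$age_class), stringsAsFactors = FALSE)
    names(counts)[4] <- "n"
  } else {
    counts <- data.frame(shared = character(), subgenome = character(),
                         age_class = character(), n = integer())
  }
  list(histogram = hist_df, counts = counts)
}
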