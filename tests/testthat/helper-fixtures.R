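# Fixtures built in code: toy gene sets, cluster objects from coordinate
# layouts, and independent oracles used across test files.

# Build a gene_set from a compact spec: data.frame with gene_id, chrom,
# start, end, and optional strand, cds, exon_count.
toy_gene_set <- function(df) {
  if (is.null(df$strand)) df$strand <- "+"
  if (is.null(df$cds)) df$cds <- "ATGGCTGCTTAA"
  if (is.null(df$exon_count)) df$exon_count <- 2L
  genes <- df[c("gene_id", "chrom", "start", "end", "strand")]
  tx <- data.frame(tx_id = paste0(df$gene_id, "_T1"), gene_id = df$gene_id,
                   exon_count = df$exon_count, cds_len = nchar(df$cds),
                   stringsAsFactors = FALSE)
  cds <- Biostrings::DNAStringSet(setNames(df$cds, tx$tx_id))
  tandemscan:::as_gene_set(genes, tx, cds)
}

# A tandem_clusters object from a list of gene-start vectors (one element
# per cluster), all on one chromosome.
clusters_from_starts <- function(starts_list, chrom = "chr1", width = 2L) {
  if (length(starts_list) == 0) {
    return(tandemscan:::new_tandem_clusters(data.frame(
      cluster_id = character(), gene_id = character(), chrom = character(),
      start = integer(), end = integer(), rank = integer(),
      subgenome = character(), stringsAsFactors = FALSE)))
  }
  members <- do.call(rbind, lapply(seq_along(starts_list), function(i) {
    s <- sort(starts_list[[i]])
    data.frame(cluster_id = sprintf("C%02d", i),
               gene_id = sprintf("C%02d_g%d", i, seq_along(s)),
               chrom = chrom, start = s, end = s + width,
               rank = NA_integer_, subgenome = "nonsyntenic",
               stringsAsFactors = FALSE)
  }))
  tandemscan:::new_tandem_clusters(members)
}

# Independent brute-force cassette classifier: walks the merged, sorted
# label sequence of two clusters' gene starts and applies the definition by
# direct enumeration (nesting excluded first, then two-way alternation).
oracle_interleaved <- function(starts_a, starts_b) {
  pos <- c(starts_a, starts_b)
  lab <- c(rep("A", length(starts_a)), rep("B", length(starts_b)))
  lab <- lab[order(pos)]
  ia <- which(lab == "A")
  ib <- which(lab == "B")
  nested <- (min(ia) > min(ib) && max(ia) < max(ib)) ||
    (min(ib) > min(ia) && max(ib) < max(ia))
  if (nested) return(FALSE)
  any(ib > min(ia) & ib < max(ia)) && any(ia > min(ib) & ia < max(ib))
}

# Brute-force cassette grouping: pairwise oracle + hand-rolled BFS over the
# interleaving relation (independent of igraph).
oracle_cassettes <- function(starts_list) {
  n <- length(starts_list)
  adj <- matrix(FALSE, n, n)
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      adj[i, j] <- adj[j, i] <- oracle_interleaved(starts_list[[i]],
                                                   starts_list[[j]])
    }
  }
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (s in seq_len(n)) {
    if (!is.na(comp[s]) || !any(adj[s, ])) next
    cid <- cid + 1
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp  # NA = not in any cassette
}

# Enumerate every assignment of positions 1..N to clusters with the given
# sizes (all distinct label sequences).
enumerate_arrangements <- function(sizes) {
  n <- sum(sizes)
  out <- list()
  rec <- function(remaining, avail) {
    if (length(remaining) == 0) {
      out[[length(out) + 1]] <<- attr(avail, "assigned")
      return(invisible())
    }
    picks <- utils::combn(avail, remaining[1], simplify = FALSE)
    for (p in picks) {
      left <- setdiff(avail, p)
      assigned <- c(attr(avail, "assigned"), list(p))
      attr(left, "assigned") <- assigned
      rec(remaining[-1], left)
    }
  }
  start <- seq_len(n)
  attr(start, "assigned") <- list()
  rec(sizes, start)
  out
}

# Random 20-letter protein string.
random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, TRUE),
        collapse = "")
}

# Random in-frame CDS (delegates to the generator's internal builder).
random_cds_fixture <- function(n_codons) tandemscan:::random_cds(n_codons)

# Write a small GFF3 + CDS FASTA pair for core_io tests; returns the paths.
write_toy_annotation <- function(dir, genes) {
  gff <- file.path(dir, "genes.gff3")
  fa <- file.path(dir, "cds.fa")
  lines <- "##gff-version 3"
  fa_lines <- character()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    tx_id <- paste0(g$gene_id, "_T1")
    lines <- c(lines,
      paste(g$chrom, "test", "gene", g$start, g$end, ".", "+", ".",
            paste0("ID=", g$gene_id), sep = "\t"),
      paste(g$chrom, "test", "mRNA", g$start, g$end, ".", "+", ".",
            paste0("ID=", tx_id, ";Parent=", g$gene_id), sep = "\t"),
      paste(g$chrom, "test", "CDS", g$start, g$start + nchar(g$cds) - 1,
            ".", "+", "0", paste0("ID=cds1;Parent=", tx_id), sep = "\t"))
    if (!isTRUE(g$skip_fasta)) {
      fa_lines <- c(fa_lines, paste0(">", tx_id), g$cds)
    }
  }
  writeLines(lines, gff)
  writeLines(fa_lines, fa)
  list(gff = gff, fasta = fa)
}
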