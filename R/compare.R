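# Cross-genotype comparison of clusters and cassettes: homology-based
# cluster links, shared/private sets, size-concordance matrix, cassette
# composition differences, and tandem vs non-tandem gene summaries.

#' Link tandem clusters across genotypes by gene homology
#'
#' Two clusters are linked when at least one homologous gene pair connects
#' them; a cluster with at least one link is shared, the rest are private.
#' Sharing is cluster-level, so shared fractions may differ between the two
#' genotypes under many-to-many links.
#'
#' @param clusters_a,clusters_b `tandem_clusters` objects.
#' @param homology Homology map with columns `gene_a`, `gene_b`.
#' @return list with `links` (data.frame `cluster_a`, `cluster_b`,
#'   `n_linked_genes`) and `counts` (data.frame per genotype: `total`,
#'   `shared`, `private`, `shared_fraction`).
#' @export
link_clusters <- function(clusters_a, clusters_b, homology) {
  ma <- clusters_a$members
  mb <- clusters_b$members
  h <- homology[homology$gene_a %in% ma$gene_id &
                  homology$gene_b %in% mb$gene_id, , drop = FALSE]
  if (nrow(h) > 0) {
    h$cluster_a <- ma$cluster_id[match(h$gene_a, ma$gene_id)]
    h$cluster_b <- mb$cluster_id[match(h$gene_b, mb$gene_id)]
    agg <- stats::aggregate(list(n_linked_genes = h$gene_a),
                            by = list(cluster_a = h$cluster_a,
                                      cluster_b = h$cluster_b),
                            FUN = length)
    links <- agg[order(agg$cluster_a, agg$cluster_b), , drop = FALSE]
  } else {
    links <- data.frame(cluster_a = character(), cluster_b = character(),
                        n_linked_genes = integer(), stringsAsFactors = FALSE)
  }
  rownames(links) <- NULL
  tot_a <- length(unique(ma$cluster_id))
  tot_b <- length(unique(mb$cluster_id))
  sh_a <- length(unique(links$cluster_a))
  sh_b <- length(unique(links$cluster_b))
  counts <- data.frame(
    genotype = c("A", "B"),
    total = c(tot_a, tot_b),
    shared = c(sh_a, sh_b),
    private = c(tot_a - sh_a, tot_b - sh_b),
    shared_fraction = c(ifelse(tot_a > 0, sh_a / tot_a, NA_real_),
                        ifelse(tot_b > 0, sh_b / tot_b, NA_real_)),
    stringsAsFactors = FALSE)
  list(links = links, counts = counts)
}

#' Cluster size concordance matrix
#'
#' One increment per cross-genotype cluster link at cell
#' (size in A, size in B); the diagonal holds size-concordant shared
#' clusters.
#'
#' @param links Link table from [link_clusters()].
#' @param clusters_a,clusters_b The linked `tandem_clusters` objects.
#' @return Integer matrix, rows = genotype A cluster sizes, columns =
#'   genotype B cluster sizes.
#' @export
size_concordance <- function(links, clusters_a, clusters_b) {
  sa <- table(clusters_a$members$cluster_id)
  sb <- table(clusters_b$members$cluster_id)
  size_a <- as.integer(sa[links$cluster_a])
  size_b <- as.integer(sb[links$cluster_b])
  max_s <- max(2, size_a, size_b)
  m <- matrix(0L, nrow = max_s, ncol = max_s,
              dimnames = list(size_a = seq_len(max_s),
                              size_b = seq_len(max_s)))
  for (k in seq_along(size_a)) {
    m[size_a[k], size_b[k]] <- m[size_a[k], size_b[k]] + 1L
  }
  m
}

#' Compare cassettes across genotypes
#'
#' A cassette is shared when at least two of its member clusters are linked
#' to clusters of a single cassette in the other genotype. Shared cassettes
#' whose member-cluster sets or member sizes differ are flagged as
#' composition differences (e.g. one genotype lacking a cluster copy of a
#' common cassette).
#'
#' @param cassettes_a,cassettes_b Cassette tables from [detect_cassettes()].
#' @param links Cluster link table from [link_clusters()].
#' @param clusters_a,clusters_b The underlying `tandem_clusters`.
#' @param min_linked_clusters Member-cluster links required for sharing
#'   (default 2).
#' @return data.frame with one row per shared cassette pair: `cassette_a`,
#'   `cassette_b`, `n_linked_clusters`, `composition_differs`; plus
#'   per-genotype shared/private counts in attribute `counts`.
#' @export
compare_cassettes <- function(cassettes_a, cassettes_b, links,
                              clusters_a, clusters_b,
                              min_linked_clusters = 2) {
  empty <- data.frame(cassette_a = character(), cassette_b = character(),
                      n_linked_clusters = integer(),
                      composition_differs = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(cassettes_a) == 0 || nrow(cassettes_b) == 0 || nrow(links) == 0) {
    attr(empty, "counts") <- cassette_share_counts(cassettes_a, cassettes_b,
                                                   empty)
    return(empty)
  }
  l <- links
  l$cassette_a <- cassettes_a$cassette_id[match(l$cluster_a,
                                                cassettes_a$cluster_id)]
  l$cassette_b <- cassettes_b$cassette_id[match(l$cluster_b,
                                                cassettes_b$cluster_id)]
  l <- l[!is.na(l$cassette_a) & !is.na(l$cassette_b), , drop = FALSE]
  rows <- list()
  if (nrow(l) > 0) {
    sa <- table(clusters_a$members$cluster_id)
    sb <- table(clusters_b$members$cluster_id)
    for (key in unique(paste(l$cassette_a, l$cassette_b))) {
      li <- l[paste(l$cassette_a, l$cassette_b) == key, , drop = FALSE]
      n_linked <- length(unique(li$cluster_a))
      if (n_linked < min_linked_clusters) next
      mem_a <- cassettes_a$cluster_id[cassettes_a$cassette_id ==
                                        li$cassette_a[1]]
      mem_b <- cassettes_b$cluster_id[cassettes_b$cassette_id ==
                                        li$cassette_b[1]]
      sizes_a <- sort(as.integer(sa[mem_a]))
      sizes_b <- sort(as.integer(sb[mem_b]))
      differs <- length(mem_a) != length(mem_b) ||
        !identical(sizes_a, sizes_b) ||
        length(unique(li$cluster_a)) < length(mem_a) ||
        length(unique(li$cluster_b)) < length(mem_b)
      rows[[length(rows) + 1]] <- data.frame(
        cassette_a = li$cassette_a[1], cassette_b = li$cassette_b[1],
        n_linked_clusters = n_linked, composition_differs = differs,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else empty
  out <- out[order(out$cassette_a, out$cassette_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "counts") <- cassette_share_counts(cassettes_a, cassettes_b, out)
  out
}

#' @noRd
cassette_share_counts <- function(cassettes_a, cassettes_b, shared) {
  tot_a <- length(unique(cassettes_a$cassette_id))
  tot_b <- length(unique(cassettes_b$cassette_id))
  sh_a <- length(unique(shared$cassette_a))
  sh_b <- length(unique(shared$cassette_b))
  data.frame(genotype = c("A", "B"), total = c(tot_a, tot_b),
             shared = c(sh_a, sh_b),
             private = c(tot_a - sh_a, tot_b - sh_b),
             stringsAsFactors = FALSE)
}

#' Exon-count and gene-length summaries, tandem vs non-tandem
#'
#' Per-gene exon counts (of the longest transcript) and full gene model
#' lengths, split by tandem-duplicate membership, plus per-cluster flags:
#' whether a cluster contains a single-exon gene and whether it mixes
#' single- and multi-exon genes (the signature of duplication through an
#' RNA intermediate).
#'
#' @param gene_set A `gene_set`.
#' @param clusters A `tandem_clusters` object.
#' @return list with `genes` (data.frame `gene_id`, `exon_count`, `length`,
#'   `tandem`) and `cluster_flags` (data.frame `cluster_id`,
#'   `has_single_exon`, `mixed_exon`, `all_multi_exon`).
#' @export
gene_summary_stats <- function(gene_set, clusters) {
  g <- gene_set$genes
  tandem_ids <- clusters$members$gene_id
  genes <- data.frame(
    gene_id = g$gene_id,
    exon_count = g$exon_count,
    length = g$end - g$start + 1L,
    tandem = g$gene_id %in% tandem_ids,
    stringsAsFactors = FALSE)

  m <- clusters$members
  m$exon_count <- g$exon_count[match(m$gene_id, g$gene_id)]
  flags <- do.call(rbind, lapply(split(m, m$cluster_id), function(d) {
    single <- d$exon_count == 1L
    data.frame(cluster_id = d$cluster_id[1],
               has_single_exon = any(single),
               mixed_exon = any(single) && any(!single),
               all_multi_exon = all(!single),
               stringsAsFactors = FALSE)
  }))
  if (is.null(flags)) {
    flags <- data.frame(cluster_id = character(), has_single_exon = logical(),
                        mixed_exon = logical(), all_multi_exon = logical(),
                        stringsAsFactors = FALSE)
  }
  rownames(flags) <- NULL
  list(genes = genes, cluster_flags = flags)
}
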