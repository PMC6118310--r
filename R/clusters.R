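# Tandem duplicate cluster identification: proximal candidate pairs,
# similarity-graph connected components, validation of externally supplied
# candidate clusters, and interleaved cassette detection.

#' @noRd
new_tandem_clusters <- function(members) {
  members <- members[order(members$cluster_id, members$chrom, members$start,
                           members$end, members$gene_id), , drop = FALSE]
  rownames(members) <- NULL
  structure(list(members = members), class = "tandem_clusters")
}

#' @export
print.tandem_clusters <- function(x, ...) {
  cat("tandem_clusters:", length(unique(x$members$cluster_id)),
      "clusters,", nrow(x$members), "genes\n")
  invisible(x)
}

#' Cluster ids of a `tandem_clusters` object
#' @param clusters A `tandem_clusters` object.
#' @return Character vector of cluster ids.
#' @export
cluster_ids <- function(clusters) unique(clusters$members$cluster_id)

#' Per-cluster summary table
#'
#' @param clusters A `tandem_clusters` object.
#' @return data.frame with one row per cluster: `cluster_id`, `chrom`,
#'   `size`, `span_start`, `span_end`, `subgenome`.
#' @export
cluster_summary <- function(clusters) {
  m <- clusters$members
  ids <- unique(m$cluster_id)
  do.call(rbind, lapply(ids, function(cid) {
    mi <- m[m$cluster_id == cid, , drop = FALSE]
    data.frame(cluster_id = cid, chrom = mi$chrom[1], size = nrow(mi),
               span_start = min(mi$start), span_end = max(mi$end),
               subgenome = mi$subgenome[1], stringsAsFactors = FALSE)
  }))
}

#' Candidate tandem duplicate gene pairs
#'
#' All same-chromosome gene pairs separated by at most `max_intervening`
#' intervening genes (rank distance `max_intervening + 1` or less). Each pair
#' is emitted once, lower rank first. Intervening genes are allowed so that
#' duplicates separated by later gene insertions, misannotation, or
#' mechanisms that do not place copies side by side are still considered.
#'
#' @param gene_set A `gene_set`.
#' @param max_intervening Maximum number of genes allowed between the two
#'   members of a pair (default 15).
#' @return data.frame with columns `gene_a`, `gene_b`, `chrom`,
#'   `n_intervening`.
#' @export
candidate_pairs <- function(gene_set, max_intervening = 15) {
  g <- gene_set$genes
  res <- lapply(split(g, g$chrom), function(gc) {
    gc <- gc[order(gc$rank), , drop = FALSE]
    n <- nrow(gc)
    if (n < 2) return(NULL)
    i <- rep(seq_len(n - 1), times = pmin(max_intervening + 1L,
                                          (n - 1):1))
    j <- i + sequence(pmin(max_intervening + 1L, (n - 1):1))
    data.frame(gene_a = gc$gene_id[i], gene_b = gc$gene_id[j],
               chrom = gc$chrom[1], n_intervening = j - i - 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(gene_a = character(), gene_b = character(),
                      chrom = character(), n_intervening = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Build tandem duplicate clusters from scored pairs
#'
#' Pairs whose adjusted similarity meets `min_adjusted` become edges of a
#' similarity graph; clusters are its connected components with at least two
#' genes. A component may chain genes farther apart than the intervening-gene
#' limit end to end, as long as each individual link respects it. Each
#' cluster's subgenome is the majority block label over member-gene midpoints
#' (ties resolve to nonsyntenic).
#'
#' @param scored_pairs data.frame from [score_pairs()] (columns `gene_a`,
#'   `gene_b`, `adjusted`).
#' @param gene_set The `gene_set` the pairs refer to.
#' @param min_adjusted Minimum adjusted similarity for a link (default 0.3).
#' @param blocks Optional subgenome block table
#'   ([read_subgenome_blocks()]); when `NULL` all clusters are labelled
#'   nonsyntenic.
#' @param id_prefix Prefix for generated cluster ids.
#' @return A `tandem_clusters` object.
#' @export
build_clusters <- function(scored_pairs, gene_set, min_adjusted = 0.3,
                           blocks = NULL, id_prefix = "TDC") {
  keep <- !is.na(scored_pairs$adjusted) &
    scored_pairs$adjusted >= min_adjusted
  edges <- scored_pairs[keep, c("gene_a", "gene_b"), drop = FALSE]
  members_from_edges(edges, gene_set, blocks, id_prefix)
}

# Connected components over an edge list -> tandem_clusters.
#' @noRd
members_from_edges <- function(edges, gene_set, blocks, id_prefix) {
  g <- gene_set$genes
  empty <- data.frame(cluster_id = character(), gene_id = character(),
                      chrom = character(), start = integer(),
                      end = integer(), rank = integer(),
                      subgenome = character(), stringsAsFactors = FALSE)
  if (nrow(edges) == 0) return(new_tandem_clusters(empty))
  gr <- igraph::graph_from_data_frame(edges, directed = FALSE)
  comp <- igraph::components(gr)
  memb <- comp$membership
  ids <- names(memb)
  gi <- match(ids, g$gene_id)
  if (anyNA(gi)) stop("unknown gene id(s): ",
                      paste(ids[is.na(gi)], collapse = ", "))
  df <- data.frame(component = as.integer(memb), gene_id = ids,
                   chrom = g$chrom[gi], start = g$start[gi], end = g$end[gi],
                   rank = g$rank[gi], stringsAsFactors = FALSE)
  # stable cluster ids: number components by (chrom, first start)
  key <- do.call(rbind, lapply(split(df, df$component), function(d) {
    data.frame(component = d$component[1], chrom = d$chrom[1],
               start = min(d$start), stringsAsFactors = FALSE)
  }))
  key <- key[order(key$chrom, key$start, key$component), , drop = FALSE]
  key$cluster_id <- sprintf("%s%04d", id_prefix, seq_len(nrow(key)))
  df$cluster_id <- key$cluster_id[match(df$component, key$component)]

  mid <- (df$start + df$end) %/% 2L
  lab <- lookup_block_label(df$chrom, mid, blocks)
  sub_by_cluster <- vapply(split(lab, df$cluster_id), majority_subgenome,
                           character(1))
  df$subgenome <- sub_by_cluster[df$cluster_id]
  new_tandem_clusters(df[c("cluster_id", "gene_id", "chrom", "start", "end",
                           "rank", "subgenome")])
}

#' Validate externally supplied candidate clusters
#'
#' Candidate clusters (e.g. from a synteny-based tandem caller) are filtered
#' so that only genes connected to the rest of their cluster by at least one
#' pair with adjusted similarity at or above the threshold are kept;
#' candidates falling below two genes are dropped. The surviving candidates
#' are merged with `adjacency_clusters`: clusters sharing any gene are
#' unioned into one.
#'
#' @param candidates data.frame with columns `cluster_id`, `gene_id`.
#' @param scored_pairs Scored pairs covering at least the within-candidate
#'   pairs ([score_pairs()]).
#' @param gene_set The `gene_set` the ids refer to.
#' @param adjacency_clusters Optional `tandem_clusters` from
#'   [build_clusters()] to merge with.
#' @inheritParams build_clusters
#' @return A `tandem_clusters` object.
#' @export
validate_candidate_clusters <- function(candidates, scored_pairs, gene_set,
                                        adjacency_clusters = NULL,
                                        min_adjusted = 0.3, blocks = NULL,
                                        id_prefix = "TDC") {
  unknown <- setdiff(candidates$gene_id, gene_set$genes$gene_id)
  if (length(unknown) > 0) {
    stop("unknown gene id(s) in candidate clusters: ",
         paste(unknown, collapse = ", "))
  }
  keep <- !is.na(scored_pairs$adjusted) &
    scored_pairs$adjusted >= min_adjusted
  good <- scored_pairs[keep, , drop = FALSE]
  edge_key <- c(paste(good$gene_a, good$gene_b), paste(good$gene_b, good$gene_a))

  cand_edges <- do.call(rbind, lapply(split(candidates, candidates$cluster_id),
                                      function(d) {
    ids <- unique(d$gene_id)
    if (length(ids) < 2) return(NULL)
    cmb <- utils::combn(sort(ids), 2)
    df <- data.frame(gene_a = cmb[1, ], gene_b = cmb[2, ],
                     stringsAsFactors = FALSE)
    df[paste(df$gene_a, df$gene_b) %in% edge_key, , drop = FALSE]
  }))
  if (is.null(cand_edges)) {
    cand_edges <- data.frame(gene_a = character(), gene_b = character(),
                             stringsAsFactors = FALSE)
  }
  adj_edges <- if (is.null(adjacency_clusters)) {
    data.frame(gene_a = character(), gene_b = character(),
               stringsAsFactors = FALSE)
  } else {
    # re-link each existing cluster as a path so merging unions them
    do.call(rbind, lapply(split(adjacency_clusters$members,
                                adjacency_clusters$members$cluster_id),
                          function(d) {
      ids <- d$gene_id[order(d$start, d$end, d$gene_id)]
      data.frame(gene_a = ids[-length(ids)], gene_b = ids[-1],
                 stringsAsFactors = FALSE)
    }))
  }
  members_from_edges(rbind(cand_edges, adj_edges), gene_set, blocks,
                     id_prefix)
}

#' Detect interleaved tandem duplicate cassettes
#'
#' A cassette is a group of at least two tandem duplicate clusters whose gene
#' coordinates interleave (the A1 B1 A2 B2 pattern), suggesting duplication
#' of a multi-gene block. Two same-chromosome clusters are interleaved when
#' at least one gene of each lies strictly between two genes of the other
#' (by start coordinate). A cluster fully nested inside another — all its
#' genes between two genes of the host but none of the host's genes inside
#' its own span — is not interleaved and does not form a cassette. Cassettes
#' are the connected components of the interleaving relation.
#'
#' @param clusters A `tandem_clusters` object.
#' @return data.frame with one row per (cassette, cluster): `cassette_id`,
#'   `cluster_id`, `chrom`, `span_start`, `span_end`. Zero rows when no
#'   clusters interleave.
#' @export
detect_cassettes <- function(clusters) {
  cs <- cluster_summary(clusters)
  empty <- data.frame(cassette_id = character(), cluster_id = character(),
                      chrom = character(), span_start = integer(),
                      span_end = integer(), stringsAsFactors = FALSE)
  if (is.null(cs) || nrow(cs) < 2) return(empty)
  m <- clusters$members
  starts <- split(m$start, m$cluster_id)

  out <- lapply(split(cs, cs$chrom), function(cc) {
    cc <- cc[order(cc$span_start, cc$span_end, cc$cluster_id), , drop = FALSE]
    n <- nrow(cc)
    if (n < 2) return(NULL)
    edges <- NULL
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (cc$span_start[j] > cc$span_end[i]) break  # sorted: no overlap
        if (clusters_interleave(starts[[cc$cluster_id[i]]],
                                starts[[cc$cluster_id[j]]])) {
          edges <- rbind(edges, data.frame(a = cc$cluster_id[i],
                                           b = cc$cluster_id[j],
                                           stringsAsFactors = FALSE))
        }
      }
    }
    edges
  })
  edges <- do.call(rbind, out)
  if (is.null(edges) || nrow(edges) == 0) return(empty)
  gr <- igraph::graph_from_data_frame(edges, directed = FALSE)
  comp <- igraph::components(gr)
  df <- data.frame(cluster_id = names(comp$membership),
                   component = as.integer(comp$membership),
                   stringsAsFactors = FALSE)
  df <- merge(df, cs, by = "cluster_id")
  key <- do.call(rbind, lapply(split(df, df$component), function(d) {
    data.frame(component = d$component[1], chrom = d$chrom[1],
               start = min(d$span_start), stringsAsFactors = FALSE)
  }))
  key <- key[order(key$chrom, key$start, key$component), , drop = FALSE]
  key$cassette_id <- sprintf("CAS%03d", seq_len(nrow(key)))
  df$cassette_id <- key$cassette_id[match(df$component, key$component)]
  df <- df[order(df$cassette_id, df$span_start, df$cluster_id), , drop = FALSE]
  rownames(df) <- NULL
  df[c("cassette_id", "cluster_id", "chrom", "span_start", "span_end")]
}

# Interleaving test on gene start coordinates. Nesting is checked first and
# excludes a pair outright: a cluster whose start-coordinate span lies fully
# inside the other's is nested, never a cassette partner, even if its genes
# fall between genes of the host. Otherwise the pair is interleaved when at
# least one gene of each cluster lies strictly between two genes of the
# other. Start coordinates are distinct by construction (load-time
# tie-break), so strict comparisons are safe.
#' @noRd
clusters_interleave <- function(starts_a, starts_b) {
  lo_a <- min(starts_a); hi_a <- max(starts_a)
  lo_b <- min(starts_b); hi_b <- max(starts_b)
  nested <- (lo_a > lo_b && hi_a < hi_b) || (lo_b > lo_a && hi_b < hi_a)
  if (nested) return(FALSE)
  any(starts_b > lo_a & starts_b < hi_a) &&
    any(starts_a > lo_b & starts_a < hi_b)
}
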