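# Gene/TE relationships at overlap fraction 1.0: a gene either fully
# contains a TE insertion or is entirely nested within (captured by) one.
# Partial overlaps are never classified.

TE_CLASSES <- c("LTR", "LINE", "SINE", "TIR")

#' Classify full-containment gene/TE relations
#'
#' Emits every same-chromosome (gene, TE) pair where one interval fully
#' contains the other: `contains` when the TE lies entirely within the gene
#' span, `captured` when the entire gene span lies within the TE. A pair
#' with identical intervals satisfies both; it is resolved to `contains`.
#' Overlap-fraction-1.0 semantics means partial overlaps yield no relation.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end` (a
#'   `gene_set$genes` table works directly).
#' @param tes TE table from [read_te_features()].
#' @return data.frame with columns `gene_id`, `te_id`, `te_class`,
#'   `relation`.
#' @export
classify_relations <- function(genes, tes) {
  empty <- data.frame(gene_id = character(), te_id = character(),
                      te_class = character(), relation = character(),
                      stringsAsFactors = FALSE)
  if (is.null(tes) || nrow(tes) == 0 || nrow(genes) == 0) return(empty)
  ggr <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(genes$start, genes$end))
  tgr <- GenomicRanges::GRanges(tes$chrom,
                                IRanges::IRanges(tes$start, tes$end))
  # TE within gene
  ov1 <- GenomicRanges::findOverlaps(tgr, ggr, type = "within")
  contains <- data.frame(
    gene_id = genes$gene_id[subjectHits(ov1)],
    te_id = tes$te_id[queryHits(ov1)],
    te_class = tes$te_class[queryHits(ov1)],
    relation = rep("contains", length(ov1)), stringsAsFactors = FALSE)
  # gene within TE
  ov2 <- GenomicRanges::findOverlaps(ggr, tgr, type = "within")
  captured <- data.frame(
    gene_id = genes$gene_id[queryHits(ov2)],
    te_id = tes$te_id[subjectHits(ov2)],
    te_class = tes$te_class[subjectHits(ov2)],
    relation = rep("captured", length(ov2)), stringsAsFactors = FALSE)
  out <- rbind(contains, captured)
  # identical intervals satisfy both; keep contains only
  dup <- duplicated(out[c("gene_id", "te_id")])
  out <- out[!(dup & out$relation == "captured"), , drop = FALSE]
  both <- paste(contains$gene_id, contains$te_id)
  out <- out[!(out$relation == "captured" &
                 paste(out$gene_id, out$te_id) %in% both), , drop = FALSE]
  out <- out[order(out$gene_id, out$te_id, out$relation), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene counts of TE containment and capture
#'
#' Cross-tabulates genes by TE class, tandem-duplicate status, and relation.
#' Counts are gene-level: a gene relating to several TEs of one class counts
#' once in that (class, relation) cell. Also reports the two headline
#' proportions — the fraction of tandem and of non-tandem genes containing
#' at least one LTR insertion.
#'
#' @param relations From [classify_relations()].
#' @param genes Gene table (for the tandem/non-tandem denominators).
#' @param tandem_gene_ids Character vector of tandem duplicate gene ids.
#' @return list with `table` (data.frame: `te_class`, `gene_group`,
#'   `relation`, `n_genes`) and `ltr_contains_proportion` (named numeric,
#'   tandem and non_tandem).
#' @export
count_table <- function(relations, genes, tandem_gene_ids) {
  grid <- expand.grid(te_class = TE_CLASSES,
                      gene_group = c("tandem", "non_tandem"),
                      relation = c("contains", "captured"),
                      stringsAsFactors = FALSE)
  rel <- unique(relations[c("gene_id", "te_class", "relation")])
  rel$gene_group <- ifelse(rel$gene_id %in% tandem_gene_ids,
                           "tandem", "non_tandem")
  grid$n_genes <- mapply(function(cl, gg, r) {
    sum(rel$te_class == cl & rel$gene_group == gg & rel$relation == r)
  }, grid$te_class, grid$gene_group, grid$relation)
  grid <- grid[order(grid$te_class, grid$gene_group, grid$relation), ,
               drop = FALSE]
  rownames(grid) <- NULL

  n_tandem <- sum(genes$gene_id %in% tandem_gene_ids)
  n_non <- nrow(genes) - n_tandem
  ltr <- function(gg, denom) {
    if (denom == 0) return(NA_real_)
    sum(rel$te_class == "LTR" & rel$relation == "contains" &
          rel$gene_group == gg) / denom
  }
  list(table = grid,
       ltr_contains_proportion = c(tandem = ltr("tandem", n_tandem),
                                   non_tandem = ltr("non_tandem", n_non)))
}

#' Distance from each gene to the nearest TE of each class
#'
#' Strand-agnostic distance in bp between closest interval boundaries; 0 for
#' any overlap. When a chromosome has no TE of a class, the distance for
#' genes on it is `NA` (flagged missing).
#'
#' @param genes Gene table (`gene_id`, `chrom`, `start`, `end`).
#' @param tes TE table.
#' @return data.frame: `gene_id` plus one distance column per TE class
#'   (`dist_LTR`, `dist_LINE`, `dist_SINE`, `dist_TIR`).
#' @export
nearest_te_distance <- function(genes, tes) {
  out <- data.frame(gene_id = genes$gene_id, stringsAsFactors = FALSE)
  ggr <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(genes$start, genes$end))
  for (cl in TE_CLASSES) {
    col <- paste0("dist_", cl)
    out[[col]] <- NA_real_
    tc <- tes[tes$te_class == cl, , drop = FALSE]
    if (nrow(tc) == 0) next
    tgr <- GenomicRanges::GRanges(tc$chrom,
                                  IRanges::IRanges(tc$start, tc$end))
    dn <- GenomicRanges::distanceToNearest(ggr, tgr)
    out[[col]][queryHits(dn)] <- mcols(dn)$distance
  }
  out
}
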