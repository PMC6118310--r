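# Gap-down-weighted pairwise similarity between genes: longest-transcript
# translation, global protein alignment, back-translation, and the adjusted
# identity that multiplies within-aligned-region identity by the ungapped
# fraction of the alignment.

# Alignment scoring used for every pairwise protein alignment. A
# deterministic global Needleman-Wunsch with BLOSUM62 and affine gaps stands
# in for a progressive aligner: with only two sequences there is nothing to
# refine.
ALN_GAP_OPEN <- 10
ALN_GAP_EXT <- 0.5

.aln_cache <- new.env(parent = emptyenv())

#' @noRd
blosum62 <- function() {
  if (is.null(.aln_cache$mat)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .aln_cache$mat <- get("BLOSUM62", envir = e)
  }
  .aln_cache$mat
}

# encode residues as 0-based substitution-matrix indices (-1 = unknown)
#' @noRd
encode_protein <- function(p, mat = blosum62()) {
  idx <- match(strsplit(p, "")[[1]], rownames(mat))
  idx[is.na(idx)] <- 0L
  as.integer(idx - 1L)
}

#' Translate the longest transcript of a gene
#'
#' Selects the gene's longest CDS, trims a single terminal stop codon if
#' present, and translates with the standard genetic code. Internal stop
#' codons are retained as `X` (they count as mismatches downstream). A gene
#' whose longest in-frame choice fails — no transcript with CDS length
#' divisible by 3 — is flagged untranslatable rather than raising an error.
#'
#' @param gene_set A `gene_set` from [read_genes()] or [simulate_genotypes()].
#' @param gene_id Gene identifier.
#' @return A list with `protein` (character or `NA` if untranslatable),
#'   `cds` (the trimmed coding sequence actually translated), `tx_id`, and
#'   `untranslatable` (logical).
#' @export
longest_transcript_protein <- function(gene_set, gene_id) {
  tx <- gene_set$transcripts[gene_set$transcripts$gene_id == gene_id, ,
                             drop = FALSE]
  if (nrow(tx) == 0) stop("unknown gene id: ", gene_id)
  tx <- tx[order(-tx$cds_len, tx$tx_id), , drop = FALSE]
  ok <- tx$cds_len %% 3L == 0L
  # a transcript one codon longer than a multiple of 3 cannot be rescued;
  # fall through the length-ordered list to the first in-frame CDS
  if (!any(ok)) {
    return(list(protein = NA_character_, cds = NA_character_,
                tx_id = tx$tx_id[1], untranslatable = TRUE))
  }
  tx_id <- tx$tx_id[which(ok)[1]]
  cds <- as.character(gene_set$cds[[tx_id]])
  translate_cds(cds, tx_id)
}

# Vectorized longest-in-frame-transcript translation for many genes in one
# translate() call; NA for untranslatable genes. Same selection rule as
# longest_transcript_protein().
#' @noRd
proteins_for <- function(gene_set, ids) {
  tx <- gene_set$transcripts
  t2 <- tx[tx$gene_id %in% ids & tx$cds_len %% 3L == 0L, , drop = FALSE]
  out <- setNames(rep(NA_character_, length(ids)), ids)
  if (nrow(t2) == 0) return(out)
  t2 <- t2[order(t2$gene_id, -t2$cds_len, t2$tx_id), , drop = FALSE]
  pick <- t2[!duplicated(t2$gene_id), , drop = FALSE]
  aa <- suppressWarnings(as.character(
    translate(gene_set$cds[pick$tx_id], if.fuzzy.codon = "X")))
  last <- substring(aa, nchar(aa))
  aa[last == "*"] <- substring(aa[last == "*"], 1,
                               nchar(aa[last == "*"]) - 1L)
  aa <- gsub("*", "X", aa, fixed = TRUE)
  out[pick$gene_id] <- aa
  out
}

# Translate a single in-frame CDS string; trims one terminal stop.
#' @noRd
translate_cds <- function(cds, tx_id = NA_character_) {
  stopifnot(nchar(cds) %% 3L == 0L, nchar(cds) > 0L)
  aa <- suppressWarnings(as.character(
    translate(DNAStringSet(cds), if.fuzzy.codon = "X")))
  if (substring(aa, nchar(aa)) == "*") {
    aa <- substring(aa, 1, nchar(aa) - 1L)
    cds <- substring(cds, 1, nchar(cds) - 3L)
  }
  aa <- gsub("*", "X", aa, fixed = TRUE)
  list(protein = aa, cds = cds, tx_id = tx_id, untranslatable = FALSE)
}

#' Globally align two protein sequences
#'
#' Needleman-Wunsch global alignment (BLOSUM62, affine gap penalties; the
#' first residue of a gap costs opening plus extension) with the column
#' bookkeeping needed by [adjusted_similarity()]: total columns, columns
#' ungapped in both rows, and ungapped columns where the residues are
#' identical. Ties among co-optimal alignments break deterministically
#' (substitution preferred over a gap in `b`, over a gap in `a`), so the
#' result is reproducible for fixed inputs.
#'
#' @param a,b Non-empty amino-acid strings.
#' @return An object of class `pairwise_alignment` with fields `aln_a`,
#'   `aln_b` (gapped rows), `score`, `n_columns`, `n_ungapped`,
#'   `n_identical`.
#' @export
align_pair <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("cannot align an empty sequence")
  # canonical argument order: ties among co-optimal alignments are broken
  # identically whichever way the pair is presented, making the score
  # symmetric
  swap <- a > b
  if (swap) { tmp <- a; a <- b; b <- tmp }
  mat <- blosum62()
  res <- .nw_align_cpp(encode_protein(a, mat), encode_protein(b, mat),
                       mat, ALN_GAP_OPEN, ALN_GAP_EXT, TRUE)
  ch_a <- strsplit(a, "")[[1]]
  ch_b <- strsplit(b, "")[[1]]
  row_chr <- function(idx, ch) {
    out <- rep("-", length(idx))
    out[idx >= 0] <- ch[idx[idx >= 0] + 1L]
    paste(out, collapse = "")
  }
  row_a <- row_chr(res$row_a, ch_a)
  row_b <- row_chr(res$row_b, ch_b)
  aln <- if (swap) alignment_from_rows(row_b, row_a) else
    alignment_from_rows(row_a, row_b)
  aln$score <- res$score
  aln
}

# Build the bookkeeping object from two equal-length gapped rows.
#' @noRd
alignment_from_rows <- function(row_a, row_b) {
  stopifnot(nchar(row_a) == nchar(row_b))
  ca <- charToRaw(row_a)
  cb <- charToRaw(row_b)
  gap <- charToRaw("-")
  ungapped <- ca != gap & cb != gap
  structure(list(
    aln_a = row_a, aln_b = row_b,
    n_columns = length(ca),
    n_ungapped = sum(ungapped),
    n_identical = sum(ungapped & ca == cb)
  ), class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("pairwise_alignment:", x$n_columns, "columns,", x$n_ungapped,
      "ungapped,", x$n_identical, "identical\n")
  invisible(x)
}

#' Back-translate a protein alignment to a codon-level alignment
#'
#' Maps each aligned residue back onto its source codon; gap columns become
#' `---`. Reading the non-gap codons of either row reproduces that row's CDS
#' exactly.
#'
#' @param alignment A `pairwise_alignment`.
#' @param cds_a,cds_b The (stop-trimmed) coding sequences that were
#'   translated into the aligned proteins; each must be exactly 3x its row's
#'   ungapped residue count.
#' @return A list with `codon_a`, `codon_b`: character vectors of 3-character
#'   codons/gaps, one element per alignment column.
#' @export
back_translate <- function(alignment, cds_a, cds_b) {
  row_to_codons <- function(row, cds, label) {
    res <- strsplit(row, "")[[1]]
    n_res <- sum(res != "-")
    if (nchar(cds) != 3L * n_res) {
      stop("CDS length ", nchar(cds), " does not match ", n_res,
           " aligned residues for ", label)
    }
    codons <- substring(cds, seq(1, nchar(cds), by = 3),
                        seq(3, nchar(cds), by = 3))
    out <- rep("---", length(res))
    out[res != "-"] <- codons
    out
  }
  list(codon_a = row_to_codons(alignment$aln_a, cds_a, "sequence A"),
       codon_b = row_to_codons(alignment$aln_b, cds_b, "sequence B"))
}

#' Adjusted pairwise similarity of an alignment
#'
#' The similarity within aligned (ungapped) regions multiplied by the
#' proportion of the total alignment that is not gapped:
#' `(n_identical / n_ungapped) * (n_ungapped / n_columns)`. The
#' down-weighting accounts for identity being undefined in gapped regions —
#' two genes can be nearly identical over a short conserved stretch yet
#' unalignable elsewhere. When every column is gapped the raw identity is
#' undefined and the adjusted similarity is 0.
#'
#' @param alignment A `pairwise_alignment`.
#' @return A list of class `similarity_score` with `raw_identity`,
#'   `ungapped_fraction`, `adjusted`.
#' @export
adjusted_similarity <- function(alignment) {
  stopifnot(alignment$n_columns > 0)
  if (alignment$n_ungapped == 0) {
    raw <- NA_real_
    adj <- 0
  } else {
    raw <- alignment$n_identical / alignment$n_ungapped
    adj <- raw * (alignment$n_ungapped / alignment$n_columns)
  }
  structure(list(
    raw_identity = raw,
    ungapped_fraction = alignment$n_ungapped / alignment$n_columns,
    adjusted = adj
  ), class = "similarity_score")
}

#' Adjusted similarity between two genes
#'
#' Convenience wrapper: longest-transcript translation of both genes, global
#' protein alignment, adjusted similarity. Untranslatable genes yield `NA`
#' scores.
#'
#' @inheritParams longest_transcript_protein
#' @param gene_a,gene_b Gene identifiers.
#' @return A one-row data.frame: `gene_a`, `gene_b`, `raw_identity`,
#'   `ungapped_fraction`, `adjusted`.
#' @export
gene_pair_similarity <- function(gene_set, gene_a, gene_b) {
  score_pairs(gene_set, data.frame(gene_a = gene_a, gene_b = gene_b,
                                   stringsAsFactors = FALSE))
}

#' Score many gene pairs
#'
#' Computes the adjusted pairwise similarity for each row of `pairs`. Each
#' protein is translated and encoded once; alignments run in compiled code.
#' Pairs involving an untranslatable gene get `NA` scores (and a message
#' reporting how many genes were excluded).
#'
#' @inheritParams longest_transcript_protein
#' @param pairs data.frame with columns `gene_a`, `gene_b`.
#' @return `pairs` with `raw_identity`, `ungapped_fraction` and `adjusted`
#'   columns appended.
#' @export
score_pairs <- function(gene_set, pairs) {
  n <- nrow(pairs)
  out <- pairs
  out$raw_identity <- rep(NA_real_, n)
  out$ungapped_fraction <- rep(NA_real_, n)
  out$adjusted <- rep(NA_real_, n)
  if (n == 0) return(out)

  ids <- unique(c(pairs$gene_a, pairs$gene_b))
  prot <- proteins_for(gene_set, ids)
  bad <- is.na(prot)
  if (any(bad)) {
    message(sum(bad), " untranslatable gene(s) excluded from similarity")
  }
  usable <- !(is.na(prot[pairs$gene_a]) | is.na(prot[pairs$gene_b]))

  mat <- blosum62()
  good_ids <- ids[!bad]
  enc <- lapply(prot[good_ids], encode_protein, mat = mat)
  sel <- which(usable)
  ia <- match(pairs$gene_a[sel], good_ids)
  ib <- match(pairs$gene_b[sel], good_ids)
  # canonical pair order by sequence content (column counts are symmetric,
  # so no un-swap is needed afterwards)
  sw <- unname(prot[pairs$gene_a[sel]] > prot[pairs$gene_b[sel]])
  tmp <- ia[sw]; ia[sw] <- ib[sw]; ib[sw] <- tmp
  counts <- .nw_score_pairs_cpp(enc, ia, ib, mat,
                                ALN_GAP_OPEN, ALN_GAP_EXT)
  n_col <- counts[, 2]
  n_ug <- counts[, 3]
  n_id <- counts[, 4]
  out$raw_identity[sel] <- ifelse(n_ug == 0, NA_real_, n_id / n_ug)
  out$ungapped_fraction[sel] <- n_ug / n_col
  out$adjusted[sel] <- ifelse(n_ug == 0, 0, n_id / n_col)
  out
}
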