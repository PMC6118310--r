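# Shared internal helpers.

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable write of a data.frame as TSV: fixed column order, no quoting, "." for
# NA, Unix newlines. Used everywhere so that re-runs are byte-identical.
#' @noRd
write_tsv_stable <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df) > 0) {
    cols <- lapply(df, function(x) {
      x <- as.character(x)
      x[is.na(x)] <- "."
      x
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con, sep = "\n")
  }
  invisible(path)
}

#' @noRd
read_tsv_plain <- function(path) {
  read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             na.strings = ".", check.names = FALSE)
}

# Majority label with deterministic tie handling: ties resolve to
# "nonsyntenic". `weights` are base counts per label.
#' @noRd
majority_subgenome <- function(labels, weights = NULL) {
  levs <- c("maize1", "maize2", "nonsyntenic")
  if (length(labels) == 0) return("nonsyntenic")
  if (is.null(weights)) weights <- rep(1, length(labels))
  tot <- vapply(levs, function(l) sum(weights[labels == l]), numeric(1))
  if (all(tot == 0)) return("nonsyntenic")
  top <- which(tot == max(tot))
  if (length(top) > 1) "nonsyntenic" else levs[top]
}

# Label genomic positions (1-based) against subgenome blocks.
#' @noRd
lookup_block_label <- function(chrom, pos, blocks) {
  out <- rep("nonsyntenic", length(chrom))
  if (is.null(blocks) || nrow(blocks) == 0) return(out)
  for (i in seq_len(nrow(blocks))) {
    hit <- chrom == blocks$chrom[i] & pos >= blocks$start[i] & pos <= blocks$end[i]
    out[hit] <- blocks$label[i]
  }
  out
}
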