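# Readers/writers for the standard formats the pipeline touches and the
# shared in-memory containers.
#
# A "gene_set" is the central container: a list with
#   $genes       data.frame: gene_id, chrom, start, end, strand, rank,
#                tx_id (longest transcript), exon_count
#   $transcripts data.frame: tx_id, gene_id, exon_count, cds_len
#   $cds         DNAStringSet keyed by tx_id
# Coordinates are 1-based closed (GFF3/IRanges convention) throughout;
# BED-like inputs are converted at the boundary.

#' Read gene models and their coding sequences
#'
#' Parses a GFF3 gene annotation (gene/mRNA/CDS features with `Parent` links)
#' together with a FASTA of coding sequences keyed by transcript id, and
#' returns a `gene_set`: genes sorted by position within each chromosome with
#' a 0-based `rank` recording chromosome order. Ties on start coordinate are
#' broken by end coordinate, then gene id, so ranks are deterministic.
#'
#' The CDS of a transcript is the concatenation of its coding exons in 5'→3'
#' order; when the FASTA already holds one record per transcript that record
#' is used directly. Every annotated mRNA must have a CDS sequence.
#'
#' @param gff3_path Path to a GFF3 file with gene, mRNA and CDS features.
#' @param cds_fasta_path Path to a FASTA file with one CDS per transcript id.
#' @return An object of class `gene_set` (see Details).
#' @export
read_genes <- function(gff3_path, cds_fasta_path) {
  validate_gff3_lines(gff3_path)
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  cds <- readDNAStringSet(cds_fasta_path)
  names(cds) <- sub("\\s.*$", "", names(cds))

  type <- as.character(gr$type)
  g <- gr[type == "gene"]
  m <- gr[type == "mRNA"]
  cd <- gr[type == "CDS"]
  if (length(g) == 0) stop("no gene features in ", gff3_path)

  genes <- data.frame(
    gene_id = as.character(g$ID),
    chrom = as.character(GenomicRanges::seqnames(g)),
    start = GenomicRanges::start(g),
    end = GenomicRanges::end(g),
    strand = as.character(GenomicRanges::strand(g)),
    stringsAsFactors = FALSE
  )
  tx_parent <- vapply(m$Parent, function(p) as.character(p)[1], character(1))
  tx <- data.frame(
    tx_id = as.character(m$ID),
    gene_id = tx_parent,
    stringsAsFactors = FALSE
  )
  cds_parent <- vapply(cd$Parent, function(p) as.character(p)[1], character(1))
  tx$exon_count <- vapply(tx$tx_id, function(t) sum(cds_parent == t), integer(1))

  missing <- setdiff(tx$tx_id, names(cds))
  if (length(missing) > 0) {
    stop("CDS sequence missing for transcript(s): ",
         paste(missing, collapse = ", "))
  }
  tx$cds_len <- width(cds)[match(tx$tx_id, names(cds))]

  as_gene_set(genes, tx, cds[tx$tx_id])
}

# Assemble + validate a gene_set from its parts; assigns ranks.
#' @noRd
as_gene_set <- function(genes, transcripts, cds) {
  stopifnot(all(genes$start <= genes$end))
  ord <- order(genes$chrom, genes$start, genes$end, genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  genes$rank <- stats::ave(seq_len(nrow(genes)), genes$chrom,
                           FUN = function(i) seq_along(i) - 1L)
  rownames(genes) <- NULL

  no_tx <- setdiff(genes$gene_id, transcripts$gene_id)
  if (length(no_tx) > 0) {
    stop("gene(s) without any transcript: ", paste(no_tx, collapse = ", "))
  }
  # canonical transcript/CDS order (gene position, then tx id) so that a
  # write/read round-trip reproduces the container exactly
  transcripts <- transcripts[order(match(transcripts$gene_id,
                                         genes$gene_id),
                                   transcripts$tx_id), , drop = FALSE]
  rownames(transcripts) <- NULL
  cds <- cds[transcripts$tx_id]
  # longest transcript per gene (deterministic tie-break on tx_id)
  tord <- order(transcripts$gene_id, -transcripts$cds_len, transcripts$tx_id)
  ts <- transcripts[tord, , drop = FALSE]
  longest <- ts[!duplicated(ts$gene_id), , drop = FALSE]
  i <- match(genes$gene_id, longest$gene_id)
  genes$tx_id <- longest$tx_id[i]
  genes$exon_count <- longest$exon_count[i]

  structure(list(genes = genes, transcripts = transcripts, cds = cds),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set:", nrow(x$genes), "genes on",
      length(unique(x$genes$chrom)), "chromosome(s);",
      nrow(x$transcripts), "transcripts\n")
  invisible(x)
}

# Minimal structural check of GFF3 body lines; reports 1-based line numbers.
#' @noRd
validate_gff3_lines <- function(path) {
  lines <- readLines(path)
  body <- !grepl("^#", lines) & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- which(body)[nf < 9]
  if (length(bad) > 0) {
    stop("malformed GFF3 line ", bad[1], " in ", path,
         " (expected 9 tab-separated fields)")
  }
  invisible(TRUE)
}

# GFF3 feature types / classification attributes mapped onto the four TE
# classes used throughout. Anything else is dropped (with a count).
TE_CLASS_MAP <- c(
  LTR_retrotransposon = "LTR", LTR_retroelement = "LTR", LTR = "LTR",
  LINE_element = "LINE", LINE_retrotransposon = "LINE", LINE = "LINE",
  SINE_element = "SINE", SINE_retrotransposon = "SINE", SINE = "SINE",
  terminal_inverted_repeat_element = "TIR", TIR_transposon = "TIR",
  DNA_transposon = "TIR", TIR = "TIR"
)

#' Read transposable-element features
#'
#' Reads a TE annotation GFF3 and maps each record's feature type onto one of
#' the four TE classes used by the pipeline: `LTR`, `LINE`, `SINE` (class 1 /
#' RNA elements) and `TIR` (class 2 / DNA elements). Records whose type cannot
#' be mapped (e.g. helitrons) are dropped; the number dropped is reported via
#' a message.
#'
#' @param gff3_path Path to a TE GFF3 file. An empty file yields an empty
#'   table.
#' @return A data.frame with columns `te_id`, `chrom`, `start`, `end`,
#'   `te_class`.
#' @export
read_te_features <- function(gff3_path) {
  empty <- data.frame(te_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      te_class = character(), stringsAsFactors = FALSE)
  lines <- tryCatch(readLines(gff3_path), error = function(e) character())
  if (all(grepl("^#", lines) | !nzchar(lines))) return(empty)
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  if (length(gr) == 0) return(empty)
  type <- as.character(gr$type)
  cls <- unname(TE_CLASS_MAP[type])
  dropped <- sum(is.na(cls))
  if (dropped > 0) {
    message(dropped, " TE record(s) with unmappable class dropped")
  }
  keep <- !is.na(cls)
  gr <- gr[keep]
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else
    paste0("te", seq_along(gr))
  ids[is.na(ids)] <- paste0("te", which(is.na(ids)))
  data.frame(
    te_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    te_class = cls[keep],
    stringsAsFactors = FALSE
  )
}

#' Read subgenome block assignments
#'
#' Reads a BED-like table (`chrom`, `start`, `end`, `label`; 0-based
#' half-open, no header) assigning genomic blocks to `maize1`, `maize2` or
#' `nonsyntenic`, and converts coordinates to the 1-based closed convention
#' used internally.
#'
#' @param path Path to the block table.
#' @return A data.frame with columns `chrom`, `start`, `end`, `label`.
#' @export
read_subgenome_blocks <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:4] <- c("chrom", "start", "end", "label")
  bad <- setdiff(unique(df$label), c("maize1", "maize2", "nonsyntenic"))
  if (length(bad) > 0) stop("unknown subgenome label(s): ",
                            paste(bad, collapse = ", "))
  df$start <- df$start + 1L  # BED -> 1-based closed
  df[c("chrom", "start", "end", "label")]
}

#' Read a cross-genotype gene homology map
#'
#' @param path Two-column TSV (no header) of homologous gene id pairs,
#'   genotype A id first.
#' @return A data.frame with columns `gene_a`, `gene_b`.
#' @export
read_homology <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  stats::setNames(df[1:2], c("gene_a", "gene_b"))
}

#' Write tandem duplicate clusters to a TSV file
#'
#' One row per member gene with columns `cluster_id`, `gene_id`, `chromosome`,
#' `start`, `end`, `rank`, `subgenome`, ordered by cluster id then gene rank,
#' so repeated writes of the same clustering are byte-identical.
#'
#' @param clusters A `tandem_clusters` object (see [build_clusters()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @seealso [read_clusters()] for the inverse.
#' @export
write_clusters <- function(clusters, path) {
  m <- clusters$members
  df <- data.frame(
    cluster_id = m$cluster_id, gene_id = m$gene_id, chromosome = m$chrom,
    start = m$start, end = m$end, rank = m$rank, subgenome = m$subgenome,
    stringsAsFactors = FALSE
  )
  df <- df[order(df$cluster_id, df$rank), , drop = FALSE]
  write_tsv_stable(df, path)
}

#' Read tandem duplicate clusters written by [write_clusters()]
#'
#' @param path Path to a cluster TSV.
#' @return A `tandem_clusters` object.
#' @export
read_clusters <- function(path) {
  df <- read_tsv_plain(path)
  members <- data.frame(
    cluster_id = df$cluster_id, gene_id = df$gene_id, chrom = df$chromosome,
    start = as.integer(df$start), end = as.integer(df$end),
    rank = as.integer(df$rank), subgenome = df$subgenome,
    stringsAsFactors = FALSE
  )
  new_tandem_clusters(members)
}
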