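# Window-based feature densities, subgenome labelling, the general linear
# model of tandem duplicate gene density, and the tandem-proportion
# correlation.

RNA_TE_CLASSES <- c("LTR", "LINE", "SINE")
DNA_TE_CLASSES <- "TIR"

# Per-window union coverage proportion of a set of intervals.
#' @noRd
window_density <- function(windows_gr, feat) {
  if (is.null(feat) || nrow(feat) == 0) return(numeric(length(windows_gr)))
  gr <- GenomicRanges::GRanges(feat$chrom,
                               IRanges::IRanges(feat$start, feat$end))
  gr <- GenomicRanges::reduce(gr)
  ov <- GenomicRanges::findOverlaps(windows_gr, gr)
  covered <- numeric(length(windows_gr))
  if (length(ov) > 0) {
    w <- IRanges::width(IRanges::pintersect(
      GenomicRanges::ranges(windows_gr)[queryHits(ov)],
      GenomicRanges::ranges(gr)[subjectHits(ov)]))
    agg <- tapply(w, queryHits(ov), sum)
    covered[as.integer(names(agg))] <- agg
  }
  covered / IRanges::width(GenomicRanges::ranges(windows_gr))
}

#' Compute per-window feature densities and subgenome labels
#'
#' Tiles each chromosome into fixed-width windows (the trailing window may be
#' shorter and is normalized by its actual width) and computes, per window,
#' the proportion of bases covered by the base-level union of: all annotated
#' genes, tandem duplicate genes, RNA transposable elements (LTR + LINE +
#' SINE), and DNA transposable elements (TIR). Each window's subgenome label
#' is the majority block assignment over its bases; windows with no block
#' coverage, or tied coverage, are nonsyntenic.
#'
#' @param gene_set A `gene_set`.
#' @param tes TE table from [read_te_features()] (may be `NULL`).
#' @param tandem_gene_ids Character vector of gene ids in tandem duplicate
#'   clusters.
#' @param blocks Subgenome block table (may be `NULL`).
#' @param window_size Window width in bp (default 1 Mb).
#' @param chrom_lengths Optional named vector of chromosome lengths; defaults
#'   to the maximum end coordinate of any feature per chromosome.
#' @return data.frame with one row per window: `chrom`, `start`, `end`,
#'   `width`, `gene_density`, `tandem_density`, `rna_te_density`,
#'   `dna_te_density`, `subgenome`.
#' @export
compute_windows <- function(gene_set, tes = NULL, tandem_gene_ids = character(),
                            blocks = NULL, window_size = 1e6,
                            chrom_lengths = NULL) {
  g <- gene_set$genes
  if (is.null(chrom_lengths)) {
    ends <- c(g$end,
              if (!is.null(tes) && nrow(tes) > 0) tes$end,
              if (!is.null(blocks) && nrow(blocks) > 0) blocks$end)
    chr <- c(g$chrom,
             if (!is.null(tes) && nrow(tes) > 0) tes$chrom,
             if (!is.null(blocks) && nrow(blocks) > 0) blocks$chrom)
    chrom_lengths <- vapply(split(ends, chr), max, numeric(1))
  }
  chrom_lengths <- chrom_lengths[order(names(chrom_lengths))]

  win <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(1, len, by = window_size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window_size - 1, len),
               stringsAsFactors = FALSE)
  }))
  win$width <- win$end - win$start + 1
  wgr <- GenomicRanges::GRanges(win$chrom,
                                IRanges::IRanges(win$start, win$end))

  gene_iv <- g[c("chrom", "start", "end")]
  tand_iv <- g[g$gene_id %in% tandem_gene_ids, c("chrom", "start", "end")]
  rna_iv <- if (!is.null(tes)) tes[tes$te_class %in% RNA_TE_CLASSES,
                                   c("chrom", "start", "end")] else NULL
  dna_iv <- if (!is.null(tes)) tes[tes$te_class %in% DNA_TE_CLASSES,
                                   c("chrom", "start", "end")] else NULL

  win$gene_density <- window_density(wgr, gene_iv)
  win$tandem_density <- window_density(wgr, tand_iv)
  win$rna_te_density <- window_density(wgr, rna_iv)
  win$dna_te_density <- window_density(wgr, dna_iv)

  win$subgenome <- "nonsyntenic"
  if (!is.null(blocks) && nrow(blocks) > 0) {
    bgr <- GenomicRanges::GRanges(blocks$chrom,
                                  IRanges::IRanges(blocks$start, blocks$end),
                                  label = blocks$label)
    ov <- GenomicRanges::findOverlaps(wgr, bgr)
    if (length(ov) > 0) {
      w <- IRanges::width(IRanges::pintersect(
        GenomicRanges::ranges(wgr)[queryHits(ov)],
        GenomicRanges::ranges(bgr)[subjectHits(ov)]))
      lab <- blocks$label[subjectHits(ov)]
      for (q in unique(queryHits(ov))) {
        sel <- queryHits(ov) == q
        win$subgenome[q] <- majority_subgenome(lab[sel], w[sel])
      }
    }
  }
  stopifnot(all(win$tandem_density <= win$gene_density + 1e-12))
  rownames(win) <- NULL
  win
}

#' Fit the general linear model of tandem duplicate gene density
#'
#' Ordinary least squares regression of tandem duplicate gene density per
#' window on annotated gene density, RNA TE density, DNA TE density, and
#' subgenome assignment (categorical; maize1 is the reference level):
#' \deqn{Y = \beta_0 + \beta_1 g + \beta_2 r + \beta_3 d + \beta_4 s + \epsilon}
#' Per-term significance comes from ANOVA of nested models (drop-one F
#' tests). Setting `include_interaction = TRUE` adds a gene-density-by-
#' subgenome interaction, whose contribution can be assessed by comparing
#' the two fits with [anova_nested()].
#'
#' @param windows Window table from [compute_windows()].
#' @param include_interaction Add the `gene_density:subgenome` term?
#' @return An object of class `density_glm`: the underlying `lm` fit plus
#'   `coefficients`, `variance_explained` (R-squared), `anova_table`
#'   (drop-one sums of squares, F and p per term), and `residuals`.
#' @export
fit_density_glm <- function(windows, include_interaction = FALSE) {
  df <- windows
  df$subgenome <- factor(df$subgenome,
                         levels = c("maize1", "maize2", "nonsyntenic"))
  df$subgenome <- droplevels(df$subgenome)
  form <- tandem_density ~ gene_density + rna_te_density + dna_te_density
  if (nlevels(df$subgenome) > 1) {
    form <- stats::update(form, . ~ . + subgenome)
    if (include_interaction) {
      form <- stats::update(form, . ~ . + gene_density:subgenome)
    }
  }
  fit <- lm(form, data = df)
  if (anyNA(coef(fit))) {
    stop("rank-deficient design; collinear term(s): ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  }
  drop1_tab <- stats::drop1(fit, test = "F")
  structure(list(
    fit = fit,
    coefficients = coef(fit),
    variance_explained = summary(fit)$r.squared,
    anova_table = drop1_tab,
    anova_pvalues = setNames(drop1_tab[["Pr(>F)"]], rownames(drop1_tab))[-1],
    residuals = residuals(fit)
  ), class = "density_glm")
}

#' @export
print.density_glm <- function(x, ...) {
  cat("density_glm: R^2 =", round(x$variance_explained, 4), "\n")
  print(round(x$coefficients, 5))
  invisible(x)
}

#' ANOVA of two nested density GLMs
#'
#' @param reduced,full Two `density_glm` fits on the same windows, `reduced`
#'   nested in `full`.
#' @return The p-value of the F test comparing the models.
#' @export
anova_nested <- function(reduced, full) {
  a <- anova(reduced$fit, full$fit)
  a[["Pr(>F)"]][2]
}

#' Correlation between genic window content and tandem share of genic bases
#'
#' Tests whether gene-dense windows carry disproportionately many tandem
#' duplicate bases: Pearson correlation between each window's genic
#' proportion and the proportion of its genic bases that lie in tandem
#' duplicates, over windows with nonzero gene density. A flat relation here
#' (despite gene density dominating the GLM) indicates duplicate density
#' simply tracks the number of genes available to duplicate.
#'
#' @param windows Window table from [compute_windows()].
#' @return list with `r`, `p`, `n`, and `undefined` (`TRUE` with `NA` r/p
#'   when either variable has zero variance).
#' @export
tandem_proportion_correlation <- function(windows) {
  w <- windows[windows$gene_density > 0, , drop = FALSE]
  if (nrow(w) < 3) stop("need at least 3 windows with nonzero gene density")
  x <- w$gene_density
  y <- w$tandem_density / w$gene_density
  # zero-variance guard with a float tolerance: ratios of doubles make an
  # exactly-constant share come out at sd ~ 1e-17
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) {
    return(list(r = NA_real_, p = NA_real_, n = nrow(w), undefined = TRUE))
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(w),
       undefined = FALSE)
}
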