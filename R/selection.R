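# Relative-rates scaffolding: orthogroup and alignment-column filters,
# likelihood-ratio tests of clade models against the single-rate null,
# omega-based constraint classification, and the HKA window decision rule.
# Likelihoods and omegas arrive as tables from external model-fitting
# engines; this module implements the filtering and decision logic applied
# to them.

#' Filter orthologous gene groups for relative-rate testing
#'
#' Retains groups whose total size lies within `[min_size, max_size]`
#' (larger groups are likely long-diverged gene families, smaller groups
#' lack branches to test), that contain maize tandem duplicates, and whose
#' tandem duplicate clusters are complete — not split across orthogroups.
#'
#' @param groups data.frame with columns `group_id`, `size`,
#'   `contains_tandem`, `tandem_cluster_complete`.
#' @param min_size,max_size Inclusive size bounds (defaults 10 and 75).
#' @return The retained rows of `groups`.
#' @export
filter_orthogroups <- function(groups, min_size = 10, max_size = 75) {
  keep <- groups$size >= min_size & groups$size <= max_size &
    groups$contains_tandem & groups$tandem_cluster_complete
  out <- groups[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter codon alignment columns by gap content
#'
#' Removes codon columns (atomically, all three nucleotide positions) with
#' more than `max_gap_fraction` gaps or fewer than `min_species` non-gap
#' sequences. Gapped columns are uninformative for substitution-rate models
#' and inflate compute; the filter is idempotent.
#'
#' @param alignment Character matrix, one row per sequence, one column per
#'   nucleotide position of an in-frame codon alignment (`-` = gap), or a
#'   character vector of equal-length aligned sequences.
#' @param max_gap_fraction Maximum tolerated gap fraction per column
#'   (default 0.5).
#' @param min_species Minimum non-gap sequences per column (default 8).
#' @return Filtered alignment in the same representation as the input.
#' @export
filter_alignment_columns <- function(alignment, max_gap_fraction = 0.5,
                                     min_species = 8) {
  vec_in <- is.character(alignment) && is.null(dim(alignment))
  m <- if (vec_in) {
    do.call(rbind, strsplit(alignment, ""))
  } else {
    alignment
  }
  if (ncol(m) %% 3L != 0L) stop("alignment length is not a codon multiple")
  n_seq <- nrow(m)
  codon_cols <- ncol(m) / 3L
  keep <- vapply(seq_len(codon_cols), function(k) {
    cols <- (3L * (k - 1L) + 1L):(3L * k)
    gaps <- max(colSums(m[, cols, drop = FALSE] == "-"))
    non_gap <- n_seq - gaps
    gaps / n_seq <= max_gap_fraction && non_gap >= min_species
  }, logical(1))
  sel <- rep(keep, each = 3L)
  out <- m[, sel, drop = FALSE]
  if (vec_in) apply(out, 1, paste, collapse = "") else out
}

#' Likelihood-ratio test of a clade model against the null
#'
#' `statistic = 2 (lnL_alt - lnL_null)`, clamped at zero, compared to a
#' chi-squared distribution with degrees of freedom equal to the parameter
#' difference. The null is the single-rate model; alternatives mark
#' foreground clades (all maize genes, maize tandem duplicates, or tandem
#' duplicates vs other maize genes) as evolving at their own rate.
#'
#' @param null,alt Lists (or one-row data.frames) with `lnL` and `n_params`;
#'   `alt` must have more parameters than `null`.
#' @return list with `statistic`, `df`, `p`.
#' @export
lrt_vs_null <- function(null, alt) {
  if (alt$n_params <= null$n_params) {
    stop("models are not nested: alternative must have more parameters")
  }
  stat <- max(0, 2 * (alt$lnL - null$lnL))
  df <- alt$n_params - null$n_params
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

#' Select the best clade model per orthogroup
#'
#' Tests each alternative model against the null by LRT; the best-fitting
#' model is the significant alternative with the highest log-likelihood
#' (the null when none is significant at `alpha`). No multiple-testing
#' correction is applied across groups.
#'
#' @param models data.frame with columns `group_id`, `model` (1 = null),
#'   `lnL`, `n_params`, `omega_fg`, `omega_bg`.
#' @param alpha Significance level (default 0.05).
#' @return data.frame per group: `group_id`, `best_model`, `p_best`,
#'   `omega_fg`, `omega_bg`.
#' @export
select_best_model <- function(models, alpha = 0.05) {
  do.call(rbind, lapply(split(models, models$group_id), function(d) {
    null <- d[d$model == 1, , drop = FALSE]
    if (nrow(null) != 1) stop("group ", d$group_id[1],
                              " must have exactly one null model (model 1)")
    alts <- d[d$model != 1, , drop = FALSE]
    best <- 1L; p_best <- NA_real_; fg <- NA_real_; bg <- NA_real_
    best_lnl <- -Inf
    for (i in seq_len(nrow(alts))) {
      lrt <- lrt_vs_null(null[1, ], alts[i, ])
      if (lrt$p < alpha && alts$lnL[i] > best_lnl) {
        best <- alts$model[i]; p_best <- lrt$p
        fg <- alts$omega_fg[i]; bg <- alts$omega_bg[i]
        best_lnl <- alts$lnL[i]
      }
    }
    data.frame(group_id = d$group_id[1], best_model = best, p_best = p_best,
               omega_fg = fg, omega_bg = bg, stringsAsFactors = FALSE)
  }))
}

#' Classify selective constraint on tandem duplicates from omega
#'
#' For a fitted model distinguishing tandem duplicate branches (foreground)
#' from other genes (background): an omega above 10 marks the group
#' untestable (dS too small for a meaningful ratio); otherwise foreground
#' omega above background means weaker purifying constraint on the tandem
#' duplicates, below means stronger, and exact equality is flagged as a tie.
#'
#' @param omega_fg,omega_bg Foreground (tandem) and background omega.
#' @return One of `"untestable"`, `"weaker"`, `"stronger"`, `"tie"`.
#' @export
classify_constraint <- function(omega_fg, omega_bg) {
  stopifnot(length(omega_fg) == 1, length(omega_bg) == 1)
  if (omega_fg > 10) return("untestable")
  if (omega_fg > omega_bg) return("weaker")
  if (omega_fg < omega_bg) return("stronger")
  "tie"
}

#' HKA window likelihood-ratio decision
#'
#' Decision rule for a 100-gene window tested with a
#' polymorphism/divergence (HKA) model: if the absolute log-likelihood of
#' the selection model exceeds that of the neutral model the window lacks
#' power and is not tested (`no_power`); otherwise a likelihood-ratio test
#' with degrees of freedom equal to the number of tandem duplicate genes in
#' the window decides between `different_rate` (p below `alpha`) and
#' `same_rate`.
#'
#' @param lnL_selection,lnL_neutral Model log-likelihoods.
#' @param n_tandem Number of tandem duplicate genes in the window (the LRT
#'   degrees of freedom; must be at least 1).
#' @param alpha Significance level (default 0.05).
#' @return list with `decision` and, when tested, `statistic`, `df`, `p`.
#' @export
hka_window_decision <- function(lnL_selection, lnL_neutral, n_tandem,
                                alpha = 0.05) {
  if (n_tandem < 1) stop("window has no tandem duplicate genes; not testable")
  if (abs(lnL_selection) > abs(lnL_neutral)) {
    return(list(decision = "no_power", statistic = NA_real_,
                df = n_tandem, p = NA_real_))
  }
  stat <- max(0, 2 * (lnL_selection - lnL_neutral))
  p <- pchisq(stat, df = n_tandem, lower.tail = FALSE)
  list(decision = if (p < alpha) "different_rate" else "same_rate",
       statistic = stat, df = n_tandem, p = p)
}
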