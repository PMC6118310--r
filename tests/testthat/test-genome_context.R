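# Base-level union oracle: logical coverage vector per chromosome.
oracle_density <- function(features, chrom, win_start, win_end) {
  covered <- logical(win_end - win_start + 1)
  f <- features[features$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(f))) {
    lo <- max(f$start[i], win_start)
    hi <- min(f$end[i], win_end)
    if (lo <= hi) covered[(lo:hi) - win_start + 1] <- TRUE
  }
  mean(covered)
}

test_that("window densities are base-level union proportions", {
  gs <- toy_gene_set(data.frame(
    gene_id = c("g1", "g2", "g3"), chrom = "chr1",
    start = c(1, 100001, 150001), end = c(200000, 250000, 350001),
    stringsAsFactors = FALSE))
  win <- compute_windows(gs, window_size = 1e6,
                         chrom_lengths = c(chr1 = 1e6))
  expect_equal(nrow(win), 1)
  # union of [1,200000], [100001,250000], [150001,350001] = [1,350001]
  expect_equal(win$gene_density, 350001 / 1e6)
  expect_equal(win$gene_density,
               oracle_density(gs$genes, "chr1", 1, 1e6))
})

test_that("trailing partial windows normalize by their actual width", {
  gs <- toy_gene_set(data.frame(
    gene_id = "g1", chrom = "chr1", start = 1000001, end = 1100000,
    stringsAsFactors = FALSE))
  win <- compute_windows(gs, window_size = 1e6,
                         chrom_lengths = c(chr1 = 1500000))
  expect_equal(win$width, c(1e6, 5e5))
  expect_equal(win$gene_density, c(0, 0.2))
})

test_that("subgenome labels follow majority base coverage with nonsyntenic ties", {
  gs <- toy_gene_set(data.frame(
    gene_id = "g1", chrom = "chr1", start = 1, end = 1000,
    stringsAsFactors = FALSE))
  blocks <- data.frame(chrom = "chr1",
                       start = c(1, 600001), end = c(600000, 900000),
                       label = c("maize1", "maize2"),
                       stringsAsFactors = FALSE)
  win <- compute_windows(gs, blocks = blocks, window_size = 1e6,
                         chrom_lengths = c(chr1 = 2e6))
  expect_equal(win$subgenome, c("maize1", "nonsyntenic"))
  # exact tie -> nonsyntenic
  blocks2 <- data.frame(chrom = "chr1", start = c(1, 500001),
                        end = c(500000, 1000000),
                        label = c("maize1", "maize2"),
                        stringsAsFactors = FALSE)
  win2 <- compute_windows(gs, blocks = blocks2, window_size = 1e6,
                          chrom_lengths = c(chr1 = 1e6))
  expect_equal(win2$subgenome, "nonsyntenic")
})

test_that("density conservation: widths times densities sum to union coverage", {
  set.seed(19)
  for (rep in 1:5) {
    n <- 30
    starts <- sample(1:4e6, n)
    gs <- toy_gene_set(data.frame(
      gene_id = sprintf("g%03d", 1:n), chrom = "chr1",
      start = starts, end = starts + sample(1000:300000, n),
      stringsAsFactors = FALSE))
    len <- max(gs$genes$end)
    win <- compute_windows(gs, window_size = 1e6,
                           chrom_lengths = c(chr1 = len))
    union_bp <- sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(gs$genes$start, gs$genes$end))))
    expect_equal(sum(win$width * win$gene_density), union_bp)
  }
})

sim_windows <- function(n, beta, sigma, seed) {
  set.seed(seed)
  s <- sample(c("maize1", "maize2", "nonsyntenic"), n, replace = TRUE)
  g <- runif(n, 0.1, 0.7)
  r <- runif(n, 0, 0.5)
  d <- runif(n, 0, 0.2)
  y <- beta["b0"] + beta["b1"] * g + beta["b2"] * r + beta["b3"] * d +
    ifelse(s == "maize2", beta["s2"], 0) +
    ifelse(s == "nonsyntenic", beta["s3"], 0) +
    rnorm(n, 0, sigma)
  data.frame(chrom = "chr1", start = 1, end = 2, width = 1,
             gene_density = g, tandem_density = y, rna_te_density = r,
             dna_te_density = d, subgenome = s, stringsAsFactors = FALSE)
}

test_that("noiseless windows recover the generating coefficients exactly", {
  beta <- c(b0 = 0.01, b1 = 0.3, b2 = 0.05, b3 = -0.04, s2 = -0.02,
            s3 = 0.015)
  win <- sim_windows(200, beta, sigma = 0, seed = 4)
  fit <- suppressWarnings(fit_density_glm(win))  # perfect-fit F warnings
  expect_equal(unname(fit$coefficients["(Intercept)"]), 0.01,
               tolerance = 1e-10)
  expect_equal(unname(fit$coefficients["gene_density"]), 0.3,
               tolerance = 1e-10)
  expect_equal(unname(fit$coefficients["subgenomemaize2"]), -0.02,
               tolerance = 1e-10)
  expect_equal(fit$variance_explained, 1, tolerance = 1e-9)
  expect_equal(unname(fitted(fit$fit) + fit$residuals),
               win$tandem_density)
})

test_that("nested-model comparison finds no interaction when none exists", {
  beta <- c(b0 = 0.01, b1 = 0.3, b2 = 0.05, b3 = -0.04, s2 = -0.02,
            s3 = 0.015)
  win <- sim_windows(400, beta, sigma = 0.01, seed = 8)
  base <- fit_density_glm(win)
  inter <- fit_density_glm(win, include_interaction = TRUE)
  expect_gte(inter$variance_explained, base$variance_explained)
  p <- anova_nested(base, inter)
  expect_gt(p, 0.001)  # no true interaction; should rarely be tiny
})

test_that("rank-deficient designs are reported, not silently dropped", {
  beta <- c(b0 = 0, b1 = 0.3, b2 = 0.05, b3 = -0.04, s2 = 0, s3 = 0)
  win <- sim_windows(50, beta, sigma = 0.01, seed = 2)
  win$dna_te_density <- win$rna_te_density  # perfectly collinear
  expect_error(fit_density_glm(win), "collinear")
})

test_that("tandem-proportion correlation handles degenerate inputs", {
  win <- data.frame(gene_density = c(0.2, 0.4, 0.6),
                    tandem_density = c(0.02, 0.04, 0.06))
  # constant tandem share -> zero variance -> flagged undefined
  out <- tandem_proportion_correlation(win)
  expect_true(out$undefined)
  # perfectly linear share
  win2 <- data.frame(gene_density = c(0.2, 0.4, 0.6, 0.8),
                     tandem_density = c(0.2, 0.4, 0.6, 0.8) *
                       c(0.1, 0.2, 0.3, 0.4))
  out2 <- tandem_proportion_correlation(win2)
  expect_equal(out2$r, 1, tolerance = 1e-9)
  expect_error(tandem_proportion_correlation(
    data.frame(gene_density = c(0, 0.2), tandem_density = c(0, 0.1))),
    "at least 3")
})
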