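small_cfg <- function(seed, ...) {
  sim_config(seed = seed, n_background_genes = 40, n_planted_clusters = 8,
             n_cassette_pairs = 1, ...)
}

test_that("the same seed reproduces identical bundles end to end", {
  s1 <- simulate_genotypes(small_cfg(101))
  s2 <- simulate_genotypes(small_cfg(101))
  expect_identical(s1$genotype_a$gene_set$genes, s2$genotype_a$gene_set$genes)
  expect_identical(as.character(s1$genotype_a$gene_set$cds),
                   as.character(s2$genotype_a$gene_set$cds))
  expect_identical(s1$genotype_b$tes, s2$genotype_b$tes)
  expect_identical(s1$homology, s2$homology)
  expect_identical(s1$truth$clusters, s2$truth$clusters)
  s3 <- simulate_genotypes(small_cfg(102))
  expect_false(identical(as.character(s1$genotype_a$gene_set$cds),
                         as.character(s3$genotype_a$gene_set$cds)))
})

test_that("age 0 plants identical copies with adjusted similarity 1", {
  plan <- data.frame(size = 2, age_my = 0, intervening = 0,
                     cassette_pair = NA_integer_, single_exon = FALSE)
  cfg <- sim_config(seed = 5, n_background_genes = 10,
                    planted_clusters = plan, n_cassette_pairs = 0)
  sim <- simulate_genotypes(cfg)
  tr <- sim$truth$clusters
  gid <- strsplit(tr$gene_ids[tr$genotype == "A"][1], ",")[[1]]
  sc <- gene_pair_similarity(sim$genotype_a$gene_set, gid[1], gid[2])
  expect_equal(sc$adjusted, 1.0)
})

test_that("pairwise divergence follows the Jukes-Cantor closed form", {
  # two copies evolved independently for time t at rate r differ per site
  # with probability (3/4)(1 - exp(-8rt/3))
  set.seed(77)
  r <- 0.0065
  t_my <- 8
  L <- 900
  p_exp <- 0.75 * (1 - exp(-8 * r * t_my / 3))
  diffs <- replicate(200, {
    anc <- random_cds_fixture(L / 3)
    c1 <- tandemscan:::mutate_jc(anc, r * t_my)
    c2 <- tandemscan:::mutate_jc(anc, r * t_my)
    sum(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  })
  n_sites <- 200 * L
  se <- sqrt(p_exp * (1 - p_exp) / n_sites)
  expect_lt(abs(mean(diffs) / L - p_exp), 4 * se)
})

test_that("the truth ledger is consistent with the emitted annotation", {
  sim <- simulate_genotypes(small_cfg(13))
  for (side in c("A", "B")) {
    bundle <- if (side == "A") sim$genotype_a else sim$genotype_b
    tr <- sim$truth$clusters[sim$truth$clusters$genotype == side, ]
    planted <- unlist(strsplit(tr$gene_ids, ","))
    expect_true(all(planted %in% bundle$gene_set$genes$gene_id))
  }
  # shared clusters appear in both ledgers and are homology-linked
  sh <- sim$truth$clusters[sim$truth$clusters$shared, ]
  both <- table(sh$truth_id)
  expect_true(all(both == 2))
  for (tid in unique(sh$truth_id)) {
    ga <- strsplit(sh$gene_ids[sh$truth_id == tid & sh$genotype == "A"],
                   ",")[[1]]
    gb <- strsplit(sh$gene_ids[sh$truth_id == tid & sh$genotype == "B"],
                   ",")[[1]]
    linked <- sim$homology$gene_a %in% ga & sim$homology$gene_b %in% gb
    expect_equal(sum(linked), length(ga))
  }
})

test_that("cassette plantings interleave coordinates (A1 < B1 < A2 < B2)", {
  sim <- simulate_genotypes(small_cfg(23))
  tr <- sim$truth$clusters
  cas <- tr[!is.na(tr$cassette_pair) & tr$genotype == "A", ]
  expect_gte(nrow(cas), 2)
  g <- sim$genotype_a$gene_set$genes
  for (cp in unique(cas$cassette_pair)) {
    members <- cas[cas$cassette_pair == cp, ]
    if (nrow(members) < 2) next
    sa <- sort(g$start[g$gene_id %in% strsplit(members$gene_ids[1], ",")[[1]]])
    sb <- sort(g$start[g$gene_id %in% strsplit(members$gene_ids[2], ",")[[1]]])
    expect_true(oracle_interleaved(sa, sb))
  }
})

test_that("planted TE configurations match their geometric definitions", {
  sim <- simulate_genotypes(small_cfg(31))
  bundle <- sim$genotype_a
  tp <- sim$truth$te_placements
  tp <- tp[tp$genotype == "A", ]
  expect_gte(nrow(tp), 12)
  g <- bundle$gene_set$genes
  te <- bundle$tes
  for (i in seq_len(nrow(tp))) {
    gi <- g[g$gene_id == tp$gene_id[i], ]
    ti <- te[te$te_id == tp$te_id[i], ]
    if (tp$config[i] == "contains") {
      expect_true(ti$start >= gi$start && ti$end <= gi$end)
    } else if (tp$config[i] == "captured") {
      expect_true(gi$start >= ti$start && gi$end <= ti$end)
    } else {
      overlap <- min(gi$end, ti$end) - max(gi$start, ti$start) + 1
      expect_gt(overlap, 0)
      expect_lt(overlap, gi$end - gi$start + 1)
      expect_false(ti$start >= gi$start && ti$end <= gi$end)
    }
  }
})

test_that("infeasible packing raises an error rather than overflowing", {
  cfg <- sim_config(seed = 1, n_background_genes = 400,
                    n_planted_clusters = 10, chromosome_length = 100000,
                    n_chromosomes = 1)
  expect_error(simulate_genotypes(cfg), "packing")
})

test_that("written bundles re-load into the same gene content", {
  sim <- simulate_genotypes(small_cfg(47))
  dir <- withr::local_tempdir()
  write_genome_bundle(sim$genotype_a, dir)
  gs <- read_genes(file.path(dir, "genes.gff3"), file.path(dir, "cds.fa"))
  orig <- sim$genotype_a$gene_set
  expect_equal(gs$genes$gene_id, orig$genes$gene_id)
  expect_equal(gs$genes$start, orig$genes$start)
  expect_equal(gs$genes$rank, orig$genes$rank)
  expect_identical(as.character(gs$cds), as.character(orig$cds))
  expect_equal(gs$genes$exon_count, orig$genes$exon_count)
  tes <- read_te_features(file.path(dir, "tes.gff3"))
  expect_equal(nrow(tes), nrow(sim$genotype_a$tes))
  blocks <- read_subgenome_blocks(file.path(dir, "blocks.bed"))
  expect_equal(blocks, sim$genotype_a$blocks)
})
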