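make_linear_gene_set <- function(n, chrom = "chr1") {
  toy_gene_set(data.frame(
    gene_id = sprintf("g%02d", seq_len(n)), chrom = chrom,
    start = seq_len(n) * 1000, end = seq_len(n) * 1000 + 500,
    stringsAsFactors = FALSE))
}

test_that("candidate pairs respect the intervening-gene bound exactly", {
  gs <- make_linear_gene_set(20)
  pairs <- candidate_pairs(gs, max_intervening = 15)
  key <- paste(pairs$gene_a, pairs$gene_b)
  # ranks 0 and 16: 15 intervening -> included
  expect_true("g01 g17" %in% key)
  # ranks 0 and 17: 16 intervening -> excluded
  expect_false("g01 g18" %in% key)
  expect_equal(max(pairs$n_intervening), 15)
  # 3 consecutive genes -> 3 pairs
  expect_equal(nrow(candidate_pairs(make_linear_gene_set(3))), 3)
  # pairs never span chromosomes
  gs2 <- toy_gene_set(data.frame(
    gene_id = c("a1", "b1"), chrom = c("chr1", "chr2"),
    start = c(100, 100), end = c(600, 600), stringsAsFactors = FALSE))
  expect_equal(nrow(candidate_pairs(gs2)), 0)
})

test_that("clusters are connected components over the similarity threshold", {
  gs <- make_linear_gene_set(4)
  scored <- data.frame(
    gene_a = c("g01", "g02", "g01", "g03"),
    gene_b = c("g02", "g03", "g03", "g04"),
    adjusted = c(0.4, 0.4, 0.1, 0.29), stringsAsFactors = FALSE)
  cl <- build_clusters(scored, gs)
  # chain g1-g2-g3 links despite weak g1-g3; g4 stays out (0.29 < 0.3)
  expect_equal(length(cluster_ids(cl)), 1)
  expect_setequal(cl$members$gene_id, c("g01", "g02", "g03"))

  # union-find oracle over the kept edges agrees with the components
  kept <- scored[scored$adjusted >= 0.3, ]
  parent <- setNames(unique(c(kept$gene_a, kept$gene_b)),
                     unique(c(kept$gene_a, kept$gene_b)))
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(nrow(kept))) {
    parent[find(kept$gene_a[i])] <- find(kept$gene_b[i])
  }
  roots <- vapply(names(parent), find, character(1))
  expect_equal(length(unique(roots)), length(cluster_ids(cl)))

  # a single strong pair forms a cluster; boundary value 0.3 is kept
  cl2 <- build_clusters(data.frame(gene_a = "g01", gene_b = "g02",
                                   adjusted = 0.3), gs)
  expect_equal(length(cluster_ids(cl2)), 1)
})

test_that("cluster subgenome labels come from majority midpoint, ties nonsyntenic", {
  gs <- make_linear_gene_set(4)
  blocks <- data.frame(chrom = "chr1",
                       start = c(1, 2600), end = c(2599, 10000),
                       label = c("maize1", "maize2"),
                       stringsAsFactors = FALSE)
  scored <- data.frame(gene_a = c("g01", "g02", "g03"),
                       gene_b = c("g02", "g03", "g04"),
                       adjusted = 0.9, stringsAsFactors = FALSE)
  cl <- build_clusters(scored, gs, blocks = blocks)
  # midpoints at 1250,2250 (maize1) and 3250,4250 (maize2): tie -> nonsyntenic
  expect_equal(unique(cl$members$subgenome), "nonsyntenic")
  # 3-1 majority
  blocks2 <- data.frame(chrom = "chr1", start = c(1, 3600),
                        end = c(3599, 10000),
                        label = c("maize1", "maize2"),
                        stringsAsFactors = FALSE)
  cl2 <- build_clusters(scored, gs, blocks = blocks2)
  expect_equal(unique(cl2$members$subgenome), "maize1")
})

test_that("candidate cluster validation keeps linked genes and merges", {
  gs <- make_linear_gene_set(6)
  scored <- data.frame(
    gene_a = c("g01", "g01", "g02", "g04"),
    gene_b = c("g02", "g03", "g03", "g05"),
    adjusted = c(0.8, 0.1, 0.2, 0.9), stringsAsFactors = FALSE)
  cand <- data.frame(cluster_id = c("s1", "s1", "s1", "s2", "s2"),
                     gene_id = c("g01", "g02", "g03", "g05", "g06"),
                     stringsAsFactors = FALSE)
  # s1: only g01-g02 passes -> {g01,g02}; s2: no passing pair -> dropped
  out <- validate_candidate_clusters(cand, scored, gs)
  expect_equal(length(cluster_ids(out)), 1)
  expect_setequal(out$members$gene_id, c("g01", "g02"))

  # merging with adjacency clusters dedups shared membership
  adj <- build_clusters(scored, gs)  # {g01,g02} and {g04,g05}
  merged <- validate_candidate_clusters(cand, scored, gs,
                                        adjacency_clusters = adj)
  expect_equal(length(cluster_ids(merged)), 2)
  expect_error(validate_candidate_clusters(
    data.frame(cluster_id = "x", gene_id = c("g01", "nope")), scored, gs),
    "nope")
})

test_that("cassette detection handles the canonical layouts", {
  # interleaved A1 B1 A2 B2
  cas <- detect_cassettes(clusters_from_starts(list(c(100, 300),
                                                    c(200, 400))))
  expect_equal(length(unique(cas$cassette_id)), 1)
  expect_equal(nrow(cas), 2)
  # fully nested B inside A -> no cassette
  expect_equal(nrow(detect_cassettes(clusters_from_starts(
    list(c(100, 400), c(200, 300))))), 0)
  # disjoint -> no cassette
  expect_equal(nrow(detect_cassettes(clusters_from_starts(
    list(c(100, 200), c(300, 400))))), 0)
  # nested span with alternating genes still counts as nested
  expect_equal(nrow(detect_cassettes(clusters_from_starts(
    list(c(100, 250, 400), c(200, 300))))), 0)
  # three-way chain A-B, B-C interleaved -> one 3-cluster cassette
  cas3 <- detect_cassettes(clusters_from_starts(
    list(c(100, 300), c(200, 500), c(400, 600))))
  expect_equal(length(unique(cas3$cassette_id)), 1)
  expect_equal(nrow(cas3), 3)
})

test_that("clusters spanning two chromosomes never form one cassette", {
  m1 <- clusters_from_starts(list(c(100, 300)), chrom = "chr1")$members
  m2 <- clusters_from_starts(list(c(200, 400)), chrom = "chr2")$members
  m2$cluster_id <- "C99"
  m2$gene_id <- paste0("x", seq_len(nrow(m2)))
  cl <- tandemscan:::new_tandem_clusters(rbind(m1, m2))
  expect_equal(nrow(detect_cassettes(cl)), 0)
})

test_that("every reported cluster has a linking pair within the rank bound", {
  sim <- simulate_genotypes(sim_config(seed = 3, n_background_genes = 60,
                                       n_planted_clusters = 10))
  ga <- sim$genotype_a
  pairs <- candidate_pairs(ga$gene_set)
  scored <- score_pairs(ga$gene_set, pairs)
  cl <- build_clusters(scored, ga$gene_set)
  strong <- scored[!is.na(scored$adjusted) & scored$adjusted >= 0.3, ]
  for (cid in cluster_ids(cl)) {
    members <- cl$members$gene_id[cl$members$cluster_id == cid]
    has_link <- any(strong$gene_a %in% members & strong$gene_b %in% members)
    expect_true(has_link)
  }
})
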