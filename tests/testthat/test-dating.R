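test_that("TMRCA is read off dated trees for all tip configurations", {
  # ultrametric tree in MY: ((a:2,b:2):10,out:12);
  tree <- ape::read.tree(text = "((a:2,b:2):10,out:12);")
  expect_equal(tmrca_from_dated_tree(tree, "a", "b"), 2)
  expect_equal(tmrca_from_dated_tree(tree, "a", "out"), 12)
  tree2 <- ape::read.tree(text = "(((a:1,b:1):4,c:5):6.9,out:11.9);")
  expect_equal(tmrca_from_dated_tree(tree2, "a", "out"), 11.9)
  expect_equal(tmrca_from_dated_tree(tree2, "b", "c"), 5)
  expect_error(tmrca_from_dated_tree(tree, "a", "zzz"), "zzz")
})

test_that("clock calibration is exact at the anchors and scale-invariant", {
  expect_equal(clock_calibrated_age(0.1, 0.1), 12)
  expect_equal(clock_calibrated_age(0, 0.2), 0)
  expect_equal(clock_calibrated_age(0.05, 0.2, calibration_my = 12), 3)
  # scale invariance
  expect_equal(clock_calibrated_age(0.03, 0.12),
               clock_calibrated_age(0.03 * 7, 0.12 * 7))
  expect_error(clock_calibrated_age(0.1, 0), "positive")
})

test_that("JC distance corrects observed differences and flags saturation", {
  expect_equal(jc_distance("AAAA", "AAAA"), 0)
  p <- 0.1
  d <- jc_distance(paste(rep("A", 100), collapse = ""),
                   paste(c(rep("C", 10), rep("A", 90)), collapse = ""))
  expect_equal(d, -0.75 * log(1 - 4 * p / 3))
  # gaps and ambiguity codes drop out of the denominator
  expect_equal(jc_distance("AC-GN", "AC-GA"), 0)
  expect_equal(jc_distance("AAAC", "AAA-"), 0)
  expect_true(is.infinite(jc_distance("AAAA", "CCCC")))
})

test_that("age classes split at 2 and 10 MY inclusive", {
  expect_equal(age_class(c(0, 2, 2.01, 9.99, 10, 15)),
               c("recent", "recent", "intermediate", "intermediate",
                 "ancient", "ancient"))
})

test_that("cluster ages recover planted ages through the outgroup calibration", {
  plan <- data.frame(size = 2, age_my = c(1, 11), intervening = 0,
                     cassette_pair = NA_integer_, single_exon = FALSE)
  cfg <- sim_config(seed = 61, n_background_genes = 10,
                    planted_clusters = plan, n_cassette_pairs = 0,
                    cds_codon_range = c(1000, 1000))
  sim <- simulate_genotypes(cfg)
  pairs <- candidate_pairs(sim$genotype_a$gene_set)
  scored <- score_pairs(sim$genotype_a$gene_set, pairs)
  cl <- build_clusters(scored, sim$genotype_a$gene_set)
  mt <- match_clusters_to_truth(cl, sim$truth, "A")
  expect_true(all(mt$exact))
  og <- sim$genotype_a$outgroup_map
  names(og) <- mt$cluster_id[match(names(og), mt$truth_id)]
  gs <- sim$genotype_a$gene_set
  gs$cds <- c(gs$cds, sim$genotype_a$outgroup_cds)
  ages <- cluster_clock_ages(gs, cl, og)
  truth_a <- sim$truth$clusters[sim$truth$clusters$genotype == "A", ]
  got <- ages$tmrca_my[match(mt$cluster_id[match(truth_a$truth_id,
                                                 mt$truth_id)],
                             ages$cluster_id)]
  expect_true(all(abs(got - truth_a$age_my) < 1.5))
  expect_equal(ages$age_class[order(ages$tmrca_my)],
               c("recent", "ancient"))
})

test_that("event deduplication counts shared once and is idempotent", {
  cl_a <- clusters_from_starts(list(c(100, 300), c(5000, 5400)))
  m_b <- clusters_from_starts(list(c(200, 500), c(9000, 9300)))$members
  m_b$gene_id <- paste0("B", m_b$gene_id)
  cl_b <- tandemscan:::new_tandem_clusters(m_b)
  # link first clusters of each genotype; second clusters stay private
  hom <- data.frame(gene_a = "C01_g1", gene_b = "BC01_g1",
                    stringsAsFactors = FALSE)
  ev <- deduplicate_events(cl_a, cl_b, hom)
  expect_equal(nrow(ev), 3)  # 1 shared + 1 private A + 1 private B
  expect_equal(sum(ev$shared), 1)
  ev2 <- deduplicate_events(cl_a, cl_b, hom)
  expect_identical(ev, ev2)
  # shared event TMRCA is the mean of the genotype estimates
  ages_a <- data.frame(cluster_id = "C01", tmrca_my = 4)
  ages_b <- data.frame(cluster_id = "C01", tmrca_my = 6)
  ev3 <- deduplicate_events(cl_a, cl_b, hom, ages_a, ages_b)
  expect_equal(ev3$tmrca_my[ev3$shared], 5)
  # no homology -> all private
  ev4 <- deduplicate_events(cl_a, cl_b, hom[0, ])
  expect_equal(nrow(ev4), 4)
  expect_false(any(ev4$shared))
})

test_that("GC content excludes ambiguity codes from the denominator", {
  expect_equal(gc_content("GGCC"), 1)
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("ATGC"), 0.5)
  expect_equal(gc_content("ATGCNNNN"), 0.5)
  expect_true(is.na(gc_content("NNNN")))
  expect_equal(gc_content(c("GG", "AT")), c(1, 0))
  expect_error(gc_content(""), "empty")
})

test_that("age distributions bin events and cross-tabulate classes", {
  ev <- data.frame(
    event_id = sprintf("E%d", 1:4),
    cluster_a = "x", cluster_b = "y",
    shared = c(TRUE, TRUE, FALSE, FALSE),
    tmrca_my = c(1, 1.2, 11, 12.5),
    age_class = age_class(c(1, 1.2, 11, 12.5)),
    subgenome = c("maize1", "maize1", "maize2", "nonsyntenic"),
    stringsAsFactors = FALSE)
  dist <- age_distribution(ev, bin_width = 1)
  occupied <- dist$histogram$bin_start[dist$histogram$count > 0]
  expect_equal(occupied, c(1, 11, 12))
  expect_equal(sum(dist$histogram$count), 4)
  cnt <- dist$counts
  expect_equal(cnt$n[cnt$shared == "shared" & cnt$subgenome == "maize1" &
                       cnt$age_class == "recent"], 2)
  empty <- age_distribution(ev[0, ])
  expect_equal(nrow(empty$histogram), 0)
})
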