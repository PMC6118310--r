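two_genotype_clusters <- function() {
  cl_a <- clusters_from_starts(list(c(100, 300), c(5000, 5400),
                                    c(9000, 9500, 9900)))
  m_b <- clusters_from_starts(list(c(150, 350), c(7000, 7500)))$members
  m_b$gene_id <- paste0("B", m_b$gene_id)
  cl_b <- tandemscan:::new_tandem_clusters(m_b)
  list(a = cl_a, b = cl_b)
}

test_that("cluster links and shared/private counts are per-genotype", {
  cl <- two_genotype_clusters()
  hom <- data.frame(
    gene_a = c("C01_g1", "C03_g1"),
    gene_b = c("BC01_g1", "BC01_g2"), stringsAsFactors = FALSE)
  out <- link_clusters(cl$a, cl$b, hom)
  # A clusters C01 and C03 both link to B cluster C01
  expect_equal(nrow(out$links), 2)
  expect_equal(out$counts$shared, c(2, 1))
  expect_equal(out$counts$private, c(1, 1))
  expect_equal(out$counts$total, c(3, 2))
  expect_equal(out$counts$shared + out$counts$private, out$counts$total)
})

test_that("size concordance puts one increment per link", {
  cl <- two_genotype_clusters()
  hom <- data.frame(
    gene_a = c("C01_g1", "C03_g1"),
    gene_b = c("BC01_g1", "BC01_g2"), stringsAsFactors = FALSE)
  links <- link_clusters(cl$a, cl$b, hom)$links
  m <- size_concordance(links, cl$a, cl$b)
  expect_equal(sum(m), nrow(links))
  expect_equal(m[2, 2], 1L)  # size-2 A cluster vs size-2 B cluster
  expect_equal(m[3, 2], 1L)  # size-3 A cluster vs size-2 B cluster
  # swapping genotypes transposes the matrix
  links_t <- data.frame(cluster_a = links$cluster_b,
                        cluster_b = links$cluster_a,
                        n_linked_genes = links$n_linked_genes)
  expect_equal(unname(size_concordance(links_t, cl$b, cl$a)), unname(t(m)))
})

test_that("cassette sharing requires two linked member clusters", {
  # two interleaved clusters per genotype forming one cassette each
  cl_a <- clusters_from_starts(list(c(100, 300), c(200, 400)))
  m_b <- clusters_from_starts(list(c(100, 300), c(200, 400)))$members
  m_b$gene_id <- paste0("B", m_b$gene_id)
  cl_b <- tandemscan:::new_tandem_clusters(m_b)
  cas_a <- detect_cassettes(cl_a)
  cas_b <- detect_cassettes(cl_b)
  hom2 <- data.frame(gene_a = c("C01_g1", "C02_g1"),
                     gene_b = c("BC01_g1", "BC02_g1"),
                     stringsAsFactors = FALSE)
  links <- link_clusters(cl_a, cl_b, hom2)$links
  shared <- compare_cassettes(cas_a, cas_b, links, cl_a, cl_b)
  expect_equal(nrow(shared), 1)
  expect_false(shared$composition_differs[1])
  counts <- attr(shared, "counts")
  expect_equal(counts$shared, c(1, 1))
  # only one member linked -> not shared
  links1 <- links[1, , drop = FALSE]
  shared1 <- compare_cassettes(cas_a, cas_b, links1, cl_a, cl_b)
  expect_equal(nrow(shared1), 0)
  expect_equal(attr(shared1, "counts")$private, c(1, 1))
})

test_that("composition differences flag missing or resized member clusters", {
  cl_a <- clusters_from_starts(list(c(100, 300, 600), c(200, 700)))
  m_b <- clusters_from_starts(list(c(100, 300), c(200, 400)))$members
  m_b$gene_id <- paste0("B", m_b$gene_id)
  cl_b <- tandemscan:::new_tandem_clusters(m_b)
  cas_a <- detect_cassettes(cl_a)
  cas_b <- detect_cassettes(cl_b)
  hom <- data.frame(gene_a = c("C01_g1", "C02_g1"),
                    gene_b = c("BC01_g1", "BC02_g1"),
                    stringsAsFactors = FALSE)
  links <- link_clusters(cl_a, cl_b, hom)$links
  shared <- compare_cassettes(cas_a, cas_b, links, cl_a, cl_b)
  expect_equal(nrow(shared), 1)
  expect_true(shared$composition_differs[1])  # sizes (3,2) vs (2,2)
})

test_that("exon summaries flag single-exon and mixed clusters", {
  gs <- toy_gene_set(data.frame(
    gene_id = c("g1", "g2", "g3", "g4", "g5"), chrom = "chr1",
    start = c(100, 900, 2000, 3000, 4000),
    end = c(600, 1500, 2700, 3800, 4300),
    exon_count = c(1L, 5L, 3L, 4L, 2L), stringsAsFactors = FALSE))
  members <- data.frame(
    cluster_id = c("c1", "c1", "c2", "c2"),
    gene_id = c("g1", "g2", "g3", "g4"),
    chrom = "chr1", start = c(100, 900, 2000, 3000),
    end = c(600, 1500, 2700, 3800), rank = NA_integer_,
    subgenome = "nonsyntenic", stringsAsFactors = FALSE)
  cl <- tandemscan:::new_tandem_clusters(members)
  out <- gene_summary_stats(gs, cl)
  expect_equal(out$genes$tandem, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  f <- out$cluster_flags
  expect_true(f$mixed_exon[f$cluster_id == "c1"])   # exons {1,5}
  expect_true(f$has_single_exon[f$cluster_id == "c1"])
  expect_false(f$has_single_exon[f$cluster_id == "c2"])  # exons {3,4}
  expect_true(f$all_multi_exon[f$cluster_id == "c2"])
  expect_equal(out$genes$length[1], 501)
})

test_that("planted single-exon fraction is recovered from the simulation", {
  cfg <- sim_config(seed = 83, n_background_genes = 60,
                    n_planted_clusters = 20, single_exon_fraction = 0.25)
  sim <- simulate_genotypes(cfg)
  pairs <- candidate_pairs(sim$genotype_a$gene_set)
  scored <- score_pairs(sim$genotype_a$gene_set, pairs)
  cl <- build_clusters(scored, sim$genotype_a$gene_set)
  flags <- gene_summary_stats(sim$genotype_a$gene_set, cl)$cluster_flags
  truth_a <- sim$truth$clusters[sim$truth$clusters$genotype == "A", ]
  frac <- mean(flags$has_single_exon)
  # binomial error around the planted per-cluster probability
  n <- nrow(flags)
  expect_lt(abs(frac - mean(truth_a$single_exon)), 3 * sqrt(0.25 * 0.75 / n))
})
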