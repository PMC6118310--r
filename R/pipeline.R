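# End-to-end orchestration: one entry point composing the stages in
# analysis order, writing stable TSV outputs and a manifest. No stage logic
# lives here; run_all() only calls the exported stage functions.

#' Pipeline run configuration
#'
#' Thresholds default to the analysis' canonical values: up to 15
#' intervening genes, adjusted similarity at least 0.3, 1-Mb windows, a
#' 12-MY outgroup calibration, ancient/recent age classes at 10/2 MY,
#' orthogroup sizes 10-75, and the 50%-gap / 8-species column filter.
#'
#' @param seed Integer seed (drives simulation when `simulate = TRUE`).
#' @param simulate Simulate the two genotypes instead of reading inputs.
#' @param sim A `sim_config` used when `simulate = TRUE`; its seed is
#'   overridden by `seed`.
#' @param inputs Named list of file paths (used when `simulate = FALSE`):
#'   `gff_a`, `cds_a`, `te_gff_a`, `blocks_a`, and the `_b` equivalents,
#'   plus `homology`.
#' @param out_dir Output directory.
#' @param max_intervening,min_similarity,window_size,calibration_my
#'   Stage thresholds (see Details).
#' @param model_table Optional path to a per-orthogroup clade-model TSV for
#'   the relative-rates stage.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1, simulate = TRUE, sim = sim_config(seed),
                       inputs = list(), out_dir = "tandemscan_out",
                       max_intervening = 15, min_similarity = 0.3,
                       window_size = 1e6, calibration_my = 12,
                       model_table = NULL) {
  stopifnot(max_intervening >= 0, min_similarity > 0, window_size > 0,
            calibration_my > 0)
  sim$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), simulate = simulate, sim = sim,
                 inputs = inputs, out_dir = out_dir,
                 max_intervening = max_intervening,
                 min_similarity = min_similarity, window_size = window_size,
                 calibration_my = calibration_my,
                 model_table = model_table),
            class = "run_config")
}

# Detect clusters + cassettes for one genotype bundle.
#' @noRd
genotype_stage <- function(bundle, cfg, id_prefix) {
  pairs <- candidate_pairs(bundle$gene_set, cfg$max_intervening)
  scored <- score_pairs(bundle$gene_set, pairs)
  clusters <- build_clusters(scored, bundle$gene_set,
                             min_adjusted = cfg$min_similarity,
                             blocks = bundle$blocks, id_prefix = id_prefix)
  cassettes <- detect_cassettes(clusters)
  list(scored = scored, clusters = clusters, cassettes = cassettes)
}

#' Run the full analysis end to end
#'
#' Executes similarity scoring, cluster and cassette detection for both
#' genotypes, window densities and the density GLM, TE
#' containment/capture, clock dating and event deduplication, the
#' cross-genotype comparison, and (when a model table is supplied) the
#' relative-rates classification. All outputs are written as TSV/JSON under
#' `config$out_dir`; re-running with the same config and seed reproduces
#' byte-identical files.
#'
#' @param config A `run_config`.
#' @return Invisibly, a manifest list (also written as `manifest.json`)
#'   with parameters, input provenance, and per-output row counts.
#' @export
run_all <- function(config) {
  stopifnot(is(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  if (config$simulate) {
    sim <- stage("simulate", simulate_genotypes(config$sim))
    ga <- sim$genotype_a; gb <- sim$genotype_b
    homology <- sim$homology
  } else {
    req <- c("gff_a", "cds_a", "gff_b", "cds_b", "homology")
    miss <- setdiff(req, names(config$inputs))
    if (length(miss) > 0) stop("missing input path(s): ",
                               paste(miss, collapse = ", "))
    load_bundle <- function(side) {
      gs <- read_genes(config$inputs[[paste0("gff_", side)]],
                       config$inputs[[paste0("cds_", side)]])
      te_path <- config$inputs[[paste0("te_gff_", side)]]
      bl_path <- config$inputs[[paste0("blocks_", side)]]
      structure(list(
        genotype = toupper(side), gene_set = gs,
        tes = if (is.null(te_path)) NULL else read_te_features(te_path),
        blocks = if (is.null(bl_path)) NULL else
          read_subgenome_blocks(bl_path),
        outgroup_cds = NULL, outgroup_map = NULL), class = "genome_bundle")
    }
    ga <- stage("load_a", load_bundle("a"))
    gb <- stage("load_b", load_bundle("b"))
    homology <- stage("load_homology", read_homology(config$inputs$homology))
    sim <- NULL
  }

  sa <- stage("clusters_a", genotype_stage(ga, config, "TDA"))
  sb <- stage("clusters_b", genotype_stage(gb, config, "TDB"))
  write_clusters(sa$clusters, file.path(config$out_dir, "clusters_a.tsv"))
  write_clusters(sb$clusters, file.path(config$out_dir, "clusters_b.tsv"))
  write_tsv_stable(sa$cassettes, file.path(config$out_dir, "cassettes_a.tsv"))
  write_tsv_stable(sb$cassettes, file.path(config$out_dir, "cassettes_b.tsv"))

  tandem_a <- unique(sa$clusters$members$gene_id)
  windows <- stage("densities", compute_windows(
    ga$gene_set, ga$tes, tandem_a, ga$blocks, config$window_size))
  win_out <- windows
  win_out[c("gene_density", "tandem_density", "rna_te_density",
            "dna_te_density")] <-
    lapply(win_out[c("gene_density", "tandem_density", "rna_te_density",
                     "dna_te_density")], function(x) sprintf("%.8f", x))
  write_tsv_stable(win_out, file.path(config$out_dir, "windows_a.tsv"))
  glm_fit <- stage("glm", fit_density_glm(windows))

  te_rel <- stage("te_overlap", classify_relations(ga$gene_set$genes, ga$tes))
  te_counts <- count_table(te_rel, ga$gene_set$genes, tandem_a)
  write_tsv_stable(te_rel, file.path(config$out_dir, "te_relations_a.tsv"))
  write_tsv_stable(te_counts$table,
                   file.path(config$out_dir, "te_counts_a.tsv"))

  ages_a <- ages_b <- NULL
  if (!is.null(ga$outgroup_map)) {
    og_a <- ga$outgroup_map
    names(og_a) <- truth_cluster_lookup(sa$clusters, sim$truth, "A")[names(og_a)]
    og_a <- og_a[!is.na(names(og_a))]
    ages_a <- stage("dating_a", cluster_clock_ages(
      merge_cds(ga), sa$clusters, og_a, config$calibration_my))
    og_b <- gb$outgroup_map
    names(og_b) <- truth_cluster_lookup(sb$clusters, sim$truth, "B")[names(og_b)]
    og_b <- og_b[!is.na(names(og_b))]
    ages_b <- stage("dating_b", cluster_clock_ages(
      merge_cds(gb), sb$clusters, og_b, config$calibration_my))
    write_age_table(ages_a, file.path(config$out_dir, "ages_a.tsv"))
    write_age_table(ages_b, file.path(config$out_dir, "ages_b.tsv"))
  }

  events <- stage("dedup", deduplicate_events(sa$clusters, sb$clusters,
                                              homology, ages_a, ages_b))
  ev_out <- events
  ev_out$tmrca_my <- ifelse(is.na(events$tmrca_my), NA,
                            sprintf("%.4f", events$tmrca_my))
  write_tsv_stable(ev_out, file.path(config$out_dir, "events.tsv"))

  links <- stage("compare", link_clusters(sa$clusters, sb$clusters, homology))
  write_tsv_stable(links$links, file.path(config$out_dir, "cluster_links.tsv"))
  write_tsv_stable(links$counts, file.path(config$out_dir, "share_counts.tsv"))
  conc <- size_concordance(links$links, sa$clusters, sb$clusters)
  conc_df <- as.data.frame(as.table(conc), stringsAsFactors = FALSE)
  names(conc_df) <- c("size_a", "size_b", "n")
  write_tsv_stable(conc_df, file.path(config$out_dir, "size_matrix.tsv"))
  cas_cmp <- stage("cassette_compare", compare_cassettes(
    sa$cassettes, sb$cassettes, links$links, sa$clusters, sb$clusters))
  write_tsv_stable(cas_cmp, file.path(config$out_dir, "cassette_shared.tsv"))

  stats_a <- gene_summary_stats(ga$gene_set, sa$clusters)
  write_tsv_stable(stats_a$cluster_flags,
                   file.path(config$out_dir, "cluster_exon_flags_a.tsv"))

  rates <- NULL
  if (!is.null(config$model_table)) {
    models <- read_tsv_plain(config$model_table)
    rates <- stage("rates", select_best_model(models))
    rates$constraint <- vapply(seq_len(nrow(rates)), function(i) {
      if (rates$best_model[i] %in% c(3, 4)) {
        classify_constraint(rates$omega_fg[i], rates$omega_bg[i])
      } else NA_character_
    }, character(1))
    write_tsv_stable(rates, file.path(config$out_dir, "rates.tsv"))
  }

  outputs <- list.files(config$out_dir, pattern = "\\.tsv$")
  manifest <- list(
    package = "tandemscan",
    version = as.character(utils::packageVersion("tandemscan")),
    parameters = list(
      seed = config$seed, simulate = config$simulate,
      max_intervening = config$max_intervening,
      min_similarity = config$min_similarity,
      window_size = config$window_size,
      calibration_my = config$calibration_my),
    summary = list(
      n_clusters_a = length(cluster_ids(sa$clusters)),
      n_clusters_b = length(cluster_ids(sb$clusters)),
      n_tandem_genes_a = length(tandem_a),
      n_cassettes_a = length(unique(sa$cassettes$cassette_id)),
      n_cassettes_b = length(unique(sb$cassettes$cassette_id)),
      n_events = nrow(events),
      glm_r_squared = round(glm_fit$variance_explained, 6)),
    rows = lapply(setNames(outputs, outputs), function(f) {
      length(readLines(file.path(config$out_dir, f))) - 1L
    })
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# gene_set whose CDS set also carries the bundle's outgroup records, so
# cluster_clock_ages can resolve outgroup ids.
#' @noRd
merge_cds <- function(bundle) {
  gs <- bundle$gene_set
  gs$cds <- c(gs$cds, bundle$outgroup_cds)
  gs
}

# named vector: truth_id -> detected cluster id (NA when not recovered)
#' @noRd
truth_cluster_lookup <- function(clusters, truth, genotype) {
  mt <- match_clusters_to_truth(clusters, truth, genotype)
  setNames(mt$cluster_id, mt$truth_id)
}

#' @noRd
write_age_table <- function(ages, path) {
  out <- ages
  for (cl in c("d_pair", "d_outgroup", "tmrca_my")) {
    out[[cl]] <- sprintf("%.6f", ages[[cl]])
  }
  write_tsv_stable(out, path)
}
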