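# End-to-end orchestration: simulate -> process -> assign -> profile ->
# analyze -> sweep, with deterministic seeds and a machine-readable run
# manifest.

#' Pipeline configuration
#'
#' Validates the full parameter set of a pipeline run; unknown keys are
#' rejected. Defaults follow the standard filtering chain: mean quality
#' >= 40, length >= 80 bp, total count >= 10, denoise ratio 0.5, 1%
#' working threshold, 999 PERMANOVA permutations, 10000 overlap-null
#' iterations.
#'
#' @param ... Named parameters overriding the defaults listed above
#'   (`seed`, `min_quality`, `min_length`, `min_total`, `denoise_ratio`,
#'   `denoise_max_dist`, `threshold`, `sweep_thresholds`, `n_perm`,
#'   `n_iter`, `n_null`, `resolution`, and the `simulate_*` sizes).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    min_quality = 40, min_length = 80, min_total = 10,
    denoise_ratio = 0.5, denoise_max_dist = 1,
    threshold = 0.01,
    sweep_thresholds = c(1e-4, 5e-4, 1e-3, 5e-3, 1e-2),
    n_perm = 999, n_iter = 10000, n_null = 199,
    resolution = "both",
    simulate_n_deer = 47, simulate_n_cattle = 32, simulate_n_negatives = 7,
    simulate_n_taxa = 30, simulate_n_families = 15,
    simulate_mean_depth = 1000, simulate_error_rate = 0.001,
    simulate_contamination_rate = 0.02, simulate_negative_depth = 30,
    use_reads = FALSE
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown configuration keys: ",
                 paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, override)
  stopifnot(
    cfg$min_quality >= 0, cfg$min_length >= 0, cfg$min_total >= 0,
    cfg$denoise_ratio > 0, cfg$denoise_ratio <= 1,
    cfg$threshold >= 0, cfg$threshold < 1,
    cfg$n_perm >= 1, cfg$n_iter >= 1, cfg$n_null >= 1,
    cfg$resolution %in% c("motu", "family", "both")
  )
  structure(cfg, class = "pipeline_config")
}

#' Run the full diet-analysis pipeline on synthetic data
#'
#' Generates a study-shaped synthetic dataset, runs the processing chain
#' (read-level when `use_reads` is on, otherwise the direct count table),
#' removes contaminated samples against the negative controls, applies
#' the working threshold, and computes RRA profiles, diversity, overlap,
#' PERMANOVA/NMDS and the threshold sweep. When `out_dir` is given, all
#' result tables are written there along with a JSON run manifest of
#' seeds and parameters.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return A named list of results: `report`, `table`, `rra`,
#'   `family_rra`, `diversity`, `diversity_tests`, `overlap`,
#'   `permanova`, `nmds`, `sweep`, plus the generating `study` inputs.
#' @export
run_diet_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- as.integer(config$seed)
  study <- simulate_study(
    seed = seed,
    n_deer = config$simulate_n_deer, n_cattle = config$simulate_n_cattle,
    n_negatives = config$simulate_n_negatives,
    n_taxa = config$simulate_n_taxa,
    n_families = config$simulate_n_families,
    mean_depth = config$simulate_mean_depth,
    error_rate = config$simulate_error_rate,
    contamination_rate = config$simulate_contamination_rate,
    negative_depth = config$simulate_negative_depth,
    reads = config$use_reads
  )

  if (config$use_reads) {
    proc <- process_reads(
      study$reads, study$manifest,
      min_quality = config$min_quality, min_len = config$min_length,
      min_total = config$min_total, max_dist = config$denoise_max_dist,
      ratio = config$denoise_ratio
    )
    table <- assign_exact(proc$derep, study$db, study$manifest)
    report <- proc$report
  } else {
    table <- attach_taxonomy(study$table, study$db)
    report <- build_report(c(raw = sum(table$count)))
  }

  nc <- negative_control_filter(table)
  table <- nc$table
  table <- apply_threshold(table, config$threshold)
  fam_table <- aggregate_family(table)

  rra <- compute_rra(table)
  family_rra <- compute_rra(fam_table)
  diversity <- diversity_report(table, tree = study$tree,
                                n_null = config$n_null, seed = seed + 10L)
  diversity_tests <- compare_sample_diversity(table)
  overlap <- dplyr::bind_rows(
    overlap_report(table, n_iter = config$n_iter, seed = seed + 20L),
    overlap_report(fam_table, n_iter = config$n_iter, seed = seed + 21L)
  )
  d <- bc_dissimilarity_matrix(table)
  perma <- permanova(d, n_perm = config$n_perm, seed = seed + 30L)
  ord <- nmds(d, seed = seed + 31L)
  sweep <- threshold_sweep(table, config$sweep_thresholds,
                           seed = seed + 40L)

  out <- list(
    study = study, report = report, table = table,
    removed_samples = nc$removed,
    rra = rra, family_rra = family_rra,
    diversity = diversity, diversity_tests = diversity_tests,
    overlap = overlap, permanova = perma, nmds = ord, sweep = sweep
  )
  if (!is.null(out_dir)) write_pipeline_outputs(out, config, out_dir)
  out
}

write_pipeline_outputs <- function(out, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(out$report, file.path(out_dir, "table1_accounting.tsv"))
  readr::write_tsv(out$diversity, file.path(out_dir, "table2_diversity.tsv"))
  readr::write_tsv(out$sweep, file.path(out_dir, "fig2_sweep.tsv"))
  readr::write_tsv(dplyr::bind_rows(out$rra, out$family_rra),
                   file.path(out_dir, "fig3_rra.tsv"))
  readr::write_tsv(tidy(out$nmds), file.path(out_dir, "fig4_nmds.tsv"))
  jsonlite::write_json(
    c(as.list(glance(out$permanova))),
    file.path(out_dir, "fig4_permanova.json"),
    auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(
    lapply(split(out$overlap, seq_len(nrow(out$overlap))), as.list),
    file.path(out_dir, "fig5_overlap.json"),
    auto_unbox = TRUE, digits = NA
  )
  write_motu_tsv(out$table, file.path(out_dir, "motu_table.tsv"))
  manifest <- list(
    package = "dietniche",
    version = as.character(utils::packageVersion("dietniche")),
    parameters = unclass(config),
    n_samples_retained = dplyr::n_distinct(out$table$sample_id),
    removed_samples = out$removed_samples
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
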