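#' Full model run with replicate averaging
#'
#' Orchestrates a complete analysis: the mutation-spectrum table, replicate
#' cohort simulations with all five strategies under common random numbers,
#' averaged detection and cost-effectiveness tables, the probabilistic
#' sensitivity analysis with its acceptability curves, and the one-way
#' tornado analysis. All artifacts are written to `out_dir` as CSV plus a
#' JSON manifest that records the config digest and seeds needed to
#' reproduce the outputs bitwise.
#'
#' @param config an `ls_config`.
#' @param replicates number of replicate cohorts averaged for the detection
#'   and ICER tables.
#' @param seed integer seed.
#' @param out_dir output directory (created if absent); `NULL` skips writing.
#' @param psa_draws PSA draws (0 skips the PSA and CEAC).
#' @param tornado_replicates replicate cohorts per tornado evaluation
#'   (0 skips the tornado).
#' @param thresholds CEAC willingness-to-pay grid.
#' @param n_patients optional reduced cohort size for the PSA/tornado stages.
#' @return list of class `ls_run`: `spectrum`, `detection` (averaged
#'   Table-2 analog), `icer` (averaged Table-3 analog), `ceac`, `tornado`,
#'   `manifest`.
#' @export
full_run <- function(config, replicates = 10, seed = 1, out_dir = NULL,
                     psa_draws = 0, tornado_replicates = 0,
                     thresholds = seq(0, 200000, by = 5000),
                     n_patients = NULL) {
  stopifnot(replicates >= 1)
  problems <- validate_config(config)
  if (length(problems)) {
    stop("invalid config: ", problems[1], call. = FALSE)
  }

  spectrum <- pooled_gene_proportions(mmr_study_counts()) |>
    dplyr::mutate(weighted_proportion = normalize_proportions(.data$pooled))

  evals <- purrr::map(seq_len(replicates),
                      function(rep) evaluate_strategies(config, seed + rep))
  detection <- dplyr::bind_rows(evals) |>
    dplyr::group_by(.data$strategy) |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric), mean),
                     .groups = "drop") |>
    dplyr::arrange(match(.data$strategy, STRATEGIES))
  icer <- icer_table(detection, gdp_per_capita = config$gdp_per_capita)

  ceac_tbl <- NULL
  psa_tbl <- NULL
  if (psa_draws > 0) {
    psa_tbl <- run_psa(config, n_draws = psa_draws, seed = seed,
                       n_patients = n_patients)
    ceac_tbl <- ceac(psa_tbl, thresholds)
  }
  tornado_tbl <- NULL
  if (tornado_replicates > 0) {
    tornado_tbl <- tornado(config, replicates = tornado_replicates,
                           seed = seed, n_patients = n_patients)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("lynchcea")),
    config_digest = rlang::hash(unclass(config)),
    seed = as.integer(seed),
    replicates = as.integer(replicates),
    psa_draws = as.integer(psa_draws),
    tornado_replicates = as.integer(tornado_replicates),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )

  out <- structure(
    list(spectrum = spectrum, detection = detection, icer = icer,
         psa = psa_tbl, ceac = ceac_tbl, tornado = tornado_tbl,
         manifest = manifest),
    class = "ls_run"
  )
  if (!is.null(out_dir)) {
    write_run(out, out_dir)
  }
  out
}

#' Write a run's artifacts to disk
#'
#' Writes `table1_weighted_proportions.csv`, `table2_detection.csv`,
#' `table3_icer.csv`, and (when computed) `ceac.csv` and `tornado.csv`,
#' plus `manifest.json`. Costs are rounded to whole USD and life-years to
#' three decimals in the table files.
#'
#' @param run an `ls_run`.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)

  write.csv(run$spectrum, p("table1_weighted_proportions.csv"), row.names = FALSE)

  det <- run$detection |>
    dplyr::mutate(dplyr::across(dplyr::starts_with("cost_") |
                                  dplyr::matches("^total_cost$"), round),
                  ly_per_carrier = round(.data$ly_per_carrier, 3),
                  cost_per_carrier = round(.data$cost_per_carrier))
  write.csv(det, p("table2_detection.csv"), row.names = FALSE)

  icer <- run$icer |>
    dplyr::mutate(ly_per_carrier = round(.data$ly_per_carrier, 3),
                  dplyr::across(c("cost_per_carrier", "icer_vs_referent",
                                  "icer_vs_previous"), round))
  write.csv(icer, p("table3_icer.csv"), row.names = FALSE)

  if (!is.null(run$ceac)) {
    write.csv(run$ceac, p("ceac.csv"), row.names = FALSE)
  }
  if (!is.null(run$tornado)) {
    write.csv(run$tornado, p("tornado.csv"), row.names = FALSE)
  }
  jsonlite::write_json(run$manifest, p("manifest.json"), auto_unbox = TRUE)
  invisible(out_dir)
}

#' @export
print.ls_run <- function(x, ...) {
  cat("<ls_run> replicate-averaged cost-effectiveness analysis\n\n")
  print(x$icer)
  invisible(x)
}
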