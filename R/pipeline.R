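#' Run the full spatial immune-profiling pipeline
#'
#' Executes phenotyping -> densities -> proximity -> G-function patterns ->
#' QC on either a simulated landscape or a cell table read from disk, and
#' optionally writes all outputs. Stages log record counts so filtering is
#' auditable; any stage error aborts with the stage name.
#'
#' @param config A list, or the path to a JSON config file, with elements:
#'   * `preset`: `"mixed_demo"`, `"unmixed_demo"` or
#'     `"tma_consistency_demo"` (simulation input), or
#'   * `input`: list with `cell_table` (CSV path) and optional
#'     `coordinate_units`;
#'   * `seed` (integer), `out_dir` (optional), `simulation` (optional
#'     overrides for [simulation_config()]), `log_level`
#'     (`"info"`/`"quiet"`).
#' @return Object of class `mif_results`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  quiet <- identical(config$log_level, "quiet")
  say <- function(stage, fmt, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L
  pconf <- panel_config(seed = seed)

  if (identical(config$preset, "tma_consistency_demo")) {
    base <- simulate_tma_base(seed = seed)
    tabs <- simulate_tma_timepoints(base, noise_sd = 1, seed = seed + 1L)
    rep <- consistency_correlation(tabs)
    say("consistency", "%d marker x pair tests, %d significant",
        nrow(rep), sum(rep$significant))
    res <- structure(list(consistency = as.data.frame(rep),
                          config = list(seed = seed, preset = config$preset)),
                     class = "mif_results")
    if (!is.null(config$out_dir)) write_outputs(res, config$out_dir)
    return(res)
  }

  sim <- NULL
  if (!is.null(config$preset)) {
    over <- if (!is.null(config$simulation)) config$simulation else list()
    sim <- stage("simulate", switch(config$preset,
      mixed_demo = do.call(simulate_mixed, c(list(seed = seed), over)),
      unmixed_demo = do.call(simulate_unmixed, c(list(seed = seed), over)),
      stop("unknown preset: ", config$preset)))
    cells <- sim$cells
    rois <- sim$rois
    say("simulate", "preset %s: %d cells in %d ROI(s)", config$preset,
        nrow(cells), nrow(rois))
  } else if (!is.null(config$input$cell_table)) {
    units <- if (!is.null(config$input$coordinate_units))
      config$input$coordinate_units else "micron"
    pconf <- panel_config(coordinate_units = units, seed = seed)
    cells <- stage("read", read_cell_table(config$input$cell_table, pconf))
    rois <- default_rois(cells)
    say("read", "%d cells in %d ROI(s)", nrow(cells), nrow(rois))
  } else {
    stop("configuration error: need either a simulation preset or an ",
         "input cell table", call. = FALSE)
  }

  registry <- phenotype_registry()
  calls <- stage("phenotype", call_phenotypes(cells, registry, pconf))
  say("phenotype", "%d cells, %d multi-lineage flagged",
      length(calls$lineage), calls$qc$multi_lineage_count)

  qc <- stage("qc", lapply(split(cells, cells$roi_id), qc_roi, config = pconf))
  say("qc", "%d/%d ROIs pass the malignant-content check",
      sum(vapply(qc, `[[`, TRUE, "pass")), length(qc))

  density <- stage("density",
                   suppressWarnings(compute_density(cells, registry, rois,
                                                    config = pconf)))
  density$cohort <- summarize_cohort(density)
  density$compartment_tests <- compare_compartments(density)
  say("density", "%d per-case rows", nrow(density$per_case))

  pdl1 <- stage("pdl1", lapply(split(cells, cells$case_id),
                               classify_case_pdl1,
                               cutoff = pconf$pdl1_case_cutoff))
  pdl1 <- data.frame(case_id = names(pdl1),
                     status = vapply(pdl1, `[[`, "", "status"),
                     fraction = vapply(pdl1, `[[`, 0, "fraction"),
                     stringsAsFactors = FALSE, row.names = NULL)

  proximity <- stage("spatial",
                     stratified_proximity(cells, registry, config = pconf))
  say("spatial", "overall radius %.2f um", attr(proximity, "overall_radius"))

  patterns <- stage("patterns",
                    phenotype_pattern_profile(cells, registry, rois = rois,
                                              config = pconf))
  cd3 <- patterns$case_calls[patterns$case_calls$phenotype == "CD3+", ]
  say("patterns", "CD3+ case calls: %s",
      paste(cd3$label, collapse = ", "))

  res <- structure(list(
    cells = cells, rois = rois, phenotype_calls = calls, qc = qc,
    density = density, pdl1 = pdl1, proximity = as.data.frame(proximity),
    overall_radius = attr(proximity, "overall_radius"),
    patterns = list(curves = patterns$curves,
                    roi_calls = patterns$roi_calls,
                    case_calls = patterns$case_calls,
                    tally = aggregate_patterns(
                      patterns$roi_calls[patterns$roi_calls$phenotype == "CD3+", ])$tally),
    truth = if (!is.null(sim)) sim$truth else NULL,
    config = list(seed = seed, preset = config$preset)
  ), class = "mif_results")
  if (!is.null(config$out_dir)) {
    paths <- stage("write", write_outputs(res, config$out_dir))
    say("write", "%d files in %s", length(paths), config$out_dir)
  }
  res
}

#' @export
print.mif_results <- function(x, ...) {
  cat("mif_results\n")
  if (!is.null(x$cells)) {
    cat(sprintf("  %d cells, %d case(s), %d ROI(s)\n", nrow(x$cells),
                length(unique(x$cells$case_id)),
                length(unique(x$cells$roi_id))))
  }
  if (!is.null(x$overall_radius)) {
    cat(sprintf("  overall radius: %.2f um\n", x$overall_radius))
  }
  if (!is.null(x$patterns)) {
    cat("  CD3+ case pattern tally:",
        paste(names(x$patterns$tally), as.integer(x$patterns$tally),
              sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}
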