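#' Read a consolidated single-cell table
#'
#' Reads a comma-delimited cell table (one row per DAPI+ nucleated cell;
#' columns `cell_id, case_id, roi_id, x, y, compartment` plus one 0/1 column
#' per panel marker). Pixel coordinates are converted to µm via
#' `config$pixel_size` when `config$coordinate_units == "pixel"`.
#'
#' @param path Path to a CSV file.
#' @param config A [panel_config()].
#' @return A validated cell table (data frame), coordinates in µm.
#' @export
read_cell_table <- function(path, config = panel_config()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cells <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c("cell_id", "case_id", "roi_id")) {
    if (col %in% names(cells)) cells[[col]] <- as.character(cells[[col]])
  }
  for (col in c("x", "y")) {
    if (col %in% names(cells) && !is.numeric(cells[[col]])) {
      suppressWarnings(num <- as.numeric(cells[[col]]))
      bad <- which(is.na(num) & !is.na(cells[[col]]))
      if (length(bad)) {
        stop("non-numeric ", col, " on data row(s): ",
             paste(head(bad, 5L), collapse = ", "), call. = FALSE)
      }
      cells[[col]] <- num
    }
  }
  validate_cell_table(cells, config)
  if (config$coordinate_units == "pixel") {
    cells$x <- cells$x * config$pixel_size
    cells$y <- cells$y * config$pixel_size
  }
  cells
}

#' Write a cell table
#'
#' Inverse of [read_cell_table()] (for µm-unit tables): writes the standard
#' CSV dialect, UTF-8, header row, marker flags as 0/1.
#'
#' @param cells A cell table.
#' @param path Output path.
#' @param config A [panel_config()].
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path, config = panel_config()) {
  validate_cell_table(cells, config)
  out <- cells[, cell_table_columns(config$markers)]
  for (m in config$markers) out[[m]] <- as.integer(out[[m]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-marker cell tables (pre-merge inputs)
#'
#' Image-analysis systems often export one table per marker: each row a
#' marker-positive cell event with coordinates. The all-nucleated-cells
#' (DAPI) table is the spine that defines cell identity; the other tables
#' annotate it (see [merge_marker_calls()]).
#'
#' @param paths Named character vector or list, marker name -> CSV path.
#'   Must include a `"DAPI"` entry. Each file needs columns
#'   `cell_id, case_id, roi_id, x, y` (the DAPI table additionally
#'   `compartment`).
#' @param config A [panel_config()].
#' @return List with `spine` (the DAPI point table) and `markers` (named
#'   list of per-marker point tables).
#' @export
read_marker_tables <- function(paths, config = panel_config()) {
  paths <- unlist(paths)
  if (!"DAPI" %in% names(paths)) {
    stop("a DAPI (all nucleated cells) table is required", call. = FALSE)
  }
  unknown <- setdiff(names(paths), c("DAPI", config$markers))
  if (length(unknown)) {
    stop("table(s) for marker(s) not in the panel: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  read_points <- function(path, need_compartment = FALSE) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    d <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    need <- c("cell_id", "case_id", "roi_id", "x", "y",
              if (need_compartment) "compartment")
    missing <- setdiff(need, names(d))
    if (length(missing)) {
      stop(basename(path), " is missing column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    for (col in c("cell_id", "case_id", "roi_id")) d[[col]] <- as.character(d[[col]])
    if (config$coordinate_units == "pixel") {
      d$x <- d$x * config$pixel_size
      d$y <- d$y * config$pixel_size
    }
    d
  }
  spine <- read_points(paths[["DAPI"]], need_compartment = TRUE)
  markers <- lapply(paths[setdiff(names(paths), "DAPI")], read_points)
  spine_rois <- unique(spine$roi_id)
  for (m in names(markers)) {
    extra <- setdiff(unique(markers[[m]]$roi_id), spine_rois)
    if (length(extra)) {
      stop("marker table '", m, "' references ROI(s) absent from the DAPI ",
           "spine: ", paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  list(spine = spine, markers = markers)
}

#' Malignant-content QC for one ROI
#'
#' Intratumoral ROIs are selected to contain predominantly malignant tissue;
#' the check recomputes the fraction of panCK+ cells among the
#' tumor-epithelial compartment and flags the ROI when it falls below
#' `config$roi_tumor_fraction_min` (default 85%).
#'
#' @param cells Cell table restricted to a single ROI.
#' @param config A [panel_config()].
#' @return List of class `roi_qc`: `roi_id`, per-compartment `counts`,
#'   `panck_fraction`, logical `pass`, character `flags`.
#' @export
qc_roi <- function(cells, config = panel_config()) {
  stopifnot(length(unique(cells$roi_id)) <= 1L)
  counts <- table(factor(cells$compartment,
                         levels = c("epithelial", "stroma", "unassigned")))
  epi <- cells[cells$compartment == "epithelial", , drop = FALSE]
  flags <- character(0)
  if (nrow(epi) == 0L) {
    frac <- NA_real_
    flags <- c(flags, "no epithelial compartment")
    pass <- FALSE
  } else {
    frac <- mean(as.logical(epi[["panCK"]]))
    pass <- frac >= config$roi_tumor_fraction_min
    if (!pass) {
      flags <- c(flags, sprintf("panCK fraction %.3f below minimum %.2f",
                                frac, config$roi_tumor_fraction_min))
    }
  }
  structure(list(roi_id = if (nrow(cells)) cells$roi_id[1L] else NA_character_,
                 counts = counts, panck_fraction = frac,
                 pass = pass, flags = flags),
            class = "roi_qc")
}

#' Write pipeline outputs to disk
#'
#' Writes the density tables, proximity table, G-curves and pattern calls as
#' delimited text plus a machine-readable JSON run summary. Re-running with
#' identical inputs and seed reproduces byte-identical files.
#'
#' @param results A `mif_results` object from [run_pipeline()].
#' @param out_dir Output directory (created if missing).
#' @return Character vector of written paths, invisibly.
#' @export
write_outputs <- function(results, out_dir) {
  if (is.null(results)) stop("results must not be NULL", call. = FALSE)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  if (file.access(out_dir, mode = 2L) != 0L) {
    stop("output directory is not writable: ", out_dir, call. = FALSE)
  }
  paths <- character(0)
  put <- function(df, name) {
    p <- file.path(out_dir, name)
    write.csv(df, p, row.names = FALSE, quote = FALSE)
    paths <<- c(paths, p)
  }
  if (!is.null(results$density)) {
    put(results$density$per_case, "density_per_case.csv")
    put(results$density$cohort, "density_cohort.csv")
  }
  if (!is.null(results$proximity)) put(results$proximity, "proximity.csv")
  if (!is.null(results$patterns)) {
    put(results$patterns$curves, "g_curves.csv")
    put(results$patterns$roi_calls, "pattern_calls_roi.csv")
    put(results$patterns$case_calls, "pattern_calls_case.csv")
  }
  if (!is.null(results$consistency)) put(results$consistency, "consistency.csv")
  summary <- list(
    package = "mifspat",
    seed = results$config$seed,
    n_cells = if (!is.null(results$cells)) nrow(results$cells) else 0L,
    n_cases = if (!is.null(results$cells))
      length(unique(results$cells$case_id)) else 0L,
    overall_radius_um = results$overall_radius,
    pdl1_status = results$pdl1,
    pattern_tally = if (!is.null(results$patterns))
      as.list(results$patterns$tally) else NULL,
    outputs = basename(paths)
  )
  p <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(summary, p, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(c(paths, p))
}
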