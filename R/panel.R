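#' The default 8-marker mIF panel
#'
#' Marker names of the nine-color panel (DAPI is implicit: every row of a
#' cell table is a nucleated, DAPI-positive event and is never encoded as a
#' flag column).
#'
#' @return Character vector of the eight marker names.
#' @export
mif_markers <- function() {
  c("panCK", "PD-L1", "PD-1", "CD3", "CD8", "Foxp3", "KI67", "CD68")
}

#' Panel / analysis configuration
#'
#' Bundles the marker panel and the scalar knobs shared across the pipeline.
#'
#' @param markers Ordered marker names; flag columns of the cell table.
#' @param pixel_size Microns per pixel of the source scan (0.5 µm/pixel at
#'   20x magnification). Used only when `coordinate_units = "pixel"`.
#' @param coordinate_units Units of the x/y columns in input tables.
#' @param merge_tolerance Maximum distance (µm) at which a marker-positive
#'   event is joined to a nucleated cell of the DAPI spine. Default is one
#'   pixel (0.5 µm).
#' @param pdl1_case_cutoff A case is PD-L1 positive when the fraction of
#'   malignant (panCK+) cells expressing PD-L1 strictly exceeds this cutoff
#'   (default 1%).
#' @param roi_tumor_fraction_min Minimum fraction of panCK+ cells among the
#'   tumor-epithelial compartment for an ROI to pass the malignant-content
#'   QC (default 85%).
#' @param lineage_priority Resolution order for cells positive for more than
#'   one lineage marker.
#' @param seed Optional integer seed recorded with the run.
#' @return An object of class `panel_config`.
#' @export
panel_config <- function(markers = mif_markers(),
                         pixel_size = 0.5,
                         coordinate_units = c("micron", "pixel"),
                         merge_tolerance = 0.5,
                         pdl1_case_cutoff = 0.01,
                         roi_tumor_fraction_min = 0.85,
                         lineage_priority = c("panCK", "CD3", "CD68"),
                         seed = NULL) {
  coordinate_units <- match.arg(coordinate_units)
  stopifnot(is.character(markers), length(markers) >= 1L,
            !anyDuplicated(markers))
  if (!is.numeric(merge_tolerance) || merge_tolerance < 0) {
    stop("merge_tolerance must be >= 0", call. = FALSE)
  }
  if (pdl1_case_cutoff < 0 || pdl1_case_cutoff > 1 ||
      roi_tumor_fraction_min < 0 || roi_tumor_fraction_min > 1) {
    stop("cutoffs must lie in [0, 1]", call. = FALSE)
  }
  if (pixel_size <= 0) stop("pixel_size must be > 0", call. = FALSE)
  structure(list(
    markers = markers,
    pixel_size = pixel_size,
    coordinate_units = coordinate_units,
    merge_tolerance = merge_tolerance,
    pdl1_case_cutoff = pdl1_case_cutoff,
    roi_tumor_fraction_min = roi_tumor_fraction_min,
    lineage_priority = lineage_priority,
    seed = seed
  ), class = "panel_config")
}

#' Define a co-expression phenotype
#'
#' A phenotype is a boolean rule over marker flags: every marker in
#' `positives` must be flagged positive and every marker in `negatives`
#' negative; markers listed in neither are unconstrained.
#'
#' @param name Display label, e.g. `"CD3+CD8+PD-1+"`.
#' @param positives,negatives Disjoint sets of marker names.
#' @param lineage One of `"tumor"`, `"t_cell"`, `"macrophage"`.
#' @param markers Panel markers used to validate the rule.
#' @return A one-row data frame with list-columns `positives`/`negatives`.
#' @export
phenotype_definition <- function(name, positives, negatives = character(0),
                                 lineage = c("tumor", "t_cell", "macrophage"),
                                 markers = mif_markers()) {
  lineage <- match.arg(lineage)
  bad <- setdiff(c(positives, negatives), markers)
  if (length(bad)) {
    stop("phenotype '", name, "' references unknown marker(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (length(intersect(positives, negatives))) {
    stop("positives and negatives overlap for '", name, "'", call. = FALSE)
  }
  data.frame(name = name, lineage = lineage,
             positives = I(list(positives)), negatives = I(list(negatives)),
             stringsAsFactors = FALSE)
}

#' The default co-expression phenotype registry
#'
#' The shipped registry enumerates the boolean co-expression rules of the
#' density table contract: 4 malignant (panCK lineage), 18 T-cell (CD3
#' lineage, with the three regulatory rows carrying an explicit CD8
#' requirement to be negative), and 4 macrophage (CD68 lineage) rows. Rules
#' are nested, not exclusive: a CD3+CD8+PD-1+ cell also matches CD3+CD8+
#' and CD3+.
#'
#' @return Data frame with columns `name`, `lineage` and list-columns
#'   `positives`, `negatives`; one row per phenotype.
#' @export
phenotype_registry <- function() {
  P <- function(name, pos, lin, neg = character(0)) {
    phenotype_definition(name, pos, neg, lin)
  }
  rows <- list(
    P("panCK+",              c("panCK"),                        "tumor"),
    P("panCK+PD-L1+",        c("panCK", "PD-L1"),               "tumor"),
    P("panCK+KI67+",         c("panCK", "KI67"),                "tumor"),
    P("panCK+KI67+PD-L1+",   c("panCK", "KI67", "PD-L1"),       "tumor"),

    P("CD3+",                      c("CD3"),                          "t_cell"),
    P("CD3+PD-L1+",                c("CD3", "PD-L1"),                 "t_cell"),
    P("CD3+PD-1+",                 c("CD3", "PD-1"),                  "t_cell"),
    P("CD3+PD-1+PD-L1+",           c("CD3", "PD-1", "PD-L1"),         "t_cell"),
    P("CD3+KI67+",                 c("CD3", "KI67"),                  "t_cell"),
    P("CD3+KI67+PD-L1+",           c("CD3", "KI67", "PD-L1"),         "t_cell"),
    P("CD3+KI67+PD-1+",            c("CD3", "KI67", "PD-1"),          "t_cell"),
    P("CD3+KI67+PD-1+PD-L1+",      c("CD3", "KI67", "PD-1", "PD-L1"), "t_cell"),
    P("CD3+Foxp3+CD8-",            c("CD3", "Foxp3"),                 "t_cell", "CD8"),
    P("CD3+Foxp3+CD8-PD-L1+",      c("CD3", "Foxp3", "PD-L1"),        "t_cell", "CD8"),
    P("CD3+Foxp3+CD8-PD-1+",       c("CD3", "Foxp3", "PD-1"),         "t_cell", "CD8"),
    P("CD3+CD8+",                  c("CD3", "CD8"),                   "t_cell"),
    P("CD3+CD8+PD-L1+",            c("CD3", "CD8", "PD-L1"),          "t_cell"),
    P("CD3+CD8+PD-1+",             c("CD3", "CD8", "PD-1"),           "t_cell"),
    P("CD3+CD8+PD-1+PD-L1+",       c("CD3", "CD8", "PD-1", "PD-L1"),  "t_cell"),
    P("CD3+CD8+KI67+",             c("CD3", "CD8", "KI67"),           "t_cell"),
    P("CD3+CD8+KI67+PD-L1+",       c("CD3", "CD8", "KI67", "PD-L1"),  "t_cell"),
    P("CD3+CD8+KI67+PD-1+",        c("CD3", "CD8", "KI67", "PD-1"),   "t_cell"),

    P("CD68+",              c("CD68"),                  "macrophage"),
    P("CD68+KI67+",         c("CD68", "KI67"),          "macrophage"),
    P("CD68+KI67+PD-L1+",   c("CD68", "KI67", "PD-L1"), "macrophage"),
    P("CD68+PD-L1+",        c("CD68", "PD-L1"),         "macrophage")
  )
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' ROI geometry table
#'
#' One row per region of interest. ROIs are axis-aligned rectangles with
#' origin at the top-left corner, y increasing downward; the default field
#' of view is 931 x 698 µm (a 20x high-magnification field).
#'
#' @param roi_id,case_id Identifiers (recycled to common length).
#' @param width,height ROI dimensions in µm.
#' @return Data frame with derived `area_mm2`.
#' @export
roi_table <- function(roi_id, case_id, width = 931, height = 698) {
  if (any(width <= 0) || any(height <= 0)) {
    stop("ROI dimensions must be strictly positive", call. = FALSE)
  }
  data.frame(roi_id = as.character(roi_id), case_id = as.character(case_id),
             width = width, height = height,
             area_mm2 = width * height / 1e6,
             stringsAsFactors = FALSE)
}

# ROI table inferred from a cell table when none is supplied: every
# distinct roi_id gets the default 931 x 698 µm window.
default_rois <- function(cells, width = 931, height = 698) {
  u <- !duplicated(cells$roi_id)
  roi_table(cells$roi_id[u], cells$case_id[u], width, height)
}

cell_table_columns <- function(markers) {
  c("cell_id", "case_id", "roi_id", "x", "y", "compartment", markers)
}

# Validate the cell-table contract; returns the table invisibly or stops
# with a named format/integrity error.
validate_cell_table <- function(cells, config = panel_config()) {
  need <- cell_table_columns(config$markers)
  missing <- setdiff(need, names(cells))
  if (length(missing)) {
    stop("cell table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(cells)) {
    bad <- which(!is.finite(cells$x) | !is.finite(cells$y))
    if (length(bad)) {
      stop("non-numeric or missing coordinate on row(s): ",
           paste(head(bad, 5L), collapse = ", "), call. = FALSE)
    }
    if (any(cells$x < 0) || any(cells$y < 0)) {
      stop("coordinates must be >= 0 (ROI-local, origin top-left)",
           call. = FALSE)
    }
    if (anyDuplicated(cells$cell_id)) {
      dup <- unique(cells$cell_id[duplicated(cells$cell_id)])
      stop("duplicate cell_id(s): ", paste(head(dup, 5L), collapse = ", "),
           call. = FALSE)
    }
    ok <- cells$compartment %in% c("epithelial", "stroma", "unassigned")
    if (!all(ok)) {
      stop("unknown compartment label(s): ",
           paste(unique(cells$compartment[!ok]), collapse = ", "),
           call. = FALSE)
    }
    for (m in config$markers) {
      v <- cells[[m]]
      if (!all(v %in% c(0L, 1L, TRUE, FALSE))) {
        stop("marker column '", m, "' must be 0/1", call. = FALSE)
      }
    }
  }
  invisible(cells)
}

# Logical marker-flag matrix (n cells x markers) from a cell table.
marker_flags <- function(cells, markers = mif_markers()) {
  m <- vapply(markers, function(k) as.logical(cells[[k]]),
              logical(nrow(cells)))
  if (nrow(cells) == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, markers))
  if (nrow(cells) == 0L) m <- matrix(logical(0), 0L, length(markers),
                                     dimnames = list(NULL, markers))
  m
}
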