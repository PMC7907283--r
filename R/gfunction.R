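#' Empirical nearest-neighbour G function
#'
#' The cross-type G function: the empirical cumulative distribution, over
#' reference points, of the distance to the nearest target point,
#' evaluated on `r_grid`. Uncorrected for edge effects by default; the
#' reduced-sample (border) correction restricts, at each radius r, to
#' reference points at least r from the window boundary.
#'
#' @param reference,target Data frames with `x`, `y` (µm). With
#'   `self = TRUE` the target set is the reference set itself and each
#'   point's nearest *other* point is used.
#' @param r_grid Ordered, non-negative radii (µm); default 0-200 µm in
#'   1 µm steps.
#' @param self Logical: same-pattern G function.
#' @param correction `"none"` (default) or `"border"`.
#' @param window For `correction = "border"`: `c(width, height)` of the
#'   ROI rectangle (origin at 0,0), µm.
#' @return Numeric vector of G values in \[0, 1\] on `r_grid`.
#' @export
empirical_g <- function(reference, target = reference, r_grid = 0:200,
                        self = FALSE, correction = c("none", "border"),
                        window = NULL) {
  correction <- match.arg(correction)
  if (is.unsorted(r_grid)) stop("r_grid must be ordered", call. = FALSE)
  n_ref <- length(reference$x)
  n_tgt <- length(target$x)
  if (n_ref == 0L || n_tgt == 0L || (self && n_ref < 2L)) {
    stop("not evaluable: empty point pattern", call. = FALSE)
  }
  nnd <- nn_query(reference, target, self = self)$dist
  if (correction == "none") {
    return(ecdf(nnd)(r_grid))
  }
  if (is.null(window)) {
    stop("border correction requires the window dimensions", call. = FALSE)
  }
  b <- pmin(reference$x, window[1L] - reference$x,
            reference$y, window[2L] - reference$y)
  g <- vapply(r_grid, function(r) {
    ok <- b >= r
    if (!any(ok)) NA_real_ else mean(nnd[ok] <= r)
  }, 0)
  # beyond the largest usable radius carry the last defined value
  if (anyNA(g)) {
    last <- max(which(!is.na(g)))
    g[is.na(g)] <- g[last]
  }
  g
}

#' Theoretical Poisson G function
#'
#' Nearest-neighbour distance distribution of a homogeneous Poisson process
#' (complete spatial randomness) with the same intensity as the observed
#' target pattern: G(r) = 1 - exp(-lambda * pi * r^2).
#'
#' @param intensity_lambda Points per µm^2 (a density of 100 cells/mm2 is
#'   `1e-4`).
#' @param r_grid Radii, µm.
#' @return Numeric vector of G values on `r_grid`.
#' @export
poisson_g <- function(intensity_lambda, r_grid = 0:200) {
  if (!is.numeric(intensity_lambda) || intensity_lambda < 0) {
    stop("intensity_lambda must be >= 0", call. = FALSE)
  }
  1 - exp(-intensity_lambda * pi * r_grid^2)
}

#' Deviation of the empirical from the Poisson G curve
#'
#' Percentage-point deviation, 100 * (G_emp(r) - G_pois(r)), the scale on
#' which the mixed/unmixed thresholds of +/-10 are defined.
#'
#' @param g_emp,g_pois G curves on the same radius grid.
#' @return Numeric vector in \[-100, 100\].
#' @export
deviation_curve <- function(g_emp, g_pois) {
  if (length(g_emp) != length(g_pois)) {
    stop("curves must be evaluated on the same radius grid", call. = FALSE)
  }
  100 * (g_emp - g_pois)
}

#' Build the full G-curve comparison for one reference/target pattern
#'
#' Convenience wrapper: empirical G, Poisson G at the observed target
#' intensity (target count / window area), and their deviation.
#'
#' @inheritParams empirical_g
#' @param window `c(width, height)` of the ROI, µm (defines the area for
#'   the observed intensity).
#' @return Object of class `g_curve`: data frame `r, g_emp, g_pois,
#'   deviation` with attributes `lambda`, `n_reference`, `n_target`.
#' @export
g_curve <- function(reference, target, window = c(931, 698), r_grid = 0:200,
                    correction = c("none", "border")) {
  correction <- match.arg(correction)
  lambda <- length(target$x) / prod(window)
  ge <- empirical_g(reference, target, r_grid, correction = correction,
                    window = window)
  gp <- poisson_g(lambda, r_grid)
  out <- data.frame(r = r_grid, g_emp = ge, g_pois = gp,
                    deviation = deviation_curve(ge, gp))
  attr(out, "lambda") <- lambda
  attr(out, "n_reference") <- length(reference$x)
  attr(out, "n_target") <- length(target$x)
  class(out) <- c("g_curve", class(out))
  out
}

#' Classify a deviation curve as mixed / unmixed / indeterminate
#'
#' The landscape call: mixed when the deviation stays within
#' \[`lower`, `upper`\] over the whole radius grid; unmixed when it exceeds
#' `upper` anywhere; indeterminate when it only drops below `lower` (a
#' branch the published rule leaves unnamed: the empirical curve runs below
#' the Poisson curve, i.e. spatial separation of the two patterns under the
#' literal threshold polarity).
#'
#' @param deviation A deviation curve (numeric, percentage points) or a
#'   `g_curve` object.
#' @param lower,upper Band thresholds, default -10 / +10.
#' @return Object of class `pattern_call`: list with `label`,
#'   `max_deviation`, `min_deviation`, `lower`, `upper`.
#' @export
classify_pattern <- function(deviation, lower = -10, upper = 10) {
  if (inherits(deviation, "g_curve")) deviation <- deviation$deviation
  stopifnot(lower < upper)
  mx <- max(deviation)
  mn <- min(deviation)
  label <- if (mx > upper) "unmixed"
           else if (mn < lower) "indeterminate"
           else "mixed"
  structure(list(label = label, max_deviation = mx, min_deviation = mn,
                 lower = lower, upper = upper), class = "pattern_call")
}

#' Aggregate ROI-level pattern calls to case level
#'
#' Majority vote over a case's ROI labels; ties give `indeterminate`. Also
#' tallies cases per label across the cohort.
#'
#' @param roi_calls Data frame with columns `case_id` and `label`.
#' @return List: `case_calls` (data frame `case_id, label, n_roi`) and
#'   `tally` (named integer vector over labels).
#' @export
aggregate_patterns <- function(roi_calls) {
  stopifnot(all(c("case_id", "label") %in% names(roi_calls)))
  cases <- unique(roi_calls$case_id)
  labels <- vapply(cases, function(cs) {
    v <- roi_calls$label[roi_calls$case_id == cs]
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_character_)
    tab <- sort(table(v), decreasing = TRUE)
    if (length(tab) > 1L && tab[1L] == tab[2L]) "indeterminate"
    else names(tab)[1L]
  }, "")
  case_calls <- data.frame(
    case_id = cases, label = labels,
    n_roi = as.integer(table(roi_calls$case_id)[cases]),
    stringsAsFactors = FALSE)
  tally <- table(factor(case_calls$label,
                        levels = c("mixed", "unmixed", "indeterminate")))
  list(case_calls = case_calls, tally = tally)
}

#' Per-phenotype spatial pattern profile
#'
#' Runs the G-function comparison for every requested immune phenotype in
#' every ROI (reference = panCK+ malignant cells, target = the phenotype's
#' cells, Poisson intensity = observed target count / ROI area), classifies
#' each deviation curve, and aggregates ROI calls per case.
#'
#' @param cells A consolidated cell table.
#' @param registry Phenotype registry.
#' @param phenotypes Target phenotype names; defaults to the key T-cell
#'   subsets `CD3+`, `CD3+CD8+`, `CD3+PD-1+`, `CD3+Foxp3+CD8-`.
#' @param rois ROI geometry table; defaults to 931 x 698 µm windows.
#' @param r_grid Radius grid, µm.
#' @param reference Reference phenotype name (default `"panCK+"`).
#' @param lower,upper Classification thresholds.
#' @param config A [panel_config()].
#' @param correction Edge correction passed to [empirical_g()].
#' @return List of class `pattern_profile`: `curves` (long data frame),
#'   `roi_calls`, `case_calls`, `tally` (for the first phenotype-less
#'   aggregate see [aggregate_patterns()]).
#' @export
phenotype_pattern_profile <- function(cells, registry = phenotype_registry(),
                                      phenotypes = c("CD3+", "CD3+CD8+",
                                                     "CD3+PD-1+",
                                                     "CD3+Foxp3+CD8-"),
                                      rois = NULL, r_grid = 0:200,
                                      reference = "panCK+",
                                      lower = -10, upper = 10,
                                      config = panel_config(),
                                      correction = c("none", "border")) {
  correction <- match.arg(correction)
  if (is.null(rois)) rois <- default_rois(cells)
  ref_sel <- phenotype_cells(cells, reference, registry, config)
  curves <- list()
  calls <- list()
  for (i in seq_len(nrow(rois))) {
    roi <- rois$roi_id[i]
    window <- c(rois$width[i], rois$height[i])
    in_roi <- cells$roi_id == roi
    ref <- cells[in_roi & ref_sel, c("x", "y")]
    for (ph in phenotypes) {
      tgt <- cells[in_roi & phenotype_cells(cells, ph, registry, config),
                   c("x", "y")]
      if (nrow(ref) == 0L || nrow(tgt) == 0L) {
        calls[[length(calls) + 1L]] <- data.frame(
          case_id = rois$case_id[i], roi_id = roi, phenotype = ph,
          label = NA_character_, max_deviation = NA_real_,
          min_deviation = NA_real_, n_reference = nrow(ref),
          n_target = nrow(tgt), stringsAsFactors = FALSE)
        next
      }
      gc <- g_curve(ref, tgt, window = window, r_grid = r_grid,
                    correction = correction)
      pc <- classify_pattern(gc, lower = lower, upper = upper)
      curves[[length(curves) + 1L]] <- cbind(
        data.frame(case_id = rois$case_id[i], roi_id = roi, phenotype = ph,
                   stringsAsFactors = FALSE), as.data.frame(gc))
      calls[[length(calls) + 1L]] <- data.frame(
        case_id = rois$case_id[i], roi_id = roi, phenotype = ph,
        label = pc$label, max_deviation = pc$max_deviation,
        min_deviation = pc$min_deviation, n_reference = nrow(ref),
        n_target = nrow(tgt), stringsAsFactors = FALSE)
    }
  }
  roi_calls <- do.call(rbind, calls)
  curves <- if (length(curves)) do.call(rbind, curves) else
    data.frame(case_id = character(0), roi_id = character(0),
               phenotype = character(0), r = numeric(0), g_emp = numeric(0),
               g_pois = numeric(0), deviation = numeric(0))
  case_calls <- list()
  for (ph in phenotypes) {
    agg <- aggregate_patterns(roi_calls[roi_calls$phenotype == ph, ])
    agg$case_calls$phenotype <- ph
    case_calls[[ph]] <- agg$case_calls
  }
  case_calls <- do.call(rbind, case_calls)
  rownames(case_calls) <- NULL
  tally <- table(factor(case_calls$label,
                        levels = c("mixed", "unmixed", "indeterminate")),
                 case_calls$phenotype)
  structure(list(curves = curves, roi_calls = roi_calls,
                 case_calls = case_calls, tally = tally),
            class = "pattern_profile")
}
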