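#' Pairwise euclidean distance matrix
#'
#' Entry (i, j) is the euclidean distance from the i-th `from` point to the
#' j-th `to` point, in the units of the coordinates (µm throughout the
#' pipeline).
#'
#' @param from,to Data frames (or lists) with numeric `x`, `y`.
#' @return A `length(from) x length(to)` numeric matrix.
#' @export
distance_matrix <- function(from, to) {
  if (length(from$x) == 0L || length(to$x) == 0L) {
    stop("not evaluable: empty point set", call. = FALSE)
  }
  d2 <- outer(from$x, to$x, "-")^2 + outer(from$y, to$y, "-")^2
  sqrt(d2)
}

#' Median nearest-neighbour distance from reference to target cells
#'
#' For every reference cell, the distance to its nearest target cell; the
#' summary is the median over reference cells. This is the "median distance
#' from malignant cells to a phenotype" used for close/far classification
#' when reference = panCK+ cells. `method = "allpairs"` instead takes the
#' median of the full distance matrix (the all-pairs reading of the
#' distance-matrix construction).
#'
#' @param reference,target Data frames with `x`, `y` (µm).
#' @param method `"nn"` (default) or `"allpairs"`.
#' @return Median distance in µm (`NA` when either set is empty).
#' @export
median_nn_distance <- function(reference, target, method = c("nn", "allpairs")) {
  method <- match.arg(method)
  if (length(reference$x) == 0L || length(target$x) == 0L) return(NA_real_)
  if (method == "allpairs") {
    return(median(distance_matrix(reference, target)))
  }
  median(nn_query(reference, target)$dist)
}

#' Overall median radius
#'
#' The single radius splitting immune phenotypes into close and far: the
#' median over all available (case x target phenotype) median distances of
#' the panCK+ reference stratum.
#'
#' @param proximity A `proximity_summary` data frame from
#'   [stratified_proximity()], or a numeric vector of median distances.
#' @return Radius in µm.
#' @export
overall_radius <- function(proximity) {
  v <- if (is.numeric(proximity)) proximity
       else proximity$median_dist[proximity$stratum == "panCK+"]
  v <- v[!is.na(v)]
  if (!length(v)) stop("no median distances available", call. = FALSE)
  median(v)
}

#' Close/far proximity label
#'
#' A phenotype is close to the malignant cells when its median distance is
#' equal to or less than the radius, far when greater.
#'
#' @param distance Median distance(s), µm.
#' @param radius Overall radius, µm.
#' @return Character vector `"close"`/`"far"`.
#' @export
classify_proximity <- function(distance, radius) {
  stopifnot(is.finite(radius))
  ifelse(distance <= radius, "close", "far")
}

#' Proximity of immune phenotypes to malignant cells, stratified by PD-L1
#'
#' Computes, per case and per target immune phenotype, the median
#' nearest-target distance from three reference strata of malignant cells:
#' all panCK+, panCK+ PD-L1-, and panCK+ PD-L1+. Distances are computed
#' within each ROI (ROIs are disjoint physical fields) and the reference
#' cells' nearest-neighbour distances are pooled across a case's ROIs
#' before taking the median. The overall radius (median over the panCK+
#' stratum's case x phenotype grid) labels every row close or far.
#'
#' @param cells A consolidated cell table.
#' @param registry Phenotype registry; targets are its non-tumor rows.
#' @param targets Optional character vector of target phenotype names.
#' @param config A [panel_config()].
#' @param method Passed to [median_nn_distance()].
#' @return Object of class `proximity_summary`: data frame `case_id,
#'   stratum, phenotype, median_dist, n_reference, n_target, proximity`
#'   with attributes `overall_radius` and `stratum_medians`.
#' @export
stratified_proximity <- function(cells, registry = phenotype_registry(),
                                 targets = NULL, config = panel_config(),
                                 method = c("nn", "allpairs")) {
  method <- match.arg(method)
  if (is.null(targets)) targets <- registry$name[registry$lineage != "tumor"]
  tum <- as.logical(cells[["panCK"]])
  if (!any(tum)) stop("no panCK+ cells present", call. = FALSE)
  pdl1 <- as.logical(cells[["PD-L1"]])
  strata <- list("panCK+" = tum,
                 "panCK+PD-L1-" = tum & !pdl1,
                 "panCK+PD-L1+" = tum & pdl1)
  target_sel <- lapply(targets, function(ph)
    phenotype_cells(cells, ph, registry, config))
  names(target_sel) <- targets

  rows <- list()
  for (case in unique(cells$case_id)) {
    in_case <- cells$case_id == case
    rois <- unique(cells$roi_id[in_case])
    for (s in names(strata)) {
      for (ph in targets) {
        pooled <- numeric(0)
        n_ref <- n_tgt <- 0L
        for (roi in rois) {
          in_roi <- in_case & cells$roi_id == roi
          ref <- cells[in_roi & strata[[s]], c("x", "y")]
          tgt <- cells[in_roi & target_sel[[ph]], c("x", "y")]
          n_ref <- n_ref + nrow(ref)
          n_tgt <- n_tgt + nrow(tgt)
          if (nrow(ref) == 0L || nrow(tgt) == 0L) next  # not evaluable here
          pooled <- c(pooled, if (method == "nn") nn_query(ref, tgt)$dist
                      else as.numeric(distance_matrix(ref, tgt)))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          case_id = case, stratum = s, phenotype = ph,
          median_dist = if (length(pooled)) median(pooled) else NA_real_,
          n_reference = n_ref, n_target = n_tgt, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  radius <- overall_radius(out)
  out$proximity <- ifelse(is.na(out$median_dist), NA_character_,
                          classify_proximity(out$median_dist, radius))
  stratum_medians <- vapply(names(strata), function(s)
    median(out$median_dist[out$stratum == s], na.rm = TRUE), 0)
  attr(out, "overall_radius") <- radius
  attr(out, "stratum_medians") <- stratum_medians
  class(out) <- c("proximity_summary", class(out))
  out
}

#' Cohort proximity matrix (heat-map layout)
#'
#' Pivots a [stratified_proximity()] result to the phenotype x stratum
#' matrix of cohort medians (median over cases of the per-case median
#' distances).
#'
#' @param proximity A `proximity_summary`.
#' @return Numeric matrix, rows = target phenotypes, columns = the three
#'   reference strata.
#' @export
proximity_matrix <- function(proximity) {
  phenotypes <- unique(proximity$phenotype)
  strata <- unique(proximity$stratum)
  out <- matrix(NA_real_, length(phenotypes), length(strata),
                dimnames = list(phenotypes, strata))
  for (ph in phenotypes) {
    for (s in strata) {
      v <- proximity$median_dist[proximity$phenotype == ph &
                                   proximity$stratum == s]
      v <- v[!is.na(v)]
      if (length(v)) out[ph, s] <- median(v)
    }
  }
  out
}

#' Target-cell counts within increasing radii of the reference pattern
#'
#' For each radius r, the number of target cells whose distance to the
#' nearest reference cell is <= r; the default radii are the swept
#' neighbourhoods 30, 50, 75, 100 and 200 µm around malignant cells.
#'
#' @param reference,target Data frames with `x`, `y` (µm).
#' @param radii Strictly increasing non-negative radii (µm).
#' @return Named integer vector of counts, nondecreasing in r.
#' @export
count_within_radius <- function(reference, target,
                                radii = c(30, 50, 75, 100, 200)) {
  if (any(radii < 0) || any(diff(radii) <= 0)) {
    stop("radii must be non-negative and strictly increasing", call. = FALSE)
  }
  if (length(target$x) == 0L) {
    return(setNames(integer(length(radii)), radii))
  }
  if (length(reference$x) == 0L) {
    stop("not evaluable: empty reference set", call. = FALSE)
  }
  nnd <- nn_query(target, reference)$dist
  setNames(vapply(radii, function(r) sum(nnd <= r), 0L), radii)
}
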