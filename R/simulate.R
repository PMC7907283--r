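#' Simulation configuration for synthetic tumor microenvironments
#'
#' The generator emulates the cell tables the pipeline consumes: a
#' 931 x 698 µm ROI per field, malignant (panCK+) cells scattered as a
#' homogeneous Poisson process inside circular tumor nests
#' (tumor-epithelial compartment), immune cells (CD3 and CD68 lineages) as
#' a Poisson scatter over the whole window, and marker co-expression drawn
#' per cell from configured frequencies. `mixing` governs the immune
#' geometry: 1 means immune cells are uniform over the window (they
#' freely enter nests: a mixed landscape); 0 means immune cells are
#' excluded from every nest dilated by `exclusion_margin` µm (an unmixed
#' landscape of cohesive nests); intermediate values thin immune cells in
#' the exclusion region to that fraction.
#'
#' @param window `c(width, height)` µm; default the 20x field 931 x 698.
#' @param n_cases,rois_per_case Cohort shape; defaults 12 cases x 10 ROIs.
#' @param n_nests,nest_radius Tumor nest count and disc radius (µm).
#' @param tumor_intensity panCK+ intensity inside nests, cells/mm2. The
#'   default (3200) keeps nest tumor purity above the 85% ROI QC threshold
#'   even under full immune mixing.
#' @param immune_intensity Named vector, window-wide intensities
#'   (cells/mm2) per immune lineage marker (`CD3`, `CD68`).
#' @param mixing Fraction in \[0, 1\], see above.
#' @param exclusion_margin µm added around nests when `mixing < 1`.
#' @param coexpression Per-lineage marker co-expression frequencies (see
#'   [default_coexpression()]).
#' @param pdl1_tumor_fraction Fraction of tumor cells expressing PD-L1.
#' @param seed Integer seed; every ROI derives its own substream
#'   deterministically from it.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(window = c(931, 698),
                              n_cases = 12, rois_per_case = 10,
                              n_nests = 5, nest_radius = 80,
                              tumor_intensity = 3200,
                              immune_intensity = c(CD3 = 310, CD68 = 150),
                              mixing = 1, exclusion_margin = 100,
                              coexpression = default_coexpression(),
                              pdl1_tumor_fraction = 0.25,
                              seed = 1L) {
  stopifnot(length(window) == 2L, all(window > 0),
            tumor_intensity >= 0, all(immune_intensity >= 0),
            mixing >= 0, mixing <= 1, exclusion_margin >= 0,
            pdl1_tumor_fraction >= 0, pdl1_tumor_fraction <= 1)
  structure(list(window = window, n_cases = n_cases,
                 rois_per_case = rois_per_case, n_nests = n_nests,
                 nest_radius = nest_radius, tumor_intensity = tumor_intensity,
                 immune_intensity = immune_intensity, mixing = mixing,
                 exclusion_margin = exclusion_margin,
                 coexpression = coexpression,
                 pdl1_tumor_fraction = pdl1_tumor_fraction,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Default marker co-expression frequencies
#'
#' Conditional marker frequencies per generative lineage, chosen so that
#' simulated phenotype densities fall inside the printed min-max ranges of
#' the cohort density table (documented, not fitted). T cells draw a
#' subtype first (cytotoxic CD8+, regulatory Foxp3+CD8-, or double
#' negative), then checkpoint/proliferation markers independently.
#'
#' @return Nested list of frequencies.
#' @export
default_coexpression <- function() {
  list(
    tumor = list(KI67 = 0.12),                       # PD-L1 set separately
    t_cell = list(CD8 = 0.35, Foxp3 = 0.05,          # subtype split
                  `PD-1` = 0.15, `PD-L1` = 0.10, KI67 = 0.08),
    macrophage = list(`PD-L1` = 0.12, KI67 = 0.07)
  )
}

# Deterministic per-ROI substream seed derived from the global seed;
# documented derivation, kept below 2^31.
substream_seed <- function(seed, case_index, roi_index) {
  as.integer((as.numeric(seed) + 7919 * case_index + 104729 * roi_index) %%
               .Machine$integer.max)
}

# Place n non-overlapping nest centers fully inside the window; rejection
# sampling with capped retries.
place_nests <- function(window, n, radius, max_tries = 1000L) {
  if (2 * radius > min(window)) {
    stop("infeasible nest packing: nest diameter exceeds window", call. = FALSE)
  }
  cx <- cy <- numeric(0)
  tries <- 0L
  while (length(cx) < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("infeasible nest packing after ", max_tries, " retries",
           call. = FALSE)
    }
    x <- runif(1, radius, window[1L] - radius)
    y <- runif(1, radius, window[2L] - radius)
    if (length(cx) == 0L || all((x - cx)^2 + (y - cy)^2 >= (2 * radius)^2)) {
      cx <- c(cx, x); cy <- c(cy, y)
    }
  }
  data.frame(x = cx, y = cy)
}

# Poisson scatter of npts ~ Pois(intensity_mm2 * area_mm2) uniform points
# in a disc.
scatter_disc <- function(center, radius, intensity_mm2) {
  area_mm2 <- pi * radius^2 / 1e6
  n <- rpois(1L, intensity_mm2 * area_mm2)
  r <- radius * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  data.frame(x = center$x + r * cos(th), y = center$y + r * sin(th))
}

simulate_roi <- function(config, case_id, roi_id, seed) {
  set.seed(seed)
  W <- config$window[1L]; H <- config$window[2L]
  nests <- place_nests(config$window, config$n_nests, config$nest_radius)

  in_nest <- function(x, y, dilate = 0) {
    inside <- rep(FALSE, length(x))
    for (i in seq_len(nrow(nests))) {
      inside <- inside | ((x - nests$x[i])^2 + (y - nests$y[i])^2 <=
                            (config$nest_radius + dilate)^2)
    }
    inside
  }

  co <- config$coexpression
  markers <- mif_markers()
  blank_flags <- function(n) {
    f <- as.data.frame(matrix(0L, n, length(markers)))
    names(f) <- markers
    f
  }

  # malignant cells: Poisson scatter inside each nest
  tum <- do.call(rbind, lapply(seq_len(nrow(nests)), function(i)
    scatter_disc(nests[i, ], config$nest_radius, config$tumor_intensity)))
  if (is.null(tum)) tum <- data.frame(x = numeric(0), y = numeric(0))
  tum_flags <- blank_flags(nrow(tum))
  tum_flags$panCK <- rep(1L, nrow(tum))
  tum_flags[["PD-L1"]] <- as.integer(runif(nrow(tum)) < config$pdl1_tumor_fraction)
  tum_flags$KI67 <- as.integer(runif(nrow(tum)) < co$tumor$KI67)
  tum$lineage <- rep("tumor", nrow(tum))

  immune <- list()
  area_mm2 <- W * H / 1e6
  for (lin_marker in names(config$immune_intensity)) {
    n <- rpois(1L, config$immune_intensity[[lin_marker]] * area_mm2)
    pts <- data.frame(x = runif(n, 0, W), y = runif(n, 0, H))
    if (config$mixing < 1 && nrow(pts)) {
      excl <- in_nest(pts$x, pts$y, dilate = config$exclusion_margin)
      keep <- !excl | (runif(nrow(pts)) < config$mixing)
      pts <- pts[keep, , drop = FALSE]
    }
    f <- blank_flags(nrow(pts))
    if (lin_marker == "CD3") {
      f$CD3 <- rep(1L, nrow(pts))
      u <- runif(nrow(pts))
      p <- co$t_cell
      cd8 <- u < p$CD8
      foxp3 <- !cd8 & u < p$CD8 + p$Foxp3
      f$CD8 <- as.integer(cd8)
      f$Foxp3 <- as.integer(foxp3)
      f[["PD-1"]] <- as.integer(runif(nrow(pts)) < p[["PD-1"]])
      f[["PD-L1"]] <- as.integer(runif(nrow(pts)) < p[["PD-L1"]])
      f$KI67 <- as.integer(runif(nrow(pts)) < p$KI67)
      pts$lineage <- rep("t_cell", nrow(pts))
    } else {
      f$CD68 <- rep(1L, nrow(pts))
      p <- co$macrophage
      f[["PD-L1"]] <- as.integer(runif(nrow(pts)) < p[["PD-L1"]])
      f$KI67 <- as.integer(runif(nrow(pts)) < p$KI67)
      pts$lineage <- rep("macrophage", nrow(pts))
    }
    immune[[lin_marker]] <- cbind(pts, f)
  }
  tum <- cbind(tum, tum_flags)
  all_cells <- rbind(tum, do.call(rbind, immune))
  rownames(all_cells) <- NULL

  compartment <- ifelse(in_nest(all_cells$x, all_cells$y),
                        "epithelial", "stroma")
  n <- nrow(all_cells)
  cells <- data.frame(
    cell_id = sprintf("%s_%s_%05d", case_id, roi_id, seq_len(n)),
    case_id = case_id, roi_id = roi_id,
    x = all_cells$x, y = all_cells$y, compartment = compartment,
    stringsAsFactors = FALSE)
  cells <- cbind(cells, all_cells[, markers, drop = FALSE])
  cells$generative_lineage <- all_cells$lineage
  cells
}

#' Simulate a synthetic tumor-microenvironment cell table
#'
#' @param config A [simulation_config()].
#' @return Object of class `mif_simulation`: list with `cells` (standard
#'   cell table; the sidecar column `generative_lineage` is carried in
#'   `truth`, not in `cells`), `rois` (geometry), and `truth` (ground
#'   truth: per-ROI pattern label, per-cell generative lineage, configured
#'   intensities). Ground truth is never consumed by the analysis stages.
#' @export
simulate_landscape <- function(config = simulation_config()) {
  all_rows <- list()
  truth_rows <- list()
  pattern <- if (config$mixing >= 0.5) "mixed" else "unmixed"
  for (ci in seq_len(config$n_cases)) {
    case_id <- sprintf("case%02d", ci)
    for (ri in seq_len(config$rois_per_case)) {
      roi_id <- sprintf("%s_roi%02d", case_id, ri)
      seed <- substream_seed(config$seed, ci, ri)
      cells <- simulate_roi(config, case_id, roi_id, seed)
      truth_rows[[roi_id]] <- data.frame(
        roi_id = roi_id, case_id = case_id, pattern = pattern,
        stringsAsFactors = FALSE)
      all_rows[[roi_id]] <- cells
    }
  }
  cells <- do.call(rbind, all_rows)
  rownames(cells) <- NULL
  lineage <- cells$generative_lineage
  cells$generative_lineage <- NULL
  rois <- roi_table(
    roi_id = vapply(truth_rows, `[[`, "", "roi_id"),
    case_id = vapply(truth_rows, `[[`, "", "case_id"),
    width = config$window[1L], height = config$window[2L])
  structure(list(
    cells = cells, rois = rois,
    truth = list(pattern = do.call(rbind, truth_rows),
                 cell_lineage = data.frame(cell_id = cells$cell_id,
                                           lineage = lineage,
                                           stringsAsFactors = FALSE),
                 tumor_intensity = config$tumor_intensity,
                 immune_intensity = config$immune_intensity,
                 config = config)
  ), class = "mif_simulation")
}

#' Mixed / unmixed landscape presets
#'
#' `simulate_mixed()` fixes `mixing = 1` (immune cells uniform over the
#' window, freely entering tumor nests); `simulate_unmixed()` fixes
#' `mixing = 0` with a 100 µm exclusion margin (immune cells kept away
#' from cohesive nests). Both default to a single ROI with at least 200
#' cells per lineage.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [simulation_config()].
#' @return A `mif_simulation` (see [simulate_landscape()]).
#' @export
simulate_mixed <- function(seed = 1L, ...) {
  over <- list(...)
  args <- utils::modifyList(
    list(n_cases = 1, rois_per_case = 1, mixing = 1, seed = seed), over)
  simulate_landscape(do.call(simulation_config, args))
}

#' @rdname simulate_mixed
#' @export
simulate_unmixed <- function(seed = 1L, ...) {
  over <- list(...)
  args <- utils::modifyList(
    list(n_cases = 1, rois_per_case = 1, mixing = 0,
         exclusion_margin = 100, seed = seed), over)
  simulate_landscape(do.call(simulation_config, args))
}

#' Simulate a base TMA marker-percentage table
#'
#' One row per core, one column per marker: percentages of DAPI+ cells
#' positive for the marker, drawn uniformly between 0 and a per-marker
#' ceiling so levels span roughly 0-60%.
#'
#' @param n_cores Number of TMA cores (default the 36 cores of a
#'   12-case x 3-core array).
#' @param seed Integer seed.
#' @param markers Marker names.
#' @return Numeric matrix, cores x markers.
#' @export
simulate_tma_base <- function(n_cores = 36, seed = 1L,
                              markers = mif_markers()) {
  set.seed(seed)
  ceiling_pct <- c(panCK = 60, `PD-L1` = 20, `PD-1` = 10, CD3 = 40,
                   CD8 = 25, Foxp3 = 5, KI67 = 15, CD68 = 20)
  ceiling_pct <- ceiling_pct[markers]
  ceiling_pct[is.na(ceiling_pct)] <- 30
  out <- vapply(ceiling_pct, function(m) runif(n_cores, 0, m),
                numeric(n_cores))
  rownames(out) <- sprintf("core%02d", seq_len(n_cores))
  colnames(out) <- markers
  out
}

#' Simulate repeated TMA staining runs
#'
#' Emulates staining the same TMA at several time points: time point 1 is
#' the base percentage table; later time points add independent Gaussian
#' noise (percentage points), truncated to \[0, 100\]. With small noise
#' the per-marker rank structure across cores is preserved, which is what
#' [consistency_correlation()] measures.
#'
#' @param base Cores x markers percentage matrix (see
#'   [simulate_tma_base()]).
#' @param n_timepoints Number of staining runs (default 3 weekly runs).
#' @param noise_sd Replicate noise SD in percentage points.
#' @param seed Integer seed.
#' @return List of percentage matrices, one per time point.
#' @export
simulate_tma_timepoints <- function(base, n_timepoints = 3, noise_sd = 1,
                                    seed = 1L) {
  stopifnot(noise_sd >= 0, n_timepoints >= 1)
  set.seed(seed)
  out <- vector("list", n_timepoints)
  out[[1L]] <- base
  for (t in seq_len(n_timepoints)[-1L]) {
    noise <- matrix(rnorm(length(base), 0, noise_sd), nrow(base), ncol(base))
    out[[t]] <- pmin(pmax(base + noise, 0), 100)
    dimnames(out[[t]]) <- dimnames(base)
  }
  names(out) <- sprintf("t%d", seq_len(n_timepoints))
  out
}

#' Plant a PD-L1 proximity gradient
#'
#' Moves a fraction of T cells toward their nearest PD-L1+ malignant cell
#' by `effect` µm (never past 1 µm away), so the PD-L1+ reference stratum's
#' median nearest-neighbour distance is smaller by construction; used to
#' test the stratified proximity orderings.
#'
#' @param cells A cell table with panCK and PD-L1 flags.
#' @param effect Shift in µm; 0 returns the table unchanged.
#' @param fraction Fraction of CD3+ cells to relocate.
#' @param seed Integer seed.
#' @return The modified cell table.
#' @export
plant_pdl1_gradient <- function(cells, effect, fraction = 0.5, seed = 1L) {
  if (effect == 0) return(cells)
  anchors_all <- as.logical(cells[["panCK"]]) & as.logical(cells[["PD-L1"]])
  if (!any(anchors_all)) {
    stop("no PD-L1+ malignant cells to anchor the gradient", call. = FALSE)
  }
  set.seed(seed)
  for (roi in unique(cells$roi_id)) {
    in_roi <- cells$roi_id == roi
    t_idx <- which(in_roi & as.logical(cells[["CD3"]]))
    a_idx <- which(in_roi & anchors_all)
    if (!length(t_idx) || !length(a_idx)) next
    moved <- t_idx[runif(length(t_idx)) < fraction]
    if (!length(moved)) next
    nn <- nn_query(cells[moved, c("x", "y")], cells[a_idx, c("x", "y")])
    for (k in seq_along(moved)) {
      i <- moved[k]
      j <- a_idx[nn$index[k]]
      d <- nn$dist[k]
      if (d <= 1) next
      new_d <- max(d - effect, 1)
      frac_along <- 1 - new_d / d
      cells$x[i] <- cells$x[i] + frac_along * (cells$x[j] - cells$x[i])
      cells$y[i] <- cells$y[i] + frac_along * (cells$y[j] - cells$y[i])
    }
  }
  cells
}
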