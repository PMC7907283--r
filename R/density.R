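#' Compartmentalized cell densities (cells/mm2)
#'
#' For every registry phenotype, counts matching cells per ROI and
#' compartment and divides by the compartment area in mm2. Compartments are
#' `epithelial` (malignant-cell nests), `stroma`, and `combined`
#' (epithelial + stroma counts over summed areas). The per-case value is
#' the unweighted mean of that case's per-ROI densities.
#'
#' Compartment areas are taken from `compartment_areas` when supplied;
#' otherwise each ROI's area is apportioned by cell count,
#' `area_mm2 * n_compartment / (n_epithelial + n_stroma)`, the best
#' available surrogate when the image-analysis tissue-category areas are
#' not exported. ROIs with a zero or unknown compartment area are excluded
#' from that compartment's average with a warning rather than contributing
#' silent zeros.
#'
#' @param cells A consolidated cell table.
#' @param registry Phenotype registry; see [phenotype_registry()].
#' @param rois ROI geometry table ([roi_table()]); defaults to a
#'   931 x 698 µm window per ROI found in `cells`.
#' @param compartment_areas Optional data frame `roi_id, epithelial, stroma`
#'   (mm2) of measured tissue-category areas.
#' @param config A [panel_config()].
#' @return List of class `density_table`: `per_roi` and `per_case` long
#'   data frames with columns `case_id, (roi_id,) phenotype, compartment,
#'   count, area_mm2, density`.
#' @export
compute_density <- function(cells, registry = phenotype_registry(),
                            rois = NULL, compartment_areas = NULL,
                            config = panel_config()) {
  if (is.null(rois)) rois <- default_rois(cells)
  membership <- call_phenotypes(cells, registry, config)$membership

  roi_ids <- rois$roi_id
  n_epi <- n_str <- setNames(numeric(length(roi_ids)), roi_ids)
  tab <- table(factor(cells$roi_id, levels = roi_ids), cells$compartment)
  if ("epithelial" %in% colnames(tab)) n_epi[] <- tab[, "epithelial"]
  if ("stroma" %in% colnames(tab)) n_str[] <- tab[, "stroma"]

  area_of <- function(roi, comp) {
    i <- match(roi, rois$roi_id)
    if (!is.null(compartment_areas) && comp %in% c("epithelial", "stroma")) {
      j <- match(roi, compartment_areas$roi_id)
      if (!is.na(j)) return(compartment_areas[[comp]][j])
    }
    total <- rois$area_mm2[i]
    n_tot <- n_epi[[roi]] + n_str[[roi]]
    switch(comp,
      epithelial = if (n_tot > 0) total * n_epi[[roi]] / n_tot else 0,
      stroma     = if (n_tot > 0) total * n_str[[roi]] / n_tot else 0,
      combined   = total)
  }

  rows <- vector("list", length(roi_ids) * nrow(registry) * 3L)
  k <- 0L
  skipped <- character(0)
  for (roi in roi_ids) {
    in_roi <- cells$roi_id == roi
    case <- rois$case_id[match(roi, rois$roi_id)]
    for (comp in c("epithelial", "stroma", "combined")) {
      a <- area_of(roi, comp)
      sel <- if (comp == "combined") {
        in_roi & cells$compartment %in% c("epithelial", "stroma")
      } else in_roi & cells$compartment == comp
      if (!is.finite(a) || a <= 0) {
        skipped <- c(skipped, paste0(roi, "/", comp))
        next
      }
      cnt <- colSums(membership[sel, , drop = FALSE])
      k <- k + 1L
      rows[[k]] <- data.frame(case_id = case, roi_id = roi,
                              phenotype = registry$name, compartment = comp,
                              count = as.integer(cnt), area_mm2 = a,
                              density = cnt / a, stringsAsFactors = FALSE)
    }
  }
  if (length(skipped)) {
    warning("excluded ROI/compartment(s) with zero or unknown area: ",
            paste(unique(skipped), collapse = ", "), call. = FALSE)
  }
  per_roi <- do.call(rbind, rows[seq_len(k)])

  agg <- stats::aggregate(density ~ case_id + phenotype + compartment,
                          data = per_roi, FUN = mean)
  structure(list(per_roi = per_roi, per_case = agg), class = "density_table")
}

#' Cohort summary of per-case densities
#'
#' Median, minimum and maximum over cases for every (phenotype,
#' compartment); the median of an even number of cases is the mean of the
#' two central values.
#'
#' @param density A `density_table` from [compute_density()], or its
#'   `per_case` data frame.
#' @return Data frame `phenotype, compartment, median, min, max, n_cases`.
#' @export
summarize_cohort <- function(density) {
  per_case <- if (inherits(density, "density_table")) density$per_case else density
  if (!nrow(per_case)) stop("need at least one case", call. = FALSE)
  sp <- split(per_case$density,
              list(phenotype = per_case$phenotype,
                   compartment = per_case$compartment), drop = TRUE)
  key <- do.call(rbind, strsplit(names(sp), ".", fixed = TRUE))
  out <- data.frame(phenotype = key[, 1L], compartment = key[, 2L],
                    median = vapply(sp, median, 0),
                    min = vapply(sp, min, 0),
                    max = vapply(sp, max, 0),
                    n_cases = vapply(sp, length, 0L),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$phenotype, out$compartment), ]
}

#' Compare tumor-epithelial vs tumor-stroma densities
#'
#' Two-sided Wilcoxon rank-sum test per phenotype between the per-case
#' epithelial and stromal density vectors, as in the density-table
#' contract. The exact null distribution is used when both groups have
#' <= 12 observations and no ties; otherwise the normal approximation with
#' tie correction. Degenerate all-identical data yields p = 1 with a note.
#'
#' Note the test is the unpaired rank-sum as named, although the design is
#' paired by case; see the methods vignette.
#'
#' @param density A `density_table` or its `per_case` data frame.
#' @return Data frame `phenotype, statistic, p_value, method, note`.
#' @export
compare_compartments <- function(density) {
  per_case <- if (inherits(density, "density_table")) density$per_case else density
  out <- lapply(unique(per_case$phenotype), function(ph) {
    d <- per_case[per_case$phenotype == ph, ]
    e <- d$density[d$compartment == "epithelial"]
    s <- d$density[d$compartment == "stroma"]
    if (length(e) < 2L || length(s) < 2L) {
      return(data.frame(phenotype = ph, statistic = NA_real_,
                        p_value = NA_real_, method = "wilcoxon rank-sum",
                        note = "fewer than 2 cases per compartment",
                        stringsAsFactors = FALSE))
    }
    res <- rank_sum_test(e, s)
    data.frame(phenotype = ph, statistic = res$statistic,
               p_value = res$p_value, method = res$method, note = res$note,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Rank-based and categorical group comparisons
#'
#' Thin comparison stage: `rank_sum_test()` is the two-sided Wilcoxon
#' rank-sum for two groups; `compare_groups()` dispatches to it for two
#' groups and to Kruskal-Wallis for more; `compare_categorical()` applies
#' the chi-square test, falling back to Fisher's exact test when any
#' expected count is below 5.
#'
#' @param x,y Numeric vectors (two groups).
#' @return A list with `statistic`, `p_value`, `method`, `note`.
#' @export
rank_sum_test <- function(x, y) {
  if (length(unique(c(x, y))) == 1L) {
    return(list(statistic = NA_real_, p_value = 1, method = "wilcoxon rank-sum",
                note = "degenerate data: all values identical"))
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- length(x) <= 12L && length(y) <= 12L && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = !exact))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "wilcoxon rank-sum (exact)"
                else "wilcoxon rank-sum (normal approximation)",
       note = if (ties && !exact) "ties present; tie-corrected approximation"
              else "")
}

#' @rdname rank_sum_test
#' @param values Numeric vector of observations.
#' @param groups Grouping factor aligned with `values`.
#' @export
compare_groups <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (nlevels(groups) == 2L) {
    sp <- split(values, groups)
    return(rank_sum_test(sp[[1L]], sp[[2L]]))
  }
  kt <- kruskal.test(values, groups)
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       method = "kruskal-wallis", note = "")
}

#' @rdname rank_sum_test
#' @param tab A contingency table (or matrix).
#' @export
compare_categorical <- function(tab) {
  tab <- as.table(tab)
  exp_counts <- suppressWarnings(chisq.test(tab)$expected)
  if (any(exp_counts < 5)) {
    ft <- fisher.test(tab)
    list(statistic = NA_real_, p_value = ft$p.value, method = "fisher exact",
         note = "expected count < 5; Fisher's exact test used")
  } else {
    ct <- chisq.test(tab)
    list(statistic = unname(ct$statistic), p_value = ct$p.value,
         method = "chi-square", note = "")
  }
}

#' Marker percentages of DAPI+ cells in a TMA core
#'
#' Percentage of nucleated cells positive for each marker: 100 x positive
#' count / total cell count.
#'
#' @param cells Cell table restricted to one core (every row is DAPI+).
#' @param markers Marker names.
#' @return Named numeric vector of percentages in \[0, 100\].
#' @export
marker_percentages <- function(cells, markers = mif_markers()) {
  if (nrow(cells) == 0L) stop("empty core: not evaluable", call. = FALSE)
  100 * colMeans(marker_flags(cells, markers))
}

#' Staining-consistency correlation across time points
#'
#' Reproducibility QC for repeated staining runs of the same TMA: for every
#' marker and every pair of time points, Spearman's rank correlation of the
#' per-core marker percentages, with Bonferroni adjustment over all marker
#' x pair tests in the run and significance called at adjusted p < 0.05.
#'
#' @param percent_tables List (length >= 2, typically 3 weekly runs) of
#'   cores x markers percentage matrices with identical dimnames.
#' @param alpha Significance level on the adjusted p-value.
#' @return Object of class `consistency_report`: data frame `marker, pair,
#'   rho, p_value, p_adj, significant, note` with attribute `n_tests`.
#' @export
consistency_correlation <- function(percent_tables, alpha = 0.05) {
  stopifnot(length(percent_tables) >= 2L)
  dims <- lapply(percent_tables, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L) {
    stop("percentage tables must share the same core x marker layout",
         call. = FALSE)
  }
  if (nrow(percent_tables[[1L]]) < 3L) stop("need >= 3 cores", call. = FALSE)
  markers <- colnames(percent_tables[[1L]])
  tp <- seq_along(percent_tables)
  pairs <- utils::combn(tp, 2L)
  rows <- list()
  for (m in markers) {
    for (j in seq_len(ncol(pairs))) {
      a <- percent_tables[[pairs[1L, j]]][, m]
      b <- percent_tables[[pairs[2L, j]]][, m]
      pair_lab <- sprintf("t%d-t%d", pairs[1L, j], pairs[2L, j])
      if (stats::sd(a) == 0 || stats::sd(b) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          marker = m, pair = pair_lab, rho = NA_real_, p_value = NA_real_,
          note = "constant vector: rho undefined", stringsAsFactors = FALSE)
        next
      }
      ct <- suppressWarnings(cor.test(a, b, method = "spearman"))
      rows[[length(rows) + 1L]] <- data.frame(
        marker = m, pair = pair_lab, rho = unname(ct$estimate),
        p_value = ct$p.value, note = "", stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  n_tests <- nrow(out)            # Bonferroni family: all tests in the run
  out$p_adj <- pmin(1, out$p_value * n_tests)
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  out <- out[, c("marker", "pair", "rho", "p_value", "p_adj",
                 "significant", "note")]
  attr(out, "n_tests") <- n_tests
  class(out) <- c("consistency_report", class(out))
  out
}
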