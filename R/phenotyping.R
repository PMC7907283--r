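#' Merge per-marker cell calls onto the DAPI spine by coordinates
#'
#' Image analysis is run once per marker, so the same physical cell appears
#' in several tables. Consolidation joins each marker-positive event to the
#' nearest nucleated cell of the DAPI spine (within `tolerance` µm, in the
#' same ROI) and sets that cell's marker flag. Matching is one-to-nearest
#' with deterministic tie-breaking (smallest `cell_id` wins an exact
#' distance tie); marker events with no spine cell within tolerance are
#' dropped and counted.
#'
#' @param tables A list as returned by [read_marker_tables()]: `spine` (the
#'   DAPI table: `cell_id, case_id, roi_id, x, y, compartment`) and
#'   `markers` (named list of marker-positive point tables).
#' @param config A [panel_config()]; `config$merge_tolerance` is the join
#'   radius in µm (default 0.5, one pixel).
#' @return A consolidated cell table (one row per spine cell, all marker
#'   flag columns 0/1) with attribute `merge_qc`: per-marker matched /
#'   unmatched event counts.
#' @export
merge_marker_calls <- function(tables, config = panel_config()) {
  spine <- tables$spine
  if (is.null(spine) || nrow(spine) == 0L) {
    stop("DAPI spine must be non-empty", call. = FALSE)
  }
  tol <- config$merge_tolerance
  if (!is.numeric(tol) || tol < 0) stop("tolerance must be >= 0", call. = FALSE)

  # smallest-cell_id tie-break: order spine so earlier index = smaller id
  ord <- order(spine$roi_id, spine$cell_id)
  spine <- spine[ord, , drop = FALSE]
  cells <- spine[, c("cell_id", "case_id", "roi_id", "x", "y", "compartment")]
  for (m in config$markers) cells[[m]] <- 0L

  qc <- data.frame(marker = character(0), matched = integer(0),
                   unmatched = integer(0), stringsAsFactors = FALSE)
  for (m in names(tables$markers)) {
    ev <- tables$markers[[m]]
    matched <- 0L
    if (nrow(ev)) {
      for (roi in unique(ev$roi_id)) {
        in_roi <- which(cells$roi_id == roi)
        e <- ev[ev$roi_id == roi, , drop = FALSE]
        if (!length(in_roi)) next
        nn <- nn_query(e, cells[in_roi, ])
        hit <- which(nn$dist <= tol)
        if (length(hit)) {
          cells[[m]][in_roi[nn$index[hit]]] <- 1L
          matched <- matched + length(hit)
        }
      }
    }
    qc <- rbind(qc, data.frame(marker = m, matched = matched,
                               unmatched = nrow(ev) - matched,
                               stringsAsFactors = FALSE))
  }
  attr(cells, "merge_qc") <- qc
  rownames(cells) <- NULL
  cells
}

#' Call co-expression phenotypes
#'
#' Evaluates every registry rule against each cell's marker flags: a cell
#' matches a phenotype iff all `positives` flags are true and all
#' `negatives` false. Rules are nested rather than exclusive, so one cell
#' can (and usually does) match several rows. Each cell is also resolved to
#' a single lineage from its lineage markers (panCK -> tumor, CD3 ->
#' t_cell, CD68 -> macrophage); cells positive for more than one lineage
#' marker take the highest-priority lineage (`config$lineage_priority`) and
#' are counted in QC; cells positive for none are `other`.
#'
#' @param cells A consolidated cell table.
#' @param registry A phenotype registry, see [phenotype_registry()].
#' @param config A [panel_config()].
#' @return Object of class `phenotype_calls`: list with `membership`
#'   (logical cells x phenotypes matrix), `lineage` (character per cell),
#'   `cell_id`, and `qc` (multi-lineage count and ids).
#' @export
call_phenotypes <- function(cells, registry = phenotype_registry(),
                            config = panel_config()) {
  for (i in seq_len(nrow(registry))) {
    bad <- setdiff(c(registry$positives[[i]], registry$negatives[[i]]),
                   config$markers)
    if (length(bad)) {
      stop("registry row '", registry$name[i],
           "' references unknown marker(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  flags <- marker_flags(cells, config$markers)
  membership <- matrix(FALSE, nrow(cells), nrow(registry),
                       dimnames = list(NULL, registry$name))
  for (i in seq_len(nrow(registry))) {
    pos <- registry$positives[[i]]
    neg <- registry$negatives[[i]]
    ok <- rep(TRUE, nrow(cells))
    for (m in pos) ok <- ok & flags[, m]
    for (m in neg) ok <- ok & !flags[, m]
    membership[, i] <- ok
  }

  lineage_marker <- c(panCK = "tumor", CD3 = "t_cell", CD68 = "macrophage")
  prio <- config$lineage_priority
  lin_flags <- flags[, prio, drop = FALSE]
  n_lin <- rowSums(lin_flags)
  first <- apply(lin_flags, 1L, function(v) {
    i <- which(v)[1L]
    if (is.na(i)) NA_character_ else prio[i]
  })
  lineage <- ifelse(is.na(first), "other", unname(lineage_marker[first]))
  multi <- which(n_lin > 1L)

  structure(list(
    membership = membership,
    lineage = lineage,
    cell_id = cells$cell_id,
    qc = list(multi_lineage_count = length(multi),
              multi_lineage_ids = cells$cell_id[multi])
  ), class = "phenotype_calls")
}

#' Case-level PD-L1 status
#'
#' A case is PD-L1 positive when the fraction of its malignant (panCK+)
#' cells that co-express PD-L1 strictly exceeds the cutoff (default 1%).
#'
#' @param cells Cell table restricted to one case.
#' @param cutoff Fraction in \[0, 1\].
#' @return List: `status` (`"positive"`, `"negative"` or
#'   `"not evaluable"` when the case has no panCK+ cell), `fraction`,
#'   `n_malignant`.
#' @export
classify_case_pdl1 <- function(cells, cutoff = 0.01) {
  tum <- as.logical(cells[["panCK"]])
  n <- sum(tum)
  if (n == 0L) {
    return(list(status = "not evaluable", fraction = NA_real_, n_malignant = 0L))
  }
  frac <- sum(tum & as.logical(cells[["PD-L1"]])) / n
  list(status = if (frac > cutoff) "positive" else "negative",
       fraction = frac, n_malignant = n)
}

# Cells matching a named registry phenotype (logical index helper).
phenotype_cells <- function(cells, phenotype, registry = phenotype_registry(),
                            config = panel_config()) {
  i <- match(phenotype, registry$name)
  if (is.na(i)) stop("unknown phenotype: ", phenotype, call. = FALSE)
  flags <- marker_flags(cells, config$markers)
  ok <- rep(TRUE, nrow(cells))
  for (m in registry$positives[[i]]) ok <- ok & flags[, m]
  for (m in registry$negatives[[i]]) ok <- ok & !flags[, m]
  ok
}
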