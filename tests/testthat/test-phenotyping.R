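spine_of <- function(x, y, roi_id = "r1") {
  data.frame(cell_id = sprintf("s%02d", seq_along(x)), case_id = "c1",
             roi_id = roi_id, x = x, y = y, compartment = "epithelial",
             stringsAsFactors = FALSE)
}
events_of <- function(x, y, roi_id = "r1") {
  data.frame(cell_id = sprintf("e%02d", seq_along(x)), case_id = "c1",
             roi_id = roi_id, x = x, y = y, stringsAsFactors = FALSE)
}

test_that("coordinate merge joins marker events to the nearest spine cell within tolerance", {
  spine <- spine_of(c(10, 20), c(10, 20))

  out <- merge_marker_calls(list(spine = spine,
                                 markers = list(CD3 = events_of(10, 10))))
  expect_identical(out$CD3[out$x == 10], 1L)      # exact-coordinate join
  expect_identical(out$CD3[out$x == 20], 0L)

  # distance 0.4 <= tolerance 0.5 -> matched
  out <- merge_marker_calls(list(spine = spine,
                                 markers = list(CD3 = events_of(10.4, 10.0))))
  expect_identical(out$CD3, c(1L, 0L))

  # nearest spine cell ~7.07 µm away -> dropped and counted
  out <- merge_marker_calls(list(spine = spine,
                                 markers = list(CD3 = events_of(15, 15))))
  expect_identical(out$CD3, c(0L, 0L))
  qc <- attr(out, "merge_qc")
  expect_identical(qc$unmatched[qc$marker == "CD3"], 1L)

  expect_error(merge_marker_calls(list(spine = spine[0, ], markers = list())),
               "non-empty")
  expect_error(merge_marker_calls(list(spine = spine, markers = list()),
                                  panel_config(merge_tolerance = -1)))
})

test_that("merge conserves the spine and accounts for every marker event", {
  for (seed in 1:5) {
    set.seed(seed)
    n_spine <- sample(20:60, 1)
    spine <- spine_of(runif(n_spine, 0, 100), runif(n_spine, 0, 100))
    markers <- list(CD3 = events_of(runif(30, 0, 120), runif(30, 0, 120)),
                    CD8 = events_of(runif(10, 0, 100), runif(10, 0, 100)))
    out <- merge_marker_calls(list(spine = spine, markers = markers),
                              panel_config(merge_tolerance = 5))
    expect_identical(nrow(out), n_spine)
    expect_setequal(out$cell_id, spine$cell_id)
    qc <- attr(out, "merge_qc")
    expect_identical(qc$matched + qc$unmatched, c(30L, 10L))
  }
})

test_that("phenotype calls match the registry rules on worked examples", {
  reg <- phenotype_registry()
  expect_identical(nrow(reg), 26L)
  expect_identical(as.vector(table(reg$lineage)[c("tumor", "t_cell", "macrophage")]),
                   c(4L, 18L, 4L))

  cells <- make_cells(1, 1, flags = list(CD3 = 1, CD8 = 1, `PD-1` = 1))
  hit <- colnames(call_phenotypes(cells)$membership)[call_phenotypes(cells)$membership[1, ]]
  expect_setequal(hit, c("CD3+", "CD3+PD-1+", "CD3+CD8+", "CD3+CD8+PD-1+"))

  cells <- make_cells(1, 1, flags = list(panCK = 1, KI67 = 1, `PD-L1` = 1))
  calls <- call_phenotypes(cells)
  expect_setequal(colnames(calls$membership)[calls$membership[1, ]],
                  c("panCK+", "panCK+PD-L1+", "panCK+KI67+", "panCK+KI67+PD-L1+"))
  expect_identical(calls$lineage, "tumor")

  none <- call_phenotypes(make_cells(1, 1))
  expect_false(any(none$membership))
  expect_identical(none$lineage, "other")

  bad <- phenotype_registry()
  bad$positives[[1]] <- "CD99"
  expect_error(call_phenotypes(make_cells(1, 1), bad), "unknown marker")
})

test_that("call_phenotypes agrees with the brute-force evaluator on all 2^8 flag vectors", {
  reg <- phenotype_registry()
  markers <- mif_markers()
  grid <- expand.grid(rep(list(0:1), length(markers)))
  names(grid) <- markers
  cells <- make_cells(seq_len(nrow(grid)), rep(1, nrow(grid)),
                      flags = as.list(grid))
  membership <- call_phenotypes(cells)$membership
  for (i in seq_len(nrow(reg))) {
    want <- vapply(seq_len(nrow(grid)), function(v) {
      oracle_match(unlist(grid[v, ]), reg$positives[[i]], reg$negatives[[i]])
    }, TRUE)
    expect_identical(unname(membership[, reg$name[i]]), want)
  }

  # nesting: matching a rule implies matching every sub-rule
  for (i in seq_len(nrow(reg))) {
    for (j in seq_len(nrow(reg))) {
      if (all(reg$positives[[i]] %in% reg$positives[[j]]) &&
          all(reg$negatives[[i]] %in% reg$negatives[[j]])) {
        expect_true(all(membership[membership[, j], i]))
      }
    }
  }
})

test_that("lineage is a partition with configurable priority and QC flags", {
  cells <- make_cells(1:4, rep(1, 4),
                      flags = list(panCK = c(1, 1, 0, 0), CD3 = c(0, 1, 1, 0),
                                   CD68 = c(0, 0, 0, 0)))
  calls <- call_phenotypes(cells)
  expect_identical(calls$lineage, c("tumor", "tumor", "t_cell", "other"))
  expect_identical(calls$qc$multi_lineage_count, 1L)
  expect_identical(calls$qc$multi_lineage_ids, cells$cell_id[2])

  flipped <- call_phenotypes(cells, config = panel_config(
    lineage_priority = c("CD3", "panCK", "CD68")))
  expect_identical(flipped$lineage[2], "t_cell")

  big <- random_cells(500, 42)
  lin <- call_phenotypes(big)$lineage
  expect_identical(sum(table(lin)), 500L)
})

test_that("case PD-L1 status uses a strict >1% rule on malignant cells", {
  case_with <- function(n_pdl1, n_tumor) {
    make_cells(seq_len(n_tumor), rep(1, n_tumor),
               flags = list(panCK = rep(1, n_tumor),
                            `PD-L1` = c(rep(1, n_pdl1),
                                        rep(0, n_tumor - n_pdl1))))
  }
  expect_identical(classify_case_pdl1(case_with(2, 100))$status, "positive")
  expect_identical(classify_case_pdl1(case_with(1, 100))$status, "negative")
  expect_identical(classify_case_pdl1(case_with(0, 100))$status, "negative")
  no_tumor <- make_cells(1:3, 1:3, flags = list(CD3 = rep(1, 3)))
  expect_identical(classify_case_pdl1(no_tumor)$status, "not evaluable")
})
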