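test_that("cell tables round-trip through CSV, including the empty table", {
  cfg <- panel_config()
  cells <- make_cells(c(10.25, 20.5, 31.125), c(5, 15.75, 600.2),
                      compartment = c("epithelial", "stroma", "unassigned"),
                      flags = list(panCK = c(1, 0, 0), CD3 = c(0, 1, 0),
                                   `PD-L1` = c(1, 1, 0)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cell_table(cells, path)
  back <- read_cell_table(path, cfg)
  expect_identical(nrow(back), nrow(cells))
  expect_equal(back$x, cells$x, tolerance = 1e-6)
  expect_equal(back$y, cells$y, tolerance = 1e-6)
  for (m in mif_markers()) expect_identical(back[[m]], cells[[m]])
  expect_identical(back$compartment, cells$compartment)

  write_cell_table(cells[0, ], path)
  expect_identical(nrow(read_cell_table(path, cfg)), 0L)
})

test_that("pixel coordinates convert to µm at the configured pixel size", {
  cells <- make_cells(100, 40)        # stored values interpreted as pixels
  path <- withr::local_tempfile(fileext = ".csv")
  write_cell_table(cells, path)
  px <- read_cell_table(path, panel_config(coordinate_units = "pixel"))
  expect_equal(px$x, 50.0, tolerance = 1e-9)   # 100 px * 0.5 µm/px
  expect_equal(px$y, 20.0, tolerance = 1e-9)

  # same geometry expressed in µm reads identically
  um_cells <- make_cells(50, 20)
  write_cell_table(um_cells, path)
  um <- read_cell_table(path, panel_config())
  expect_equal(px$x, um$x, tolerance = 1e-6)
  expect_equal(px$y, um$y, tolerance = 1e-6)
})

test_that("format errors are specific: missing column, bad coordinate, duplicate id", {
  cells <- make_cells(c(1, 2), c(3, 4))
  path <- withr::local_tempfile(fileext = ".csv")

  broken <- cells; broken$CD8 <- NULL
  write.csv(broken, path, row.names = FALSE)
  expect_error(read_cell_table(path), "CD8")

  broken <- cells; broken$x <- c("1.0", "oops")
  write.csv(broken, path, row.names = FALSE)
  expect_error(read_cell_table(path), "row")

  broken <- cells; broken$cell_id <- c("a", "a")
  write.csv(broken, path, row.names = FALSE)
  expect_error(read_cell_table(path), "duplicate")

  expect_error(read_cell_table(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("read_marker_tables loads per-marker point sets around the DAPI spine", {
  dir <- withr::local_tempdir()
  spine <- make_cells(seq(10, 50, 10), rep(10, 5))
  write.csv(spine[, c("cell_id", "case_id", "roi_id", "x", "y", "compartment")],
            file.path(dir, "dapi.csv"), row.names = FALSE)
  cd3 <- spine[1:2, c("cell_id", "case_id", "roi_id", "x", "y")]
  write.csv(cd3, file.path(dir, "cd3.csv"), row.names = FALSE)

  got <- read_marker_tables(c(DAPI = file.path(dir, "dapi.csv")))
  expect_identical(nrow(got$spine), 5L)
  expect_length(got$markers, 0L)

  got <- read_marker_tables(c(DAPI = file.path(dir, "dapi.csv"),
                              CD3 = file.path(dir, "cd3.csv")))
  expect_identical(nrow(got$markers$CD3), 2L)

  expect_error(read_marker_tables(c(CD3 = file.path(dir, "cd3.csv"))), "DAPI")
  expect_error(read_marker_tables(c(DAPI = file.path(dir, "dapi.csv"),
                                    CD99 = file.path(dir, "cd3.csv"))), "CD99")

  stray <- cd3; stray$roi_id <- "elsewhere"
  write.csv(stray, file.path(dir, "stray.csv"), row.names = FALSE)
  expect_error(read_marker_tables(c(DAPI = file.path(dir, "dapi.csv"),
                                    CD3 = file.path(dir, "stray.csv"))),
               "elsewhere")
})

test_that("ROI malignant-content QC applies the 85% rule and is monotone", {
  cells_at <- function(n_pos, n_tot) {
    make_cells(seq_len(n_tot), rep(1, n_tot),
               flags = list(panCK = c(rep(1, n_pos), rep(0, n_tot - n_pos))))
  }
  expect_true(qc_roi(cells_at(90, 100))$pass)    # 0.90 >= 0.85
  rep80 <- qc_roi(cells_at(80, 100))
  expect_false(rep80$pass)                       # 0.80 < 0.85
  expect_match(rep80$flags, "below minimum")

  none <- make_cells(1:3, 1:3, compartment = "stroma")
  rep0 <- qc_roi(none)
  expect_false(rep0$pass)
  expect_match(rep0$flags, "no epithelial compartment")
  expect_identical(unname(rep0$counts[["stroma"]]), 3L)

  # monotone: lowering the threshold never turns a pass into a flag
  for (seed in 1:10) {
    cells <- random_cells(60, seed, p = 0.6)
    hi <- qc_roi(cells, panel_config(roi_tumor_fraction_min = 0.8))$pass
    lo <- qc_roi(cells, panel_config(roi_tumor_fraction_min = 0.5))$pass
    expect_true(!hi || lo)
  }
})

test_that("run_pipeline completes on presets, errors without input, and is deterministic", {
  res <- run_pipeline(list(preset = "mixed_demo", seed = 7, log_level = "quiet"))
  expect_s3_class(res, "mif_results")
  expect_gt(nrow(res$patterns$roi_calls), 0L)

  expect_error(run_pipeline(list(seed = 1, log_level = "quiet")),
               "configuration error")

  res2 <- run_pipeline(list(preset = "mixed_demo", seed = 7, log_level = "quiet"))
  expect_identical(res$patterns$roi_calls, res2$patterns$roi_calls)
  expect_identical(res$cells, res2$cells)
})

test_that("write_outputs produces the output set, byte-identical across reruns", {
  res <- run_pipeline(list(preset = "unmixed_demo", seed = 3, log_level = "quiet"))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_outputs(res, d1)
  expect_true(all(file.exists(file.path(
    d1, c("density_per_case.csv", "density_cohort.csv", "proximity.csv",
          "g_curves.csv", "pattern_calls_roi.csv", "pattern_calls_case.csv",
          "run_summary.json")))))
  p2 <- write_outputs(res, d2)
  for (k in seq_along(p1)) {
    expect_identical(readLines(p1[k]), readLines(p2[k]))
  }

  blocker <- withr::local_tempfile(fileext = ".txt")
  writeLines("x", blocker)
  expect_error(write_outputs(res, file.path(blocker, "sub")), "output directory")
  expect_error(write_outputs(NULL, d1), "NULL")
})

test_that("the CLI simulate subcommand writes a readable table and ground truth", {
  dir <- withr::local_tempdir()
  cfg_path <- file.path(dir, "config.json")
  jsonlite::write_json(list(preset = "mixed_demo",
                            simulation = list(rois_per_case = 1)),
                       cfg_path, auto_unbox = TRUE)
  mif_cli(c("simulate", "--config", cfg_path, "--seed", "5",
            "--out-dir", dir))
  cells <- read_cell_table(file.path(dir, "cells.csv"))
  expect_gt(nrow(cells), 100L)
  truth <- read.csv(file.path(dir, "ground_truth_pattern.csv"))
  expect_identical(truth$pattern, "mixed")
  expect_error(mif_cli(character(0)), "usage")
  expect_error(mif_cli(c("frobnicate")), "unknown subcommand")
})
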