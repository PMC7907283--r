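test_that("density arithmetic: counts over compartment area in mm2", {
  # 650 panCK+ cells filling one default 931 x 698 µm ROI
  set.seed(1)
  cells <- make_cells(runif(650, 0, 931), runif(650, 0, 698),
                      flags = list(panCK = rep(1, 650)))
  dens <- suppressWarnings(compute_density(cells))  # no stroma cells: warned
  combined <- dens$per_roi[dens$per_roi$phenotype == "panCK+" &
                             dens$per_roi$compartment == "combined", ]
  expect_equal(combined$density, 650 / 0.649838, tolerance = 1e-12)
  expect_equal(round(combined$density, 2), 1000.25)

  # zero matching cells -> 0.0 cells/mm2, not an error
  zero <- dens$per_roi[dens$per_roi$phenotype == "CD68+" &
                         dens$per_roi$compartment == "combined", ]
  expect_identical(zero$density, 0)
})

test_that("densities recompose: per-ROI counts are additive across compartments", {
  sim <- simulate_mixed(11)
  dens <- compute_density(sim$cells, rois = sim$rois)
  pr <- dens$per_roi
  for (ph in c("panCK+", "CD3+", "CD3+CD8+", "CD68+")) {
    e <- pr[pr$phenotype == ph & pr$compartment == "epithelial", ]
    s <- pr[pr$phenotype == ph & pr$compartment == "stroma", ]
    cmb <- pr[pr$phenotype == ph & pr$compartment == "combined", ]
    expect_identical(e$count + s$count, cmb$count)
    # densities recompose exactly given the areas
    expect_equal(e$density * e$area_mm2 + s$density * s$area_mm2,
                 cmb$density * cmb$area_mm2, tolerance = 1e-9)
  }
})

test_that("nested phenotypes never out-dense their parent rule", {
  sim <- simulate_mixed(12)
  dens <- compute_density(sim$cells, rois = sim$rois)
  pc <- dens$per_case
  chains <- list(c("CD3+", "CD3+CD8+", "CD3+CD8+PD-1+"),
                 c("panCK+", "panCK+KI67+", "panCK+KI67+PD-L1+"),
                 c("CD68+", "CD68+PD-L1+"))
  for (chain in chains) {
    for (comp in c("epithelial", "stroma", "combined")) {
      v <- vapply(chain, function(ph)
        pc$density[pc$phenotype == ph & pc$compartment == comp], 0)
      expect_true(all(diff(v) <= 1e-12))
    }
  }
})

test_that("cohort summaries are order statistics over cases", {
  per_case <- data.frame(case_id = sprintf("c%d", 1:4), phenotype = "CD3+",
                         compartment = "combined", density = c(1, 2, 3, 4))
  s <- summarize_cohort(per_case)
  expect_equal(s$median, 2.5)
  expect_equal(s$min, 1)
  expect_equal(s$max, 4)

  single <- summarize_cohort(per_case[2, ])
  expect_true(single$median == 2 && single$min == 2 && single$max == 2)

  zeros <- per_case; zeros$density <- 0
  expect_equal(unlist(summarize_cohort(zeros)[, c("median", "min", "max")]),
               c(median = 0, min = 0, max = 0))
  expect_error(summarize_cohort(per_case[0, ]), "at least one case")
})

test_that("compartment comparison is the two-sided rank-sum with exact small-sample null", {
  # complete separation at n = 3,3: exact two-sided p = 2/20
  expect_equal(rank_sum_test(c(1, 2, 3), c(101, 102, 103))$p_value, 0.1)
  # identical vectors -> no signal
  expect_equal(rank_sum_test(c(5, 6, 7), c(5, 6, 7))$p_value, 1)
  deg <- rank_sum_test(c(2, 2), c(2, 2))
  expect_equal(deg$p_value, 1)
  expect_match(deg$note, "degenerate")

  per_case <- rbind(
    data.frame(case_id = sprintf("c%d", 1:3), phenotype = "CD3+",
               compartment = "epithelial", density = c(1, 2, 3)),
    data.frame(case_id = sprintf("c%d", 1:3), phenotype = "CD3+",
               compartment = "stroma", density = c(101, 102, 103)))
  out <- compare_compartments(per_case)
  expect_equal(out$p_value, 0.1)

  kw <- compare_groups(c(1, 2, 9, 10, 20, 21), rep(c("a", "b", "c"), each = 2))
  expect_identical(kw$method, "kruskal-wallis")
  ct <- compare_categorical(matrix(c(20, 5, 6, 19), 2))
  expect_true(ct$p_value < 0.05)
  ft <- compare_categorical(matrix(c(3, 1, 1, 3), 2))
  expect_identical(ft$method, "fisher exact")
})

test_that("marker percentages are fractions of DAPI+ cells", {
  cells <- make_cells(1:100, rep(1, 100),
                      flags = list(CD3 = c(rep(1, 30), rep(0, 70)),
                                   panCK = rep(1, 100)))
  pct <- marker_percentages(cells)
  expect_equal(unname(pct["CD3"]), 30)
  expect_equal(unname(pct["panCK"]), 100)
  expect_equal(unname(pct["CD68"]), 0)
  expect_error(marker_percentages(cells[0, ]), "not evaluable")
})

test_that("consistency correlation: rho endpoints, Bonferroni, constant vectors", {
  base <- simulate_tma_base(n_cores = 12, seed = 4)
  identical_runs <- list(t1 = base, t2 = base)
  rep <- consistency_correlation(identical_runs)
  expect_true(all(rep$rho == 1))
  expect_true(all(rep$significant))
  expect_equal(rep$p_adj, pmin(1, rep$p_value * nrow(rep)))

  reversed <- base
  for (m in colnames(base)) reversed[, m] <- -base[, m]
  rep <- consistency_correlation(list(base, reversed))
  expect_true(all(rep$rho == -1))

  const <- base; const[, "CD3"] <- 7
  rep <- consistency_correlation(list(const, base))
  expect_true(is.na(rep$rho[rep$marker == "CD3"]))
  expect_match(rep$note[rep$marker == "CD3"], "constant")

  expect_error(consistency_correlation(list(base[1:2, ], base[1:2, ])),
               ">= 3 cores")
  expect_error(consistency_correlation(list(base, base[1:6, ])), "layout")
})

test_that("small replicate noise keeps rank agreement high and significant", {
  base <- simulate_tma_base(n_cores = 36, seed = 9)
  tabs <- simulate_tma_timepoints(base, n_timepoints = 2, noise_sd = 1,
                                  seed = 10)
  rep <- consistency_correlation(tabs)
  # low-abundance markers (Foxp3 spans only 0-5%) tolerate less noise, so
  # the guarantee is on the bulk of the panel, not every marker
  expect_gte(median(rep$rho), 0.9)
  expect_true(all(rep$significant))
})

test_that("Spearman rho is invariant under monotone transformation of one run", {
  base <- simulate_tma_base(n_cores = 36, seed = 2)
  tabs <- simulate_tma_timepoints(base, n_timepoints = 2, noise_sd = 3,
                                  seed = 3)
  warped <- tabs
  warped[[2]] <- sqrt(warped[[2]]) * 10       # strictly monotone on [0,100]
  expect_equal(consistency_correlation(tabs)$rho,
               consistency_correlation(warped)$rho, tolerance = 1e-12)
})

test_that("rank-sum p-values are calibrated under label permutation", {
  set.seed(99)
  vals <- rnorm(24)
  p <- replicate(200, {
    idx <- sample(24, 12)
    rank_sum_test(vals[idx], vals[-idx])$p_value
  })
  expect_lt(mean(p < 0.05), 0.12)   # near nominal under the null
  expect_gt(mean(p > 0.5), 0.3)
})
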