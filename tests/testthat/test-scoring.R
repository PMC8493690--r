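test_that("mean Z-line length is the arithmetic mean, NA when empty", {
  expect_equal(mean_z_length(c(2, 4)), 3)
  expect_true(is.na(mean_z_length(numeric(0))))
  expect_equal(mean_z_length(3.1), 3.1)
})

test_that("the well-organized call uses a strict > 3.1 um rule", {
  p <- scoring_params()
  expect_true(classify_well_organized(3.2, p))
  expect_false(classify_well_organized(3.1, p))   # boundary excluded
  expect_false(classify_well_organized(NA_real_, p))
})

test_that("HSI is healthy count over total cells", {
  cells <- cell_records("W01", c(rep(5, 50), rep(1, 150)))
  wm <- compute_hsi(cells)
  expect_equal(wm$hsi, 0.25)
  expect_equal(wm$n_cells_total, 200)
  cells0 <- cell_records("W01", rep(1, 200))
  expect_equal(compute_hsi(cells0)$hsi, 0)
  expect_warning(compute_hsi(cells[0, ]), "zero cells")
})

test_that("HSI monotonically non-increasing in the cutoff", {
  set.seed(8)
  cells <- cell_records("W01", c(rnorm(100, 5, 1), rnorm(100, 1, .3)))
  cuts <- seq(0.5, 6, by = 0.25)
  hsi <- vapply(cuts, function(cc) {
    compute_hsi(cells, scoring_params(z_cutoff_um = cc))$hsi
  }, 1)
  expect_true(all(diff(hsi) <= 0))
})

test_that("the YAP call thresholds the nuclear/cytoplasm ratio", {
  p <- scoring_params()
  expect_true(classify_yap_nuclear(200, 100, p))    # ratio 2.0
  expect_false(classify_yap_nuclear(100, 100, p))   # ratio 1.0
  # raising the threshold never adds nuclear-localized cells
  set.seed(9)
  nucv <- runif(200, 50, 300); cytv <- runif(200, 50, 300)
  n1 <- sum(classify_yap_nuclear(nucv, cytv,
                                 scoring_params(yap_ratio_threshold = 1.1)))
  n2 <- sum(classify_yap_nuclear(nucv, cytv,
                                 scoring_params(yap_ratio_threshold = 1.5)))
  expect_lte(n2, n1)
})

test_that("YAP index is the nuclear fraction over measurable cells", {
  cells <- cell_records("W01", NA_real_, nuc = c(rep(200, 1000),
                                                 rep(100, 3000)),
                        cyt = 100, measurable = TRUE)
  expect_equal(compute_yap_index(cells), 0.25)
  cells_all <- cell_records("W01", NA_real_, nuc = rep(300, 10), cyt = 100,
                            measurable = TRUE)
  expect_equal(compute_yap_index(cells_all), 1.0)
  # unmeasurable cells leave the denominator
  cells$yap_measurable[1:2000] <- FALSE
  wm <- compute_well_metrics(cells)
  expect_equal(wm$n_yap_measurable, 2000)
})

test_that("percent of control is the ratio of group means", {
  wells <- data.frame(well = c("W01", "W02", "W03", "W04"),
                      hsi = c(0.5, 0.5, 0.25, 0.25))
  layout <- data.frame(well = wells$well,
                       group_label = c("DMSO", "DMSO", "SUN", "SUN"),
                       dose_uM = c(0, 0, 1, 1), is_control = c(1, 1, 0, 0))
  g <- relative_to_control(wells, layout, "hsi", "DMSO")
  expect_equal(g$percent_of_control[g$group_label == "DMSO"], 100)
  expect_equal(g$percent_of_control[g$group_label == "SUN"], 50)
  expect_error(relative_to_control(wells, layout, "hsi", "missing"),
               "no valid wells")
  wells0 <- wells; wells0$hsi[1:2] <- 0
  expect_error(relative_to_control(wells0, layout, "hsi", "DMSO"),
               "zero")
})

test_that("cutoff search maximizes separation with smallest-tie rule", {
  # perfectly separated classes: every cutoff strictly between the classes
  # attains J = 1; the smallest maximizing grid value is returned
  cut <- optimize_cutoff(rep(5, 20), rep(1, 20), grid = seq(1, 5, 0.5))
  expect_equal(cut, 1.0)   # 1 > 1 is FALSE, so J(1.0) is already 1
  expect_warning(cut2 <- optimize_cutoff(rep(3, 5), rep(3, 5),
                                         grid = seq(1, 5, 0.5)),
                 "grid minimum")
  expect_equal(cut2, 1.0)
})

test_that("grid cutoff agrees with an exhaustive fine-grid maximizer", {
  set.seed(12)
  ctrl <- rnorm(4000, 4.5, 0.8)
  pos <- rnorm(4000, 1.5, 0.8)
  fine <- seq(0.5, 6, by = 0.01)
  j <- vapply(fine, function(cc) mean(ctrl > cc) - mean(pos > cc), 1)
  brute <- fine[which.max(j)]
  cut <- optimize_cutoff(ctrl, pos)
  expect_lt(abs(cut - brute), 0.3)
})

test_that("well counts decompose exactly", {
  set.seed(13)
  cells <- cell_records("W01", c(rnorm(80, 5, 1), rnorm(120, 1, 0.5)))
  wm <- compute_hsi(cells)
  n_not <- wm$n_cells_total - wm$n_healthy
  expect_equal(wm$n_healthy + n_not, wm$n_cells_total)
  expect_gte(wm$hsi, 0); expect_lte(wm$hsi, 1)
})
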