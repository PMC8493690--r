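test_that("cell truth sampling follows the group's healthy fraction", {
  g1 <- group_spec("all", healthy_fraction = 1.0)
  g0 <- group_spec("none", healthy_fraction = 0.0)
  set.seed(1)
  expect_true(all(replicate(50, sample_cell_truth(g1)$healthy)))
  expect_false(any(replicate(50, sample_cell_truth(g0)$healthy)))

  # 10,000 Bernoulli draws at p = 0.5: inside the 99% binomial interval
  gh <- group_spec("half", healthy_fraction = 0.5)
  set.seed(7)
  flags <- vapply(seq_len(10000), function(i) sample_cell_truth(gh)$healthy,
                  TRUE)
  expect_lt(abs(mean(flags) - 0.5), 0.015)
})

test_that("group and noise specifications validate their inputs", {
  expect_error(group_spec("x", healthy_fraction = 1.2), "\\[0, 1\\]")
  expect_error(group_spec("x", z_length_healthy = dist_spec(1, 0.1),
                          z_length_disrupted = dist_spec(2, 0.1)),
               "must exceed")
  expect_error(noise_spec(photon_scale = -1), "non-negative")
  expect_error(sim_config(list(group_spec("a"), group_spec("a"))),
               "unique")
  expect_error(sim_config(list(group_spec("a")), pixel_size_um = 0),
               "positive")
})

test_that("a rendered stripe spans its true length in pixels", {
  # one healthy cell, one 5.0 um segment at 0.25 um/px: 20 px end to end
  img <- stripe_field(5.0, 0, px = 0.25)
  on_rows <- which(rowSums(img > 1250) > 0)
  expect_equal(max(on_rows) - min(on_rows) + 1, 20)
})

test_that("rendering an empty field gives background plus noise only", {
  cfg <- tiny_config(cells = 5)
  set.seed(3)
  out <- render_field(list(), matrix(numeric(0), 0, 2), cfg)
  expect_equal(nrow(out$truth), 0)
  expect_lt(max(out$field$nuclei), 150)  # background 100 + read noise
  expect_equal(count_cells(segment_nuclei(out$field$nuclei, 0.25)), 0)
})

test_that("identical config and seed reproduce fields bit for bit", {
  cfg <- tiny_config(fields = 1L)
  p1 <- simulate_plate(cfg)
  p2 <- simulate_plate(cfg)
  expect_identical(p1$fields[[1]]$nuclei, p2$fields[[1]]$nuclei)
  expect_identical(p1$fields[[1]]$marker, p2$fields[[1]]$marker)
  expect_identical(p1$truth, p2$truth)
})

test_that("plate generation writes wells x fields images and truth tables", {
  cfg <- tiny_config(groups = list(
    group_spec("DMSO", is_control = TRUE),
    group_spec("SUN", dose_uM = 1, healthy_fraction = 0.2)),
    wells = 2L, fields = 3L, cells = 6)
  dir <- withr::local_tempdir()
  paths <- generate_plate(cfg, dir)
  expect_length(paths$images, 2 * 2 * 3)
  expect_true(all(file.exists(unlist(paths))))
  layout <- read.csv(paths$layout)
  expect_setequal(names(layout), c("well", "group_label", "dose_uM",
                                   "is_control"))
  expect_equal(nrow(layout), 4)

  # 16-bit TIFF roundtrip is lossless
  plate <- load_plate(dir, cfg$pixel_size_um)
  expect_length(plate$fields, 12)
  mem <- simulate_plate(cfg)
  f_disk <- plate$fields[[1]]
  f_mem <- mem$fields[[which(vapply(mem$fields, function(f)
    f$well == f_disk$well && f$field == f_disk$field, TRUE))[1]]]
  expect_equal(f_disk$nuclei, f_mem$nuclei, ignore_attr = TRUE)
})

test_that("per-well true fractions equal the per-cell flag means exactly", {
  cfg <- tiny_config(wells = 2L, fields = 2L, cells = 8)
  plate <- simulate_plate(cfg)
  for (w in unique(plate$truth$well)) {
    d <- plate$truth[plate$truth$well == w, ]
    wt <- plate$well_truth[plate$well_truth$well == w, ]
    expect_identical(wt$true_healthy_fraction, mean(d$healthy))
    expect_identical(wt$true_yap_nuclear_fraction, mean(d$yap_nuclear))
  }
})

test_that("lower healthy fraction yields lower downstream HSI", {
  cfg <- tiny_config(groups = list(
    group_spec("hi", healthy_fraction = 0.9, is_control = TRUE),
    group_spec("lo", healthy_fraction = 0.2)),
    wells = 5L, fields = 1L, cells = 15, seed = 11L)
  plate <- simulate_plate(cfg)
  cells <- segment_plate(plate$fields)
  wm <- merge(compute_well_metrics(cells), plate$layout, by = "well")
  hi <- mean(wm$hsi[wm$group_label == "hi"])
  lo <- mean(wm$hsi[wm$group_label == "lo"])
  expect_gt(hi, lo)
})

test_that("placement respects minimum spacing and errors when infeasible", {
  set.seed(2)
  pts <- sarcscreen:::place_cells(30, c(200, 200), 20, 10)
  d <- as.matrix(dist(pts))
  diag(d) <- Inf
  expect_gte(min(d), 20)
  expect_error(sarcscreen:::place_cells(500, c(100, 100), 20, 10),
               "too small")
})
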