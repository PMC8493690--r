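test_that("blank or noise-only fields yield zero nuclei", {
  expect_equal(count_cells(segment_nuclei(matrix(0, 64, 64), 0.25)), 0)
  set.seed(4)
  noisy <- matrix(rpois(64 * 64, 100) + rnorm(64 * 64, 0, 3), 64, 64)
  expect_equal(count_cells(segment_nuclei(noisy, 0.25)), 0)
})

test_that("well-separated rendered nuclei are counted exactly", {
  cfg <- tiny_config(cells = 25, fields = 1L, noiseless = TRUE, seed = 5L)
  plate <- simulate_plate(cfg)
  nuc <- segment_nuclei(plate$fields[[1]]$nuclei, cfg$pixel_size_um)
  expect_equal(count_cells(nuc), nrow(plate$truth))
  # labels are consecutive 1..K
  expect_identical(sort(unique(as.vector(nuc[nuc > 0]))),
                   seq_len(count_cells(nuc)))
})

test_that("counts are additive across a well's fields", {
  cfg <- tiny_config(cells = 10, fields = 3L, seed = 9L)
  plate <- simulate_plate(cfg)
  counts <- vapply(plate$fields, function(f) {
    count_cells(segment_nuclei(f$nuclei, cfg$pixel_size_um))
  }, 1L)
  cells <- segment_plate(plate$fields)
  expect_equal(nrow(cells), sum(counts))
})

test_that("territories partition the marker foreground, one per nucleus", {
  # dumbbell: two nuclei inside one connected marker blob
  nuc_img <- matrix(0, 128, 128)
  mark <- matrix(0, 128, 128)
  nuc_img <- sarcscreen:::draw_ellipse(nuc_img, 64, 40, 18, 12, 0, 3000)
  nuc_img <- sarcscreen:::draw_ellipse(nuc_img, 64, 88, 18, 12, 0, 3000)
  mark <- sarcscreen:::draw_capsule(mark, 64, 64, 0, 1, 80, 44, 800)
  nuc <- segment_nuclei(round(nuc_img), 0.25)
  expect_equal(count_cells(nuc), 2)
  terr <- assign_territories(nuc, round(mark), 0.25)
  expect_equal(sort(unique(terr[terr > 0])), c(1L, 2L))
  # each territory contains exactly its own nucleus
  for (k in 1:2) {
    expect_true(all(terr[nuc == k] == k))
  }
  # territories are disjoint by construction (single label raster) and
  # cover the blob foreground
  blob <- mark > 400
  expect_gt(mean(terr[blob] > 0), 0.95)
})

test_that("single nucleus claims the entire foreground blob", {
  nuc_img <- matrix(0, 96, 96)
  mark <- matrix(0, 96, 96)
  nuc_img <- sarcscreen:::draw_ellipse(nuc_img, 48, 48, 18, 12, 0, 3000)
  mark <- sarcscreen:::draw_ellipse(mark, 48, 48, 35, 25, 0.5, 800)
  nuc <- segment_nuclei(round(nuc_img), 0.25)
  terr <- assign_territories(nuc, round(mark), 0.25)
  blob <- mark > 400
  expect_gt(mean(terr[blob] == 1), 0.95)
})

test_that("straight stripes measure within two pixels at any orientation", {
  px <- 0.25
  for (L in c(1, 2, 4, 5, 8)) {
    for (th in c(0, pi / 4, pi / 2)) {
      segs <- detect_z_lines(stripe_field(L, th, px), NULL, px)
      expect_equal(nrow(segs), 1)
      expect_lt(abs(segs$length_um - L), 2 * px + 1e-9)
    }
  }
})

test_that("blank territories yield no segments", {
  img <- matrix(0, 64, 64)
  segs <- detect_z_lines(img, NULL, 0.25)
  expect_equal(nrow(segs), 0)
})

test_that("measured lengths are scale equivariant", {
  # same physical stripe rendered at two pixel sizes
  for (px in c(0.25, 0.5)) {
    segs <- detect_z_lines(stripe_field(5, pi / 4, px), NULL, px)
    expect_lt(abs(segs$length_um - 5), 2 * px + 1e-9)
  }
})

test_that("per-cell mean Z-line length recovers generator truth", {
  # one healthy cell with known segment lengths near 5 um
  cfg <- tiny_config(cells = 1, fields = 1L, noiseless = TRUE, seed = 21L,
                     healthy_fraction = 1)
  plate <- simulate_plate(cfg)
  cells <- segment_plate(plate$fields)
  expect_equal(nrow(cells), 1)
  expect_lt(abs(cells$mean_z_length_um - plate$truth$mean_true_length_um),
            0.25)
})

test_that("uniform YAP image gives equal nuclear and cytoplasm means", {
  nuc <- matrix(0L, 64, 64)
  nuc[28:36, 28:36] <- 1L
  terr <- matrix(0L, 64, 64)
  terr[20:44, 20:44] <- 1L
  img <- matrix(500, 64, 64)
  ym <- measure_yap(img, nuc, terr)
  expect_equal(ym$yap_nuclear_mean, ym$yap_cytoplasm_mean)
})

test_that("rendered YAP ratios are recovered within 15 percent", {
  for (target in c(2.0, 1.0)) {
    g <- group_spec("g", yap_nuclear_fraction = as.numeric(target > 1.3),
                    yap_ratio_nuclear = dist_spec(target, 0),
                    yap_ratio_cytosolic = dist_spec(target, 0))
    cfg <- sim_config(list(g), mode = "yap_4x", rng_seed = 31L,
                      wells_per_group = 1L, fields_per_well = 1L,
                      cells_per_field_mean = 40,
                      noise = noise_spec(0, 0, 50))
    plate <- simulate_plate(cfg)
    cells <- segment_plate(plate$fields)
    ratio <- cells$yap_nuclear_mean / pmax(cells$yap_cytoplasm_mean, 1e-6)
    expect_lt(abs(median(ratio) - target) / target, 0.15)
  }
})
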