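test_that("thinning reduces a thick stripe to a one-pixel path", {
  m <- matrix(0L, 30, 30)
  m[14:17, 5:25] <- 1L  # 4 px thick horizontal bar
  sk <- thin_binary(m)
  expect_true(all(sk[m == 0] == 0))       # skeleton inside the object
  expect_true(all(rowSums(sk)[rowSums(sk) > 0] > 0))
  expect_lte(max(colSums(sk[, 6:24])), 1) # one pixel per column mid-bar
})

test_that("skeleton path length matches straight and diagonal runs", {
  m <- matrix(0L, 20, 20)
  m[10, 3:14] <- 1L  # 12-pixel horizontal run
  expect_equal(skeleton_path_px(m), 12)
  m2 <- matrix(0L, 20, 20)
  for (i in 1:10) m2[4 + i, 4 + i] <- 1L  # 10-pixel diagonal
  expect_equal(skeleton_path_px(m2), 9 * sqrt(2) + 1)
  m3 <- matrix(0L, 5, 5); m3[3, 3] <- 1L
  expect_equal(skeleton_path_px(m3), 1)
})

test_that("branched skeletons report the longest geodesic path", {
  # a T: 15-px horizontal bar with a 5-px stem off its middle
  m <- matrix(0L, 30, 30)
  m[10, 5:19] <- 1L
  m[11:15, 12] <- 1L
  # longest geodesic runs arm to arm (14 steps), not into the stem
  expect_equal(skeleton_path_px(m), 15)
})
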