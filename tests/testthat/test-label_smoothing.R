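test_that("zero-strength smoothing is the identity with 'none' records", {
  fx <- small_atlas()
  g <- gaussian_label_smoothing(fx$degraded, smooth_params("gaussian", sigma = 0))
  expect_identical(g$labels$data, fx$degraded$data)
  expect_true(all(g$records$filter == "none"))
  a <- adaptive_morph_smoothing(fx$degraded,
                                smooth_params("adaptive_opening", size = 0))
  expect_identical(a$labels$data, fx$degraded$data)
  expect_true(all(a$records$filter == "none"))
})

test_that("Gaussian smoothing barely moves a large smooth ball", {
  b <- array(0L, c(50, 50, 50))
  b[ball_mask(18, 50)] <- 1L
  g <- gaussian_label_smoothing(b, smooth_params("gaussian", sigma = 0.5,
                                                 iterations = 2))
  expect_gte(dice(g$labels == 1L, b == 1L), 0.99)
})

test_that("Gaussian baseline loses the sparse fragmented label; records say so", {
  fx <- memo_fixture("smooth_fixture", function() {
    make_synthetic_atlas(shape = c(64, 64, 64), jitter = 2,
                         fragmented_label = TRUE, seed = 5)
  })
  g <- gaussian_label_smoothing(fx$degraded,
                                smooth_params("gaussian", sigma = 1))
  rec <- g$records
  expect_true(any(rec$n_after == 0L & rec$n_before > 0L))
  frag <- rec[rec$label_id == 9999L, ]
  expect_equal(frag$n_after, 0L)
})

test_that("halved structuring element is used for small labels", {
  # 4000-voxel label (<= 5000): radius 4 halves to 2
  lab <- array(0L, c(30, 30, 30))
  lab[ball_mask(9.8, 30)] <- 2L
  expect_true(sum(lab == 2L) < 5000 && sum(lab == 2L) > 3500)
  a <- adaptive_morph_smoothing(lab, smooth_params("adaptive_opening", size = 4))
  expect_equal(a$records$filter[a$records$label_id == 2L], "opening_halved")
  big <- array(0L, c(40, 40, 40))
  big[ball_mask(13, 40)] <- 2L  # > 5000 voxels
  a2 <- adaptive_morph_smoothing(big, smooth_params("adaptive_opening", size = 4))
  expect_equal(a2$records$filter[1], "opening")
})

test_that("adaptive smoothing never loses a label and stays in the dilation envelope", {
  fx <- memo_fixture("smooth_fixture", function() {
    make_synthetic_atlas(shape = c(64, 64, 64), jitter = 2,
                         fragmented_label = TRUE, seed = 5)
  })
  orig <- fx$degraded$data
  for (size in c(2L, 4L)) {
    a <- adaptive_morph_smoothing(fx$degraded,
                                  smooth_params("adaptive_opening", size = size))
    expect_setequal(label_ids(a$labels), label_ids(fx$degraded))
    expect_true(all(a$records$n_after > 0L))
    # no voxel labeled outside the union of original labels dilated by size
    envelope <- volatlas:::mask_dilate_ball(orig != 0L, size)
    expect_false(any(a$labels$data != 0L & !envelope))
  }
  # the scattered label survives via the closing fallback
  a <- adaptive_morph_smoothing(fx$degraded,
                                smooth_params("adaptive_opening", size = 3))
  expect_equal(a$records$filter[a$records$label_id == 9999L], "closing")
})

test_that("plane interpolation rebuilds intervening masks from signed distances", {
  lab <- array(0L, c(9, 40, 40))
  for (p in c(1, 9)) {
    r <- if (p == 1) 4 else 8
    disk <- outer((seq_len(40) - 20)^2, (seq_len(40) - 20)^2, `+`) <= r^2
    pl <- lab[p, , ]
    pl[disk] <- 3L
    lab[p, , ] <- pl
  }
  out <- interpolate_label_between_planes(lab, 3L, 1, 9)
  # end planes untouched
  expect_identical(out[1, , ], lab[1, , ])
  expect_identical(out[9, , ], lab[9, , ])
  # midpoint: disk of radius 6 +- 1 voxel
  w <- which(out[5, , ] == 3L, arr.ind = TRUE)
  rr <- sqrt((w[, 1] - 20)^2 + (w[, 2] - 20)^2)
  expect_lte(max(rr), 7)
  expect_gte(sqrt(sum(out[5, , ] == 3L) / pi), 5)

  # identical end masks: every intervening plane equals them
  lab2 <- array(0L, c(5, 20, 20))
  disk <- outer((seq_len(20) - 10)^2, (seq_len(20) - 10)^2, `+`) <= 16
  for (p in c(1, 5)) {
    pl <- lab2[p, , ]; pl[disk] <- 1L; lab2[p, , ] <- pl
  }
  out2 <- interpolate_label_between_planes(lab2, 1L, 1, 5)
  for (p in 2:4) expect_identical(out2[p, , ] == 1L, disk)

  # adjacent planes: nothing to do; absent label errors
  expect_identical(interpolate_label_between_planes(lab2, 1L, 1, 2), lab2)
  expect_error(interpolate_label_between_planes(lab2, 7L, 1, 5), "absent")
})

test_that("smoothing records export round-trips through CSV", {
  fx <- small_atlas()
  a <- adaptive_morph_smoothing(fx$degraded,
                                smooth_params("adaptive_opening", size = 2))
  p <- tempfile(fileext = ".csv")
  write_smoothing_records(a$records, p)
  back <- read.csv(p)
  expect_equal(back$n_before, a$records$n_before)
})
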