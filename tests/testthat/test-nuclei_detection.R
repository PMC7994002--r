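test_that("preprocessing honours its range and percentile contracts", {
  expect_true(all(preprocess_roi(array(7, c(8, 8, 8))) == 0))
  set.seed(3)
  x <- array(rexp(16^3), c(16, 16, 16))
  p <- detect_params()
  out <- preprocess_roi(x, p)
  expect_gte(min(out), 0)
  expect_lte(max(out), 1)
  # values above the 98.5th percentile clip to the top of the scale before
  # the saturation step; with saturation at p50 they stay at the maximum
  hi <- quantile(x, 0.985, names = FALSE)
  p2 <- detect_params(unsharp_amount = 0, erosion_size = 0L)
  out2 <- preprocess_roi(x, p2)
  expect_true(all(out2[x > hi] == max(out2)))
})

test_that("a single Gaussian blob is found at its centre and scale", {
  fx <- make_synthetic_nuclei_volume(shape = c(40, 40, 40), n_nuclei = 1,
                                     radius_mean = 5, radius_sd = 0,
                                     snr = 50, seed = 2)
  b <- detect_blobs(fx$vol$data,
                    params = detect_params(nucleus_radius = 5, preprocess = FALSE))
  expect_equal(nrow(b), 1L)
  expect_lt(sqrt(sum((as.numeric(b[1, 1:3]) - as.numeric(fx$truth[1, 1:3]))^2)),
            1)
  expect_lt(abs(b$radius[1] - 5) / 5, 0.3)
  # two spheres well apart give exactly two blobs
  fx2 <- make_synthetic_nuclei_volume(shape = c(40, 40, 40), n_nuclei = 2,
                                      radius_mean = 5, radius_sd = 0,
                                      min_separation = 20, snr = 50, seed = 3)
  b2 <- detect_blobs(fx2$vol$data,
                     params = detect_params(nucleus_radius = 5, preprocess = FALSE))
  expect_equal(nrow(b2), 2L)
  # blank volume: nothing
  expect_equal(nrow(detect_blobs(array(0, c(20, 20, 20)),
                                 params = detect_params(preprocess = FALSE))), 0L)
})

test_that("whole-volume detection is chunk-order independent and near-unchunked", {
  fx <- std_nuclei()
  det <- std_detection()
  single <- det$single
  chunked <- det$chunked
  expect_lte(abs(nrow(chunked) - nrow(single)) / nrow(single), 0.02)
  # a nucleus inside an overlap slab appears exactly once
  overlap_centres <- fx$truth[fx$truth$plane > 55 & fx$truth$plane < 64, ]
  expect_gt(nrow(overlap_centres), 0)
  for (t in seq_len(nrow(overlap_centres))) {
    dd <- sqrt((chunked$plane - overlap_centres$plane[t])^2 +
               (chunked$row - overlap_centres$row[t])^2 +
               (chunked$col - overlap_centres$col[t])^2)
    expect_equal(sum(dd <= 4), 1L)
  }
})

test_that("duplicate pruning merges to means, is idempotent, respects tolerance", {
  blobs <- data.frame(plane = c(10, 11, 30), row = c(10, 10, 10),
                      col = c(10, 10, 10), radius = c(3, 3, 3),
                      response = c(0.5, 0.4, 0.6))
  region <- rbind(c(1, 40), c(1, 40), c(1, 40))
  out <- prune_duplicates(blobs, list(region), tolerance = c(2, 2, 2))
  expect_equal(nrow(out), 2L)
  expect_equal(sort(out$plane), c(10.5, 30))
  # farther apart than tolerance on one axis: both retained
  blobs2 <- data.frame(plane = c(10, 13), row = c(10, 10), col = c(10, 10),
                       radius = c(3, 3), response = c(0.5, 0.4))
  expect_equal(nrow(prune_duplicates(blobs2, list(region), c(2, 2, 2))), 2L)
  # idempotence on pairwise-isolated duplicates
  once <- prune_duplicates(blobs, list(region), c(2, 2, 2))
  twice <- prune_duplicates(once, list(region), c(2, 2, 2))
  expect_identical(once, twice)
  # blobs outside every region untouched; count never increases
  far <- data.frame(plane = 100, row = 100, col = 100, radius = 3,
                    response = 1)
  out2 <- prune_duplicates(rbind(blobs, far), list(region), c(2, 2, 2))
  expect_true(any(out2$plane == 100))
  expect_lte(nrow(out2), nrow(blobs) + 1L)
})

test_that("optimal matching beats greedy and equals the permutation oracle", {
  # greedy nearest-first would pair (9 -> 10) then (12 -> 0): total 13
  truth <- data.frame(plane = c(0, 10, 20), row = 0, col = 0)
  det <- data.frame(plane = c(9, 12, 21), row = 0, col = 0)
  cost <- outer(det$plane, truth$plane, function(a, b) abs(a - b))
  oracle <- brute_assignment(cost)
  got <- volatlas:::hungarian_assign(cost)
  expect_equal(sum(cost[cbind(seq_len(3), got)]), oracle$cost)
  set.seed(21)
  for (t in 1:20) {
    cost <- matrix(runif(36), 6, 6)
    got <- volatlas:::hungarian_assign(cost)
    expect_equal(sum(cost[cbind(1:6, got)]), brute_assignment(cost)$cost,
                 tolerance = 1e-12)
  }
})

test_that("evaluation counts and the two border passes behave as specified", {
  truth <- data.frame(plane = c(10, 20, 30), row = c(10, 20, 30),
                      col = c(10, 20, 30), radius = 3)
  ev <- evaluate_detections(truth, truth, match_tol = 1, inner_margin = 2,
                            spacing = c(1, 1, 1), roi_dim = c(40, 40, 40))
  expect_equal(ev$recall, 1)
  expect_equal(ev$precision, 1)
  ev0 <- evaluate_detections(truth[0, ], truth, match_tol = 1, inner_margin = 2,
                             spacing = c(1, 1, 1), roi_dim = c(40, 40, 40))
  expect_equal(ev0$recall, 0)
  expect_equal(ev0$fn, 3L)
  evee <- evaluate_detections(truth[0, ], truth[0, ], match_tol = 1,
                              inner_margin = 2, spacing = c(1, 1, 1),
                              roi_dim = c(40, 40, 40))
  expect_equal(evee$recall, 1)
  expect_equal(evee$precision, 1)
  # inner truth matched by a border-shell detection in the second pass
  truth2 <- data.frame(plane = 4, row = 20, col = 20, radius = 3)
  det2 <- data.frame(plane = 2.5, row = 20, col = 20, radius = 3)  # border
  ev2 <- evaluate_detections(det2, truth2, match_tol = 3, inner_margin = 2,
                             spacing = c(1, 1, 1), roi_dim = c(40, 40, 40))
  expect_equal(ev2$recall, 1)
  expect_equal(ev2$fn, 0L)
  # counts are consistent within the evaluated region
  fx <- std_nuclei()
  det <- std_detection()$single
  ev3 <- evaluate_detections(det, fx$truth, match_tol = 5, inner_margin = 2,
                             spacing = c(1, 1, 1), roi_dim = c(128, 128, 128))
  n_inner_truth <- sum(fx$truth$plane >= 3 & fx$truth$plane <= 126 &
                       fx$truth$row >= 3 & fx$truth$row <= 126 &
                       fx$truth$col >= 3 & fx$truth$col <= 126)
  expect_equal(round(ev3$recall * n_inner_truth) + ev3$fn, n_inner_truth)
})

test_that("anisotropic input is recovered by near-isotropic interpolation", {
  fx <- make_synthetic_nuclei_volume(shape = c(64, 64, 64), n_nuclei = 10,
                                     min_separation = 18, snr = 20, seed = 6)
  # simulate coarse plane sampling: take every other plane
  coarse <- fx$vol$data[seq(1, 64, by = 2), , ]
  p <- detect_params(nucleus_radius = 5, preprocess = FALSE,
                     isotropic_interp = TRUE)
  b <- detect_blobs(coarse, spacing = c(2, 1, 1), params = p)
  truth_c <- fx$truth
  truth_c$plane <- (truth_c$plane + 1) / 2
  ev <- evaluate_detections(b, truth_c, match_tol = 5, inner_margin = 2,
                            spacing = c(2, 1, 1), roi_dim = c(32, 64, 64))
  expect_gte(ev$recall, 0.8)
})

test_that("grid search surfaces a parameterisation ranking", {
  fx <- make_synthetic_nuclei_volume(shape = c(48, 48, 48), n_nuclei = 8,
                                     min_separation = 16, snr = 10, seed = 8)
  g <- detection_grid_search(fx$vol$data, fx$truth,
                             grid = list(nucleus_radius = c(3, 5),
                                         preprocess = FALSE),
                             match_tol = 5)
  expect_equal(nrow(g), 2L)
  expect_true(all(c("recall", "precision") %in% names(g)))
  expect_gte(g$recall[1], g$recall[nrow(g)] - 1e-9)
})

test_that("blob CSV round-trips", {
  b <- data.frame(plane = c(1.5, 2), row = c(3, 4), col = c(5, 6),
                  radius = c(2, 3), response = c(0.5, 0.6))
  p <- tempfile(fileext = ".csv")
  write_blobs(b, p)
  expect_equal(read_blobs(p), b)
})
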