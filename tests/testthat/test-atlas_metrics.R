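test_that("compactness hits the closed-form anchors and is scale invariant", {
  ball <- ball_mask(30)
  cb <- compactness(ball)
  expect_lt(abs(cb$compactness / (36 * pi) - 1), 0.15)
  cube <- array(FALSE, c(48, 48, 48)); cube[5:44, 5:44, 5:44] <- TRUE
  cc <- compactness(cube)
  expect_lt(abs(cc$compactness / 216 - 1), 0.10)
  expect_equal(compactness(cube, spacing = c(2, 2, 2))$compactness,
               cc$compactness, tolerance = 1e-12)
  expect_error(compactness(array(FALSE, c(3, 3, 3))), "empty")
  # discrete estimates stay above 90% of the continuous sphere bound
  expect_gte(cb$compactness, 0.9 * 36 * pi)
})

test_that("the ball is the most compact of equal-volume shapes", {
  ball <- ball_mask(16)
  n_vox <- sum(ball)
  side <- round(n_vox^(1 / 3))
  cube <- array(FALSE, c(side + 8, side + 8, side + 8))
  cube[5:(4 + side), 5:(4 + side), 5:(4 + side)] <- TRUE
  set.seed(3)
  jagged <- cube
  surf <- which(label_surfaces(array(as.integer(jagged), dim(jagged))))
  jagged[sample(surf, length(surf) %/% 2)] <- FALSE  # roughen the faces
  c_ball <- compactness(ball)$compactness
  c_cube <- compactness(cube)$compactness
  c_jag <- compactness(jagged)$compactness
  expect_lt(c_ball, c_cube)
  expect_lt(c_cube, c_jag)
})

test_that("dice identities and symmetry", {
  a <- array(FALSE, c(4, 5, 10)); a[1:2, , ] <- TRUE
  b <- array(FALSE, c(4, 5, 10)); b[2:3, , ] <- TRUE
  disj <- array(FALSE, c(4, 5, 10)); disj[4, , ] <- TRUE
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, disj), 0)
  expect_equal(dice(a, b), 0.5)  # |A| = |B| = 100, overlap 50
  expect_equal(dice(a, b), dice(b, a))
  expect_equal(dice(array(FALSE, c(2, 2, 2)), array(FALSE, c(2, 2, 2))), 1)
})

test_that("smoothing report identities and bounds", {
  fx <- small_atlas()
  lab <- fx$degraded$data
  rep0 <- smoothing_report(lab, lab)
  expect_true(all(abs(rep0$compaction) < 1e-12))
  expect_true(all(rep0$displacement == 0))
  expect_true(all(abs(rep0$quality) < 1e-12))
  expect_equal(attr(rep0, "labels_lost"), 0L)

  # strictly-inside smoothed label: displacement 0; disjoint: displacement 1
  orig <- array(0L, c(20, 20, 20)); orig[ball_mask(7, 20)] <- 1L
  inner <- array(0L, c(20, 20, 20)); inner[ball_mask(4, 20)] <- 1L
  rin <- smoothing_report(orig, inner)
  expect_equal(rin$displacement, 0)
  shifted <- array(0L, c(20, 20, 20)); shifted[1:3, 1:3, 1:3] <- 1L
  rdis <- smoothing_report(orig, shifted)
  expect_equal(rdis$displacement, 1)

  # atlas-wide quality invariant under label ID permutation
  relab <- lab
  relab[lab == 1L] <- 101L
  relab[lab == 2L] <- 1L
  relab[relab == 101L] <- 2L
  a <- adaptive_morph_smoothing(lab, smooth_params("adaptive_opening", size = 2))
  relab_sm <- a$labels
  relab_sm[a$labels == 1L] <- 101L
  relab_sm[a$labels == 2L] <- 1L
  relab_sm[relab_sm == 101L] <- 2L
  q1 <- attr(smoothing_report(lab, a$labels), "atlas_wide_quality")
  q2 <- attr(smoothing_report(relab, relab_sm), "atlas_wide_quality")
  expect_equal(q1, q2, tolerance = 1e-12)
})

test_that("displacement stays within [0, 1] over randomized mask pairs", {
  set.seed(99)
  for (t in seq_len(200)) {
    o <- array(0L, c(7, 7, 7))
    s <- array(0L, c(7, 7, 7))
    o[sample(343, sample(5:60, 1))] <- 1L
    s[sample(343, sample(5:60, 1))] <- 1L
    r <- smoothing_report(o, s)
    expect_true(r$displacement >= 0 && r$displacement <= 1)
    expect_lte(r$quality, r$compaction)
  }
})

test_that("edge distances equal brute-force nearest-edge search", {
  # coincident surfaces: zero total
  lab <- array(0L, c(6, 6, 6)); lab[3, 3, 3] <- 1L
  edge <- lab == 1L
  expect_equal(edge_distance_stats(lab, edge)$total, 0)
  # single voxel 3 um away
  lab2 <- array(0L, c(1, 1, 9)); lab2[1, 1, 2] <- 1L
  edge2 <- array(FALSE, c(1, 1, 9)); edge2[1, 1, 5] <- TRUE
  expect_equal(edge_distance_stats(lab2, edge2, spacing = c(1, 1, 1))$total, 3)
  # random instance vs oracle, anisotropic spacing
  set.seed(12)
  lab3 <- array(sample(0:2, 9 * 8 * 7, TRUE, prob = c(0.7, 0.15, 0.15)),
                c(9, 8, 7))
  edge3 <- array(runif(9 * 8 * 7) < 0.05, c(9, 8, 7))
  edge3[1, 1, 1] <- TRUE
  got <- edge_distance_stats(lab3, edge3, spacing = c(2, 1, 1))
  want <- brute_edge_dist(lab3, edge3, spacing = c(2, 1, 1))
  expect_equal(got$total, want$total, tolerance = 1e-9)
  expect_equal(got$per_label$sum_dist, unname(want$per_label), tolerance = 1e-9)
  expect_equal(sum(got$per_label$sum_dist), got$total)
  # enlarging the edge map cannot increase the total
  edge4 <- edge3 | array(runif(length(edge3)) < 0.1, dim(edge3))
  expect_lte(edge_distance_stats(lab3, edge4, spacing = c(2, 1, 1))$total,
             got$total)
  expect_error(edge_distance_stats(lab3, array(FALSE, dim(lab3))), "empty")
})

test_that("intensity CV uses the population sd and volume weights", {
  lab <- array(1L, c(4, 4, 4))
  vol <- array(5, c(4, 4, 4))
  cv0 <- intensity_cv(vol, lab)
  expect_equal(cv0$cv, 0)
  # equal counts of 0 and 2: mu 1, sigma 1, CV 1
  vol2 <- array(rep(c(0, 2), 32), c(4, 4, 4))
  expect_equal(intensity_cv(vol2, lab)$cv, 1)
  # volume-weighted aggregate equals hand computation
  lab3 <- array(0L, c(6, 6, 6))
  lab3[1:2, , ] <- 1L
  lab3[3:6, , ] <- 2L
  set.seed(5)
  vol3 <- array(rexp(216) + 1, c(6, 6, 6))
  got <- intensity_cv(vol3, lab3)
  by_hand <- vapply(1:2, function(id) {
    v <- vol3[lab3 == id]
    sqrt(mean((v - mean(v))^2)) / mean(v)
  }, 0)
  w <- c(sum(lab3 == 1L), sum(lab3 == 2L))
  expect_equal(got$cv, by_hand)
  expect_equal(attr(got, "weighted_mean_cv"), sum(by_hand * w) / sum(w))
  # zero-mean labels are flagged and excluded
  vol4 <- vol3
  vol4[lab3 == 1L] <- 0
  expect_warning(got4 <- intensity_cv(vol4, lab3), "zero mean")
  expect_true(is.na(got4$cv[1]))
  expect_equal(attr(got4, "weighted_mean_cv"), by_hand[2])
})
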