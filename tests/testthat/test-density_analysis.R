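test_that("heat maps conserve in-bounds blob counts", {
  b <- data.frame(plane = c(1, 2.4, 2.6, 50), row = c(1, 3, 3, 1),
                  col = c(1, 3, 3, 1))
  hm <- nuclei_heatmap(b, shape = c(5, 5, 5))
  expect_equal(hm[1, 1, 1], 1L)
  expect_equal(hm[2, 3, 3] + hm[3, 3, 3], 2L)  # two blobs, rounded voxels
  expect_equal(sum(hm), 3L)
  expect_equal(attr(hm, "n_dropped"), 1L)
  set.seed(9)
  n <- 300
  b2 <- data.frame(plane = runif(n, 1, 20), row = runif(n, 1, 20),
                   col = runif(n, 1, 20))
  expect_equal(sum(nuclei_heatmap(b2, shape = c(20, 20, 20))), n)
})

test_that("per-label stats equal brute-force masked sums", {
  lab <- array(0L, c(10, 10, 10))
  lab[1:5, , ] <- 1L
  lab[6:10, , ] <- 2L
  hm <- array(1L, c(10, 10, 10))
  st <- per_label_stats(hm, label_volume(lab, spacing = c(20, 1, 1)))
  expect_equal(st$count, c(500L, 500L))
  expect_equal(st$volume_mm3, rep(500 * 20 * 1e-9, 2))
  expect_equal(st$density_cv, c(0, 0))
  # counts over labels conserve the heat-map total within the labeled region
  set.seed(10)
  hm2 <- array(rpois(1000, 0.5), c(10, 10, 10))
  st2 <- per_label_stats(hm2, lab)
  expect_equal(sum(st2$count), sum(hm2[lab != 0L]))
  by_hand <- sapply(1:2, function(id) sum(hm2[lab == id]))
  expect_equal(st2$count, by_hand)
})

test_that("DBSCAN parameterisation follows the 2*ndim rule", {
  expect_equal(dbscan_min_samples(3), 6L)
  expect_equal(cluster_params()$min_samples, 6L)
  expect_equal(cluster_params()$eps, 20)
})

test_that("per-label clustering matches the density-reachability oracle", {
  lab <- array(1L, c(5, 40, 40))
  # 10 mutually close points: one cluster, no noise
  pts <- data.frame(plane = rep(3, 10), row = 10 + runif(10, 0, 2),
                    col = 10 + runif(10, 0, 2))
  cl <- cluster_label_nuclei(pts, lab, spacing = c(1, 1, 1))
  expect_equal(cl$n_clusters, 1L)
  expect_equal(cl$n_noise, 0L)
  # 5 mutually distant points with min_samples 6: all noise
  far <- data.frame(plane = rep(3, 5), row = c(1, 1, 39, 39, 20) + 0.0,
                    col = c(1, 39, 1, 39, 20) + 0.0)
  cl2 <- cluster_label_nuclei(far, lab, spacing = c(5, 5, 5))
  expect_equal(cl2$n_clusters, 0L)
  expect_equal(cl2$n_noise, 5L)
  # random cloud vs oracle
  set.seed(14)
  n <- 150
  pts3 <- cbind(runif(n, 0, 60), runif(n, 0, 60), runif(n, 0, 60))
  got <- volatlas:::cpp_dbscan(pts3, 12, 4L)
  want <- brute_dbscan(pts3, 12, 4L)
  expect_equal(max(got), want$n_clusters)
  expect_equal(got == 0L, unname(want$noise))
  # core points must agree exactly on cluster partition
  core_idx <- which(want$core)
  relabel <- function(v) as.integer(factor(v, levels = unique(v)))
  expect_equal(relabel(got[core_idx]), relabel(want$labels[core_idx]))
})

test_that("total noise is invariant to label ID permutation", {
  set.seed(15)
  lab <- array(0L, c(6, 30, 30))
  lab[, 1:15, ] <- 1L
  lab[, 16:30, ] <- 2L
  pts <- data.frame(plane = runif(80, 1, 6), row = runif(80, 1, 30),
                    col = runif(80, 1, 30))
  a <- cluster_label_nuclei(pts, lab, spacing = c(4, 4, 4))
  lab2 <- lab
  lab2[lab == 1L] <- 7L
  lab2[lab == 2L] <- 1L
  b <- cluster_label_nuclei(pts, lab2, spacing = c(4, 4, 4))
  expect_equal(attr(a, "total_noise"), attr(b, "total_noise"))
})

test_that("k-NN elbow distances match brute force and lattice geometry", {
  # cubic lattice with pitch 3: points with >= 5 face neighbours (8 interior
  # + 24 face points of the 4x4x4 grid) have their 5th-NN distance at the
  # pitch; edge and corner points reach into the diagonals
  g <- expand.grid(i = 1:4, j = 1:4, k = 1:4) * 3
  d6 <- knn_elbow_distances(as.matrix(g), k = 5)
  expect_equal(d6[1:32], rep(3, 32))
  expect_true(all(d6 >= 3 - 1e-9))
  expect_false(is.unsorted(d6))
  set.seed(16)
  pts <- matrix(runif(90), ncol = 3)
  got <- knn_elbow_distances(pts, k = 5, spacing = c(2, 1, 1))
  want <- sort(brute_knn_kth(sweep(pts, 2, c(2, 1, 1), `*`), 5))
  expect_equal(got, unname(want), tolerance = 1e-12)
  expect_error(knn_elbow_distances(pts[1:4, ], k = 5), "more than k")
})

test_that("misaligning a label boundary through nucleus clumps raises noise", {
  d <- c(4, 160, 60)
  true_lab <- array(0L, d)
  true_lab[, , 1:30] <- 1L
  true_lab[, , 31:60] <- 2L
  shifted <- array(0L, d)
  shifted[, , 1:26] <- 1L   # boundary moved 4 voxels into region 1
  shifted[, , 27:60] <- 2L
  # clumps of 6 nuclei spanning columns 24..29 (mutually within eps), clump
  # centres > eps apart: wholly inside label 1 under the true boundary,
  # split 3/3 by the shifted one
  clumps <- lapply(1:6, function(t) {
    data.frame(plane = rep(2, 6), row = rep(25 * t, 6), col = 24:29)
  })
  blobs <- do.call(rbind, clumps)
  p <- cluster_params(eps = 20, min_samples = 6)
  noise_true <- attr(cluster_label_nuclei(blobs, true_lab,
                                          spacing = c(1, 1, 1), p),
                     "total_noise")
  noise_shift <- attr(cluster_label_nuclei(blobs, shifted,
                                           spacing = c(1, 1, 1), p),
                      "total_noise")
  expect_equal(noise_true, 0L)
  expect_gt(noise_shift, noise_true)
})
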