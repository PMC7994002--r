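test_that("extension start scanning skips discontiguous labeled planes", {
  lab <- array(0L, c(60, 6, 6))
  lab[10:50, 3:4, 3:4] <- 1L
  expect_equal(find_extension_start(lab), 10L)
  expect_equal(find_extension_start(lab, override = 13L), 13L)
  lab[5, 3, 3] <- 1L  # isolated plane
  expect_equal(find_extension_start(lab), 10L)
  expect_error(find_extension_start(array(0L, c(4, 4, 4))), "no labeled")
})

test_that("lateral extension reproduces unlabeled planes of the phantom", {
  fx <- memo_fixture("ext_fixture", function() {
    make_synthetic_atlas(shape = c(64, 64, 64), jitter = 1,
                         unlabeled_fraction = 0.15, seed = 9)
  })
  lab <- fx$degraded
  st <- find_extension_start(lab)
  expect_equal(st, 10L)  # floor(0.15 * 64) = 9 unlabeled planes
  edge <- anatomical_edge_map(fx$vol, lab, edge_map_params(gaussian_sigma = 2))
  ext <- extend_labels_lateral(fx$vol, lab, st, edge,
                               extension_params(erosion_base = 2))
  # no new label IDs
  expect_true(all(label_ids(ext) %in% label_ids(lab)))
  # per-plane DSC against ground truth on reconstructed planes with tissue
  for (p in c(6, 8, 9)) {
    tp <- fx$truth$data[p, , ]
    ep <- ext$data[p, , ]
    ids <- setdiff(unique(as.vector(tp)), 0L)
    dscs <- vapply(ids, function(id) {
      dice(array(tp == id, c(dim(tp), 1)), array(ep == id, c(dim(tp), 1)))
    }, 0)
    expect_gte(mean(dscs), 0.85)
    # every above-threshold voxel labeled
    fg <- tp != 0L  # tissue equals truth foreground in the phantom
    expect_gte(dice(array(ep != 0L, c(dim(tp), 1)), array(fg, c(dim(tp), 1))),
               0.95)
  }
  # labels absent from the template stay absent: the central core label
  # does not extend into far-lateral planes where truth lacks it
  core_planes_truth <- which(apply(fx$truth$data == 1L, 1, any))
  expect_false(any(ext$data[seq_len(min(core_planes_truth) - 1L), , ] == 1L))
})

test_that("extension with no unlabeled planes is the identity", {
  fx <- small_atlas()
  edge <- anatomical_edge_map(fx$vol, fx$truth, edge_map_params(gaussian_sigma = 2))
  first_labeled <- min(which(apply(fx$truth$data != 0L, 1, any)))
  out <- extend_labels_lateral(fx$vol, fx$truth, first_labeled, edge,
                               extension_params())
  expect_identical(out$data, fx$truth$data)
  expect_error(
    extend_labels_lateral(fx$vol, fx$degraded,
                          which(!apply(fx$degraded$data != 0L, 1, any))[1],
                          edge, extension_params()),
    "no labels")
})

test_that("compressed planes expand to the histology bounding box", {
  d <- c(3, 40, 30)
  vol <- array(0, d)
  vol[2, 5:36, 4:27] <- 100          # foreground bbox rows 5:36, cols 4:27
  vol[2, 39:40, 1:2] <- 100          # small blob, removed as < min_object_px
  lab <- array(0L, d)
  lab[2, 10:25, 8:20] <- 4L          # compressed labels
  out <- expand_compressed_planes(vol, lab, planes = 2L)
  w <- which(out[2, , ] == 4L, arr.ind = TRUE)
  expect_equal(range(w[, 1]), c(5, 36))
  expect_equal(range(w[, 2]), c(4, 27))
  # area scales roughly by the bbox area ratio
  ratio <- (32 * 24) / (16 * 13)
  expect_lt(abs(sum(out[2, , ] == 4L) / sum(lab[2, , ] == 4L) - ratio), 0.2 * ratio)
  # already-matching bbox: unchanged
  lab2 <- array(0L, d)
  lab2[2, 5:36, 4:27] <- 4L
  out2 <- expand_compressed_planes(vol, lab2, planes = 2L)
  expect_identical(out2, lab2)
  # empty foreground: warn, unchanged
  expect_warning(out3 <- expand_compressed_planes(array(0, d), lab, planes = 2L),
                 "foreground")
  expect_identical(out3, lab)
})

test_that("in-plane rotation: identity, exact right angles, small-angle loss", {
  x <- array(rnorm(5 * 9 * 9), c(5, 9, 9))
  expect_identical(rotate_to_midline(x, list(list(plane = 1, degrees = 0))), x)
  mk <- array(0L, c(5, 21, 21)); mk[3, 8, 15] <- 1L
  r <- rotate_to_midline(mk, list(list(plane = 1, degrees = 90)))
  # out(u, v) = in(v, n + 1 - u) for a quarter turn about the slice centre
  expect_equal(which(r == 1L, arr.ind = TRUE)[1, ], c(dim1 = 3, dim2 = 7, dim3 = 8))
  blob <- array(0, c(12, 40, 40)); blob[4:9, 15:25, 15:25] <- 1
  back <- rotate_to_midline(rotate_to_midline(blob, list(list(plane = 1, degrees = 3))),
                            list(list(plane = 1, degrees = -3)))
  expect_gte(dice(blob > 0.5, back > 0.5), 0.95)
})

test_that("mirroring follows the documented reflection index map", {
  set.seed(6)
  v <- array(rnorm(1000), c(10, 10, 10))
  l <- array(sample(0:3, 1000, TRUE), c(10, 10, 10))
  mm <- mirror_across_midline(v, l, mirror_params(0.5))
  for (i in 1:10) {
    expect_identical(mm$vol[i, , ], mm$vol[11 - i, , ])
    expect_identical(mm$labels[i, , ], mm$labels[11 - i, , ])
  }
  # labels confined to the kept half double exactly
  l2 <- array(0L, c(10, 10, 10)); l2[2:4, 3:6, 3:6] <- 5L
  mm2 <- mirror_across_midline(v, l2, mirror_params(0.5))
  expect_equal(sum(mm2$labels != 0L), 2L * sum(l2 != 0L))
  # fraction 0.48, N = 100: output plane i > 48 takes input plane 97 - i
  v3 <- array(seq_len(100), c(100, 1, 1))
  mm3 <- mirror_across_midline(v3, array(0L, c(100, 1, 1)), mirror_params(0.48))
  expect_equal(as.vector(mm3$vol)[49:96], 48:1)
  expect_equal(as.vector(mm3$vol)[97:100], rep(1, 4))  # clamped
  # involution on the reflected half
  mm4 <- mirror_across_midline(mm3$vol, mm3$labels, mirror_params(0.48))
  expect_identical(mm4$vol, mm3$vol)
})

test_that("piecewise affine shear ramps, anchors, conserves and clips", {
  x <- array(0L, c(12, 20, 12)); x[4:8, 4:8, 4:8] <- 7L
  roi <- rbind(c(1, 12), c(1, 20), c(1, 12))
  expect_identical(piecewise_affine_shear(x, roi, 1, 2, max_shift = 0), x)
  sh <- piecewise_affine_shear(x, roi, 1, 2, max_shift = 6)
  expect_equal(sum(sh == 7L), sum(x == 7L))  # no content reaches the border
  # plane k shifted by round(6 (k-1) / 11) along axis 2
  for (k in c(4, 8)) {
    shift <- as.integer(round(6 * (k - 1) / 11))
    expected <- matrix(0L, 20, 12)
    expected[(1 + shift):20, ] <- x[k, 1:(20 - shift), ]
    expect_identical(sh[k, , ], expected)
  }
  at <- piecewise_affine_shear(x, roi, 1, 2, attach_axis = 3, max_shift = 6)
  expect_identical(at[, , 1], x[, , 1])  # attachment face anchored
  expect_identical(at[1, , ], x[1, , ])  # zero-shift end anchored
  expect_error(piecewise_affine_shear(x, roi, 1, 2, max_shift = 25), "extent")
  # clipping: content pushed past the ROI edge disappears
  x2 <- array(0L, c(6, 6, 6)); x2[6, 5:6, 3] <- 1L
  sh2 <- piecewise_affine_shear(x2, rbind(c(1, 6), c(1, 6), c(1, 6)), 1, 2,
                                max_shift = 3)
  expect_lt(sum(sh2), sum(x2))
})

test_that("stripping keeps the dilated label neighbourhood and crops with pad", {
  d <- c(30, 30, 30)
  vol <- array(50, d)
  lab <- array(0L, d)
  lab[12:18, 12:18, 12:18] <- 2L
  st <- strip_non_cns(vol, lab, pad = 5, dilate = 2)
  expect_equal(dim(st$labels), c(17, 17, 17))  # bbox 7 + 2*5 pad
  # voxels within the ball-2 dilation keep intensity; farther ones are zeroed
  keep <- st$vol != 0
  dil <- volatlas:::mask_dilate_ball(st$labels != 0L, 2)
  expect_identical(keep, dil)
  # brute check of the ball-2 dilation on a small window
  w <- which(st$labels != 0L, arr.ind = TRUE)
  far <- st$vol[1, 1, 1]
  expect_equal(far, 0)
  expect_error(strip_non_cns(vol, array(0L, d)), "empty")
})
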