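test_that("volumes validate spacing and shape", {
  expect_error(volume(array(0, c(2, 2, 2)), spacing = c(1, -1, 1)), "positive")
  expect_error(volume(1:8), "array")
  expect_error(label_volume(array(0.5, c(2, 2, 2))), "integer")
  v <- volume(array(runif(8), c(2, 2, 2)), spacing = c(20, 1, 1))
  expect_s3_class(v, "volume")
  expect_false(is_label_volume(v))
  l <- label_volume(array(1:8, c(2, 2, 2)))
  expect_true(is_label_volume(l))
  expect_identical(label_ids(l), 1:8)
})

test_that("MHD and NRRD round-trips are bit-exact for integers and doubles", {
  lab <- label_volume(array(sample.int(1000L, 64), c(4, 4, 4)),
                      spacing = c(20, 1.5, 1.5))
  vol <- volume(array(rnorm(64), c(4, 4, 4)), spacing = c(20, 1.5, 1.5))
  for (ext in c(".mhd", ".nrrd")) {
    p1 <- tempfile(fileext = ext)
    write_volume(lab, p1)
    back <- read_volume(p1, label = TRUE)
    expect_identical(back$data, lab$data)
    expect_equal(back$spacing, lab$spacing)
    p2 <- tempfile(fileext = ext)
    write_volume(vol, p2)
    expect_identical(read_volume(p2)$data, vol$data)
  }
})

test_that("NIfTI written by an independent writer reads with its spacing", {
  skip_if_not_installed("oro.nifti")
  arr <- array(sample.int(99L, 3 * 4 * 5, replace = TRUE), c(3, 4, 5))
  nii <- oro.nifti::nifti(arr, datatype = 8L)  # int32
  oro.nifti::pixdim(nii)[2:4] <- c(20, 1, 1)
  p <- tempfile()
  oro.nifti::writeNIfTI(nii, p)
  v <- read_volume(paste0(p, ".nii.gz"), label = TRUE)
  expect_equal(v$spacing, c(20, 1, 1))
  expect_equal(as.integer(v$data), as.integer(arr))
})

test_that("NIfTI round-trip preserves integer labels bit-exactly", {
  lab <- label_volume(array(sample.int(5000L, 60), c(3, 4, 5)),
                      spacing = c(25, 1, 1))
  p <- tempfile(fileext = ".nii.gz")
  write_volume(lab, p)
  back <- read_volume(p, label = TRUE)
  expect_identical(back$data, lab$data)
  expect_equal(back$spacing, lab$spacing)
})

test_that("TIFF stacks round-trip integers and demand explicit spacing", {
  lab <- label_volume(array(sample.int(60000L, 48), c(3, 4, 4)))
  p <- tempfile(fileext = ".tif")
  write_volume(lab, p)
  expect_error(read_volume(p), "spacing")
  back <- read_volume(p, spacing = c(5, 1, 1), label = TRUE)
  expect_identical(back$data, lab$data)
})

test_that("a truncated raw file errors instead of zero-filling", {
  lab <- label_volume(array(1:27, c(3, 3, 3)))
  p <- tempfile(fileext = ".mhd")
  write_volume(lab, p)
  rawfile <- sub("\\.mhd$", ".raw", p)
  bytes <- readBin(rawfile, "raw", file.info(rawfile)$size)
  writeBin(bytes[1:40], rawfile)
  expect_error(read_volume(p, label = TRUE), "truncated")
})

test_that("unsupported formats are rejected", {
  f <- tempfile(fileext = ".xyz")
  writeLines("x", f)
  expect_error(read_volume(f), "unsupported")
})

test_that("threshold_foreground obeys its contract on constructed inputs", {
  z <- array(0, c(4, 4, 4))
  expect_false(any(threshold_foreground(z, "fixed", value = 10)))
  half <- array(rep(c(0, 100), each = 32), c(4, 4, 4))
  m <- threshold_foreground(half, "mean")  # threshold 50, strict >
  expect_identical(m, half > 50)
  expect_warning(m0 <- threshold_foreground(z, "otsu"), "constant")
  expect_false(any(m0))
  expect_error(threshold_foreground(half, "fixed"), "value")
})

test_that("otsu foreground recovers the phantom tissue mask", {
  fx <- small_atlas()
  expect_gte(dice(threshold_foreground(fx$vol$data, "otsu"), fx$tissue), 0.95)
})

test_that("in-painting matches the brute-force nearest-donor search", {
  # line with equidistant center voxel: documented lowest-linear-index tie-break
  lab <- array(0L, c(1, 1, 9))
  lab[1, 1, 1] <- 1L
  lab[1, 1, 9] <- 2L
  filled <- in_paint_labels(lab, array(TRUE, dim(lab)))
  expect_identical(as.vector(filled), c(1L, 1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L))

  set.seed(31)
  lab <- array(0L, c(12, 11, 10))
  lab[sample(length(lab), 25)] <- sample(1:4, 25, replace = TRUE)
  target <- array(runif(length(lab)) < 0.4, dim(lab))
  got <- in_paint_labels(lab, target)
  expect_identical(got, brute_inpaint(lab, target))
  # anisotropic spacing changes the metric, still matches brute force
  lv <- label_volume(lab, spacing = c(4, 1, 2))
  got2 <- in_paint_labels(lv, target)
  expect_identical(got2$data, brute_inpaint(lab, target, c(4, 1, 2)))

  # contracts
  expect_identical(in_paint_labels(lab, lab != 0L), lab)
  one <- array(0L, c(3, 3, 3)); one[2, 2, 2] <- 7L
  expect_true(all(in_paint_labels(one, array(TRUE, dim(one))) == 7L))
  expect_error(in_paint_labels(array(0L, c(2, 2, 2)), array(TRUE, c(2, 2, 2))),
               "donor")
  expect_true(all(unique(as.vector(got)) %in% c(0L, unique(as.vector(lab)))))
  expect_identical(sum(target & got == 0L), 0L)
})

test_that("downsampling: chunked equals unchunked, labels stay order-0", {
  set.seed(4)
  x <- array(runif(64^3), c(64, 64, 64))
  a <- downsample(x, c(23, 17, 9))
  b <- downsample(x, c(23, 17, 9), chunked = TRUE, chunk_planes = 5L)
  expect_identical(a, b)

  lab <- array(sample(c(0L, 3L, 17L, 90L), 64^3, replace = TRUE), c(64, 64, 64))
  al <- downsample(lab, c(13, 21, 7))
  bl <- downsample(lab, c(13, 21, 7), chunked = TRUE, chunk_planes = 4L)
  expect_identical(al, bl)
  expect_true(all(unique(as.vector(al)) %in% unique(as.vector(lab))))

  # trivial cases
  expect_identical(downsample(lab, dim(lab)), lab)
  const <- array(7, c(8, 8, 8))
  expect_true(all(downsample(const, c(4, 4, 4)) == 7))
  # spacing rescales by the shape ratio
  v <- volume(x, spacing = c(2, 1, 1))
  expect_equal(downsample(v, c(32, 32, 32))$spacing, c(4, 2, 2))
  # upsampling a label volume stays order-0
  up <- downsample(label_volume(lab[1:8, 1:8, 1:8]), c(16, 16, 16))
  expect_true(all(unique(as.vector(up$data)) %in% unique(as.vector(lab))))
})

test_that("ontology tables read from CSV", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("id,name,parent_id,level", "1,forebrain,0,1", "2,midbrain,0,1"), p)
  ont <- read_ontology(p)
  expect_equal(ont$name[ont$id == 2], "midbrain")
  lv <- read_volume({
    f <- tempfile(fileext = ".mhd")
    write_volume(label_volume(array(1:8, c(2, 2, 2))), f)
    f
  }, label = TRUE, ontology = ont)
  expect_equal(lv$ontology$name[1], "forebrain")
})
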