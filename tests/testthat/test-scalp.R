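test_that("scalp interpolation is exact for constants, nodes and planes", {
  set.seed(31)
  pos <- cbind(runif(24), runif(24))
  # constant field
  rc <- interpolate_scalp(rep(4.2, 24), pos, c(15, 15))
  expect_true(all(abs(rc$grid[rc$mask] - 4.2) < 1e-12))
  expect_true(all(is.na(rc$grid[!rc$mask])))
  # analytic plane reproduced at interior grid points
  vals <- 2 + 3 * pos[, 1] - 1.5 * pos[, 2]
  rp <- interpolate_scalp(vals, pos, c(21, 21))
  gx <- seq(min(pos[, 1]), max(pos[, 1]), length.out = 21)
  gy <- seq(min(pos[, 2]), max(pos[, 2]), length.out = 21)
  plane <- outer(gx, gy, function(x, y) 2 + 3 * x - 1.5 * y)
  expect_lt(max(abs(rp$grid - plane), na.rm = TRUE), 1e-6)
  # bounded by channel range (linear scheme)
  set.seed(32)
  v2 <- rnorm(24)
  rb <- interpolate_scalp(v2, pos, c(15, 15))
  expect_gte(min(rb$grid, na.rm = TRUE), min(v2) - 1e-12)
  expect_lte(max(rb$grid, na.rm = TRUE), max(v2) + 1e-12)
  # exact at a channel location: put a grid that passes through a channel
  pos3 <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(0.5, 0.5))
  r3 <- interpolate_scalp(c(1, 2, 3, 4, 9), pos3, c(3, 3))
  expect_equal(r3$grid[2, 2], 9, tolerance = 1e-6)  # centre node = 5th channel
  expect_equal(r3$grid[1, 1], 1, tolerance = 1e-6)
})

test_that("scalp interpolation rejects degenerate channel sets", {
  expect_error(interpolate_scalp(1:2, cbind(c(0, 1), c(0, 1)), c(4, 4)), "3 channels")
  dup <- rbind(c(0, 0), c(0, 0), c(1, 1), c(0, 1))
  expect_error(interpolate_scalp(1:4, dup, c(4, 4)), "duplicate")
  col <- cbind(seq(0, 1, length.out = 5), seq(0, 1, length.out = 5))
  expect_error(interpolate_scalp(1:5, col, c(4, 4)), "collinear")
})

test_that("scalp-time volumes honour the shape and mask contracts", {
  sim <- tiny_group(n_subjects = 1, seed = 12)
  ds <- sim$datasets[[1]]
  set <- build_scalp_time_volumes(ds, c(12, 12))
  expect_equal(dim(set$volumes), c(12, 12, 8, length(ds$condition_labels)))
  expect_equal(dim(set$mask), c(12, 12, 8))
  # mask constant across time slices and across repeated builds
  expect_true(all(apply(set$mask, 3, identical, set$mask[, , 1])))
  set2 <- build_scalp_time_volumes(ds, c(12, 12))
  expect_identical(set$mask, set2$mask)
  # zero channel data propagates to zero volumes inside the mask
  ds0 <- eeg_dataset(array(0, dim(ds$data)), ds$channel_positions,
                     ds$time_axis, ds$condition_labels)
  v0 <- build_scalp_time_volumes(ds0, c(12, 12))
  expect_true(all(v0$volumes[, , , 1][v0$mask] == 0))
})

test_that("a -100..400 ms window at 200 Hz yields 101 time slices", {
  ta <- seq(-100, 400, by = 5)
  expect_length(ta, 101)
  dat <- array(rnorm(2 * 4 * 101), c(2, 4, 101))
  pos <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  ds <- eeg_dataset(dat, pos, ta, c("A", "B"))
  set <- build_scalp_time_volumes(ds, c(6, 6))
  expect_equal(dim(set$volumes)[3], 101L)
  expect_equal(set$grid_meta$voxel_size[3], 5)
  expect_equal(set$grid_meta$origin[3], -100)
})

test_that("NIfTI round trip preserves data, mask and metadata", {
  sim <- tiny_group(n_subjects = 1, seed = 21)
  set <- build_scalp_time_volumes(sim$datasets[[1]], c(12, 12))
  dir <- withr::local_tempdir()
  write_volumes(set, dir)
  back <- read_volumes(dir)
  expect_identical(back$mask, set$mask)
  expect_equal(back$condition_labels, set$condition_labels)
  expect_equal(back$grid_meta$voxel_size, set$grid_meta$voxel_size)
  in_mask <- which(set$mask)
  for (t in c(1, dim(set$volumes)[4])) {
    expect_equal(back$volumes[, , , t][in_mask], set$volumes[, , , t][in_mask],
                 tolerance = 1e-6)  # float32 storage
  }
  # NaN voxels on disk come back masked
  expect_true(all(is.na(back$volumes[, , , 1][!back$mask])))
})

test_that("mixed shapes across NIfTI files are rejected", {
  dir <- withr::local_tempdir()
  RNifti::writeNifti(RNifti::asNifti(array(1, c(4, 4, 2))), file.path(dir, "a.nii"))
  RNifti::writeNifti(RNifti::asNifti(array(1, c(5, 4, 2))), file.path(dir, "b.nii"))
  expect_error(read_volumes(c(file.path(dir, "a.nii"), file.path(dir, "b.nii"))),
               "shape")
})

test_that("sanitize_source_map zeroes NaNs and counts them", {
  v <- array(c(NaN, 1.5, NaN, 2), c(2, 2, 1))
  expect_message(out <- sanitize_source_map(v), "2")
  expect_equal(as.vector(out), c(0, 1.5, 0, 2))
  expect_equal(attr(out, "n_replaced"), 2L)
  # all-finite volume is untouched
  vf <- array(1:8, c(2, 2, 2))
  expect_equal(as.vector(sanitize_source_map(vf)), as.vector(vf))
  # all-NaN volume warns
  expect_warning(z <- sanitize_source_map(array(NaN, c(2, 2, 1))), "no finite")
  expect_true(all(z == 0))
})
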