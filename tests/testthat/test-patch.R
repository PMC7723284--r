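# Three-view patch extraction, boundary handling, sampling, augmentation.

ramp_volume <- function(n = 32) {
  # I[x, y, z] = (x-1) + 10 (y-1) + 100 (z-1)
  g <- seq_len(n) - 1
  outer(outer(g, 10 * g, `+`), 100 * g, `+`)
}

test_that("view patches equal direct index slices on a ramp volume", {
  vol <- ramp_volume(32)
  spec <- patch_spec(4, 4)
  v <- c(9, 9, 9)
  ax <- extract_view_patch(vol, v, "axial", spec)
  expect_equal(dim(ax), c(4, 4))
  expect_equal(ax[1, 1], 6 + 60 + 800)
  expect_equal(ax, vol[7:10, 7:10, 9])
  expect_equal(extract_view_patch(vol, v, "coronal", spec), vol[7:10, 9, 7:10])
  expect_equal(extract_view_patch(vol, v, "sagittal", spec), vol[9, 7:10, 7:10])
})

test_that("constant volumes give constant patches; bounds are not padded", {
  vol <- array(7, c(96, 96, 96))
  p <- extract_view_patch(vol, c(48, 48, 48), "axial")
  expect_equal(dim(p), c(32, 32))
  expect_true(all(p == 7))
  expect_error(extract_view_patch(vol, c(2, 48, 48), "axial"), "does not fit")
  expect_error(extract_view_patch(vol, c(48, 48, 90), "sagittal"), "does not fit")
})

test_that("TVP stacks axial/coronal/sagittal channels in order", {
  vol <- ramp_volume(48)
  spec <- patch_spec(8, 8)
  v <- c(20, 22, 24)
  tvp <- extract_tvp(vol, v, spec, roi_code = 17L, class_label = "NC")
  expect_equal(dim(tvp$data), c(8, 8, 3))
  expect_equal(tvp$data[, , 1], extract_view_patch(vol, v, "axial", spec))
  expect_equal(tvp$data[, , 2], extract_view_patch(vol, v, "coronal", spec))
  expect_equal(tvp$data[, , 3], extract_view_patch(vol, v, "sagittal", spec))
  # the center pixel of every channel is the voxel value itself
  ctr <- spec$alpha / 2 + 1
  expect_equal(unique(tvp$data[ctr, ctr, ]), vol[v[1], v[2], v[3]])
  expect_equal(dim(extract_tvp(vol, c(24, 24, 24))$data), c(32, 32, 3))
})

test_that("random-voxel patches equal the brute-force slicing oracle", {
  set.seed(31)
  vol <- array(rnorm(40^3), c(40, 40, 40))
  spec <- patch_spec(6, 6)
  for (rep in 1:25) {
    v <- sample(10:30, 3, replace = TRUE)
    expect_identical(
      extract_view_patch(vol, v, "axial", spec),
      vol[(v[1] - 3):(v[1] + 2), (v[2] - 3):(v[2] + 2), v[3]]
    )
    expect_identical(
      extract_view_patch(vol, v, "coronal", spec),
      vol[(v[1] - 3):(v[1] + 2), v[2], (v[3] - 3):(v[3] + 2)]
    )
    expect_identical(
      extract_view_patch(vol, v, "sagittal", spec),
      vol[v[1], (v[2] - 3):(v[2] + 2), (v[3] - 3):(v[3] + 2)]
    )
  }
})

test_that("boundary voxels are those with a differing 6-neighbor", {
  seg <- array(0L, c(9, 9, 9))
  seg[3:7, 3:7, 3:7] <- 17L
  expect_false(is_boundary_voxel(seg, c(5, 5, 5)))
  expect_true(is_boundary_voxel(seg, c(3, 5, 5)))
  iso <- array(0L, c(5, 5, 5))
  iso[3, 3, 3] <- 53L
  expect_true(is_boundary_voxel(iso, c(3, 3, 3)))
  # volume-face voxels are always boundary
  face <- array(17L, c(5, 5, 5))
  expect_true(is_boundary_voxel(face, c(1, 3, 3)))
  expect_false(is_boundary_voxel(face, c(3, 3, 3)))
})

test_that("training enumeration emits exactly one TVP per in-bounds labeled voxel", {
  scan <- cached_nc_scan()
  ds <- enumerate_training_tvps(scan)
  seg <- scan$segmentation
  in_catalog <- sum(seg %in% default_roi_catalog()$code)
  # all structure voxels fit their windows at the default geometry
  expect_equal(nrow(ds$info), in_catalog)
  expect_equal(attr(ds, "n_skipped"), 0L)
  expect_true(all(ds$info$class_label == "NC"))
  # every emitted center carries the recorded label
  labs <- seg[cbind(ds$info$x, ds$info$y, ds$info$z)]
  expect_identical(labs, ds$info$roi_code)
  # restricted enumeration matches a direct voxel count
  ds17 <- enumerate_training_tvps(scan, codes = 17L)
  expect_equal(nrow(ds17$info), sum(seg == 17L))
})

test_that("enumeration of an unlabeled scan is empty", {
  scan <- cached_nc_scan()
  scan$segmentation <- array(0L, dim(scan$segmentation))
  ds <- enumerate_training_tvps(scan)
  expect_equal(nrow(ds$info), 0)
  expect_equal(dim(ds$data)[4], 0)
})

test_that("test sampling draws distinct interior voxels, reproducibly", {
  scan <- cached_nc_scan()
  ds <- sample_test_tvps(scan, 17L, n = 32, seed = 6)
  expect_equal(nrow(ds$info), 32)
  centers <- ds$info[, c("x", "y", "z")]
  expect_equal(nrow(unique(centers)), 32)
  for (i in seq_len(32)) {
    expect_false(is_boundary_voxel(scan$segmentation, unlist(centers[i, ])))
  }
  ds2 <- sample_test_tvps(scan, 17L, n = 32, seed = 6)
  expect_identical(ds$info, ds2$info)
  ds3 <- sample_test_tvps(scan, 17L, n = 32, seed = 7)
  expect_false(identical(ds$info, ds3$info))
})

test_that("test sampling errors when a region is too small, naming it", {
  seg <- array(0L, c(96, 96, 96))
  seg[40:42, 40:42, 40:42] <- 18L # 27 voxels, 1 interior
  scan <- list(
    subject_id = "tiny", class_label = "NC",
    volume = array(0, c(96, 96, 96)), segmentation = seg
  )
  expect_error(sample_test_tvps(scan, 18L, n = 32, seed = 1), "region 18")
})

test_that("augmentation with zero ranges is the identity; rescale acts linearly", {
  scan <- cached_nc_scan()
  tvp <- extract_tvp(scan$volume, c(34, 46, 44))
  same <- augment_tvp(tvp, seed = 1, shear_deg = 0, zoom = 0, rescale = 0)
  expect_equal(same$data, tvp$data, tolerance = 1e-12)

  const <- array(3, c(32, 32, 3))
  out <- augment_tvp(const, seed = 11, shear_deg = 0, zoom = 0, rescale = 0.1)
  f <- out[1, 1, 1] / 3
  expect_true(f >= 0.9 && f <= 1.1)
  expect_equal(out, const * f, tolerance = 1e-12)

  warped <- augment_tvp(tvp, seed = 5)
  expect_equal(dim(warped$data), c(32, 32, 3))
  expect_false(identical(warped$data, tvp$data))
})
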