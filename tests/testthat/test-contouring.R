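test_that("structure approximation thresholds the smoothed volume against intensity_max", {
  # uniform volume exactly at the 105 per-mille boundary is all foreground
  u <- grayscale_volume(array(105, c(6, 6, 6)), 0.082, intensity_max = 1000)
  st <- approximate_structure(u, contour_params())
  expect_true(all(st$data))
  # all-zero volume gives an empty structure
  z <- grayscale_volume(array(0, c(6, 6, 6)), 0.082, intensity_max = 1000)
  expect_false(any(approximate_structure(z)$data))
})

test_that("structure approximation equals direct convolution + threshold on a phantom shell", {
  ph <- generate_phantom(phantom_spec(shape = c(24L, 22L, 22L),
                                      geometry = "spherical_shell",
                                      cortical_thickness_voxels = 3L))
  g <- ph$grayscale
  st <- approximate_structure(g, contour_params())
  # oracle: explicit normalized 3x3x3 Gaussian, sigma 0.8, then >= 0.105 max
  k1 <- exp(-(-1:1)^2 / (2 * 0.8^2))
  kern <- outer(outer(k1, k1), k1); dim(kern) <- c(3, 3, 3)
  kern <- kern / sum(kern)
  d <- dim(g$data)
  sm <- array(0, d)
  wn <- array(0, d)
  for (di in -1:1) for (dj in -1:1) for (dl in -1:1) {
    # shift with zero padding; track the in-lattice kernel mass for the
    # boundary renormalization
    out <- array(0, d)
    cov <- array(0, d)
    i1 <- pmax(1, 1 + di):pmin(d[1], d[1] + di)
    j1 <- pmax(1, 1 + dj):pmin(d[2], d[2] + dj)
    l1 <- pmax(1, 1 + dl):pmin(d[3], d[3] + dl)
    out[i1, j1, l1] <- g$data[i1 - di, j1 - dj, l1 - dl]
    cov[i1, j1, l1] <- 1
    sm <- sm + kern[di + 2, dj + 2, dl + 2] * out
    wn <- wn + kern[di + 2, dj + 2, dl + 2] * cov
  }
  ref <- sm / wn >= 0.105 * g$intensity_max
  expect_identical(st$data, ref)
  # the noise-free shell at 40% of max is recovered up to a one-voxel band
  # of partially averaged surface voxels
  expect_true(all(st$data[ph$truth$bone$data]))
  expect_false(any(st$data & !dilate_voxels(ph$truth$bone$data, 1L)))
})

test_that("lowering the threshold never shrinks the structure foreground", {
  ph <- generate_phantom(phantom_spec(shape = c(20L, 20L, 20L),
                                      geometry = "spherical_shell",
                                      cortical_thickness_voxels = 3L,
                                      blur_sigma_voxels = 0.8))
  hi <- approximate_structure(ph$grayscale, contour_params(threshold_permille = 200))
  lo <- approximate_structure(ph$grayscale, contour_params(threshold_permille = 105))
  expect_true(all(lo$data[hi$data]))
})

test_that("close_and_fill bridges narrow gaps, fills cavities and matches the brute-force oracle", {
  set.seed(31)
  # hollow sphere with wall gaps narrower than twice the closing radius
  d <- c(26L, 26L, 26L)
  A <- array(0, d)
  I1 <- slice.index(A, 1); I2 <- slice.index(A, 2); I3 <- slice.index(A, 3)
  r2 <- (I1 - 13.5)^2 + (I2 - 13.5)^2 + (I3 - 13.5)^2
  shellv <- r2 <= 8^2 & r2 > 5^2
  shellv[12:15, 12:15, 1:26] <- shellv[12:15, 12:15, 1:26] &
    !(I3[12:15, 12:15, 1:26] > 18)              # carve a gap ~4 wide
  solid <- close_and_fill(binary_volume(shellv, 0.082), 3L)
  ball <- r2 <= 8^2
  expect_true(all(solid$data[ball & r2 <= 5^2]))  # interior filled
  expect_identical(solid$data, oracle_close_and_fill(shellv, 3L))

  # already-solid cube is unchanged (idempotence on a convex solid)
  cube <- array(FALSE, c(20, 20, 20))
  cube[5:16, 5:16, 5:16] <- TRUE
  expect_identical(close_and_fill(binary_volume(cube, 0.082), 7L)$data, cube)

  # blobs farther apart than twice the closing radius stay separate
  two <- array(FALSE, c(30, 14, 14))
  two[3:6, 5:10, 5:10] <- TRUE
  two[24:27, 5:10, 5:10] <- TRUE
  closed <- close_and_fill(binary_volume(two, 0.082), 3L)
  expect_equal(max(label_components(closed$data)), 2L)
  expect_identical(closed$data, oracle_close_and_fill(two, 3L))
})

test_that("close_and_fill output contains its input and errors on empty structures", {
  set.seed(32)
  for (i in 1:6) {
    d <- sample(8:14, 3L, replace = TRUE)
    a <- array(stats::runif(prod(d)) > 0.9, d)
    if (!any(a)) a[2, 2, 2] <- TRUE
    out <- close_and_fill(binary_volume(a, 0.082), 2L)
    expect_true(all(out$data[a]))
  }
  expect_error(close_and_fill(binary_volume(array(FALSE, c(4, 4, 4)), 0.082), 3L),
               class = "cb_validation_error")
  expect_error(auto_contour(grayscale_volume(array(0, c(6, 6, 6)), 0.082,
                                             intensity_max = 100)),
               class = "cb_validation_error")
})

test_that("auto_contour is deterministic and reproduces the phantom periosteal solid to one voxel", {
  ph <- generate_phantom(six_config_spec())
  c1 <- auto_contour(ph$grayscale)
  c2 <- auto_contour(ph$grayscale)
  expect_identical(c1$data, c2$data)
  tru <- ph$truth$periosteal_solid$data
  # within a one-voxel surface band in both directions
  expect_true(all(c1$data[erode_voxels(tru, 1L)]))
  expect_false(any(c1$data & !dilate_voxels(tru, 1L)))
  # channel mouths are bridged: below the one-voxel surface band the solid
  # covers every through-channel opening (precondition for detection)
  expect_true(all(c1$data[erode_voxels(tru, 1L) &
                            ph$truth$channel_labels$data > 0]))
})

test_that("corrected contours load verbatim up to cavity filling and validate the lattice", {
  ph <- generate_phantom(phantom_spec(shape = c(24L, 22L, 22L),
                                      geometry = "spherical_shell",
                                      cortical_thickness_voxels = 3L))
  auto <- auto_contour(ph$grayscale)
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "contour.nii")
  write_volume(auto, f)
  loaded <- load_corrected_contour(f, gray = ph$grayscale)
  expect_identical(loaded$data, auto$data)   # identical contour, identical pipeline
  # a cavity introduced by the operator is filled on load
  holed <- auto$data
  holed[12, 11, 11] <- FALSE
  lo <- load_corrected_contour(binary_volume(holed, 0.082))
  expect_true(lo$data[12, 11, 11])
  # mismatched lattice is rejected
  small <- binary_volume(array(TRUE, c(4, 4, 4)), 0.082)
  expect_error(load_corrected_contour(small, gray = ph$grayscale),
               class = "cb_validation_error")
})
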