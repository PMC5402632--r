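test_that("the cortical mask of a cube has the exact shell count and face structure", {
  d <- c(28L, 28L, 28L)
  s <- array(FALSE, d)
  s[5:24, 5:24, 5:24] <- TRUE
  mask <- build_cortical_mask(binary_volume(s, 0.082), detection_params())
  expect_equal(sum(mask$shell$data), 20^3 - 12^3)   # 6272
  expect_equal(mask$thickness_mm, 4 * 0.082)
  # faces are disjoint subsets of the shell here (local thickness >= 2)
  expect_false(any(mask$periosteal_face$data & mask$endosteal_face$data))
  expect_true(all(mask$shell$data[mask$periosteal_face$data]))
  expect_true(all(mask$shell$data[mask$endosteal_face$data]))
})

test_that("an exhausted solid yields shell = solid, an empty endosteal face and a warning", {
  d <- c(13L, 13L, 13L)
  A <- array(0, d)
  I1 <- slice.index(A, 1); I2 <- slice.index(A, 2); I3 <- slice.index(A, 3)
  ball <- (I1 - 7)^2 + (I2 - 7)^2 + (I3 - 7)^2 <= 3^2
  expect_warning(mask <- build_cortical_mask(binary_volume(ball, 0.082),
                                             detection_params()),
                 "endosteal face is empty")
  expect_identical(mask$shell$data, ball)
  expect_false(any(mask$endosteal_face$data))
  expect_error(build_cortical_mask(binary_volume(array(FALSE, c(4, 4, 4)), 0.082)),
               class = "cb_validation_error")
})

test_that("a plus-cross channel through the mask is one interruption of exactly 20 voxels", {
  sl <- slab_with_channel("plus", 3L)
  mask <- build_cortical_mask(binary_volume(sl$solid, sl$voxel_size_mm),
                              detection_params())
  res <- detect_interruptions(binary_volume(sl$bone, sl$voxel_size_mm), mask,
                              detection_params())
  expect_equal(res$n_interruptions, 1L)
  expect_equal(res$records$voxel_count, 20L)
  expect_equal(res$records$volume_mm3, 20 * 0.082^3)
  expect_equal(res$records$surface_mm2, 20 * 0.082^3 / 0.328)
})

test_that("channels narrower than 3 voxels and blind pits are not detected", {
  dp <- detection_params()
  two <- slab_with_channel("square", 2L)
  mask <- build_cortical_mask(binary_volume(two$solid, two$voxel_size_mm), dp)
  res2 <- detect_interruptions(binary_volume(two$bone, two$voxel_size_mm), mask, dp)
  expect_equal(res2$n_interruptions, 0L)
  # blind pit reaching only the periosteal face (outer two layers of the wall)
  blind <- slab_with_channel("plus", 3L, k_range = 15:17)
  resb <- detect_interruptions(binary_volume(blind$bone, blind$voxel_size_mm),
                               mask, dp)
  expect_equal(resb$n_interruptions, 0L)
  # blind pit from the endosteal side only
  endo <- slab_with_channel("plus", 3L, k_range = 11:14)
  rese <- detect_interruptions(binary_volume(endo$bone, endo$voxel_size_mm),
                               mask, dp)
  expect_equal(rese$n_interruptions, 0L)
})

test_that("two disjoint qualifying channels are counted separately", {
  sl <- slab_with_channel("plus", 3L, ctr = c(7L, 7L))
  offs <- rbind(c(0L, 0L), c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  for (k in 11:17) for (p in 1:5)
    sl$bone[17L + offs[p, 1], 17L + offs[p, 2], k] <- FALSE
  dp <- detection_params()
  mask <- build_cortical_mask(binary_volume(sl$solid, sl$voxel_size_mm), dp)
  res <- detect_interruptions(binary_volume(sl$bone, sl$voxel_size_mm), mask, dp)
  expect_equal(res$n_interruptions, 2L)
  expect_equal(res$records$voxel_count, c(20L, 20L))
  # records sorted by size then centroid; labels renumbered 1..n
  expect_equal(res$records$label, 1:2)
  expect_equal(n_labels(res$label_map), 2L)
})

test_that("detection agrees with the brute-force oracle on random configurations", {
  set.seed(51)
  for (i in 1:12) {
    d <- sample(10:18, 3L, replace = TRUE)
    solid <- random_solid(d)
    if (sum(solid) < 30) next
    dp <- detection_params(min_component_voxels = sample(c(1L, 5L, 20L), 1L))
    mask <- suppressWarnings(build_cortical_mask(binary_volume(solid, 0.082), dp))
    bone <- random_bone(solid, d)
    res <- detect_interruptions(binary_volume(bone, 0.082), mask, dp)
    ref <- oracle_detect(bone, mask$shell$data, mask$periosteal_face$data,
                         mask$endosteal_face$data, r = 1L,
                         min_vox = dp$min_component_voxels)
    expect_identical(label_sets(res$label_map$data), label_sets(ref))
  }
})

test_that("no record falls below the minimum component size and counts are rotation invariant", {
  set.seed(52)
  sl <- slab_with_channel("plus", 3L)
  dp <- detection_params()
  base <- detect_interruptions(
    binary_volume(sl$bone, sl$voxel_size_mm),
    build_cortical_mask(binary_volume(sl$solid, sl$voxel_size_mm), dp), dp)
  expect_true(all(base$records$voxel_count >= dp$min_component_voxels))
  perms <- list(c(2, 1, 3), c(3, 2, 1), c(1, 3, 2))
  for (p in perms) {
    solid_p <- aperm(sl$solid, p)
    bone_p <- aperm(sl$bone, p)
    res_p <- detect_interruptions(
      binary_volume(bone_p, sl$voxel_size_mm),
      build_cortical_mask(binary_volume(solid_p, sl$voxel_size_mm), dp), dp)
    expect_equal(res_p$n_interruptions, base$n_interruptions)
    expect_equal(sort(res_p$records$voxel_count),
                 sort(base$records$voxel_count))
  }
  # mirror flip along the slice axis
  flip <- function(a) a[rev(seq_len(dim(a)[1])), , ]
  res_f <- detect_interruptions(
    binary_volume(flip(sl$bone), sl$voxel_size_mm),
    build_cortical_mask(binary_volume(flip(sl$solid), sl$voxel_size_mm), dp), dp)
  expect_equal(res_f$n_interruptions, base$n_interruptions)
})

test_that("adding bone voxels never increases the void volume", {
  set.seed(53)
  sl <- slab_with_channel("square", 4L)
  dp <- detection_params()
  mask <- build_cortical_mask(binary_volume(sl$solid, sl$voxel_size_mm), dp)
  shell <- mask$shell$data
  bone1 <- sl$bone
  void_of <- function(bone) sum(shell & !dilate_voxels(bone & shell, 1L))
  for (i in 1:5) {
    empty <- which(!bone1 & sl$solid)
    bone2 <- bone1
    bone2[sample(empty, min(10, length(empty)))] <- TRUE
    expect_lte(void_of(bone2), void_of(bone1))
    bone1 <- bone2
  }
})

test_that("generation-2 parameters give the printed mask thickness and minimum diameter", {
  gen2 <- detection_geometry(voxel_size_mm = 0.061, mask_thickness_voxels = 5L)
  expect_equal(gen2$mask_thickness_mm, 0.305)
  expect_equal(gen2$min_diameter_mm, 0.183)
  gen1 <- detection_geometry(voxel_size_mm = 0.082, mask_thickness_voxels = 4L)
  expect_equal(gen1$min_diameter_mm, 0.246)
  expect_equal(gen1$mask_thickness_mm, 0.328)
  expect_equal(gen1$min_volume_voxels, 20L)
  expect_equal(gen1$min_volume_mm3, 20 * 0.082^3)
})

test_that("joint summaries aggregate deterministically", {
  sl <- slab_with_channel("plus", 3L)
  dp <- detection_params()
  res <- detect_interruptions(
    binary_volume(sl$bone, sl$voxel_size_mm),
    build_cortical_mask(binary_volume(sl$solid, sl$voxel_size_mm), dp), dp)
  s <- summarize_interruptions(res)
  expect_equal(s$n_interruptions, 1L)
  expect_equal(s$total_surface_mm2, res$records$surface_mm2)
  # empty result
  empty <- detect_interruptions(
    binary_volume(sl$solid, sl$voxel_size_mm),
    build_cortical_mask(binary_volume(sl$solid, sl$voxel_size_mm), dp), dp)
  se <- summarize_interruptions(empty)
  expect_equal(se$n_interruptions, 0L)
  expect_equal(se$total_surface_mm2, 0)
  # additivity of surfaces is by construction: volume / thickness per record
  expect_equal(res$total_surface_mm2, sum(res$records$volume_mm3) / 0.328)
})
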