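# Shared phantom builders.
#
# six_config_spec() carves the six archetypal configurations of the
# detection criteria into one capsule phantom: three qualifying channels
# (through the cortex, width >= 3: a minimal plus-cross, a 3x3 square, a
# 5-voxel-wide circle) and three non-qualifying ones (a 2-voxel-wide through
# channel, a blind periosteal pit, a blind endosteal pit).
six_config_spec <- function(blur = 0, noise = 0, seed = 1L) {
  chans <- list(
    channel_spec(axis = 2, direction = +1, cross_section = "plus_cross",
                 width_voxels = 3, depth = "through", position = c(26L, 28L)),
    channel_spec(axis = 2, direction = -1, cross_section = "square",
                 width_voxels = 3, depth = "through", position = c(32L, 28L)),
    channel_spec(axis = 3, direction = +1, cross_section = "circle",
                 width_voxels = 5, depth = "through", position = c(38L, 28L)),
    channel_spec(axis = 3, direction = -1, cross_section = "square",
                 width_voxels = 2, depth = "through", position = c(26L, 28L)),
    channel_spec(axis = 2, direction = +1, cross_section = "plus_cross",
                 width_voxels = 3, depth = "blind_periosteal",
                 position = c(38L, 28L)),
    channel_spec(axis = 3, direction = +1, cross_section = "plus_cross",
                 width_voxels = 3, depth = "blind_endosteal",
                 position = c(32L, 28L))
  )
  phantom_spec(shape = c(64L, 56L, 56L), outer_radius_voxels = 16,
               channels = chans,
               trabecular = list(strut_spacing_voxels = 8L,
                                 strut_thickness_voxels = 2L),
               blur_sigma_voxels = blur, noise_sd_fraction = noise,
               seed = seed)
}

# Five qualifying channels of width >= 3 spread over shaft and cap.
five_channel_spec <- function(blur = 0, noise = 0, seed = 1L) {
  chans <- list(
    channel_spec(axis = 2, direction = +1, cross_section = "square",
                 width_voxels = 3, depth = "through", position = c(26L, 28L)),
    channel_spec(axis = 2, direction = -1, cross_section = "circle",
                 width_voxels = 5, depth = "through", position = c(32L, 28L)),
    channel_spec(axis = 3, direction = +1, cross_section = "square",
                 width_voxels = 4, depth = "through", position = c(38L, 28L)),
    channel_spec(axis = 3, direction = -1, cross_section = "circle",
                 width_voxels = 3, depth = "through", position = c(26L, 28L)),
    channel_spec(axis = 1, direction = +1, cross_section = "square",
                 width_voxels = 3, depth = "through", position = c(28L, 28L))
  )
  phantom_spec(shape = c(64L, 56L, 56L), outer_radius_voxels = 16,
               channels = chans,
               trabecular = list(strut_spacing_voxels = 8L,
                                 strut_thickness_voxels = 2L),
               blur_sigma_voxels = blur, noise_sd_fraction = noise,
               seed = seed)
}

# Flat-wall fixture: a slab solid with a carved channel, where every voxel
# count is known exactly. Returns solid, bone and the voxel size.
slab_with_channel <- function(cross = "plus", width = 3L, k_range = 11:17,
                              d = c(24L, 24L, 20L), wall = 4:16,
                              ctr = c(12L, 12L)) {
  solid <- array(FALSE, d)
  solid[, , wall] <- TRUE
  bone <- solid
  offs <- if (cross == "plus") {
    h <- (width - 1L) %/% 2L
    rbind(cbind(seq.int(-h, h), 0L), cbind(0L, seq.int(-h, h)))
  } else {
    as.matrix(expand.grid(0:(width - 1L), 0:(width - 1L)))
  }
  for (k in k_range)
    for (p in seq_len(nrow(offs)))
      bone[ctr[1] + offs[p, 1], ctr[2] + offs[p, 2], k] <- FALSE
  list(solid = solid, bone = bone, voxel_size_mm = 0.082)
}
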