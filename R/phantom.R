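# Synthetic joint phantoms with exact ground truth.
#
# A phantom is a closed cortical shell (sphere, capsule = cylinder with
# hemispherical caps at both ends, or ellipsoid) of known thickness around a
# medullary interior (optionally with an axis-aligned rod lattice standing in
# for trabeculae), into which channels and pits of known cross-section, width
# and depth are carved. The ground truth (periosteal solid, bone, channel
# label map, and which channels meet the detection criteria) is computed from
# the analytic geometry alone and shares no code with the detection module,
# so agreement between the two is a genuine test.

#' Channel specification for a phantom
#'
#' @param axis lattice axis the channel runs along (1 = slice, 2, 3).
#' @param direction `+1` to enter from the low-index border, `-1` from the
#'   high-index border.
#' @param cross_section `"plus_cross"`, `"square"` or `"circle"`. Plus and
#'   circle cross-sections require an odd width.
#' @param width_voxels in-plane width of the channel (voxels).
#' @param depth `"through"` (pierces the whole cortex), `"blind_periosteal"`
#'   (opens at the periosteal surface only), `"blind_endosteal"` (opens at
#'   the endosteal surface only) or `"intracortical"` (enclosed cavity).
#' @param position integer pair: channel centre in the two non-axis
#'   dimensions (default: lattice centre).
#' @return An object of class `cb_channel_spec`.
#' @export
channel_spec <- function(axis = 2L, direction = 1L,
                         cross_section = c("plus_cross", "square", "circle"),
                         width_voxels = 3L,
                         depth = c("through", "blind_periosteal",
                                   "blind_endosteal", "intracortical"),
                         position = NULL) {
  axis <- as.integer(axis)
  if (!axis %in% 1:3) stop_validation("axis must be 1, 2 or 3")
  direction <- as.integer(direction)
  if (!direction %in% c(-1L, 1L)) stop_validation("direction must be +1 or -1")
  cross_section <- match.arg(cross_section)
  width_voxels <- as.integer(width_voxels)
  if (width_voxels < 1L) stop_validation("width_voxels must be >= 1")
  if (cross_section %in% c("plus_cross", "circle") && width_voxels %% 2L == 0L)
    stop_validation("plus_cross and circle cross-sections require odd width")
  depth <- match.arg(depth)
  structure(list(axis = axis, direction = direction,
                 cross_section = cross_section, width_voxels = width_voxels,
                 depth = depth, position = position),
            class = "cb_channel_spec")
}

#' Phantom specification
#'
#' Defaults emulate a first-generation HR-pQCT finger-joint acquisition:
#' 82 um voxels, a cortical shell 5 voxels (~0.41 mm) thick — close to the
#' 0.39 mm average cortical thickness of MCP joints — bone at 40% of the
#' acquisition maximum on a zero background.
#'
#' @param shape lattice dimensions (slices, rows, cols).
#' @param voxel_size_mm isotropic voxel size (default 0.082).
#' @param geometry `"capped_cylinder_shell"` (capsule, default),
#'   `"spherical_shell"` or `"ellipsoid_shell"`.
#' @param cortical_thickness_voxels shell thickness in voxels (default 5).
#' @param outer_radius_voxels outer radius (default: largest radius leaving a
#'   6-voxel background margin).
#' @param channels list of [channel_spec()] objects; carved regions must not
#'   overlap.
#' @param trabecular `NULL` or `list(strut_spacing_voxels, strut_thickness_voxels)`
#'   for an axis-aligned rod lattice inside the medullary cavity.
#' @param intensity `list(bone_fraction_of_max, background_fraction)`
#'   (defaults 0.4 and 0).
#' @param intensity_max maximum possible voxel value (default 32767, a
#'   signed 16-bit export).
#' @param blur_sigma_voxels Gaussian blur of the rendered volume (0 = none).
#' @param noise_sd_fraction additive Gaussian noise standard deviation as a
#'   fraction of the bone intensity, truncated at 0 (0 = none).
#' @param seed RNG seed for the noise (generation is deterministic given the
#'   seed).
#' @return An object of class `cb_phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 56L, 56L), voxel_size_mm = 0.082,
                         geometry = c("capped_cylinder_shell",
                                      "spherical_shell", "ellipsoid_shell"),
                         cortical_thickness_voxels = 5L,
                         outer_radius_voxels = NULL,
                         channels = list(), trabecular = NULL,
                         intensity = list(bone_fraction_of_max = 0.4,
                                          background_fraction = 0),
                         intensity_max = 32767,
                         blur_sigma_voxels = 0, noise_sd_fraction = 0,
                         seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L))
    stop_validation("shape must be three dimensions of at least 8 voxels")
  geometry <- match.arg(geometry)
  cortical_thickness_voxels <- as.integer(cortical_thickness_voxels)
  if (cortical_thickness_voxels < 1L)
    stop_validation("cortical_thickness_voxels must be >= 1")
  if (!is.list(channels) ||
      !all(vapply(channels, inherits, logical(1), "cb_channel_spec")))
    stop_validation("channels must be a list of channel_spec() objects")
  if (is.null(intensity$bone_fraction_of_max))
    intensity$bone_fraction_of_max <- 0.4
  if (is.null(intensity$background_fraction))
    intensity$background_fraction <- 0
  if (blur_sigma_voxels < 0 || noise_sd_fraction < 0)
    stop_validation("blur_sigma_voxels and noise_sd_fraction must be >= 0")
  structure(list(shape = shape,
                 voxel_size_mm = check_scalar_pos(voxel_size_mm, "voxel_size_mm"),
                 geometry = geometry,
                 cortical_thickness_voxels = cortical_thickness_voxels,
                 outer_radius_voxels = outer_radius_voxels,
                 channels = channels, trabecular = trabecular,
                 intensity = intensity,
                 intensity_max = check_scalar_pos(intensity_max, "intensity_max"),
                 blur_sigma_voxels = blur_sigma_voxels,
                 noise_sd_fraction = noise_sd_fraction,
                 seed = as.integer(seed)),
            class = "cb_phantom_spec")
}

# Analytic solid for a given margin shrink `shrink` (0 = periosteal surface,
# t = endosteal surface). Pure geometry, no morphology.
phantom_solid <- function(spec, shrink = 0) {
  d <- spec$shape
  A <- array(0, d)
  I1 <- slice.index(A, 1); I2 <- slice.index(A, 2); I3 <- slice.index(A, 3)
  ctr <- (d + 1) / 2
  margin <- 6
  if (spec$geometry == "spherical_shell") {
    R0 <- if (is.null(spec$outer_radius_voxels))
      floor(min(d) / 2) - margin else spec$outer_radius_voxels
    R <- R0 - shrink
    if (R <= 0) return(array(FALSE, d))
    (I1 - ctr[1])^2 + (I2 - ctr[2])^2 + (I3 - ctr[3])^2 <= R^2
  } else if (spec$geometry == "capped_cylinder_shell") {
    R0 <- if (is.null(spec$outer_radius_voxels))
      floor(min(d[2], d[3]) / 2) - margin else spec$outer_radius_voxels
    R <- R0 - shrink
    if (R <= 0) return(array(FALSE, d))
    zA <- margin + R0
    zB <- d[1] - margin - R0
    if (zB < zA) stop_validation("lattice too short for a capsule phantom")
    dz <- pmax(0, zA - I1, I1 - zB)
    dz^2 + (I2 - ctr[2])^2 + (I3 - ctr[3])^2 <= R^2
  } else { # ellipsoid_shell
    ax <- if (is.null(spec$outer_radius_voxels))
      d / 2 - margin else rep(spec$outer_radius_voxels, 3)
    ax <- ax - shrink
    if (any(ax <= 0)) return(array(FALSE, d))
    ((I1 - ctr[1]) / ax[1])^2 + ((I2 - ctr[2]) / ax[2])^2 +
      ((I3 - ctr[3]) / ax[3])^2 <= 1
  }
}

# Cross-section offsets (u, v) of a channel in its two non-axis dimensions.
channel_offsets <- function(cross_section, width) {
  h <- (width - 1) %/% 2
  if (cross_section == "plus_cross") {
    offs <- rbind(cbind(seq.int(-h, h), 0L), cbind(0L, seq.int(-h, h)))
  } else if (cross_section == "square") {
    g <- expand.grid(u = seq.int(-h, width - 1L - h), v = seq.int(-h, width - 1L - h))
    offs <- as.matrix(g)
  } else { # circle
    g <- expand.grid(u = seq.int(-h, h), v = seq.int(-h, h))
    offs <- as.matrix(g[g$u^2 + g$v^2 <= (h + 0.25)^2, , drop = FALSE])
  }
  unique(offs)
}

# Does the cross-section contain a centred plus-cross of width 3? (The
# geometric qualification criterion, evaluated independently of detection.)
contains_plus3 <- function(offs) {
  need <- rbind(c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  all(apply(need, 1, function(p) any(offs[, 1] == p[1] & offs[, 2] == p[2])))
}

# Linear voxel indices carved by one channel, computed from the analytic
# solid/inner geometry by scanning the channel's central column from its
# entry border.
carve_channel <- function(ch, solid, inner, d) {
  ax <- ch$axis
  others <- setdiff(1:3, ax)
  pos <- ch$position
  if (is.null(pos)) pos <- floor((d[others] + 1) / 2)
  pos <- as.integer(pos)
  if (length(pos) != 2L || any(pos < 1L) || any(pos > d[others]))
    stop_validation("channel position outside the lattice")
  line_of <- function(arr) {
    co <- list(NULL, NULL, NULL)
    co[[ax]] <- seq_len(d[ax]); co[[others[1]]] <- pos[1]; co[[others[2]]] <- pos[2]
    arr[co[[1]], co[[2]], co[[3]]]
  }
  ls <- line_of(solid); li <- line_of(inner)
  ord <- if (ch$direction > 0) seq_len(d[ax]) else rev(seq_len(d[ax]))
  sA <- which(ls[ord])[1]
  iA <- which(li[ord])[1]
  if (is.na(sA) || is.na(iA) || iA <= sA)
    stop_validation("channel column does not cross the cortical wall")
  L <- iA - sA
  span <- switch(ch$depth,
    through = seq_len(min(length(ord), iA + 2L)),
    blind_periosteal = seq.int(sA, sA + ceiling(L / 2) - 1L),
    blind_endosteal = seq.int(sA + floor(L / 2), min(length(ord), iA + 2L)),
    intracortical = {
      if (L < 4L) stop_validation("cortex too thin for an intracortical cavity")
      seq.int(sA + 1L, sA + max(1L, L - 3L))
    })
  axis_idx <- ord[span]
  offs <- channel_offsets(ch$cross_section, ch$width_voxels)
  u <- pos[1] + offs[, 1]; v <- pos[2] + offs[, 2]
  okuv <- u >= 1L & u <= d[others[1]] & v >= 1L & v <= d[others[2]]
  u <- u[okuv]; v <- v[okuv]
  if (length(u) == 0L) stop_validation("channel cross-section outside lattice")
  g <- expand.grid(a = axis_idx, s = seq_along(u))
  coord <- matrix(0L, nrow(g), 3L)
  coord[, ax] <- g$a
  coord[, others[1]] <- u[g$s]
  coord[, others[2]] <- v[g$s]
  idx <- coord[, 1] + d[1] * (coord[, 2] - 1L) + d[1] * d[2] * (coord[, 3] - 1L)
  as.integer(idx)
}

#' Generate a synthetic joint phantom
#'
#' Renders the phantom described by `spec` into a grayscale volume
#' (intensity-scaled bone, optional Gaussian blur and truncated additive
#' Gaussian noise, quantized to integers as scanner exports are) and returns
#' it together with the analytic ground truth: the periosteal solid, the bone
#' lattice, a label map of the carved channels and the ids of channels that
#' meet the detection criteria (through the cortex, width >= 3 voxels with a
#' plus-cross contained in the cross-section).
#'
#' @param spec a [phantom_spec()].
#' @return A list with `grayscale` (a [grayscale_volume()]) and `truth`
#'   (class `cb_phantom_truth`: `periosteal_solid`, `bone`, `channel_labels`,
#'   `expected_detected`, `cortical_thickness_voxels`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "cb_phantom_spec"))
  d <- spec$shape
  solid <- phantom_solid(spec, 0)
  if (!any(solid)) stop_validation("phantom geometry is empty")
  inner <- phantom_solid(spec, spec$cortical_thickness_voxels)
  bone <- solid & !inner

  if (!is.null(spec$trabecular)) {
    sp <- as.integer(spec$trabecular$strut_spacing_voxels)
    th <- as.integer(spec$trabecular$strut_thickness_voxels)
    if (is.na(sp) || is.na(th) || sp < 2L || th < 1L || th >= sp)
      stop_validation("invalid trabecular specification")
    A <- array(0, d)
    I1 <- slice.index(A, 1); I2 <- slice.index(A, 2); I3 <- slice.index(A, 3)
    m1 <- (I1 %% sp) < th; m2 <- (I2 %% sp) < th; m3 <- (I3 %% sp) < th
    struts <- (m2 & m3) | (m1 & m3) | (m1 & m2)
    bone <- bone | (struts & inner)
  }

  labels <- array(0L, d)
  carved <- vector("list", length(spec$channels))
  for (i in seq_along(spec$channels)) {
    idx <- carve_channel(spec$channels[[i]], solid, inner, d)
    carved[[i]] <- idx
  }
  if (length(carved) > 1L) {
    all_idx <- unlist(carved)
    if (anyDuplicated(all_idx) > 0L)
      stop_validation("phantom channels overlap")
  }
  for (i in seq_along(carved)) {
    idx <- carved[[i]]
    bone[idx] <- FALSE
    lab_idx <- idx[solid[idx]]
    if (length(lab_idx) == 0L)
      stop_validation(sprintf("channel %d carves no solid voxels", i))
    labels[lab_idx] <- i
  }
  expected <- which(vapply(spec$channels, function(ch) {
    ch$depth == "through" && ch$width_voxels >= 3L &&
      contains_plus3(channel_offsets(ch$cross_section, ch$width_voxels))
  }, logical(1)))

  imax <- spec$intensity_max
  bone_val <- spec$intensity$bone_fraction_of_max * imax
  bg_val <- spec$intensity$background_fraction * imax
  g <- array(bg_val, d)
  g[bone] <- bone_val
  if (spec$blur_sigma_voxels > 0)
    g <- gaussian_smooth(g, spec$blur_sigma_voxels,
                         max(1L, ceiling(2 * spec$blur_sigma_voxels)))
  if (spec$noise_sd_fraction > 0) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    }
    set.seed(spec$seed)
    g <- g + stats::rnorm(length(g), sd = spec$noise_sd_fraction * bone_val)
  }
  g <- round(pmin(pmax(g, 0), imax))
  dim(g) <- d

  vs <- spec$voxel_size_mm
  truth <- structure(list(
    periosteal_solid = binary_volume(solid, vs),
    bone = binary_volume(bone, vs),
    channel_labels = if (length(carved))
      label_map(labels, vs) else label_map(labels, vs),
    expected_detected = as.integer(expected),
    cortical_thickness_voxels = spec$cortical_thickness_voxels,
    channels = spec$channels
  ), class = "cb_phantom_truth")

  list(grayscale = grayscale_volume(g, vs, imax), truth = truth)
}

#' Recovery report: detections versus phantom ground truth
#'
#' Matches detected interruptions to the phantom's carved channels with the
#' same one-to-one overlap matcher used for inter-operator reliability
#' (overlap of at least `min_overlap_voxels`). `n_matched_to_truth` counts
#' detections matched to a channel that meets the detection criteria;
#' `false_positives` counts detections not matched to any carved channel.
#'
#' @param truth a `cb_phantom_truth`.
#' @param result a `cb_joint_result` on the same lattice.
#' @param min_overlap_voxels matching threshold (default 20).
#' @return A list with `n_true`, `n_detected`, `n_matched_to_truth`,
#'   `false_positives`, and the underlying `match` result.
#' @export
recovery_report <- function(truth, result, min_overlap_voxels = 20L) {
  stopifnot(inherits(truth, "cb_phantom_truth"),
            inherits(result, "cb_joint_result"))
  m <- match_interruptions(result$label_map, truth$channel_labels,
                           min_overlap_voxels)
  matched_any <- nrow(m$pairs)
  matched_true <- sum(m$pairs$label_b %in% truth$expected_detected)
  list(n_true = length(truth$expected_detected),
       n_detected = result$n_interruptions,
       n_matched_to_truth = matched_true,
       false_positives = result$n_interruptions - matched_any,
       match = m)
}
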