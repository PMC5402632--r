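# Periosteal auto-contouring.
#
# The outer (periosteal) contour of all bone in the field of view is found in
# two stages: (1) a first structure approximation by Gaussian smoothing and a
# constant per-mille threshold against the acquisition's maximum possible
# voxel value, and (2) morphological closing (dilation, cavity fill, erosion)
# that bridges cortical gaps and fills the medullary cavity, yielding a solid
# volume bounded by the periosteal surface. Defaults follow finger-joint
# practice: threshold 105 per mille (thinner, lower-mineralized cortex than
# radius/tibia) and 7 closing steps (smaller bones).

#' Auto-contouring parameters
#'
#' @param gauss_sigma Gaussian standard deviation in voxels (default 0.8).
#' @param gauss_support Gaussian kernel radius in voxels (default 1, i.e. a
#'   3x3x3 kernel).
#' @param threshold_permille structure threshold per 1000 of the maximum
#'   possible voxel value (default 105).
#' @param closing_steps voxel distance of the closing (dilation followed by
#'   erosion; default 7).
#' @return An object of class `cb_contour_params`.
#' @export
contour_params <- function(gauss_sigma = 0.8, gauss_support = 1L,
                           threshold_permille = 105L, closing_steps = 7L) {
  gauss_sigma <- check_scalar_pos(gauss_sigma, "gauss_sigma")
  gauss_support <- as.integer(check_scalar_pos(gauss_support, "gauss_support"))
  closing_steps <- as.integer(check_scalar_pos(closing_steps, "closing_steps"))
  threshold_permille <- as.integer(threshold_permille)
  if (threshold_permille < 1L || threshold_permille > 1000L)
    stop_validation("threshold_permille must be in [1, 1000]")
  structure(list(gauss_sigma = gauss_sigma, gauss_support = gauss_support,
                 threshold_permille = threshold_permille,
                 closing_steps = closing_steps),
            class = "cb_contour_params")
}

#' First structure approximation
#'
#' Gaussian-smooths the grayscale volume (kernel truncated at
#' `gauss_support` voxels) and keeps voxels whose smoothed intensity is at
#' least `threshold_permille / 1000 * intensity_max`.
#'
#' @param gray a [grayscale_volume()].
#' @param params a [contour_params()].
#' @return A [binary_volume()] on the same lattice.
#' @export
approximate_structure <- function(gray, params = contour_params()) {
  stopifnot(inherits(gray, "cb_grayscale"), inherits(params, "cb_contour_params"))
  sm <- gaussian_smooth(gray$data, params$gauss_sigma, params$gauss_support)
  thr <- params$threshold_permille / 1000 * gray$intensity_max
  # tiny tolerance so intensities exactly at the threshold stay foreground
  # despite convolution round-off
  binary_volume(sm >= thr - 1e-9 * gray$intensity_max, gray$voxel_size_mm)
}

#' Morphological closing and cavity fill
#'
#' Dilates the structure by a Euclidean ball of `closing_steps` voxels,
#' fills every background component not connected to the lattice border, and
#' erodes back by `closing_steps` voxels. The Euclidean metric keeps the
#' reconstructed periosteal surface flush on curved anatomy (a city-block
#' closing would emboss diamond-shaped bumps of up to `(sqrt(3)-1) *
#' closing_steps` voxels on oblique surfaces and sag the bridge over cortical
#' gaps, distorting the constant-thickness mask). The lattice is padded with
#' `closing_steps + 1` background voxels during the operation so dilation
#' never clips at the border. A final cavity fill guarantees the solid
#' contains no fully enclosed background.
#'
#' @param structure a [binary_volume()] (non-empty).
#' @param closing_steps voxel distance of the closing.
#' @return A contour solid (class `cb_contour_solid`, a binary volume).
#' @export
close_and_fill <- function(structure, closing_steps = 7L) {
  stopifnot(inherits(structure, "cb_binary"))
  closing_steps <- as.integer(check_scalar_pos(closing_steps, "closing_steps"))
  a <- structure$data
  if (!any(a)) stop_validation("no bone found: structure approximation is empty")
  d <- dim(a)
  pad <- closing_steps + 1L
  p <- pad3(a, pad)
  p <- euclidean_dilate(p, closing_steps)
  p <- fill_cavities(p)
  p <- euclidean_erode(p, closing_steps)
  p <- fill_cavities(p)
  solid <- crop3(p, pad, d)
  out <- binary_volume(solid, structure$voxel_size_mm)
  class(out) <- c("cb_contour_solid", class(out))
  out
}

#' Fully automated periosteal contour
#'
#' Composition of [approximate_structure()] and [close_and_fill()]: the
#' fully-automated entry point of the pipeline.
#'
#' @inheritParams approximate_structure
#' @return A contour solid (class `cb_contour_solid`).
#' @export
auto_contour <- function(gray, params = contour_params()) {
  close_and_fill(approximate_structure(gray, params), params$closing_steps)
}

#' Load an operator-corrected contour solid
#'
#' Entry point of the semi-automated pathway: reads a binary volume edited in
#' any external tool, checks it matches the grayscale lattice, and sanitizes
#' it by filling fully enclosed background cavities.
#'
#' @param path file readable by [read_volume()], or a [binary_volume()]
#'   already in memory.
#' @param gray optional [grayscale_volume()] whose lattice the contour must
#'   match (checked when supplied).
#' @param voxel_size_mm passed to [read_volume()] when the file lacks one.
#' @return A contour solid (class `cb_contour_solid`).
#' @export
load_corrected_contour <- function(path, gray = NULL, voxel_size_mm = NULL) {
  vol <- if (inherits(path, "cb_binary")) path
         else read_volume(path, voxel_size_mm = voxel_size_mm, kind = "binary")
  if (!is.null(gray)) check_same_lattice(vol, gray, "contour and grayscale volume")
  solid <- fill_cavities(vol$data)
  out <- binary_volume(solid, vol$voxel_size_mm)
  class(out) <- c("cb_contour_solid", class(out))
  out
}
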