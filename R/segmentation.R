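# Bone segmentation: binary bone model from the grayscale volume.
#
# The scanner's standard evaluation protocol combines Laplace-Hamming
# filtering (edge enhancement plus high-frequency noise suppression) with a
# constant threshold. The manufacturer's exact coefficients are unpublished;
# the filter here is therefore fully parameterized and its frequency response
# is explicit package policy (see the methods vignette): a Hamming-shaped
# roll-off above the cutoff combined with discrete-Laplacian sharpening.

#' Bone segmentation parameters
#'
#' @param filter_mode `"laplace_hamming"` (default) or `"gaussian"`
#'   (smoothing + threshold fallback).
#' @param lh_cutoff_fraction low-pass cutoff as a fraction of the Nyquist
#'   frequency, in (0, 1] (default 0.4). Frequencies below the cutoff pass
#'   unattenuated; above it the response rolls off with a Hamming taper.
#' @param lh_epsilon Laplacian sharpening weight in `[0, 1]` (default 0.5).
#'   With `lh_epsilon = 0` and `lh_cutoff_fraction = 1` the filter is the
#'   identity and segmentation reduces to plain thresholding.
#' @param threshold_permille threshold per 1000 of the filtered volume's
#'   dynamic range (default 400).
#' @return An object of class `cb_segmentation_params`.
#' @export
segmentation_params <- function(filter_mode = c("laplace_hamming", "gaussian"),
                                lh_cutoff_fraction = 0.4, lh_epsilon = 0.5,
                                threshold_permille = 400L) {
  filter_mode <- match.arg(filter_mode)
  if (!is.numeric(lh_cutoff_fraction) || lh_cutoff_fraction <= 0 ||
      lh_cutoff_fraction > 1)
    stop_validation("lh_cutoff_fraction must be in (0, 1]")
  if (!is.numeric(lh_epsilon) || lh_epsilon < 0 || lh_epsilon > 1)
    stop_validation("lh_epsilon must be in [0, 1]")
  threshold_permille <- as.integer(threshold_permille)
  if (threshold_permille < 1L || threshold_permille > 1000L)
    stop_validation("threshold_permille must be in [1, 1000]")
  structure(list(filter_mode = filter_mode,
                 lh_cutoff_fraction = lh_cutoff_fraction,
                 lh_epsilon = lh_epsilon,
                 threshold_permille = threshold_permille),
            class = "cb_segmentation_params")
}

#' Laplace-Hamming filter
#'
#' Frequency-domain filter applied via the 3D FFT. With per-axis frequencies
#' expressed as fractions `f` of Nyquist, the response is
#' `H(f) = W(r) * (1 + eps * sum_axes(1 - cos(pi * f_axis)))` where the
#' normalized radial frequency is r = |f| / sqrt(3) and the low-pass
#' `W(r)` is 1 below the cutoff and `0.54 + 0.46 * cos(pi * (r - cutoff) /
#' (1 - cutoff))` above it (Hamming taper). The second factor is the
#' sharpening response of the negated discrete Laplacian. The filter is
#' linear; `eps = 0`, `cutoff = 1` gives the identity.
#'
#' @param x 3D numeric array.
#' @param cutoff_fraction cutoff as a fraction of Nyquist, in (0, 1].
#' @param epsilon Laplacian sharpening weight.
#' @return Filtered 3D numeric array (real part of the inverse transform).
#' @export
laplace_hamming_filter <- function(x, cutoff_fraction = 0.4, epsilon = 0.5) {
  x <- check_array3(x, "x")
  d <- dim(x)
  # per-axis frequency as fraction of Nyquist, folded: 0..1
  faxis <- lapply(d, function(n) {
    k <- seq_len(n) - 1L
    pmin(k, n - k) / (n / 2)
  })
  f1 <- array(rep(faxis[[1]], times = d[2] * d[3]), d)
  f2 <- array(rep(rep(faxis[[2]], each = d[1]), times = d[3]), d)
  f3 <- array(rep(faxis[[3]], each = d[1] * d[2]), d)
  r <- sqrt((f1^2 + f2^2 + f3^2) / 3)
  c0 <- cutoff_fraction
  W <- array(1, d)
  if (c0 < 1) {
    hi <- r > c0
    W[hi] <- 0.54 + 0.46 * cos(pi * pmin((r[hi] - c0) / (1 - c0), 1))
  }
  sharpen <- 1 + epsilon * ((1 - cos(pi * f1)) + (1 - cos(pi * f2)) +
                              (1 - cos(pi * f3)))
  H <- W * sharpen
  Re(fft(fft(x) * H, inverse = TRUE)) / length(x)
}

#' Binary bone model
#'
#' Filters the grayscale volume (Laplace-Hamming by default) and thresholds
#' at `threshold_permille / 1000` of the filtered dynamic range, whose
#' endpoints are clamped to `[0, intensity_max]`. When a contour solid is
#' supplied, the bone model is restricted to voxels inside it.
#'
#' @param gray a [grayscale_volume()].
#' @param params a [segmentation_params()].
#' @param contour optional contour solid (from [auto_contour()] or
#'   [load_corrected_contour()]) restricting the output.
#' @return A [binary_volume()] of mineralized-bone voxels.
#' @export
binarize_bone <- function(gray, params = segmentation_params(),
                          contour = NULL) {
  stopifnot(inherits(gray, "cb_grayscale"),
            inherits(params, "cb_segmentation_params"))
  filtered <- switch(params$filter_mode,
    laplace_hamming = laplace_hamming_filter(gray$data,
                                             params$lh_cutoff_fraction,
                                             params$lh_epsilon),
    gaussian = gaussian_smooth(gray$data, sigma = 0.8, support = 1L))
  lo <- max(min(filtered), 0)
  hi <- min(max(filtered), gray$intensity_max)
  if (hi <= lo) {
    bone <- array(FALSE, dim(gray$data))
  } else {
    thr <- lo + params$threshold_permille / 1000 * (hi - lo)
    bone <- filtered >= thr
  }
  if (!is.null(contour)) {
    stopifnot(inherits(contour, "cb_binary"))
    check_same_lattice(contour, gray, "contour and grayscale volume")
    bone <- bone & contour$data
  }
  binary_volume(bone, gray$voxel_size_mm)
}
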