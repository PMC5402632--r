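#' @useDynLib cortibreak, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Validation errors carry a dedicated condition class so callers (and the
# command-line wrapper) can distinguish bad input (exit code 1) from runtime
# failure (exit code 2).
stop_validation <- function(msg, call. = FALSE) {
  cond <- structure(
    class = c("cb_validation_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  )
  stop(cond)
}

check_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_validation(sprintf("'%s' must be a single positive finite number", name))
  as.numeric(x)
}

check_array3 <- function(data, name = "data") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_validation(sprintf("'%s' must be a 3D array", name))
  if (any(dim(data) < 1L))
    stop_validation(sprintf("all dimensions of '%s' must be >= 1", name))
  data
}

#' Grayscale volume
#'
#' A 3D isotropic scalar lattice with its physical voxel size, the basic
#' container for an HR-pQCT-like acquisition. Axis convention: array
#' dimension 1 indexes the transverse slice (the scanner's axial direction);
#' "consecutive slices" in the interruption criteria means consecutive
#' indices along dimension 1. Lattice indices are 1-based; the physical
#' position of index `i` along an axis is `(i - 1) * voxel_size_mm`
#' (voxel centers).
#'
#' @param data 3D numeric array (slices x rows x cols).
#' @param voxel_size_mm isotropic voxel edge length in millimetres
#'   (0.082 for first-generation HR-pQCT, 0.061 for second-generation).
#' @param intensity_max maximum possible voxel value of the acquisition
#'   (e.g. the integer type maximum of the export), used as the reference
#'   for per-mille thresholds. Must be at least the maximum observed
#'   intensity; defaults to `max(data, 1)` when not supplied.
#' @return An object of class `cb_grayscale` with fields `data`,
#'   `voxel_size_mm`, `intensity_max`.
#' @export
grayscale_volume <- function(data, voxel_size_mm, intensity_max = NULL) {
  data <- check_array3(data)
  storage.mode(data) <- "double"
  voxel_size_mm <- check_scalar_pos(voxel_size_mm, "voxel_size_mm")
  if (is.null(intensity_max)) intensity_max <- max(max(data), 1)
  intensity_max <- check_scalar_pos(intensity_max, "intensity_max")
  if (intensity_max < max(data))
    stop_validation("intensity_max must be >= the maximum observed intensity")
  structure(list(data = data, voxel_size_mm = voxel_size_mm,
                 intensity_max = intensity_max),
            class = c("cb_grayscale", "cb_volume"))
}

#' Binary volume
#'
#' A 3D boolean lattice sharing the axis convention of
#' [grayscale_volume()].
#'
#' @param data 3D logical (or coercible 0/1) array.
#' @param voxel_size_mm isotropic voxel edge length in millimetres.
#' @return An object of class `cb_binary`.
#' @export
binary_volume <- function(data, voxel_size_mm) {
  data <- check_array3(data)
  if (!is.logical(data)) {
    if (!all(data %in% c(0, 1)))
      stop_validation("binary volume data must be logical or 0/1")
    data <- array(data != 0, dim(data))
  }
  if (anyNA(data)) stop_validation("binary volume data must not contain NA")
  voxel_size_mm <- check_scalar_pos(voxel_size_mm, "voxel_size_mm")
  structure(list(data = data, voxel_size_mm = voxel_size_mm),
            class = c("cb_binary", "cb_volume"))
}

#' Label map
#'
#' A 3D non-negative integer lattice; 0 is background and component labels
#' are contiguous `1..K`.
#'
#' @param data 3D integer array.
#' @param voxel_size_mm isotropic voxel edge length in millimetres.
#' @param compact relabel to contiguous `1..K` preserving label order
#'   (default `FALSE`: non-contiguous labels are a validation error).
#' @return An object of class `cb_labelmap`.
#' @export
label_map <- function(data, voxel_size_mm, compact = FALSE) {
  data <- check_array3(data)
  if (anyNA(data) || any(data < 0) || any(data != round(data)))
    stop_validation("label map data must be non-negative integers")
  storage.mode(data) <- "integer"
  present <- sort(unique(data[data > 0L]))
  if (isTRUE(compact)) {
    if (length(present) && !identical(present, seq_along(present))) {
      lut <- integer(max(present))
      lut[present] <- seq_along(present)
      pos <- data > 0L
      data[pos] <- lut[data[pos]]
    }
  } else if (length(present) && !identical(present, seq_along(present))) {
    stop_validation("label values must be contiguous 1..K (use compact = TRUE)")
  }
  voxel_size_mm <- check_scalar_pos(voxel_size_mm, "voxel_size_mm")
  structure(list(data = data, voxel_size_mm = voxel_size_mm),
            class = c("cb_labelmap", "cb_volume"))
}

#' Number of labels in a label map
#' @param x a `cb_labelmap`.
#' @return Integer count of distinct non-zero labels.
#' @export
n_labels <- function(x) {
  stopifnot(inherits(x, "cb_labelmap"))
  as.integer(max(0L, max(x$data)))
}

# Extract the bare array from a cb_volume or pass an array through.
vol_data <- function(x) {
  if (inherits(x, "cb_volume")) x$data else check_array3(x, "volume")
}

check_same_lattice <- function(a, b, what = "volumes") {
  if (!identical(dim(vol_data(a)), dim(vol_data(b))))
    stop_validation(sprintf("%s must share the same lattice dimensions", what))
  invisible(TRUE)
}

#' @export
print.cb_volume <- function(x, ...) {
  d <- dim(x$data)
  kind <- if (inherits(x, "cb_grayscale")) "grayscale"
          else if (inherits(x, "cb_labelmap")) "label map"
          else if (inherits(x, "cb_contour_solid")) "contour solid"
          else "binary"
  cat(sprintf("<cortibreak %s volume> %d x %d x %d voxels @ %g mm\n",
              kind, d[1], d[2], d[3], x$voxel_size_mm))
  if (inherits(x, "cb_grayscale"))
    cat(sprintf("  intensity range [%g, %g], intensity_max %g\n",
                min(x$data), max(x$data), x$intensity_max))
  if (inherits(x, "cb_binary"))
    cat(sprintf("  %d foreground voxels\n", sum(x$data)))
  if (inherits(x, "cb_labelmap"))
    cat(sprintf("  %d labels\n", n_labels(x)))
  invisible(x)
}
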