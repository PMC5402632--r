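# 3D binary morphology on plain arrays.
#
# All morphological steps of the interruption pipeline use the face-connected
# 3D cross (the city-block unit ball {(0,0,0)} + the 6 face neighbours) as
# structuring element, iterated once per "step". This element gives the
# voxel-distance semantics of "dilated by n voxels" and reproduces the
# minimal 5-voxel plus-shaped opening of the detection criteria: a channel
# that survives a 1-voxel cross erosion must span >= 3 consecutive slices and
# be >= 3 voxels wide in-plane.

# Shift a 3D array by an integer offset, filling vacated cells with `fill`.
shift3 <- function(a, off, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  src <- vector("list", 3L)
  dst <- vector("list", 3L)
  for (ax in 1:3) {
    o <- off[ax]
    if (abs(o) >= d[ax]) return(out)
    if (o >= 0) {
      src[[ax]] <- seq_len(d[ax] - o)
      dst[[ax]] <- seq_len(d[ax] - o) + o
    } else {
      src[[ax]] <- seq_len(d[ax] + o) - o
      dst[[ax]] <- seq_len(d[ax] + o)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

cross_offsets <- function() {
  list(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L),
       c(0L, -1L, 0L), c(0L, 0L, 1L), c(0L, 0L, -1L))
}

#' Dilate a binary lattice with the face-connected cross
#'
#' One step dilates by the 6-neighbour (city-block) unit ball; `steps`
#' iterations dilate by a city-block distance of `steps` voxels. The lattice
#' boundary is treated as background (no wrap-around).
#'
#' @param a 3D logical array (or a `cb_binary`; the bare array is used).
#' @param steps number of unit-cross iterations (non-negative integer).
#' @return 3D logical array.
#' @export
dilate_voxels <- function(a, steps = 1L) {
  a <- vol_data(a)
  steps <- as.integer(steps)
  if (steps < 0) stop_validation("steps must be >= 0")
  for (i in seq_len(steps)) {
    out <- a
    for (off in cross_offsets()) out <- out | shift3(a, off, FALSE)
    a <- out
  }
  a
}

#' Erode a binary lattice with the face-connected cross
#'
#' Dual of [dilate_voxels()]; voxels outside the lattice count as background,
#' so foreground touching the lattice border is eroded from the border too.
#'
#' @inheritParams dilate_voxels
#' @return 3D logical array.
#' @export
erode_voxels <- function(a, steps = 1L) {
  a <- vol_data(a)
  steps <- as.integer(steps)
  if (steps < 0) stop_validation("steps must be >= 0")
  for (i in seq_len(steps)) {
    out <- a
    for (off in cross_offsets()) out <- out & shift3(a, off, FALSE)
    a <- out
  }
  a
}

#' Label connected components of a binary lattice
#'
#' Deterministic labeling (labels ordered by the column-major scan position
#' of each component's first voxel, contiguous `1..K`).
#'
#' @param a 3D logical array or `cb_binary`.
#' @param connectivity `"face"` (6 neighbours), `"face_edge"` (18) or
#'   `"face_edge_vertex"` (26).
#' @return 3D integer array of labels (0 = background).
#' @export
label_components <- function(a, connectivity = c("face", "face_edge",
                                                 "face_edge_vertex")) {
  a <- vol_data(a)
  conn <- connectivity_degree(match.arg(connectivity))
  label_components3d_cpp(a, dim(a), conn)
}

connectivity_degree <- function(connectivity) {
  switch(connectivity,
         face = 6L, face_edge = 18L, face_edge_vertex = 26L,
         stop_validation("unknown connectivity"))
}

#' Fill enclosed cavities of a binary lattice
#'
#' Background components that do not reach the lattice border (flood fill
#' from the border, face connectivity) are turned into foreground. This is
#' the cavity-fill used when building the periosteal contour solid.
#'
#' @param a 3D logical array or `cb_binary`.
#' @return 3D logical array with all fully enclosed background filled.
#' @export
fill_cavities <- function(a) {
  a <- vol_data(a)
  bg <- label_components3d_cpp(!a, dim(a), 6L)
  border <- border_labels(bg)
  if (length(border) == 0L) return(array(TRUE, dim(a)))
  keep <- array(bg %in% border, dim(a))
  !keep
}

# Labels of a label array present on any face of the lattice.
border_labels <- function(lab) {
  d <- dim(lab)
  vals <- c(lab[1, , ], lab[d[1], , ],
            lab[, 1, ], lab[, d[2], ],
            lab[, , 1], lab[, , d[3]])
  sort(unique(vals[vals > 0L]))
}

# Pad a logical array with `n` background voxels on every side; crop inverse.
pad3 <- function(a, n, fill = FALSE) {
  if (n == 0L) return(a)
  d <- dim(a)
  out <- array(fill, d + 2L * n)
  out[n + seq_len(d[1]), n + seq_len(d[2]), n + seq_len(d[3])] <- a
  out
}

crop3 <- function(a, n, d) {
  if (n == 0L) return(a)
  a[n + seq_len(d[1]), n + seq_len(d[2]), n + seq_len(d[3])]
}

#' Squared Euclidean distance transform
#'
#' Squared Euclidean distance (in voxel units, between voxel centers) from
#' every lattice site to the nearest foreground voxel, by the separable
#' lower-envelope algorithm. `Inf` where the foreground is empty.
#'
#' @param a 3D logical array or `cb_binary`.
#' @return 3D numeric array of squared distances.
#' @export
distance_transform_sq <- function(a) {
  a <- vol_data(a)
  d2 <- edt3d_sq_cpp(a, dim(a))
  d2[d2 >= 1e14] <- Inf
  d2
}

#' Euclidean dilation and erosion of a binary lattice
#'
#' Dilation by the Euclidean ball of the given radius (voxels): all sites
#' within distance `radius` of the foreground. Erosion is the dual (sites
#' farther than `radius` from the background); voxels outside the lattice
#' count as background. These are the metric used by the contouring closing;
#' the detection-side unit steps use the face-connected cross
#' ([dilate_voxels()], [erode_voxels()]).
#'
#' @param a 3D logical array or `cb_binary`.
#' @param radius ball radius in voxels (non-negative).
#' @return 3D logical array.
#' @export
euclidean_dilate <- function(a, radius) {
  a <- vol_data(a)
  if (radius < 0) stop_validation("radius must be >= 0")
  if (radius == 0 || !any(a)) return(a)
  d2 <- distance_transform_sq(a)
  array(d2 <= radius^2 + 1e-9, dim(a))
}

#' @rdname euclidean_dilate
#' @export
euclidean_erode <- function(a, radius) {
  a <- vol_data(a)
  if (radius < 0) stop_validation("radius must be >= 0")
  if (radius == 0 || !any(a)) return(a)
  r <- as.integer(ceiling(radius)) + 1L
  p <- pad3(a, r)
  d2 <- distance_transform_sq(!p)
  out <- p & array(d2 > radius^2 + 1e-9, dim(p))
  crop3(out, r, dim(a))
}

# Sampled, truncated, normalized 3D Gaussian kernel. `support` is the kernel
# radius in voxels, so support = 1 gives a 3x3x3 kernel.
gaussian_kernel3 <- function(sigma, support) {
  r <- as.integer(support)
  ax <- seq.int(-r, r)
  g1 <- exp(-ax^2 / (2 * sigma^2))
  k <- outer(outer(g1, g1), g1)
  dim(k) <- c(length(ax), length(ax), length(ax))
  k / sum(k)
}

#' Gaussian smoothing of a 3D lattice
#'
#' Direct convolution with a sampled Gaussian truncated at `support` voxels
#' (kernel edge `2*support + 1`). At the lattice boundary the kernel is
#' renormalized over the voxels actually present, so constant volumes are
#' exactly invariant (unit DC gain everywhere).
#'
#' @param x 3D numeric array.
#' @param sigma Gaussian standard deviation in voxels.
#' @param support kernel radius in voxels (default `max(1, ceiling(2*sigma))`).
#' @return 3D numeric array of the same shape.
#' @export
gaussian_smooth <- function(x, sigma, support = NULL) {
  x <- check_array3(x, "x")
  sigma <- check_scalar_pos(sigma, "sigma")
  if (is.null(support)) support <- max(1, ceiling(2 * sigma))
  support <- as.integer(support)
  if (support < 1) stop_validation("support must be >= 1")
  k <- gaussian_kernel3(sigma, support)
  r <- support
  out <- array(0, dim(x))
  wsum <- array(0, dim(x))
  ones <- array(1, dim(x))
  for (dz in -r:r) for (dy in -r:r) for (dx in -r:r) {
    w <- k[dx + r + 1L, dy + r + 1L, dz + r + 1L]
    out <- out + w * shift3(x, c(dx, dy, dz), 0)
    wsum <- wsum + w * shift3(ones, c(dx, dy, dz), 0)
  }
  out / wsum
}
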