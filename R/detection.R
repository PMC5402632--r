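# Cortical interruption detection.
#
# The analysis compartment is a constant-thickness cortical mask: the outer
# shell of the periosteal contour solid, obtained by eroding the solid by
# `mask_thickness_voxels` (face-connected cross) and subtracting. Within the
# mask, bone is dilated by 1 voxel (equivalently, the void is eroded), void
# components connected to both the periosteal and endosteal boundary are
# selected, and the survivors are dilated back and clipped to the non-bone
# part of the mask. Because the erosion element is the face-connected cross,
# a surviving through-channel must be at least 3 voxels wide in both in-plane
# directions of its course with a 5-voxel plus-shaped cross-section: a
# discontinuity in at least 3 consecutive slices and at least 3 voxels wide.

#' Interruption detection parameters
#'
#' @param mask_thickness_voxels cortical mask thickness in voxels (default 4,
#'   i.e. 0.328 mm at the 82 um first-generation voxel size; use 5 at the
#'   61 um second-generation voxel size for a comparable 0.305 mm mask).
#' @param dilation_radius_voxels radius of the bone dilation / void
#'   restoration steps (default 1).
#' @param min_component_voxels minimal intra-cortical interruption volume in
#'   voxels (default 20 = 5-voxel plus-shaped opening x 4-voxel mask depth).
#' @param void_connectivity connectivity used to label void components:
#'   `"face"` (default), `"face_edge"`, `"face_edge_vertex"`.
#' @return An object of class `cb_detection_params`.
#' @export
detection_params <- function(mask_thickness_voxels = 4L,
                             dilation_radius_voxels = 1L,
                             min_component_voxels = 20L,
                             void_connectivity = c("face", "face_edge",
                                                   "face_edge_vertex")) {
  mask_thickness_voxels <- as.integer(mask_thickness_voxels)
  if (mask_thickness_voxels < 2L)
    stop_validation("mask_thickness_voxels must be >= 2")
  dilation_radius_voxels <- as.integer(dilation_radius_voxels)
  if (dilation_radius_voxels < 0L)
    stop_validation("dilation_radius_voxels must be >= 0")
  min_component_voxels <- as.integer(min_component_voxels)
  if (min_component_voxels < 1L)
    stop_validation("min_component_voxels must be >= 1")
  structure(list(mask_thickness_voxels = mask_thickness_voxels,
                 dilation_radius_voxels = dilation_radius_voxels,
                 min_component_voxels = min_component_voxels,
                 void_connectivity = match.arg(void_connectivity)),
            class = "cb_detection_params")
}

#' Constant-thickness cortical mask
#'
#' Erodes the contour solid by `mask_thickness_voxels` and subtracts, giving
#' the shell that serves as the analysis compartment. The periosteal face is
#' the set of shell voxels face-adjacent to background outside the solid; the
#' endosteal face is the set of shell voxels face-adjacent to the eroded
#' interior. Where the solid is thinner than the mask thickness the erosion
#' exhausts it locally; if it is exhausted everywhere the endosteal face is
#' empty and a warning is emitted (no through-interruption can be detected
#' there).
#'
#' @param solid a contour solid (or any non-empty [binary_volume()]).
#' @param params a [detection_params()].
#' @return An object of class `cb_cortical_mask` with binary fields `shell`,
#'   `periosteal_face`, `endosteal_face` and the thickness in voxels and mm.
#' @export
build_cortical_mask <- function(solid, params = detection_params()) {
  stopifnot(inherits(solid, "cb_binary"))
  s <- solid$data
  if (!any(s)) stop_validation("contour solid is empty")
  t <- params$mask_thickness_voxels
  interior <- erode_voxels(s, t)
  shell <- s & !interior
  outside <- !s
  peri <- shell & dilate_voxels(outside, 1L)
  endo <- shell & dilate_voxels(interior, 1L)
  if (!any(interior))
    warning("erosion exhausted the solid: endosteal face is empty, ",
            "through-interruption detection is impossible", call. = FALSE)
  vs <- solid$voxel_size_mm
  structure(list(shell = binary_volume(shell, vs),
                 periosteal_face = binary_volume(peri, vs),
                 endosteal_face = binary_volume(endo, vs),
                 thickness_voxels = t,
                 thickness_mm = t * vs),
            class = "cb_cortical_mask")
}

#' @export
print.cb_cortical_mask <- function(x, ...) {
  cat(sprintf(paste0("<cortical mask> thickness %d voxels (%.3f mm), ",
                     "%d shell / %d periosteal / %d endosteal voxels\n"),
              x$thickness_voxels, x$thickness_mm, sum(x$shell$data),
              sum(x$periosteal_face$data), sum(x$endosteal_face$data)))
  invisible(x)
}

#' Detect cortical interruptions
#'
#' Core detection step. Writing r for `dilation_radius_voxels`:
#' (a) cortical bone = bone within the shell; (b) dilate cortical bone by `r`
#' (face-connected cross); (c) void = shell voxels not covered by the dilated
#' bone; (d) label void components (`void_connectivity`) and keep those
#' containing at least one periosteal-face and one endosteal-face voxel
#' (connection to both boundaries, evaluated on the eroded void);
#' (e) dilate the kept components by `r` and clip to shell voxels that are
#' not bone, restoring (approximately) the original void; components merged
#' by the restoration are counted once; (f) relabel and drop components
#' smaller than `min_component_voxels`.
#'
#' Records are ordered by descending voxel count, ties broken by
#' lexicographic centroid, and the label map is renumbered accordingly.
#'
#' @param bone binary bone model (from [binarize_bone()]).
#' @param mask a [build_cortical_mask()] result.
#' @param params a [detection_params()].
#' @return An object of class `cb_joint_result`: `records` (data frame with
#'   label, voxel_count, volume_mm3, surface_mm2, centroid and bounding box),
#'   `n_interruptions`, `total_surface_mm2`, `label_map`, `params`, and
#'   intermediate voxel `counts` for step-by-step inspection.
#' @export
detect_interruptions <- function(bone, mask, params = detection_params()) {
  stopifnot(inherits(bone, "cb_binary"), inherits(mask, "cb_cortical_mask"))
  check_same_lattice(bone, mask$shell, "bone model and cortical mask")
  vs <- bone$voxel_size_mm
  shell <- mask$shell$data
  r <- params$dilation_radius_voxels
  conn <- params$void_connectivity

  cortical_bone <- bone$data & shell                      # (a)
  dil <- dilate_voxels(cortical_bone, r)                  # (b)
  void <- shell & !dil                                    # (c)
  lab <- label_components(void, conn)                     # (d)
  k <- max(0L, max(lab))
  keep <- integer(0)
  if (k > 0L) {
    peri_hit <- tabulate(lab[mask$periosteal_face$data & lab > 0L], k)
    endo_hit <- tabulate(lab[mask$endosteal_face$data & lab > 0L], k)
    keep <- which(peri_hit > 0L & endo_hit > 0L)
  }
  n_candidates <- k
  kept_void <- array(lab %in% keep & lab > 0L, dim(lab))
  restored <- dilate_voxels(kept_void, r) & shell & !bone$data  # (e)
  final <- label_components(restored, conn)               # (f)
  kf <- max(0L, max(final))
  counts <- if (kf > 0L) tabulate(final[final > 0L], kf) else integer(0)
  keep_f <- which(counts >= params$min_component_voxels)

  thickness_mm <- mask$thickness_mm
  recs <- make_records(final, keep_f, counts, vs, thickness_mm)
  out_map <- relabel_map(final, recs$old_label)
  recs$old_label <- NULL

  res <- structure(list(
    records = recs,
    n_interruptions = nrow(recs),
    total_surface_mm2 = sum(recs$surface_mm2),
    total_volume_mm3 = sum(recs$volume_mm3),
    label_map = label_map(out_map, vs),
    params = params,
    voxel_size_mm = vs,
    mask_thickness_mm = thickness_mm,
    counts = list(bone_voxels = sum(bone$data),
                  shell_voxels = sum(shell),
                  cortical_bone_voxels = sum(cortical_bone),
                  void_voxels_after_erosion = sum(void),
                  void_components = n_candidates,
                  components_connected_both = length(keep),
                  components_after_restoration = kf,
                  components_kept = nrow(recs))
  ), class = "cb_joint_result")
  res
}

# Build the per-interruption record table for the labels in `keep_f`,
# ordered by descending voxel count then lexicographic centroid, and return
# alongside the old labels so the map can be renumbered consistently.
make_records <- function(final, keep_f, counts, vs, thickness_mm) {
  empty <- data.frame(label = integer(0), voxel_count = integer(0),
                      volume_mm3 = numeric(0), surface_mm2 = numeric(0),
                      centroid_slice = numeric(0), centroid_row = numeric(0),
                      centroid_col = numeric(0),
                      bbox_slice_min = integer(0), bbox_slice_max = integer(0),
                      bbox_row_min = integer(0), bbox_row_max = integer(0),
                      bbox_col_min = integer(0), bbox_col_max = integer(0),
                      old_label = integer(0))
  if (length(keep_f) == 0L) return(empty)
  idx <- which(final > 0L & array(final %in% keep_f, dim(final)))
  sub <- arrayInd(idx, dim(final))
  labv <- final[idx]
  rows <- lapply(keep_f, function(l) {
    m <- sub[labv == l, , drop = FALSE]
    data.frame(voxel_count = as.integer(counts[l]),
               centroid_slice = mean(m[, 1]), centroid_row = mean(m[, 2]),
               centroid_col = mean(m[, 3]),
               bbox_slice_min = min(m[, 1]), bbox_slice_max = max(m[, 1]),
               bbox_row_min = min(m[, 2]), bbox_row_max = max(m[, 2]),
               bbox_col_min = min(m[, 3]), bbox_col_max = max(m[, 3]),
               old_label = as.integer(l))
  })
  recs <- do.call(rbind, rows)
  ord <- order(-recs$voxel_count, recs$centroid_slice, recs$centroid_row,
               recs$centroid_col, recs$old_label)
  recs <- recs[ord, , drop = FALSE]
  recs$label <- seq_len(nrow(recs))
  recs$volume_mm3 <- recs$voxel_count * vs^3
  recs$surface_mm2 <- recs$volume_mm3 / thickness_mm
  rownames(recs) <- NULL
  recs[, c("label", "voxel_count", "volume_mm3", "surface_mm2",
           "centroid_slice", "centroid_row", "centroid_col",
           "bbox_slice_min", "bbox_slice_max", "bbox_row_min", "bbox_row_max",
           "bbox_col_min", "bbox_col_max", "old_label")]
}

relabel_map <- function(final, old_labels) {
  out <- array(0L, dim(final))
  for (i in seq_along(old_labels)) out[final == old_labels[i]] <- i
  out
}

#' @export
print.cb_joint_result <- function(x, ...) {
  cat(sprintf("<cortibreak joint result> %d interruption(s), total surface %.3f mm^2\n",
              x$n_interruptions, x$total_surface_mm2))
  if (x$n_interruptions > 0)
    print(utils::head(x$records[, c("label", "voxel_count", "volume_mm3",
                                    "surface_mm2")], 10L))
  invisible(x)
}

#' Joint-level summary of detected interruptions
#'
#' One-row data frame with the joint-level quantities reported per joint:
#' number of interruptions, total and median interruption surface, and total
#' intra-cortical interruption volume. These per-joint values are the inputs
#' to any downstream paired comparison (Friedman/Wilcoxon in base R).
#'
#' @param result a `cb_joint_result` from [detect_interruptions()].
#' @return A one-row `data.frame`.
#' @export
summarize_interruptions <- function(result) {
  stopifnot(inherits(result, "cb_joint_result"))
  data.frame(
    n_interruptions = result$n_interruptions,
    total_surface_mm2 = result$total_surface_mm2,
    median_surface_mm2 = if (result$n_interruptions > 0)
      stats::median(result$records$surface_mm2) else 0,
    total_volume_mm3 = result$total_volume_mm3
  )
}

#' Analytic detection geometry
#'
#' Recomputes the printed parameter arithmetic of the method from the voxel
#' size and the morphological constraints: minimum in-plane interruption
#' diameter (`min_width_voxels * voxel_size_mm`), physical mask thickness,
#' and the minimal detectable intra-cortical volume (the plus-shaped opening
#' of `2 * min_width_voxels - 1` voxels times the mask depth).
#'
#' @param voxel_size_mm isotropic voxel size in mm (0.082 generation 1,
#'   0.061 generation 2).
#' @param mask_thickness_voxels cortical mask thickness in voxels.
#' @param min_width_voxels minimal in-plane width of a detectable channel.
#' @return A list with `min_diameter_mm`, `mask_thickness_mm`,
#'   `min_opening_voxels`, `min_volume_voxels`, `min_volume_mm3`.
#' @export
detection_geometry <- function(voxel_size_mm = 0.082,
                               mask_thickness_voxels = 4L,
                               min_width_voxels = 3L) {
  voxel_size_mm <- check_scalar_pos(voxel_size_mm, "voxel_size_mm")
  mask_thickness_voxels <- as.integer(mask_thickness_voxels)
  min_width_voxels <- as.integer(min_width_voxels)
  opening <- 2L * min_width_voxels - 1L
  min_vox <- opening * mask_thickness_voxels
  list(min_diameter_mm = min_width_voxels * voxel_size_mm,
       mask_thickness_mm = mask_thickness_voxels * voxel_size_mm,
       min_opening_voxels = opening,
       min_volume_voxels = min_vox,
       min_volume_mm3 = min_vox * voxel_size_mm^3)
}
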