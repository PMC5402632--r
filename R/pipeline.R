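# End-to-end pipeline: contour -> segment -> mask -> detect, with resolved
# configuration, structured logging of intermediate voxel counts, and result
# artifacts written next to each run.

#' Run configuration
#'
#' @param input path of the grayscale volume, or a [grayscale_volume()].
#' @param out_dir output directory (created if missing); `NULL` runs without
#'   writing artifacts.
#' @param format,voxel_size_mm,intensity_max passed to [read_volume()].
#' @param contour optional operator-corrected periosteal contour (path or
#'   [binary_volume()]); supplying one switches the run from the fully- to
#'   the semi-automated procedure.
#' @param contour_params a [contour_params()].
#' @param segmentation_params a [segmentation_params()].
#' @param detection_params a [detection_params()].
#' @param qc write a PNG slice overlay of mask and detected interruptions.
#' @param seed recorded in the resolved configuration (the pipeline itself is
#'   deterministic).
#' @param log_level `"info"` to emit step messages, `"quiet"` to suppress.
#' @return An object of class `cb_run_config`.
#' @export
run_config <- function(input, out_dir = NULL, format = NULL,
                       voxel_size_mm = NULL, intensity_max = NULL,
                       contour = NULL,
                       contour_params = cortibreak::contour_params(),
                       segmentation_params = cortibreak::segmentation_params(),
                       detection_params = cortibreak::detection_params(),
                       qc = FALSE, seed = 1L,
                       log_level = c("info", "quiet")) {
  structure(list(input = input, out_dir = out_dir, format = format,
                 voxel_size_mm = voxel_size_mm, intensity_max = intensity_max,
                 contour = contour, contour_params = contour_params,
                 segmentation_params = segmentation_params,
                 detection_params = detection_params, qc = isTRUE(qc),
                 seed = as.integer(seed),
                 log_level = match.arg(log_level)),
            class = "cb_run_config")
}

#' Load a run configuration from YAML or JSON
#'
#' Keys mirror the [run_config()] arguments; parameter groups are nested
#' (`contour_params`, `segmentation_params`, `detection_params`), each
#' optional with package defaults.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON configuration file.
#' @return A `cb_run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' does not exist", path))
  cfg <- if (grepl("\\.ya?ml$", tolower(path))) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$input)) stop_validation("config must name an input volume")
  run_config(
    input = cfg$input,
    out_dir = cfg$out_dir,
    format = cfg$format,
    voxel_size_mm = cfg$voxel_size_mm,
    intensity_max = cfg$intensity_max,
    contour = cfg$contour,
    contour_params = do.call(contour_params,
                             as_list_or_empty(cfg$contour_params)),
    segmentation_params = do.call(segmentation_params,
                                  as_list_or_empty(cfg$segmentation_params)),
    detection_params = do.call(detection_params,
                               as_list_or_empty(cfg$detection_params)),
    qc = isTRUE(cfg$qc),
    seed = if (is.null(cfg$seed)) 1L else cfg$seed,
    log_level = if (is.null(cfg$log_level)) "info" else cfg$log_level
  )
}

as_list_or_empty <- function(x) if (is.null(x)) list() else as.list(x)

#' Detect cortical interruptions in a grayscale volume
#'
#' In-memory composition of the four pipeline steps: periosteal contouring
#' (automatic, or the supplied corrected contour), bone segmentation within
#' the contour, constant-thickness cortical mask construction, and
#' interruption detection.
#'
#' @param gray a [grayscale_volume()].
#' @param contour `NULL` for the fully-automated procedure, or a contour
#'   solid / binary volume for the semi-automated one.
#' @param contour_params,segmentation_params,detection_params parameter
#'   objects (package defaults).
#' @return A `cb_joint_result` (see [detect_interruptions()]); the contour,
#'   bone model and mask are attached as attributes `"contour"`, `"bone"`,
#'   `"mask"` for inspection.
#' @export
detect_cortical_interruptions <- function(gray, contour = NULL,
    contour_params = cortibreak::contour_params(),
    segmentation_params = cortibreak::segmentation_params(),
    detection_params = cortibreak::detection_params()) {
  stopifnot(inherits(gray, "cb_grayscale"))
  solid <- if (is.null(contour)) auto_contour(gray, contour_params)
           else load_corrected_contour(contour, gray = gray)
  bone <- binarize_bone(gray, segmentation_params, contour = solid)
  mask <- build_cortical_mask(solid, detection_params)
  res <- detect_interruptions(bone, mask, detection_params)
  attr(res, "contour") <- solid
  attr(res, "bone") <- bone
  attr(res, "mask") <- mask
  res
}

#' Run the full pipeline from a configuration
#'
#' Reads the input, runs [detect_cortical_interruptions()] (fully-automated,
#' or semi-automated when `contour` is set), and writes artifacts to
#' `out_dir`: the interruption label map (`interruptions.nii`), the
#' per-interruption table (`interruptions.csv`), the joint summary with all
#' intermediate voxel counts (`summary.json`), and the resolved configuration
#' (`config.json`). Identical configuration and inputs produce byte-identical
#' CSV/JSON outputs.
#'
#' @param cfg a [run_config()] or the path of a YAML/JSON configuration.
#' @return The `cb_joint_result`, invisibly.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- load_run_config(cfg)
  stopifnot(inherits(cfg, "cb_run_config"))
  log_info <- function(fmt, ...) {
    if (cfg$log_level == "info") message(sprintf(paste0("[cortibreak] ", fmt), ...))
  }
  gray <- if (inherits(cfg$input, "cb_grayscale")) cfg$input else
    with_stage("volume_io", read_volume(cfg$input, format = cfg$format,
                                        voxel_size_mm = cfg$voxel_size_mm,
                                        intensity_max = cfg$intensity_max))
  log_info("input volume %s @ %g mm, intensity_max %g",
           paste(dim(gray$data), collapse = "x"), gray$voxel_size_mm,
           gray$intensity_max)
  mode <- if (is.null(cfg$contour)) "fully-automated" else "semi-automated"
  log_info("procedure: %s", mode)

  solid <- with_stage("contouring",
    if (is.null(cfg$contour)) auto_contour(gray, cfg$contour_params)
    else load_corrected_contour(cfg$contour, gray = gray,
                                voxel_size_mm = gray$voxel_size_mm))
  log_info("contour solid: %d voxels", sum(solid$data))
  bone <- with_stage("segmentation",
                     binarize_bone(gray, cfg$segmentation_params, contour = solid))
  log_info("bone model: %d voxels", sum(bone$data))
  mask <- with_stage("detection", build_cortical_mask(solid, cfg$detection_params))
  log_info("cortical mask: %d shell voxels (thickness %.3f mm)",
           sum(mask$shell$data), mask$thickness_mm)
  res <- with_stage("detection",
                    detect_interruptions(bone, mask, cfg$detection_params))
  log_info("void components %d, connected to both boundaries %d, kept %d",
           res$counts$void_components, res$counts$components_connected_both,
           res$n_interruptions)
  attr(res, "contour") <- solid
  attr(res, "bone") <- bone
  attr(res, "mask") <- mask

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_volume(res$label_map, file.path(cfg$out_dir, "interruptions.nii"))
    utils::write.csv(res$records, file.path(cfg$out_dir, "interruptions.csv"),
                     row.names = FALSE)
    summary_out <- c(list(procedure = mode),
                     as.list(summarize_interruptions(res)), res$counts)
    jsonlite::write_json(summary_out, file.path(cfg$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(serialize_config(cfg),
                         file.path(cfg$out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (cfg$qc) write_qc_png(gray, mask, res, file.path(cfg$out_dir, "qc.png"))
    log_info("artifacts written to %s", cfg$out_dir)
  }
  invisible(res)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "cb_validation_error"))
      stop_validation(sprintf("[%s] %s", stage, conditionMessage(e)))
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

serialize_config <- function(cfg) {
  list(input = if (is.character(cfg$input)) cfg$input else "<in-memory volume>",
       out_dir = cfg$out_dir,
       format = cfg$format,
       voxel_size_mm = cfg$voxel_size_mm,
       intensity_max = cfg$intensity_max,
       contour = if (is.null(cfg$contour)) NULL
                 else if (is.character(cfg$contour)) cfg$contour
                 else "<in-memory volume>",
       contour_params = unclass(cfg$contour_params),
       segmentation_params = unclass(cfg$segmentation_params),
       detection_params = unclass(cfg$detection_params),
       qc = cfg$qc, seed = cfg$seed, log_level = cfg$log_level)
}

# Middle-slice overlay: grayscale in gray, mask boundary in blue, detected
# interruptions in green.
write_qc_png <- function(gray, mask, res, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    warning("package 'png' not available; QC render skipped", call. = FALSE)
    return(invisible(NULL))
  }
  s <- which.max(vapply(seq_len(dim(res$label_map$data)[1]),
                        function(i) sum(res$label_map$data[i, , ] > 0), 0))
  if (length(s) == 0 || max(res$label_map$data) == 0)
    s <- dim(gray$data)[1] %/% 2
  g <- gray$data[s, , ] / gray$intensity_max
  m <- mask$shell$data[s, , ]
  l <- res$label_map$data[s, , ] > 0
  rgb <- array(0, c(dim(g), 3))
  rgb[, , 1] <- g
  rgb[, , 2] <- pmin(1, g + 0.8 * l)
  rgb[, , 3] <- pmin(1, g + 0.35 * (m & !l))
  png::writePNG(rgb, path)
  invisible(path)
}
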