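# Volume I/O: NIfTI (RNifti), multi-page TIFF stacks (tiff) and uncompressed
# MetaImage (.mha/.mhd, read/written directly: header of "Key = Value" lines
# plus a raw little-endian payload). A JSON sidecar (<path>.json) carries the
# voxel size, the acquisition intensity_max and the volume kind whenever the
# container has no slot for them; it is written for every format and used on
# read when present.

infer_format <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) return("nifti")
  if (grepl("\\.(mha|mhd)$", lower)) return("metaimage")
  if (grepl("\\.(tif|tiff)$", lower)) return("tiff_stack")
  stop_validation(sprintf("cannot infer volume format from '%s'", path))
}

sidecar_path <- function(path) paste0(path, ".json")

volume_kind <- function(vol) {
  if (inherits(vol, "cb_labelmap")) "label"
  else if (inherits(vol, "cb_binary")) "binary"
  else if (inherits(vol, "cb_grayscale")) "grayscale"
  else stop_validation("vol must be a cortibreak volume object")
}

#' Write a 3D volume to disk
#'
#' Grayscale volumes are stored as float64 (NIfTI/MetaImage), label maps as
#' int32 and binary volumes as uint8, so every lattice round-trips exactly.
#' TIFF stacks store 16-bit unsigned samples; writing non-integer data or
#' values outside `[0, 65535]` to a TIFF is a validation error (the
#' combination would be lossy). A JSON sidecar `<path>.json` records
#' `voxel_size_mm`, `kind` and (for grayscale) `intensity_max`.
#'
#' @param vol a [grayscale_volume()], [binary_volume()] or [label_map()].
#' @param path output file; extension `.nii`/`.nii.gz`, `.mha`/`.mhd`,
#'   `.tif`/`.tiff` selects the format when `format` is `NULL`.
#' @param format one of `"nifti"`, `"metaimage"`, `"tiff_stack"`, or `NULL`
#'   to infer from the extension.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = NULL) {
  if (!inherits(vol, "cb_volume"))
    stop_validation("vol must be a cortibreak volume object")
  if (is.null(format)) format <- infer_format(path)
  format <- match.arg(format, c("nifti", "metaimage", "tiff_stack"))
  if (!dir.exists(dirname(path)))
    stop(sprintf("directory '%s' does not exist", dirname(path)))
  kind <- volume_kind(vol)
  switch(format,
         nifti = write_nifti_volume(vol, path, kind),
         metaimage = write_metaimage_volume(vol, path, kind),
         tiff_stack = write_tiff_volume(vol, path, kind))
  side <- list(voxel_size_mm = vol$voxel_size_mm, kind = kind)
  if (kind == "grayscale") side$intensity_max <- vol$intensity_max
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a 3D volume from disk
#'
#' The voxel size is taken from the file header when present (NIfTI,
#' MetaImage), else from the JSON sidecar, else from the `voxel_size_mm`
#' override, which is then required. Anisotropic header voxels are a
#' validation error unless an explicit override is supplied, because the
#' interruption pipeline assumes isotropy.
#'
#' @param path input file.
#' @param format `"nifti"`, `"metaimage"`, `"tiff_stack"` or `NULL` (infer
#'   from the extension).
#' @param voxel_size_mm explicit isotropic voxel size override (mm).
#' @param intensity_max explicit acquisition maximum override; when absent it
#'   comes from the sidecar, falling back to `max(data, 1)`.
#' @param kind `"grayscale"`, `"binary"` or `"label"`; default from the
#'   sidecar, else `"grayscale"`.
#' @return A [grayscale_volume()], [binary_volume()] or [label_map()].
#' @export
read_volume <- function(path, format = NULL, voxel_size_mm = NULL,
                        intensity_max = NULL, kind = NULL) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  if (is.null(format)) format <- infer_format(path)
  format <- match.arg(format, c("nifti", "metaimage", "tiff_stack"))
  raw <- switch(format,
                nifti = read_nifti_volume(path),
                metaimage = read_metaimage_volume(path),
                tiff_stack = read_tiff_volume(path))
  side <- if (file.exists(sidecar_path(path)))
    jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE) else list()

  vs <- voxel_size_mm
  # the JSON sidecar stores the voxel size at full precision (NIfTI headers
  # hold float32 pixdims), so it takes precedence over the header
  if (is.null(vs) && !is.null(side$voxel_size_mm)) vs <- side$voxel_size_mm
  if (is.null(vs) && !is.null(raw$spacing)) {
    sp <- raw$spacing
    if (max(sp) - min(sp) > 1e-6 * max(sp))
      stop_validation(paste0("anisotropic voxels in '", path,
                             "'; supply voxel_size_mm explicitly"))
    vs <- sp[1]
  }
  if (is.null(vs))
    stop_validation("voxel size not stored in file; supply voxel_size_mm")

  if (is.null(kind)) kind <- if (!is.null(side$kind)) side$kind else "grayscale"
  kind <- match.arg(kind, c("grayscale", "binary", "label"))
  if (is.null(intensity_max) && !is.null(side$intensity_max))
    intensity_max <- side$intensity_max

  data <- raw$data
  switch(kind,
         grayscale = grayscale_volume(data, vs, intensity_max),
         binary = binary_volume(data != 0, vs),
         label = label_map(round(data), vs, compact = TRUE))
}

## --- NIfTI ------------------------------------------------------------

write_nifti_volume <- function(vol, path, kind) {
  arr <- vol$data
  datatype <- switch(kind, grayscale = "double", binary = "uint8",
                     label = "int32")
  if (kind == "binary") {
    arr <- array(as.integer(arr), dim(arr))
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(vol$voxel_size_mm, 3L)
  RNifti::writeNifti(img, path, datatype = datatype)
}

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop_validation(sprintf("'%s' is not a 3D volume", path))
  list(data = array(as.numeric(arr), dim(arr)),
       spacing = RNifti::pixdim(img)[1:3])
}

## --- MetaImage --------------------------------------------------------

met_types <- list(
  MET_UCHAR = list(what = "integer", size = 1L, signed = FALSE),
  MET_CHAR = list(what = "integer", size = 1L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_SHORT = list(what = "integer", size = 2L, signed = TRUE),
  MET_UINT = list(what = "integer", size = 4L, signed = TRUE),
  MET_INT = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT = list(what = "numeric", size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "numeric", size = 8L, signed = TRUE)
)

write_metaimage_volume <- function(vol, path, kind) {
  arr <- vol$data
  d <- dim(arr)
  etype <- switch(kind, grayscale = "MET_DOUBLE", binary = "MET_UCHAR",
                  label = "MET_INT")
  is_mhd <- grepl("\\.mhd$", tolower(path))
  datafile <- if (is_mhd) paste0(tools::file_path_sans_ext(basename(path)),
                                 ".raw") else "LOCAL"
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    sprintf("ElementSpacing = %.17g %.17g %.17g", vol$voxel_size_mm,
            vol$voxel_size_mm, vol$voxel_size_mm),
    sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
    sprintf("ElementType = %s", etype),
    sprintf("ElementDataFile = %s", datafile)
  )
  payload <- switch(kind,
                    grayscale = as.numeric(arr),
                    binary = as.integer(arr),
                    label = as.integer(arr))
  size <- met_types[[etype]]$size
  if (is_mhd) {
    writeLines(hdr, path)
    con <- file(file.path(dirname(path), datafile), "wb")
    on.exit(close(con))
    writeBin(payload, con, size = size, endian = "little")
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
    writeBin(payload, con, size = size, endian = "little")
  }
}

read_metaimage_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  fields <- list()
  datafile <- NULL
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L)
      stop_validation(sprintf("'%s': no ElementDataFile entry", path))
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) != 3L)
      stop_validation(sprintf("'%s': malformed MetaImage header line", path))
    key <- kv[2]; val <- trimws(kv[3])
    fields[[key]] <- val
    if (key == "ElementDataFile") { datafile <- val; break }
  }
  if (!is.null(fields$CompressedData) &&
      tolower(fields$CompressedData) == "true")
    stop_validation("compressed MetaImage payloads are not supported")
  if (!is.null(fields$BinaryDataByteOrderMSB) &&
      tolower(fields$BinaryDataByteOrderMSB) == "true")
    stop_validation("big-endian MetaImage payloads are not supported")
  if (is.null(fields$DimSize) || is.null(fields$ElementType))
    stop_validation(sprintf("'%s': DimSize/ElementType missing", path))
  d <- as.integer(strsplit(fields$DimSize, "\\s+")[[1]])
  if (length(d) != 3L)
    stop_validation("only 3D MetaImage volumes are supported")
  tp <- met_types[[fields$ElementType]]
  if (is.null(tp))
    stop_validation(sprintf("unsupported ElementType '%s'", fields$ElementType))
  n <- prod(d)
  if (identical(datafile, "LOCAL")) {
    vals <- readBin(con, what = tp$what, n = n, size = tp$size,
                    signed = tp$signed, endian = "little")
  } else {
    rawpath <- file.path(dirname(path), datafile)
    if (!file.exists(rawpath))
      stop(sprintf("MetaImage data file '%s' does not exist", rawpath))
    con2 <- file(rawpath, "rb")
    on.exit(close(con2), add = TRUE)
    vals <- readBin(con2, what = tp$what, n = n, size = tp$size,
                    signed = tp$signed, endian = "little")
  }
  if (length(vals) != n)
    stop_validation(sprintf("'%s': truncated MetaImage payload", path))
  spacing <- if (!is.null(fields$ElementSpacing))
    as.numeric(strsplit(fields$ElementSpacing, "\\s+")[[1]]) else NULL
  list(data = array(as.numeric(vals), d), spacing = spacing)
}

## --- TIFF stack -------------------------------------------------------

write_tiff_volume <- function(vol, path, kind) {
  arr <- vol$data
  vals <- if (is.logical(arr)) as.integer(arr) else as.numeric(arr)
  if (any(vals != round(vals)) || min(vals) < 0 || max(vals) > 65535)
    stop_validation(paste0("tiff_stack stores 16-bit unsigned integers; ",
                           "data must be integer-valued in [0, 65535] ",
                           "(lossy format/type combination)"))
  d <- dim(arr)
  pages <- lapply(seq_len(d[1]), function(s) {
    m <- matrix(vals[seq.int(s, length(vals), by = d[1])], d[2], d[3])
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
}

read_tiff_volume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # drop replicated channels
    round(p * 65535)
  })
  d2 <- dim(pages[[1]])
  arr <- array(0, c(length(pages), d2[1], d2[2]))
  for (s in seq_along(pages)) arr[s, , ] <- pages[[s]]
  list(data = arr, spacing = NULL)
}
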