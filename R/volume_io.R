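#' Write a parameter volume or mask as NIfTI-1 with a JSON sidecar
#'
#' Missing voxels (outside `valid_mask`) are written as `NaN`. The sidecar
#' (`<path without .nii/.nii.gz>.json`) records modality, units, and voxel
#' geometry so that reading restores the object exactly.
#'
#' @param x A [parameter_volume()] or [binary_mask()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "tumor_mask")) x <- x$mask
  if (inherits(x, "parameter_volume")) {
    vals <- x$values
    vals[!x$valid_mask] <- NaN
    side <- list(kind = "parameter_volume", modality = x$modality,
                 units = x$units)
  } else if (inherits(x, "binary_mask")) {
    vals <- array(as.numeric(x$values), dim = dim(x$values))
    side <- list(kind = "binary_mask", label = x$label)
  } else stop("cannot write object of class ", paste(class(x), collapse = "/"))
  g <- if (inherits(x, "parameter_volume")) x$geometry else x$geometry
  img <- RNifti::asNifti(vals, internal = FALSE)
  RNifti::pixdim(img) <- c(g$in_plane, g$in_plane, g$thickness)
  RNifti::writeNifti(img, path)
  side$geometry <- list(in_plane = g$in_plane, thickness = g$thickness,
                        dim = g$dim)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Read a NIfTI-1 parameter volume
#'
#' Geometry is taken from the NIfTI header (and cross-checked against the JSON
#' sidecar when present); voxels stored as `NaN` are flagged invalid. If
#' `study_geometry` is supplied the file's geometry must match it, enforcing
#' the one-grid-per-study convention.
#'
#' @param path NIfTI file path.
#' @param modality Modality code (see [modality_table()]); defaults to the
#'   sidecar's value.
#' @param units Units string; defaults to sidecar, then modality standard.
#' @param study_geometry Optional [voxel_geometry()] to validate against.
#' @return A [parameter_volume()].
#' @export
read_volume <- function(path, modality = NULL, units = NULL,
                        study_geometry = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("malformed NIfTI file: ", path,
                                           " (", conditionMessage(e), ")"))
  vals <- array(as.numeric(img), dim = dim(img))
  if (length(dim(vals)) == 2) dim(vals) <- c(dim(vals), 1L)
  pd <- RNifti::pixdim(img)
  geom <- voxel_geometry(pd[1], pd[3], dim(vals))
  side <- read_sidecar(path)
  if (!is.null(side)) {
    if (is.null(modality) && !is.null(side$modality)) modality <- side$modality
    if (is.null(units) && !is.null(side$units)) units <- side$units
    if (!is.null(side$geometry)) {
      sg <- voxel_geometry(side$geometry$in_plane, side$geometry$thickness,
                           side$geometry$dim)
      check_same_geometry(geom, sg, "NIfTI header and sidecar")
    }
  }
  if (is.null(modality))
    stop("modality not given and no sidecar metadata found for ", path)
  if (!is.null(study_geometry))
    check_same_geometry(geom, study_geometry, "volume and study")
  parameter_volume(vals, modality, geom, units = units)
}

#' Read a NIfTI-1 binary mask
#'
#' @inheritParams read_volume
#' @param label Label for the mask; defaults to the sidecar's, then filename.
#' @return A [binary_mask()].
#' @export
read_mask <- function(path, label = NULL, study_geometry = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim = dim(img))
  if (length(dim(vals)) == 2) dim(vals) <- c(dim(vals), 1L)
  if (!all(vals %in% c(0, 1)))
    stop("mask file is not strictly binary: ", path)
  pd <- RNifti::pixdim(img)
  geom <- voxel_geometry(pd[1], pd[3], dim(vals))
  side <- read_sidecar(path)
  if (is.null(label))
    label <- if (!is.null(side$label)) side$label else basename(path)
  if (!is.null(study_geometry))
    check_same_geometry(geom, study_geometry, "mask and study")
  binary_mask(vals, geom, label = label)
}

#' Read a study of co-registered volumes from a JSON config
#'
#' The config maps modality codes to file paths (and optional units), e.g.
#' `{"volumes": {"postgd": "postgd.nii.gz", ...}, "masks": {"brain": ...}}`.
#' Paths are resolved relative to the config file. All files must share one
#' geometry; a mismatch raises a consistency error.
#'
#' @param config_path Path to the JSON config.
#' @return A list with elements `volumes` (named list of [parameter_volume()]),
#'   `masks` (named list of [binary_mask()]) and `geometry`.
#' @export
read_study <- function(config_path) {
  cfg <- jsonlite::read_json(config_path, simplifyVector = TRUE)
  base <- dirname(config_path)
  geom <- NULL
  vols <- list()
  for (m in names(cfg$volumes)) {
    entry <- cfg$volumes[[m]]
    path <- if (is.list(entry)) entry$path else entry
    units <- if (is.list(entry)) entry$units else NULL
    v <- read_volume(file.path(base, path), modality = m, units = units,
                     study_geometry = geom)
    if (is.null(geom)) geom <- v$geometry
    vols[[m]] <- v
  }
  masks <- list()
  for (m in names(cfg$masks)) {
    masks[[m]] <- read_mask(file.path(base, cfg$masks[[m]]), label = m,
                            study_geometry = geom)
    if (is.null(geom)) geom <- masks[[m]]$geometry
  }
  list(volumes = vols, masks = masks, geometry = geom)
}

#' Read/write a 2-D binary raster (PNG or TIFF)
#'
#' Single-channel rasters holding stain or tissue masks. Values must be
#' strictly binary (0/1 after scaling).
#'
#' @param path File ending in `.png`, `.tif` or `.tiff`.
#' @return `read_raster()`: a logical matrix. `write_raster()`: `path`.
#' @export
read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
              png = png::readPNG(path),
              tif = ,
              tiff = tiff::readTIFF(path),
              stop("unsupported raster format: ", ext))
  if (length(dim(m)) == 3) m <- m[, , 1]
  if (!all(m %in% c(0, 1))) stop("raster is not strictly binary: ", path)
  matrix(as.logical(m), nrow = nrow(m))
}

#' @rdname read_raster
#' @param mask Logical matrix to write.
#' @export
write_raster <- function(mask, path) {
  stopifnot(is.matrix(mask))
  m <- matrix(as.numeric(mask), nrow = nrow(mask))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(m, path),
         tif = ,
         tiff = tiff::writeTIFF(m, path, bits.per.sample = 8),
         stop("unsupported raster format: ", ext))
  invisible(path)
}
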