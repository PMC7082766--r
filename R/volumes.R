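#' MRI modalities handled by the pipeline
#'
#' The six co-registered parameter maps used for multimodal delineation, with
#' their physical units. ADC appears once here; at the abnormality-channel
#' level it contributes two directional channels (increased and decreased).
#'
#' @return A data frame with columns `modality` and `units`.
#' @export
modality_table <- function() {
  data.frame(
    modality = c("postgd", "t1", "t2", "cbv", "cbf", "adc"),
    units    = c("a.u.", "s", "s", "%", "mL/100g/min", "um^2/ms"),
    stringsAsFactors = FALSE
  )
}

#' A single co-registered 3-D MRI parameter map
#'
#' Missing data are encoded as `NaN`/`NA` in `values` and excluded from all
#' downstream computation via `valid_mask`.
#'
#' @param values Numeric 3-D array.
#' @param modality One of `modality_table()$modality`.
#' @param geometry A [voxel_geometry()] matching `dim(values)`.
#' @param units Units string; defaults to the standard units for the modality.
#' @param valid_mask Optional logical array marking voxels with data; defaults
#'   to `is.finite(values)`.
#' @return An object of class `parameter_volume`.
#' @export
parameter_volume <- function(values, modality, geometry, units = NULL,
                             valid_mask = NULL) {
  modality <- match.arg(modality, modality_table()$modality)
  stopifnot(inherits(geometry, "voxel_geometry"))
  values <- as.array(values)
  if (!identical(dim(values), as.integer(geometry$dim)))
    stop("values dimensions do not match geometry")
  if (is.null(valid_mask)) valid_mask <- is.finite(values)
  valid_mask <- array(as.logical(valid_mask), dim = dim(values))
  if (any(!is.finite(values[valid_mask])))
    stop("non-finite values inside valid_mask")
  if (is.null(units)) {
    mt <- modality_table()
    units <- mt$units[mt$modality == modality]
  }
  structure(list(values = values, modality = modality, units = units,
                 geometry = geometry, valid_mask = valid_mask),
            class = "parameter_volume")
}

#' @export
print.parameter_volume <- function(x, ...) {
  cat(sprintf("parameter_volume '%s' [%s]: %d/%d valid voxels\n",
              x$modality, x$units, sum(x$valid_mask), length(x$valid_mask)))
  print(x$geometry)
  invisible(x)
}

#' A binary 3-D mask on the study grid
#'
#' @param values Logical (or 0/1) 3-D array.
#' @param geometry A [voxel_geometry()].
#' @param label Free-text label.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, geometry, label = "") {
  stopifnot(inherits(geometry, "voxel_geometry"))
  values <- as.array(values)
  if (!identical(dim(values), as.integer(geometry$dim)))
    stop("mask dimensions do not match geometry")
  if (is.numeric(values) && !all(values %in% c(0, 1)))
    stop("mask values must be strictly binary")
  values <- array(as.logical(values), dim = dim(values))
  structure(list(values = values, geometry = geometry, label = label),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary_mask '%s': %d set voxels (%.4g uL)\n",
              x$label, sum(x$values), volume_from_mask(x)))
  invisible(x)
}

# Accept binary_mask, tumor_mask or a bare logical array.
as_mask_array <- function(x) {
  if (inherits(x, "tumor_mask")) x <- x$mask
  if (inherits(x, "binary_mask")) return(x$values)
  if (is.array(x) && is.logical(x)) return(x)
  if (is.array(x)) return(array(as.logical(x), dim = dim(x)))
  stop("not a mask: expected binary_mask, tumor_mask, or logical array")
}

#' Volume enclosed by a binary mask, in microlitres
#'
#' @param mask A [binary_mask()] (or a `tumor_mask`).
#' @param geometry Required if `mask` is a bare array.
#' @return Volume in uL: set-voxel count times voxel volume.
#' @examples
#' g <- voxel_geometry(0.5, 1, c(10, 10, 2))
#' m <- array(FALSE, c(10, 10, 2)); m[1:10, 1:10, 1] <- TRUE
#' volume_from_mask(binary_mask(m, g))  # 100 voxels * 0.25 uL = 25 uL
#' @export
volume_from_mask <- function(mask, geometry = NULL) {
  if (is.null(geometry)) {
    if (inherits(mask, "tumor_mask")) geometry <- mask$mask$geometry
    else if (inherits(mask, "binary_mask")) geometry <- mask$geometry
    else stop("geometry required for bare arrays")
  }
  sum(as_mask_array(mask)) * voxel_volume_ul(geometry)
}
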