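#' Build the contralateral (normal-hemisphere) reference mask
#'
#' The reference region is every brain voxel strictly beyond the midline on
#' the side without tumor, excluding ventricles. It is a single pooled 3-D
#' region: it is not subdivided by slice or tissue class. The midline is
#' supplied per slice (a column index per slice, or one scalar), which
#' accommodates tumor-induced midline shift; there is no automatic midline
#' detection.
#'
#' @param brain_mask [binary_mask()] of the whole brain.
#' @param midline Column index (1-based) of the midline plane: scalar or one
#'   value per slice. Voxels in this column belong to neither hemisphere.
#' @param tumor_side `"left"` (lower column indices) or `"right"`.
#' @param ventricle_mask [binary_mask()] of ventricles (excluded).
#' @return A [binary_mask()] labelled `"contralateral"`.
#' @export
build_contralateral_mask <- function(brain_mask, midline, tumor_side = c("left", "right"),
                                     ventricle_mask = NULL) {
  tumor_side <- match.arg(tumor_side)
  brain <- as_mask_array(brain_mask)
  geom <- brain_mask$geometry
  dm <- dim(brain)
  midline <- as.numeric(midline)
  if (length(midline) == 1) midline <- rep(midline, dm[3])
  if (length(midline) != dm[3])
    stop("midline must be scalar or one value per slice")
  if (any(midline < 1 | midline > dm[2]))
    stop("midline column index outside grid")
  cols <- array(rep(seq_len(dm[2]), each = dm[1]), dim = dm)
  mid <- array(rep(midline, each = dm[1] * dm[2]), dim = dm)
  contra <- if (tumor_side == "left") brain & cols > mid else brain & cols < mid
  if (!is.null(ventricle_mask)) {
    check_same_geometry(geom, ventricle_mask$geometry, "brain and ventricle masks")
    contra <- contra & !as_mask_array(ventricle_mask)
  }
  if (!any(contra))
    stop("degenerate reference: contralateral mask is empty")
  binary_mask(contra, geom, label = "contralateral")
}

#' Per-modality normal statistics over the contralateral region
#'
#' Computes, for each modality, the mean and sample standard deviation
#' (n - 1 denominator) over voxels in the contralateral mask intersected with
#' the volume's valid mask. One pooled region per study.
#'
#' @param volumes Named list of [parameter_volume()] objects.
#' @param contralateral [binary_mask()] from [build_contralateral_mask()].
#' @return A `reference_stats` data frame with columns `modality`, `mean`,
#'   `sd`, `n_voxels`, `units`.
#' @export
compute_reference_stats <- function(volumes, contralateral) {
  stopifnot(length(volumes) >= 1)
  contra <- as_mask_array(contralateral)
  rows <- lapply(volumes, function(v) {
    stopifnot(inherits(v, "parameter_volume"))
    check_same_geometry(v$geometry, contralateral$geometry,
                        "volume and contralateral mask")
    sel <- contra & v$valid_mask
    n <- sum(sel)
    if (n < 2)
      stop("degenerate reference: fewer than 2 usable voxels for ", v$modality)
    x <- v$values[sel]
    data.frame(modality = v$modality, mean = mean(x), sd = stats::sd(x),
               n_voxels = n, units = v$units, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("reference_stats", "data.frame")
  out
}

reference_row <- function(stats, modality) {
  i <- match(modality, stats$modality)
  if (is.na(i)) stop("no reference statistics for modality '", modality, "'")
  stats[i, ]
}

#' Write reference statistics to CSV
#'
#' @param stats A `reference_stats` data frame.
#' @param path Output CSV path.
#' @export
write_reference_stats <- function(stats, path) {
  utils::write.csv(as.data.frame(stats), path, row.names = FALSE)
  invisible(path)
}
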