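#' A single stained histology section
#'
#' A binary-thresholded stain mask with a tissue mask marking usable tissue
#' (damaged or missing tissue is excluded), its pixel size, and its axial
#' position along the imaging volume. Sections are assumed already in
#' register with their image slice; only downscaling, block averaging, and
#' missing-data masking happen here.
#'
#' @param binary_mask Logical matrix of stain-positive pixels.
#' @param tissue_mask Logical matrix of usable tissue, same shape.
#' @param stain One of `"epcam"`, `"pimonidazole"`, `"cresyl_violet"`,
#'   `"collagen_iv"`.
#' @param pixel_size_um Pixel edge length in micrometres.
#' @param position_um Axial position of the section in micrometres, measured
#'   from the first slice boundary of the target volume.
#' @return An object of class `stain_section`.
#' @export
stain_section <- function(binary_mask, tissue_mask, stain, pixel_size_um,
                          position_um) {
  stain <- match.arg(stain, c("epcam", "pimonidazole", "cresyl_violet",
                              "collagen_iv"))
  stopifnot(is.matrix(binary_mask), is.matrix(tissue_mask),
            identical(dim(binary_mask), dim(tissue_mask)),
            pixel_size_um > 0)
  structure(list(binary_mask = matrix(as.logical(binary_mask), nrow(binary_mask)),
                 tissue_mask = matrix(as.logical(tissue_mask), nrow(tissue_mask)),
                 stain = stain, pixel_size_um = as.numeric(pixel_size_um),
                 position_um = as.numeric(position_um)),
            class = "stain_section")
}

#' An ordered stack of sections for one stain
#'
#' @param sections List of [stain_section()]s (sorted by position on
#'   construction).
#' @param target_geometry [voxel_geometry()] of the imaging volume the stack
#'   maps into.
#' @param section_spacing_um Nominal spacing between sections; default 200.
#' @return An object of class `histology_stack`.
#' @export
histology_stack <- function(sections, target_geometry, section_spacing_um = 200) {
  stopifnot(length(sections) >= 1, inherits(target_geometry, "voxel_geometry"),
            section_spacing_um > 0)
  stains <- unique(vapply(sections, function(s) s$stain, ""))
  if (length(stains) != 1) stop("a histology stack holds a single stain")
  pos <- vapply(sections, function(s) s$position_um, 0)
  structure(list(sections = sections[order(pos)],
                 target_geometry = target_geometry,
                 section_spacing_um = section_spacing_um,
                 stain = stains),
            class = "histology_stack")
}

#' Percentage-staining map of one section
#'
#' Divides the section into `block_size_px` x `block_size_px` blocks and
#' reports, per block, 100 x (stain-positive pixels) / (tissue pixels).
#' Blocks containing no tissue pixels are missing (`NA`). Rasters whose
#' dimensions are not multiples of the block size are padded with non-tissue.
#'
#' @param section A [stain_section()].
#' @param block_size_px Block edge in pixels (>= 1).
#' @return Numeric matrix of percentages in `[0, 100]`, `NA` where no tissue.
#' @export
staining_fraction_map <- function(section, block_size_px) {
  stopifnot(inherits(section, "stain_section"), block_size_px >= 1)
  b <- as.integer(block_size_px)
  pos <- section$binary_mask & section$tissue_mask
  tis <- section$tissue_mask
  nr <- ceiling(nrow(tis) / b) * b
  nc <- ceiling(ncol(tis) / b) * b
  pad <- function(m) {
    out <- matrix(FALSE, nr, nc)
    out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
    out
  }
  pos <- pad(pos); tis <- pad(tis)
  block_sum <- function(m) {
    # sum within b x b tiles via two folds
    m1 <- rowsum(m * 1, rep(seq_len(nr / b), each = b))
    t(rowsum(t(m1), rep(seq_len(nc / b), each = b)))
  }
  p <- block_sum(pos); t_ <- block_sum(tis)
  out <- 100 * p / t_
  out[t_ == 0] <- NA_real_
  out
}

#' Downscale a binary raster without interpolation
#'
#' Nearest-neighbour subsampling: one source pixel (the first of each
#' `factor` x `factor` block) represents the block, so the output stays
#' strictly binary. Dimensions that are not multiples of `factor` are
#' handled by the implicit non-tissue padding of partial blocks.
#'
#' @param mask Logical matrix.
#' @param factor Integer >= 1.
#' @return Logical matrix of size `ceiling(dim / factor)`.
#' @export
downscale_mask <- function(mask, factor) {
  stopifnot(is.matrix(mask), factor >= 1)
  f <- as.integer(factor)
  if (f == 1) return(matrix(as.logical(mask), nrow(mask)))
  mask[seq(1, nrow(mask), by = f), seq(1, ncol(mask), by = f), drop = FALSE]
}

#' Assemble a histology stack into an image-space fraction volume
#'
#' Each image-space voxel receives the mean of the per-section block
#' fractions over all sections mapping into its slice, ignoring missing
#' blocks ("averaging all contributing sections"). A section at axial
#' position p (um) maps to slice `floor(p / slice_thickness) + 1`. Section
#' rasters must tile the in-plane grid with an integer number of pixels per
#' voxel.
#'
#' @param stack A [histology_stack()].
#' @return A `fraction_volume`: list with `values` (3-D array, percent, `NaN`
#'   off coverage), `coverage` (logical array: >= 1 contributing block),
#'   `geometry`, `stain`.
#' @export
stack_to_volume <- function(stack) {
  stopifnot(inherits(stack, "histology_stack"))
  g <- stack$target_geometry
  dm <- g$dim
  thick_um <- g$thickness * 1000
  sum_arr <- array(0, dim = dm)
  n_arr <- array(0L, dim = dm)
  any_mapped <- FALSE
  for (s in stack$sections) {
    slice <- floor(s$position_um / thick_um) + 1
    if (slice < 1 || slice > dm[3]) next
    ratio <- g$in_plane * 1000 / s$pixel_size_um
    if (abs(ratio - round(ratio)) > 1e-6)
      stop("section pixel size does not tile the voxel grid (",
           s$pixel_size_um, " um into ", g$in_plane * 1000, " um)")
    fr <- staining_fraction_map(s, round(ratio))
    if (nrow(fr) < dm[1] || ncol(fr) < dm[2])
      stop("section raster smaller than the in-plane grid")
    fr <- fr[seq_len(dm[1]), seq_len(dm[2])]
    ok <- !is.na(fr)
    sl_sum <- sum_arr[, , slice]
    sl_n <- n_arr[, , slice]
    sl_sum[ok] <- sl_sum[ok] + fr[ok]
    sl_n[ok] <- sl_n[ok] + 1L
    sum_arr[, , slice] <- sl_sum
    n_arr[, , slice] <- sl_n
    any_mapped <- TRUE
  }
  if (!any_mapped)
    stop("empty volume: no section maps into any slice of the target geometry")
  values <- sum_arr / n_arr
  values[n_arr == 0] <- NaN
  structure(list(values = values, coverage = n_arr > 0, geometry = g,
                 stain = stack$stain),
            class = "fraction_volume")
}

#' @export
print.fraction_volume <- function(x, ...) {
  cat(sprintf("fraction_volume '%s': %d covered voxels, mean %.3g%%\n",
              x$stain, sum(x$coverage), mean(x$values[x$coverage])))
  invisible(x)
}

#' Histology-derived gold-standard tumor map
#'
#' A voxel is tumor when it is strictly more than `epcam_threshold` percent
#' EpCAM positive or strictly more than `pimo_threshold` percent
#' pimonidazole positive. Voxels covered by neither stain are invalid and
#' excluded from all downstream analyses; the returned object carries this
#' validity mask.
#'
#' @param epcam,pimo `fraction_volume`s on the same geometry.
#' @param epcam_threshold EpCAM threshold in percent; default 0.001.
#' @param pimo_threshold Pimonidazole threshold in percent; default 1.
#' @return A `tumor_mask` with method `"gold_standard"` and an extra element
#'   `valid` ([binary_mask()] of voxels covered by at least one stain).
#' @export
gold_standard_map <- function(epcam, pimo, epcam_threshold = 0.001,
                              pimo_threshold = 1) {
  stopifnot(inherits(epcam, "fraction_volume"), inherits(pimo, "fraction_volume"))
  check_same_geometry(epcam$geometry, pimo$geometry, "stain volumes")
  e <- epcam$values > epcam_threshold & epcam$coverage
  p <- pimo$values > pimo_threshold & pimo$coverage
  e[is.na(e)] <- FALSE; p[is.na(p)] <- FALSE
  tm <- new_tumor_mask(e | p, epcam$geometry, "gold_standard",
                       list(epcam_threshold = epcam_threshold,
                            pimo_threshold = pimo_threshold))
  tm$valid <- binary_mask(epcam$coverage | pimo$coverage, epcam$geometry,
                          label = "histology_coverage")
  tm
}
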