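#' Size-filter a binary vessel mask
#'
#' Removes connected components smaller than 5 pixels (noise) or larger than
#' 4000 pixels (ventricles / staining artifacts); components with 5 to 4000
#' pixels inclusive are retained unchanged. 8-connectivity.
#'
#' @param mask Logical matrix.
#' @param min_px,max_px Size bounds; components with `count < min_px` or
#'   `count > max_px` are removed. Defaults 5 and 4000.
#' @return Logical matrix.
#' @export
preprocess_vessel_mask <- function(mask, min_px = 5, max_px = 4000) {
  stopifnot(is.matrix(mask))
  mask <- matrix(as.logical(mask), nrow(mask))
  lab <- label_components(mask, connectivity = 8)
  if (max(lab) == 0) return(mask)
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(sizes >= min_px & sizes <= max_px)
  out <- array(lab %in% keep, dim = dim(mask))
  matrix(out, nrow(mask))
}

#' Per-component vessel morphometry
#'
#' For each 8-connected component: pixel count; centroid; skeleton by
#' topology-preserving (Zhang-Suen) thinning; skeleton length as the summed
#' inter-pixel step lengths along the skeleton (1 per axial step, sqrt(2)
#' per diagonal step); and the maximum inscribed radius as the largest
#' Euclidean distance-transform value attained on the skeleton.
#'
#' @param mask Logical matrix (normally already size-filtered with
#'   [preprocess_vessel_mask()]).
#' @param pixel_size_um Pixel edge length in micrometres.
#' @return Data frame with one row per component: `component`, `pixel_count`,
#'   `centroid_row`, `centroid_col`, `skeleton_length_px`,
#'   `max_inscribed_radius_px`, plus the same morphometrics in micrometres
#'   (`central_diameter_um = 2 * radius * pixel size`,
#'   `cross_sectional_area_um2 = count * pixel size^2`,
#'   `in_plane_length_um = skeleton length * pixel size`).
#' @export
analyze_components <- function(mask, pixel_size_um) {
  stopifnot(is.matrix(mask), pixel_size_um > 0)
  mask <- matrix(as.logical(mask), nrow(mask))
  lab <- label_components(mask, connectivity = 8)
  n <- max(lab)
  empty <- data.frame(component = integer(), pixel_count = integer(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      skeleton_length_px = numeric(),
                      max_inscribed_radius_px = numeric(),
                      central_diameter_um = numeric(),
                      cross_sectional_area_um2 = numeric(),
                      in_plane_length_um = numeric())
  if (n == 0) return(empty)
  # Euclidean distance to background, on a background-padded copy so border
  # components are measured correctly.
  pad <- matrix(0, nrow(mask) + 2, ncol(mask) + 2)
  pad[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  dt <- EBImage::distmap(pad)[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)]
  rows <- lapply(seq_len(n), function(i) {
    sel <- lab == i
    idx <- which(sel, arr.ind = TRUE)
    # thin within the component's bounding box (cheaper, same result)
    r1 <- min(idx[, 1]); r2 <- max(idx[, 1])
    c1 <- min(idx[, 2]); c2 <- max(idx[, 2])
    sub <- matrix(FALSE, r2 - r1 + 3, c2 - c1 + 3)
    sub[cbind(idx[, 1] - r1 + 2, idx[, 2] - c1 + 2)] <- TRUE
    skel <- thin_zhang_suen(sub)
    skel_full <- matrix(FALSE, nrow(mask), ncol(mask))
    sk_idx <- which(skel, arr.ind = TRUE)
    skel_full[cbind(sk_idx[, 1] + r1 - 2, sk_idx[, 2] + c1 - 2)] <- TRUE
    len <- skeleton_length_px(skel)
    rad <- max(dt[skel_full])
    data.frame(component = i, pixel_count = nrow(idx),
               centroid_row = mean(idx[, 1]), centroid_col = mean(idx[, 2]),
               skeleton_length_px = len, max_inscribed_radius_px = rad,
               central_diameter_um = 2 * rad * pixel_size_um,
               cross_sectional_area_um2 = nrow(idx) * pixel_size_um^2,
               in_plane_length_um = len * pixel_size_um)
  })
  do.call(rbind, rows)
}

#' Windowed vessel parameter maps
#'
#' Tiles the raster into `window_px` x `window_px` windows and reports the
#' five vessel parameters per window: vessel area fraction (vessel pixels /
#' tissue pixels), density (component centroids per mm^2 of window tissue),
#' and the means over components whose centroid lies in the window of
#' central diameter (um), cross-sectional area (um^2), and in-plane length
#' (um). Windows with no tissue are missing; windows with tissue but no
#' centroid have density 0 and missing morphometrics.
#'
#' @param components Data frame from [analyze_components()].
#' @param mask The (preprocessed) vessel mask the components came from.
#' @param pixel_size_um Pixel edge in micrometres.
#' @param window_px Window edge in pixels; must divide both raster dimensions.
#' @param tissue_mask Optional logical matrix of usable tissue; default all.
#' @return A `vessel_maps` list of five matrices (`area_fraction`,
#'   `central_diameter`, `cross_sectional_area`, `density`,
#'   `in_plane_length`) plus `window_px` and `pixel_size_um`.
#' @export
vessel_parameter_maps <- function(components, mask, pixel_size_um, window_px,
                                  tissue_mask = NULL) {
  stopifnot(is.matrix(mask), window_px >= 1)
  if (nrow(mask) %% window_px != 0 || ncol(mask) %% window_px != 0)
    stop("window_px must tile the raster exactly")
  if (is.null(tissue_mask)) tissue_mask <- matrix(TRUE, nrow(mask), ncol(mask))
  nwr <- nrow(mask) / window_px
  nwc <- ncol(mask) / window_px
  win_of <- function(i) ceiling(i / window_px)
  wr_px <- rep(seq_len(nwr), each = window_px)
  wc_px <- rep(seq_len(nwc), each = window_px)
  block_sum <- function(m) {
    m1 <- rowsum(m * 1, wr_px)
    t(rowsum(t(m1), wc_px))
  }
  vess_px <- block_sum(mask & tissue_mask)
  tis_px <- block_sum(tissue_mask)
  area_fraction <- vess_px / tis_px
  area_fraction[tis_px == 0] <- NA_real_
  mm2_per_px <- (pixel_size_um / 1000)^2
  shape <- function(fill = NA_real_) matrix(fill, nwr, nwc)
  density <- shape(0)
  density[tis_px == 0] <- NA_real_
  diam <- shape(); csa <- shape(); len <- shape()
  if (nrow(components)) {
    wr <- win_of(components$centroid_row)
    wc <- win_of(components$centroid_col)
    key <- paste(wr, wc)
    for (k in unique(key)) {
      sel <- key == k
      i <- wr[sel][1]; j <- wc[sel][1]
      if (is.na(area_fraction[i, j])) next  # no tissue in window
      density[i, j] <- sum(sel) / (tis_px[i, j] * mm2_per_px)
      diam[i, j] <- mean(components$central_diameter_um[sel])
      csa[i, j] <- mean(components$cross_sectional_area_um2[sel])
      len[i, j] <- mean(components$in_plane_length_um[sel])
    }
  }
  structure(list(area_fraction = area_fraction, central_diameter = diam,
                 cross_sectional_area = csa, density = density,
                 in_plane_length = len, window_px = window_px,
                 pixel_size_um = pixel_size_um),
            class = "vessel_maps")
}
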