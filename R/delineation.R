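#' The seven abnormality channels
#'
#' Each MRI modality maps to one directional abnormality channel, except ADC
#' which contributes separate increased and decreased channels (a voxel can
#' satisfy at most one of the two). Order is the canonical parameter-table
#' order, used throughout for deterministic tie-breaking.
#'
#' @return Data frame with columns `channel`, `modality`, `direction`.
#' @export
channel_table <- function() {
  data.frame(
    channel   = c("postgd_high", "t1_high", "t2_low", "cbv_low", "cbf_low",
                  "adc_high", "adc_low"),
    modality  = c("postgd", "t1", "t2", "cbv", "cbf", "adc", "adc"),
    direction = c("above", "above", "below", "below", "below", "above", "below"),
    stringsAsFactors = FALSE
  )
}

#' Voxel-wise abnormality channel for one modality
#'
#' A valid voxel is abnormal when its value is strictly greater than
#' `mean + k*sd` (direction `"above"`) or strictly less than `mean - k*sd`
#' (direction `"below"`), with mean and SD taken from the contralateral
#' reference. Boundary-equal values are normal. If the reference SD is zero a
#' degenerate-threshold warning is raised and every deviation from the mean
#' in the requested direction triggers the channel.
#'
#' @param volume A [parameter_volume()].
#' @param stats A `reference_stats` data frame containing the modality.
#' @param direction `"above"` or `"below"`.
#' @param k Threshold multiplier in SD units (> 0); default 1.
#' @return Logical array; `FALSE` outside the volume's valid mask.
#' @export
abnormality_channel <- function(volume, stats, direction = c("above", "below"),
                                k = 1) {
  direction <- match.arg(direction)
  stopifnot(k > 0)
  r <- reference_row(stats, volume$modality)
  if (r$sd == 0)
    warning("degenerate threshold: reference SD is 0 for ", volume$modality,
            "; every deviation from the mean triggers")
  thr_hi <- r$mean + k * r$sd
  thr_lo <- r$mean - k * r$sd
  out <- if (direction == "above") volume$values > thr_hi else volume$values < thr_lo
  out[!volume$valid_mask] <- FALSE
  out[is.na(out)] <- FALSE
  out
}

#' Build the full abnormality channel set
#'
#' Applies [abnormality_channel()] for every row of [channel_table()] present
#' in `volumes`. All six modalities are required unless `allow_missing = TRUE`
#' (reduced protocol), in which case channels of absent modalities are
#' omitted.
#'
#' @param volumes Named list of [parameter_volume()] keyed by modality.
#' @param stats `reference_stats` for the same study.
#' @param k Threshold multiplier in SD units; default 1.
#' @param allow_missing Permit a reduced protocol with missing modalities.
#' @return A `channel_set`: list with `channels` (named list of logical
#'   arrays, canonical order), `k`, `reference`, `geometry`.
#' @export
build_channel_set <- function(volumes, stats, k = 1, allow_missing = FALSE) {
  ct <- channel_table()
  missing <- setdiff(unique(ct$modality), names(volumes))
  if (length(missing) && !allow_missing)
    stop("missing modality volume(s): ", paste(missing, collapse = ", "),
         " (set allow_missing = TRUE for a reduced protocol)")
  ct <- ct[ct$modality %in% names(volumes), ]
  geom <- volumes[[ct$modality[1]]]$geometry
  channels <- list()
  for (i in seq_len(nrow(ct))) {
    v <- volumes[[ct$modality[i]]]
    check_same_geometry(v$geometry, geom, "channel volumes")
    channels[[ct$channel[i]]] <-
      abnormality_channel(v, stats, ct$direction[i], k = k)
  }
  structure(list(channels = channels, k = k, reference = stats,
                 geometry = geom),
            class = "channel_set")
}

#' @export
print.channel_set <- function(x, ...) {
  cat(sprintf("channel_set (k = %g): %d channels\n", x$k, length(x$channels)))
  for (nm in names(x$channels))
    cat(sprintf("  %-12s %d abnormal voxels\n", nm, sum(x$channels[[nm]])))
  invisible(x)
}

new_tumor_mask <- function(mask_array, geometry, method, parameters,
                           label = method, log = character()) {
  structure(list(mask = binary_mask(mask_array, geometry, label = label),
                 method = method, parameters = parameters, log = log),
            class = "tumor_mask")
}

#' @export
print.tumor_mask <- function(x, ...) {
  cat(sprintf("tumor_mask [%s]: %d voxels, %.4g uL\n", x$method,
              sum(x$mask$values), volume_from_mask(x)))
  invisible(x)
}

#' Multimodal tumor map: voxels abnormal on >= `min_count` channels
#'
#' The multimodal rule labels a voxel tumor when it is abnormal on
#' `min_count` (default 2) or more of the abnormality channels. Because the
#' increased- and decreased-ADC channels are mutually exclusive, ADC can
#' contribute at most one count.
#'
#' @param channel_set A `channel_set` from [build_channel_set()].
#' @param min_count Minimum number of abnormal channels; default 2.
#' @return A `tumor_mask` with method `"multimodal"`.
#' @export
multimodal_combine <- function(channel_set, min_count = 2) {
  stopifnot(inherits(channel_set, "channel_set"), min_count >= 1)
  counts <- Reduce(`+`, channel_set$channels)
  new_tumor_mask(counts >= min_count, channel_set$geometry, "multimodal",
                 list(min_count = min_count, k = channel_set$k,
                      channels = names(channel_set$channels)))
}

#' Single-modality comparator: post-Gd intensity > 2 SD above reference
#'
#' @param postgd The post-gadolinium T1-weighted [parameter_volume()].
#' @param stats `reference_stats` containing `postgd`.
#' @return A `tumor_mask` with method `"sd2"`.
#' @export
sd2_method <- function(postgd, stats) {
  stopifnot(postgd$modality == "postgd")
  m <- abnormality_channel(postgd, stats, "above", k = 2)
  new_tumor_mask(m, postgd$geometry, "sd2", list(k = 2))
}

#' Single-modality comparator: refined morphological routine
#'
#' A deterministic emulation of the steps a human delineator makes on the
#' post-Gd image: threshold at `mean + k*sd`, morphological closing, keep the
#' largest 26-connected component (restricted to the tumor-side hemisphere
#' when `midline`/`tumor_side` are given), and fill fully enclosed holes.
#' Every step is logged in the returned object's `log`.
#'
#' @param postgd The post-Gd [parameter_volume()].
#' @param stats `reference_stats` containing `postgd`.
#' @param k Threshold multiplier; default 2.
#' @param closing_radius Radius (voxels) of the closing element; default 1.
#' @param midline,tumor_side Optional hemisphere restriction for component
#'   selection (same convention as [build_contralateral_mask()]).
#' @return A `tumor_mask` with method `"refined"`; empty with a warning if no
#'   voxel crosses the threshold.
#' @export
refined_method <- function(postgd, stats, k = 2, closing_radius = 1,
                           midline = NULL, tumor_side = "left") {
  stopifnot(postgd$modality == "postgd")
  log <- character()
  m <- abnormality_channel(postgd, stats, "above", k = k)
  log <- c(log, sprintf("threshold: mean + %g*sd -> %d voxels", k, sum(m)))
  if (!any(m)) {
    warning("refined method: threshold yields an empty mask")
    return(new_tumor_mask(m, postgd$geometry, "refined",
                          list(k = k, closing_radius = closing_radius),
                          log = c(log, "empty mask; remaining steps skipped")))
  }
  if (closing_radius > 0) {
    m <- binary_close(m, r = closing_radius)
    log <- c(log, sprintf("closing: radius %d -> %d voxels", closing_radius, sum(m)))
  }
  lab <- label_components(m, connectivity = 26)
  n_comp <- max(lab)
  if (!is.null(midline)) {
    dm <- dim(m)
    midv <- rep(as.numeric(midline), length.out = dm[3])
    cols <- array(rep(seq_len(dm[2]), each = dm[1]), dim = dm)
    mid <- array(rep(midv, each = dm[1] * dm[2]), dim = dm)
    hemi <- if (tumor_side == "left") cols < mid else cols > mid
    sizes <- tabulate(lab[lab > 0 & hemi], nbins = n_comp)
    if (all(sizes == 0)) sizes <- tabulate(lab[lab > 0], nbins = n_comp)
  } else {
    sizes <- tabulate(lab[lab > 0], nbins = n_comp)
  }
  keep <- which.max(sizes)
  m <- lab == keep
  log <- c(log, sprintf("largest 26-connected component: %d of %d kept (%d voxels)",
                        keep, n_comp, sum(m)))
  m <- fill_holes(m)
  log <- c(log, sprintf("hole fill -> %d voxels", sum(m)))
  new_tumor_mask(m, postgd$geometry, "refined",
                 list(k = k, closing_radius = closing_radius,
                      midline = midline, tumor_side = tumor_side),
                 log = log)
}

#' Independent-observer consensus mask
#'
#' Voxels delineated by only a single observer are excluded: a voxel is
#' consensus tumor when marked by at least `min_votes` (default 2) observers.
#'
#' @param observer_masks List of at least two [binary_mask()] on one grid.
#' @param min_votes Minimum number of observers; default 2.
#' @return A `tumor_mask` with method `"observer_consensus"`.
#' @export
observer_consensus <- function(observer_masks, min_votes = 2) {
  if (length(observer_masks) < 2)
    stop("observer consensus requires at least 2 observer masks")
  geom <- observer_masks[[1]]$geometry
  arrays <- lapply(observer_masks, function(m) {
    check_same_geometry(m$geometry, geom, "observer masks")
    as_mask_array(m)
  })
  votes <- Reduce(`+`, arrays)
  new_tumor_mask(votes >= min_votes, geom, "observer_consensus",
                 list(n_observers = length(observer_masks),
                      min_votes = min_votes))
}
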