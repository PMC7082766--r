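#' Voxel-wise confusion counts over the valid region
#'
#' Counts true/false positives/negatives between a predicted tumor mask and
#' the gold standard, restricted to `valid` voxels; voxels outside `valid`
#' (e.g. missing histology) contribute nowhere.
#'
#' @param pred,gold Masks (`tumor_mask`, [binary_mask()] or logical array).
#' @param valid Mask of evaluable voxels.
#' @return A `confusion` list with `tp`, `fp`, `tn`, `fn`, `n_valid`.
#' @export
confusion <- function(pred, gold, valid) {
  p <- as_mask_array(pred); g <- as_mask_array(gold); v <- as_mask_array(valid)
  stopifnot(identical(dim(p), dim(g)), identical(dim(p), dim(v)))
  if (!any(v)) stop("valid mask is empty")
  p <- p[v]; g <- g[v]
  structure(list(tp = sum(p & g), fp = sum(p & !g),
                 tn = sum(!p & !g), fn = sum(!p & g),
                 n_valid = sum(v)),
            class = "confusion")
}

#' Youden index from sensitivity and specificity
#'
#' `Y = sensitivity + specificity - 1`, the net voxel-classification benefit.
#'
#' @param sensitivity,specificity Proportions in `[0, 1]`.
#' @return The Youden index in `[-1, 1]`.
#' @examples
#' youden_index(0.82, 0.86)  # 0.68
#' @export
youden_index <- function(sensitivity, specificity) {
  sensitivity + specificity - 1
}

#' Evaluation report from confusion counts
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, accuracy
#' `(tp+tn)/n`, Jaccard `tp/(tp+fp+fn)` and Youden index. A zero denominator
#' yields `NA` (with a message), never a silent zero. If `geometry` is given
#' the report also carries prediction and gold volumes in uL.
#'
#' @param counts A `confusion` object.
#' @param geometry Optional [voxel_geometry()] for volumes.
#' @return An `eval_report` list.
#' @export
report <- function(counts, geometry = NULL) {
  stopifnot(inherits(counts, "confusion"))
  safe_div <- function(num, den, what) {
    if (den == 0) {
      message("report: zero denominator for ", what, "; returning NA")
      return(NA_real_)
    }
    num / den
  }
  sens <- safe_div(counts$tp, counts$tp + counts$fn, "sensitivity")
  spec <- safe_div(counts$tn, counts$tn + counts$fp, "specificity")
  acc <- safe_div(counts$tp + counts$tn, counts$n_valid, "accuracy")
  jac <- safe_div(counts$tp, counts$tp + counts$fp + counts$fn, "jaccard")
  out <- list(sensitivity = sens, specificity = spec, accuracy = acc,
              jaccard = jac, youden = youden_index(sens, spec),
              counts = counts)
  if (!is.null(geometry)) {
    vv <- voxel_volume_ul(geometry)
    out$pred_volume_ul <- (counts$tp + counts$fp) * vv
    out$gold_volume_ul <- (counts$tp + counts$fn) * vv
  }
  structure(out, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("sensitivity %.3f  specificity %.3f  accuracy %.3f  J %.3f  Y %.3f\n",
              x$sensitivity, x$specificity, x$accuracy, x$jaccard, x$youden))
  invisible(x)
}

#' Jaccard overlap of two masks
#'
#' `|a intersect b| / |a union b|`; raises an error when both masks are empty
#' (the ratio is undefined and the caller must decide).
#'
#' @param a,b Masks on a shared grid.
#' @return Jaccard index in `[0, 1]`.
#' @export
jaccard_pair <- function(a, b) {
  aa <- as_mask_array(a); bb <- as_mask_array(b)
  stopifnot(identical(dim(aa), dim(bb)))
  un <- sum(aa | bb)
  if (un == 0) stop("Jaccard undefined: both masks are empty")
  sum(aa & bb) / un
}

#' Interobserver agreement metrics
#'
#' Pairwise Jaccard matrix, pairwise percentage volume differences
#' (`|Vi - Vj| / mean(Vi, Vj) * 100`), and mean +/- SD summaries over pairs.
#' Pairs involving an empty observer mask have undefined volume error (`NA`,
#' with a message).
#'
#' @param observer_masks List of >= 2 [binary_mask()]s.
#' @return List with `jaccard` and `volume_error_pct` (symmetric matrices)
#'   and a one-row `summary` data frame.
#' @export
interobserver_metrics <- function(observer_masks) {
  n <- length(observer_masks)
  if (n < 2) stop("need at least 2 observer masks")
  geom <- observer_masks[[1]]$geometry
  vols <- vapply(observer_masks, volume_from_mask, 0)
  J <- matrix(1, n, n); VE <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    J[i, j] <- J[j, i] <- jaccard_pair(observer_masks[[i]], observer_masks[[j]])
    if (vols[i] == 0 || vols[j] == 0) {
      message("interobserver_metrics: empty observer mask; volume error NA for pair ",
              i, "-", j)
      VE[i, j] <- VE[j, i] <- NA_real_
    } else {
      VE[i, j] <- VE[j, i] <- abs(vols[i] - vols[j]) / mean(c(vols[i], vols[j])) * 100
    }
  }
  up <- upper.tri(J)
  list(jaccard = J, volume_error_pct = VE,
       volumes_ul = vols,
       summary = data.frame(n_pairs = sum(up),
                            jaccard_mean = mean(J[up]), jaccard_sd = stats::sd(J[up]),
                            volume_error_mean = mean(VE[up], na.rm = TRUE),
                            volume_error_sd = stats::sd(VE[up], na.rm = TRUE)))
}

eval_domain <- function(channel_set, gold, valid) {
  g <- as_mask_array(gold); v <- as_mask_array(valid)
  stopifnot(identical(dim(g), dim(v)))
  V <- vapply(channel_set$channels, function(ch) ch[v],
              logical(sum(v)))
  list(V = V, g = g[v], n = sum(v))
}

subset_accuracy <- function(V, g, min_count) {
  # accuracy of the >= min_count rule for every subset of channels
  k <- ncol(V)
  B <- matrix(0, k, 2^k)
  for (j in seq_len(k)) B[j, ] <- bitwAnd(seq_len(2^k) - 1, bitwShiftL(1, j - 1)) > 0
  counts <- (V * 1) %*% B
  M <- counts >= min_count
  colMeans(M == g)
}

#' Channel importance by systematic ablation
#'
#' Removes each abnormality channel in turn, recomputes the multimodal mask
#' with the same `min_count`, and records the change in sensitivity,
#' specificity, and accuracy. The relative contribution of a channel is its
#' accuracy drop, floored at zero, normalized so contributions sum to 1
#' (raw signed deltas are retained). Ranks break ties by the canonical
#' channel order.
#'
#' @param channel_set A `channel_set`.
#' @param gold Gold-standard mask.
#' @param valid Mask of evaluable voxels.
#' @param min_count Multimodal threshold; default 2.
#' @return An `importance_table` data frame: one row per channel with
#'   `accuracy_full`, `accuracy_without`, `delta_accuracy`, `delta_sensitivity`,
#'   `delta_specificity`, `contribution`, `rank`.
#' @export
ablation_importance <- function(channel_set, gold, valid, min_count = 2) {
  stopifnot(inherits(channel_set, "channel_set"),
            length(channel_set$channels) >= 2)
  d <- eval_domain(channel_set, gold, valid)
  metrics <- function(keep) {
    cnt <- rowSums(d$V[, keep, drop = FALSE])
    m <- cnt >= min_count
    tp <- sum(m & d$g); fp <- sum(m & !d$g)
    fn <- sum(!m & d$g); tn <- sum(!m & !d$g)
    c(acc = (tp + tn) / d$n,
      sens = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      spec = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
  }
  k <- ncol(d$V)
  full <- metrics(seq_len(k))
  rows <- lapply(seq_len(k), function(i) {
    wo <- metrics(setdiff(seq_len(k), i))
    data.frame(channel = colnames(d$V)[i],
               accuracy_full = unname(full["acc"]),
               accuracy_without = unname(wo["acc"]),
               delta_accuracy = unname(full["acc"] - wo["acc"]),
               delta_sensitivity = unname(full["sens"] - wo["sens"]),
               delta_specificity = unname(full["spec"] - wo["spec"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  floored <- pmax(out$delta_accuracy, 0)
  if (any(out$delta_accuracy < 0))
    message("ablation_importance: negative accuracy drop floored at 0 for ",
            paste(out$channel[out$delta_accuracy < 0], collapse = ", "))
  out$contribution <- if (sum(floored) > 0) floored / sum(floored) else 0
  # rank by contribution, ties by canonical order (row order is canonical)
  out$rank <- rank(-out$contribution, ties.method = "first")
  class(out) <- c("importance_table", "data.frame")
  out
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  p <- all_permutations(n - 1)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rest <- (seq_len(n))[-i]
    out[[i]] <- cbind(i, matrix(rest[p], nrow(p)))
  }
  unname(do.call(rbind, out))
}

#' Delta accuracy as channels are added in order
#'
#' For each ordering of the channels, the multimodal mask is rebuilt after
#' each addition (voxels with at least `min_count` abnormal channels among
#' those added so far; with fewer than `min_count` channels added the mask
#' is typically empty) and the gain in accuracy at each addition recorded.
#' The baseline is the empty model (all-normal prediction). Orders are
#' exhaustive for up to 7 channels, or sampled with a seed beyond that. The
#' per-position accuracy depends only on the set of channels added, so the
#' implementation tabulates accuracies over all channel subsets once and
#' reads each order off that table.
#'
#' @inheritParams ablation_importance
#' @param orders `"exhaustive"` or the number of sampled orders.
#' @param seed Seed used when sampling orders.
#' @return List with `aggregate` (mean delta accuracy per channel x
#'   position), `deltas` (orders x positions matrix), `orders` (channel index
#'   matrix), `baseline_accuracy`, `final_accuracy`.
#' @export
addition_order_analysis <- function(channel_set, gold, valid, min_count = 2,
                                    orders = "exhaustive", seed = 1) {
  d <- eval_domain(channel_set, gold, valid)
  k <- ncol(d$V)
  if (identical(orders, "exhaustive")) {
    if (k > 8) stop("exhaustive ordering impractical for > 8 channels; sample instead")
    ord <- all_permutations(k)
  } else {
    set.seed(seed)
    ord <- t(replicate(as.integer(orders), sample.int(k)))
  }
  accS <- subset_accuracy(d$V, d$g, min_count)
  acc0 <- accS[1]  # empty subset: all-normal prediction
  bit <- bitwShiftL(1, seq_len(k) - 1)
  deltas <- matrix(0, nrow(ord), k)
  for (o in seq_len(nrow(ord))) {
    masks <- cumsum(bit[ord[o, ]])  # cumulative subset bitmasks (disjoint bits)
    acc <- accS[masks + 1]
    deltas[o, ] <- diff(c(acc0, acc))
  }
  agg <- matrix(NA_real_, k, k,
                dimnames = list(channel = colnames(d$V),
                                position = paste0("pos", seq_len(k))))
  for (ch in seq_len(k)) for (pos in seq_len(k)) {
    sel <- ord[, pos] == ch
    if (any(sel)) agg[ch, pos] <- mean(deltas[sel, pos])
  }
  list(aggregate = agg, deltas = deltas, orders = ord,
       baseline_accuracy = unname(acc0),
       final_accuracy = unname(accS[2^k]))
}

#' Occult tumor rim analysis
#'
#' The clinically occult rim is histologically confirmed tumor missed by the
#' independent observers: `rim = gold \ consensus`. All importance analyses
#' are re-run with the evaluation domain restricted to `valid \ consensus`
#' and the rim as positives; per-channel abnormal fractions on the rim are
#' reported alongside. If the rim is empty the analyses are skipped and the
#' result flagged.
#'
#' @param gold Gold-standard `tumor_mask` (or mask).
#' @param consensus Observer-consensus `tumor_mask` (or mask).
#' @param channel_set A `channel_set`.
#' @param valid Mask of evaluable voxels.
#' @param min_count Multimodal threshold; default 2.
#' @return List with `rim` ([binary_mask()]), `empty` flag, `importance`
#'   (an `importance_table` or `NULL`), `channel_rim_fraction` (data frame),
#'   and `report` (multimodal performance on the restricted domain).
#' @export
occult_rim_analysis <- function(gold, consensus, channel_set, valid,
                                min_count = 2) {
  g <- as_mask_array(gold); cns <- as_mask_array(consensus)
  v <- as_mask_array(valid)
  rim <- g & !cns
  geom <- channel_set$geometry
  out <- list(rim = binary_mask(rim, geom, label = "occult_rim"),
              empty = !any(rim))
  if (out$empty) {
    message("occult_rim_analysis: rim is empty (consensus covers gold); analyses skipped")
    return(out)
  }
  domain <- v & !cns
  out$importance <- ablation_importance(channel_set, rim, domain, min_count)
  frac <- vapply(channel_set$channels, function(ch) mean(ch[rim]), 0)
  out$channel_rim_fraction <- data.frame(channel = names(frac),
                                         rim_abnormal_fraction = unname(frac),
                                         stringsAsFactors = FALSE)
  mm <- multimodal_combine(channel_set, min_count)
  out$report <- report(confusion(mm, rim, domain), geom)
  out
}

#' Per-region histology summaries
#'
#' Voxel-count-weighted mean and SD of each parameter volume over each
#' region (typically contralateral, tumor core, and occult rim), using
#' covered (non-missing) voxels only. Regions must be pairwise disjoint.
#'
#' @param values Named list of 3-D numeric arrays or `fraction_volume`s
#'   (`NaN`/`NA` marks missing voxels).
#' @param regions Named list of masks.
#' @return Tidy data frame: `region`, `parameter`, `n_voxels`, `mean`, `sd`.
#'   Regions with zero covered voxels for a parameter are missing rows
#'   (logged via message).
#' @export
region_histology_summary <- function(values, regions) {
  arrs <- lapply(values, function(v) {
    if (inherits(v, "fraction_volume")) { x <- v$values; x[!v$coverage] <- NA; x }
    else as.array(v)
  })
  masks <- lapply(regions, as_mask_array)
  nm <- names(masks)
  for (i in seq_along(masks)) for (j in seq_along(masks)) {
    if (i < j && any(masks[[i]] & masks[[j]]))
      stop("regions must be disjoint: ", nm[i], " overlaps ", nm[j])
  }
  rows <- list()
  for (rg in names(masks)) for (pm in names(arrs)) {
    x <- arrs[[pm]][masks[[rg]]]
    x <- x[is.finite(x)]
    if (length(x) == 0) {
      message("region_histology_summary: no covered voxels for ", pm,
              " in region ", rg, "; row omitted")
      next
    }
    rows[[length(rows) + 1]] <-
      data.frame(region = rg, parameter = pm, n_voxels = length(x),
                 mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else 0,
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
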