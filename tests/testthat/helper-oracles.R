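# Independent brute-force oracles and small fixture builders. Oracles are
# deliberately naive (explicit enumeration) and share no code with the
# package's implementation paths.

tiny_geometry <- function(dim = c(8, 8, 4), in_plane = 0.5, thickness = 1) {
  voxel_geometry(in_plane, thickness, dim)
}

const_volume <- function(value, modality, geom) {
  parameter_volume(array(value, geom$dim), modality, geom)
}

# reference_stats data frame straight from numbers
make_ref_stats <- function(modality, mean, sd, n = 100) {
  out <- data.frame(modality = modality, mean = mean, sd = sd,
                    n_voxels = n, units = "a.u.", stringsAsFactors = FALSE)
  class(out) <- c("reference_stats", "data.frame")
  out
}

# channel_set built directly from logical arrays (bypasses thresholding)
make_channel_set <- function(channels, geom, k = 1) {
  structure(list(channels = channels, k = k, reference = NULL,
                 geometry = geom),
            class = "channel_set")
}

random_channel_set <- function(geom, n_channels = 7, p = 0.3, seed = 1) {
  set.seed(seed)
  nm <- channel_table()$channel[seq_len(n_channels)]
  ch <- lapply(seq_len(n_channels), function(i)
    array(runif(prod(geom$dim)) < p, geom$dim))
  names(ch) <- nm
  make_channel_set(ch, geom)
}

# --- oracles ---------------------------------------------------------------

brute_confusion <- function(pred, gold, valid) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(valid)) {
    if (!valid[i]) next
    if (pred[i] && gold[i]) tp <- tp + 1L
    else if (pred[i] && !gold[i]) fp <- fp + 1L
    else if (!pred[i] && gold[i]) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

brute_jaccard <- function(a, b) {
  inter <- 0L; un <- 0L
  for (i in seq_along(a)) {
    if (a[i] || b[i]) un <- un + 1L
    if (a[i] && b[i]) inter <- inter + 1L
  }
  inter / un
}

brute_multimodal <- function(channels, min_count) {
  cnt <- Reduce(`+`, lapply(channels, as.numeric))
  array(cnt >= min_count, dim = dim(channels[[1]]))
}

brute_metrics <- function(mask, gold, valid) {
  cc <- brute_confusion(mask, gold, valid)
  c(acc = (cc$tp + cc$tn) / (cc$tp + cc$tn + cc$fp + cc$fn),
    sens = cc$tp / (cc$tp + cc$fn),
    spec = cc$tn / (cc$tn + cc$fp))
}

brute_ablation_deltas <- function(channels, gold, valid, min_count) {
  full <- brute_metrics(brute_multimodal(channels, min_count), gold, valid)
  sapply(seq_along(channels), function(i) {
    wo <- brute_metrics(brute_multimodal(channels[-i], min_count), gold, valid)
    full["acc"] - wo["acc"]
  })
}

# naive per-order addition loop: rebuild the mask after each addition
brute_addition_deltas <- function(channels, gold, valid, min_count, orders) {
  n_valid <- sum(valid)
  acc_of <- function(mask) {
    ok <- 0L
    for (i in seq_along(valid)) {
      if (!valid[i]) next
      if (mask[i] == gold[i]) ok <- ok + 1L
    }
    ok / n_valid
  }
  empty <- array(FALSE, dim = dim(gold))
  acc0 <- acc_of(empty)
  deltas <- matrix(0, nrow(orders), ncol(orders))
  for (o in seq_len(nrow(orders))) {
    prev <- acc0
    for (j in seq_len(ncol(orders))) {
      sub <- channels[orders[o, seq_len(j)]]
      acc <- acc_of(brute_multimodal(sub, min_count))
      deltas[o, j] <- acc - prev
      prev <- acc
    }
  }
  list(deltas = deltas, baseline = acc0)
}
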