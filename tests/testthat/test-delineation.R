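test_that("abnormality thresholds are strict inequalities at mean +/- k*sd", {
  geom <- tiny_geometry(c(2, 2, 1))
  st <- make_ref_stats("postgd", 10, 2)
  above <- function(x) abnormality_channel(const_volume(x, "postgd", geom), st, "above", 1)[1]
  below <- function(x) abnormality_channel(const_volume(x, "postgd", geom), st, "below", 1)[1]
  expect_false(above(12.0))   # boundary-equal is normal
  expect_true(above(12.01))
  expect_true(below(7.9))
  expect_false(below(8.0))
  # k = 2 boundary for the single-modality comparator
  s2 <- function(x) sd2_method(const_volume(x, "postgd", geom), st)$mask$values[1]
  expect_false(s2(14.0))
  expect_true(s2(14.1))
  # invalid voxels never trigger
  vals <- array(c(100, NaN, 100, 100), geom$dim)
  ch <- abnormality_channel(parameter_volume(vals, "postgd", geom), st, "above", 1)
  expect_false(ch[2, 1, 1])  # the NaN voxel stays normal
  expect_true(ch[1, 1, 1])
})

test_that("zero reference SD warns and flags every deviation", {
  geom <- tiny_geometry(c(2, 1, 1))
  st <- make_ref_stats("postgd", 10, 0)
  v <- parameter_volume(array(c(10, 10.0001), geom$dim), "postgd", geom)
  expect_warning(ch <- abnormality_channel(v, st, "above", 1), "degenerate")
  expect_identical(as.vector(ch), c(FALSE, TRUE))
})

test_that("channel set follows the parameter table directions, ADC split in two", {
  geom <- tiny_geometry(c(2, 2, 1))
  st <- do.call(rbind, lapply(modality_table()$modality, function(m)
    make_ref_stats(m, 10, 2)))
  class(st) <- c("reference_stats", "data.frame")
  mk <- function(vals) {
    vols <- lapply(modality_table()$modality, function(m)
      const_volume(10, m, geom))
    names(vols) <- modality_table()$modality
    for (m in names(vals)) vols[[m]]$values[1, 1, 1] <- vals[[m]]
    vols
  }
  # 2 SD above on postgd and 2 SD below on cbf, normal elsewhere
  cs <- build_channel_set(mk(list(postgd = 14.1, cbf = 5.9)), st, k = 1)
  expect_identical(names(cs$channels), channel_table()$channel)
  at <- vapply(cs$channels, function(ch) ch[1, 1, 1], NA)
  expect_identical(names(which(at)), c("postgd_high", "cbf_low"))
  # ADC far above: adc_high set, adc_low unset (mutual exclusion)
  cs2 <- build_channel_set(mk(list(adc = 30)), st, k = 1)
  expect_true(cs2$channels$adc_high[1, 1, 1])
  expect_false(cs2$channels$adc_low[1, 1, 1])
  expect_false(any(cs2$channels$adc_high & cs2$channels$adc_low))
  # reduced protocol without CBV
  vols <- mk(list()); vols$cbv <- NULL
  expect_error(build_channel_set(vols, st), "missing modality")
  cs3 <- build_channel_set(vols, st, allow_missing = TRUE)
  expect_length(cs3$channels, 6)
  expect_false("cbv_low" %in% names(cs3$channels))
})

test_that("multimodal combination counts channels against min_count", {
  geom <- tiny_geometry(c(4, 4, 1))
  ch <- list(a = array(FALSE, geom$dim), b = array(FALSE, geom$dim),
             c = array(FALSE, geom$dim))
  ch$a[1, 1, 1] <- TRUE; ch$b[1, 1, 1] <- TRUE   # two channels at (1,1)
  ch$c[2, 2, 1] <- TRUE                          # one channel at (2,2)
  cs <- make_channel_set(ch, geom)
  mm <- multimodal_combine(cs, 2)
  expect_true(mm$mask$values[1, 1, 1])
  expect_false(mm$mask$values[2, 2, 1])
  # min_count 1 equals the union of channels
  mm1 <- multimodal_combine(cs, 1)
  expect_identical(mm1$mask$values, Reduce(`|`, ch))
})

test_that("masks shrink as min_count or k grows (monotonicity)", {
  geom <- tiny_geometry(c(8, 8, 2))
  for (seed in 1:3) {
    cs <- random_channel_set(geom, 7, p = 0.35, seed = seed)
    prev <- NULL
    for (mc in 1:7) {
      m <- multimodal_combine(cs, mc)$mask$values
      if (!is.null(prev)) expect_true(all(prev | !m))  # m subset of prev
      prev <- m
    }
  }
  st <- make_ref_stats("postgd", 0, 1)
  set.seed(8)
  v <- parameter_volume(array(rnorm(prod(geom$dim)), geom$dim), "postgd", geom)
  prev <- NULL
  for (k in c(0.5, 1, 1.5, 2, 2.5)) {
    ch <- abnormality_channel(v, st, "above", k)
    if (!is.null(prev)) expect_true(all(prev | !ch))
    prev <- ch
  }
})

test_that("sd2 method is definitionally the k=2 above channel", {
  geom <- tiny_geometry(c(6, 6, 2))
  st <- make_ref_stats("postgd", 50, 5)
  set.seed(3)
  v <- parameter_volume(array(rnorm(prod(geom$dim), 50, 5), geom$dim),
                        "postgd", geom)
  expect_identical(sd2_method(v, st)$mask$values,
                   abnormality_channel(v, st, "above", k = 2))
})

test_that("refined method recovers a clean blob and rejects speckles", {
  geom <- tiny_geometry(c(24, 24, 4))
  vals <- array(10, geom$dim)
  blob <- array(FALSE, geom$dim); blob[8:14, 4:10, 2:3] <- TRUE
  vals[blob] <- 30
  st <- make_ref_stats("postgd", 10, 2)
  v <- parameter_volume(vals, "postgd", geom)
  r <- refined_method(v, st, k = 2, closing_radius = 0)
  expect_identical(r$mask$values, blob)           # noiseless blob, exact
  expect_true(length(r$log) >= 2)

  # three isolated supra-threshold speckles vanish (largest component wins)
  vals2 <- vals
  vals2[2, 20, 1] <- 40; vals2[20, 2, 4] <- 40; vals2[22, 22, 1] <- 40
  r2 <- refined_method(parameter_volume(vals2, "postgd", geom), st,
                       closing_radius = 0)
  expect_identical(r2$mask$values, blob)

  # hemisphere restriction picks the tumor-side component
  vals3 <- array(10, geom$dim)
  left <- array(FALSE, geom$dim); left[10:12, 2:4, 2] <- TRUE    # small, left
  right <- array(FALSE, geom$dim); right[4:16, 16:22, 2:3] <- TRUE  # big, right
  vals3[left | right] <- 30
  r3 <- refined_method(parameter_volume(vals3, "postgd", geom), st,
                       closing_radius = 0, midline = 12, tumor_side = "left")
  expect_identical(r3$mask$values, left)

  # enclosed holes are filled
  vals4 <- array(10, geom$dim)
  ring <- array(FALSE, geom$dim); ring[6:12, 6:12, 1:4] <- TRUE
  hole <- array(FALSE, geom$dim); hole[9, 9, 2:3] <- TRUE
  vals4[ring & !hole] <- 30
  r4 <- refined_method(parameter_volume(vals4, "postgd", geom), st,
                       closing_radius = 0)
  expect_identical(r4$mask$values, ring)

  # all-background volume: empty mask with a warning, not an error
  expect_warning(r5 <- refined_method(const_volume(10, "postgd", geom), st),
                 "empty")
  expect_false(any(r5$mask$values))
})

test_that("observer consensus excludes single-observer voxels", {
  geom <- tiny_geometry(c(2, 2, 1))
  vote <- function(...) {
    pattern <- list(...)
    lapply(pattern, function(p) {
      m <- array(FALSE, geom$dim); m[1, 1, 1] <- p
      binary_mask(m, geom)
    })
  }
  expect_false(observer_consensus(vote(TRUE, FALSE, FALSE, FALSE))$mask$values[1, 1, 1])
  expect_true(observer_consensus(vote(TRUE, TRUE, FALSE, FALSE))$mask$values[1, 1, 1])
  expect_false(observer_consensus(vote(FALSE, FALSE, FALSE, FALSE))$mask$values[1, 1, 1])
  expect_error(observer_consensus(vote(TRUE)), "at least 2")

  # permutation invariance and containment in the union
  set.seed(12)
  obs <- lapply(1:4, function(i)
    binary_mask(array(runif(prod(geom$dim) * 0 + 16) < 0.5, c(2, 2, 4)),
                tiny_geometry(c(2, 2, 4))))
  c1 <- observer_consensus(obs)$mask$values
  c2 <- observer_consensus(rev(obs))$mask$values
  expect_identical(c1, c2)
  expect_true(all(Reduce(`|`, lapply(obs, as_mask_array)) | !c1))
})

test_that("two independent 1-SD channels co-fire at about 0.1587^2 on pure noise", {
  geom <- voxel_geometry(0.5, 1, c(40, 40, 10))
  st <- rbind(make_ref_stats("postgd", 0, 1), make_ref_stats("adc", 0, 1))
  class(st) <- c("reference_stats", "data.frame")
  set.seed(21)
  n <- prod(geom$dim)
  a <- parameter_volume(array(rnorm(n), geom$dim), "postgd", geom)
  b <- parameter_volume(array(rnorm(n), geom$dim), "adc", geom)
  joint <- mean(abnormality_channel(a, st, "above", 1) &
                  abnormality_channel(b, st, "below", 1))
  p <- pnorm(-1)^2
  mc_sd <- sqrt(p * (1 - p) / n)
  expect_lt(abs(joint - p), 3 * mc_sd)
  expect_lt(joint, 0.05)  # the alpha-control rationale for requiring 2 channels
})
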