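test_that("confusion counts match explicit enumeration", {
  geom <- tiny_geometry(c(6, 1, 1))
  # voxels a..f; pred {a,b,c,d}, gold {b,c,e}, valid all six
  pred <- array(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE), geom$dim)
  gold <- array(c(FALSE, TRUE, TRUE, FALSE, TRUE, FALSE), geom$dim)
  valid <- array(TRUE, geom$dim)
  cc <- confusion(pred, gold, valid)
  expect_equal(cc$tp, 2); expect_equal(cc$fp, 2)
  expect_equal(cc$fn, 1); expect_equal(cc$tn, 1)
  expect_equal(cc$tp + cc$fp + cc$tn + cc$fn, cc$n_valid)

  ident <- confusion(gold, gold, valid)
  expect_equal(ident$fp, 0); expect_equal(ident$fn, 0)
  none <- confusion(array(FALSE, geom$dim), gold, valid)
  expect_equal(none$tp, 0); expect_equal(none$fp, 0)
  expect_error(confusion(pred, gold, array(FALSE, geom$dim)), "empty")

  # voxels outside valid contribute nowhere
  v2 <- valid; v2[5:6] <- FALSE
  pred2 <- pred; pred2[5:6] <- TRUE  # garbage outside valid
  cc2 <- confusion(pred2, gold, v2)
  expect_equal(cc2$n_valid, 4)
  expect_equal(cc2$tp, 2); expect_equal(cc2$fp, 2)
})

test_that("report reproduces the printed Youden worked examples and identities", {
  expect_equal(youden_index(0.82, 0.86), 0.68)
  expect_equal(youden_index(0.61, 0.98), 0.59)
  # via counts engineered to those rates
  cc <- structure(list(tp = 82, fn = 18, tn = 86, fp = 14, n_valid = 200),
                  class = "confusion")
  r <- report(cc)
  expect_equal(r$sensitivity, 0.82)
  expect_equal(r$specificity, 0.86)
  expect_equal(r$youden, 0.68)
  expect_equal(r$jaccard, 82 / (82 + 14 + 18))

  # Youden identity over a grid of counts
  for (tp in c(0, 3, 10)) for (fp in c(0, 2)) for (tn in c(1, 8)) for (fn in c(0, 4)) {
    if (tp + fn == 0 || tn + fp == 0) next
    cc <- structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                         n_valid = tp + fp + tn + fn), class = "confusion")
    r <- report(cc)
    expect_equal(r$youden, r$sensitivity + r$specificity - 1)
  }

  # perfect prediction
  cc <- structure(list(tp = 7, fp = 0, tn = 5, fn = 0, n_valid = 12),
                  class = "confusion")
  r <- report(cc)
  expect_equal(unname(unlist(r[c("sensitivity", "specificity", "accuracy",
                                 "jaccard", "youden")])), rep(1, 5))

  # zero denominators give NA, not silent zeros
  cc0 <- structure(list(tp = 0, fp = 0, tn = 5, fn = 0, n_valid = 5),
                   class = "confusion")
  expect_message(r0 <- report(cc0), "zero denominator")
  expect_true(is.na(r0$sensitivity))
})

test_that("Jaccard overlap: examples, symmetry, and size bound", {
  geom <- tiny_geometry(c(2, 2, 1))
  a <- array(c(TRUE, TRUE, TRUE, FALSE), geom$dim)   # (0,0),(0,1),(1,0) in 2x2
  b <- array(c(FALSE, TRUE, TRUE, TRUE), geom$dim)
  expect_equal(jaccard_pair(a, b), 0.5)  # 2 of 4
  expect_equal(jaccard_pair(a, a), 1)
  expect_equal(jaccard_pair(a, array(c(FALSE, FALSE, FALSE, TRUE), geom$dim)), 0)
  expect_error(jaccard_pair(array(FALSE, geom$dim), array(FALSE, geom$dim)),
               "undefined")
  set.seed(14)
  for (i in 1:5) {
    g <- tiny_geometry(c(8, 8, 2))
    x <- array(runif(128) < 0.4, g$dim); y <- array(runif(128) < 0.4, g$dim)
    if (!any(x | y)) next
    expect_equal(jaccard_pair(x, y), jaccard_pair(y, x))
    expect_equal(jaccard_pair(x, y), brute_jaccard(x, y))
    if (sum(x) > 0 && sum(y) > 0)
      expect_lte(jaccard_pair(x, y), min(sum(x), sum(y)) / max(sum(x), sum(y)))
  }
})

test_that("interobserver metrics: pairwise volume error and Jaccard summaries", {
  geom <- voxel_geometry(1, 1, c(12, 12, 2))  # 1 uL voxels
  m1 <- array(FALSE, geom$dim); m1[1:9, 1:10, 1] <- TRUE  # 90 uL
  m2 <- array(FALSE, geom$dim); m2[1:10, 1:11, 1] <- TRUE # 110 uL
  im <- interobserver_metrics(list(binary_mask(m1, geom), binary_mask(m2, geom)))
  expect_equal(im$volume_error_pct[1, 2], 20)  # |90-110| / 100 * 100

  same <- replicate(4, binary_mask(m1, geom), simplify = FALSE)
  im4 <- interobserver_metrics(same)
  expect_equal(im4$summary$n_pairs, 6)  # choose(4, 2)
  expect_true(all(im4$jaccard == 1))
  expect_true(all(im4$volume_error_pct == 0))

  empty <- binary_mask(array(FALSE, geom$dim), geom)
  expect_message(ime <- interobserver_metrics(list(binary_mask(m1, geom), empty)),
                 "empty observer")
  expect_true(is.na(ime$volume_error_pct[1, 2]))
})

test_that("ablation importance matches brute force and behaves monotonically", {
  for (seed in 1:4) {
    geom <- tiny_geometry(c(8, 8, 4))
    cs <- random_channel_set(geom, 5, p = 0.3, seed = seed)
    set.seed(seed + 100)
    gold <- array(runif(prod(geom$dim)) < 0.3, geom$dim)
    valid <- array(runif(prod(geom$dim)) < 0.9, geom$dim)
    imp <- ablation_importance(cs, gold, valid, min_count = 2)
    bf <- brute_ablation_deltas(cs$channels, gold, valid, 2)
    expect_equal(imp$delta_accuracy, unname(bf))
    # removing a channel can only shrink the mask
    expect_true(all(imp$delta_sensitivity >= -1e-12))
    expect_true(all(imp$delta_specificity <= 1e-12))
    expect_equal(sum(imp$contribution), if (any(imp$delta_accuracy > 0)) 1 else 0)
    expect_setequal(imp$rank, seq_len(5))
  }
})

test_that("redundant channels contribute nothing; essential channels carry sensitivity", {
  geom <- tiny_geometry(c(6, 6, 1))
  tumor <- array(FALSE, geom$dim); tumor[2:4, 2:4, 1] <- TRUE
  dup <- list(postgd_high = tumor, t1_high = tumor,
              t2_low = array(FALSE, geom$dim))
  cs <- make_channel_set(dup, geom)
  valid <- array(TRUE, geom$dim)
  imp <- ablation_importance(cs, tumor, valid, 2)
  # A and B duplicate each other... removing either kills the >= 2 count
  sens_wo <- function(drop) {
    keep <- setdiff(names(dup), drop)
    m <- brute_multimodal(dup[keep], 2)
    brute_metrics(m, tumor, valid)["sens"]
  }
  expect_equal(unname(sens_wo("postgd_high")), 0)
  # a channel identical to another *when three share the voxels* is redundant
  tri <- list(postgd_high = tumor, t1_high = tumor, t2_low = tumor)
  imp3 <- ablation_importance(make_channel_set(tri, geom), tumor, valid, 2)
  expect_true(all(imp3$delta_accuracy == 0))
  expect_true(all(imp3$contribution == 0))
})

test_that("addition-order deltas telescope and match the brute-force loop", {
  geom <- tiny_geometry(c(8, 8, 2))
  cs <- random_channel_set(geom, 4, p = 0.35, seed = 6)
  set.seed(61)
  gold <- array(runif(prod(geom$dim)) < 0.25, geom$dim)
  valid <- array(TRUE, geom$dim)
  res <- addition_order_analysis(cs, gold, valid, min_count = 2)
  expect_equal(nrow(res$orders), factorial(4))
  # telescoping conservation per order
  expect_equal(unname(rowSums(res$deltas)),
               rep(res$final_accuracy - res$baseline_accuracy, factorial(4)))
  # first addition with min_count 2 cannot change the (empty) mask
  expect_true(all(res$deltas[, 1] == 0))
  # independent naive loop reproduces every delta
  bf <- brute_addition_deltas(cs$channels, gold, valid, 2, res$orders)
  expect_equal(res$deltas, bf$deltas)
  expect_equal(res$baseline_accuracy, bf$baseline)
})

test_that("occult rim analysis isolates gold-minus-consensus and ranks rim channels", {
  geom <- tiny_geometry(c(10, 10, 2))
  gold <- array(FALSE, geom$dim); gold[3:8, 3:8, ] <- TRUE
  core <- array(FALSE, geom$dim); core[4:7, 4:7, ] <- TRUE  # consensus
  rim <- gold & !core
  valid <- array(TRUE, geom$dim)
  # rim abnormal only on adc_high and t2_low; other channels mark the core
  ch <- list(postgd_high = core, t1_high = core, t2_low = gold,
             cbv_low = array(FALSE, geom$dim), cbf_low = array(FALSE, geom$dim),
             adc_high = gold, adc_low = array(FALSE, geom$dim))
  cs <- make_channel_set(ch, geom)
  res <- occult_rim_analysis(gold, core, cs, valid, min_count = 2)
  expect_identical(res$rim$values, rim)
  expect_false(res$empty)
  top2 <- res$importance$channel[res$importance$rank <= 2]
  expect_setequal(top2, c("t2_low", "adc_high"))
  # containment edge cases
  full <- occult_rim_analysis(gold, gold, cs, valid)
  expect_true(full$empty)
  none <- occult_rim_analysis(gold, array(FALSE, geom$dim), cs, valid)
  expect_identical(none$rim$values, gold)
})

test_that("region summaries pool voxel-weighted means over disjoint regions", {
  geom <- tiny_geometry(c(4, 4, 1))
  vals <- array(2, geom$dim); vals[, 3:4, 1] <- 8
  r1 <- array(FALSE, geom$dim); r1[, 1:2, 1] <- TRUE   # constant 2, 8 voxels
  r2 <- array(FALSE, geom$dim); r2[, 3:4, 1] <- TRUE   # constant 8, 8 voxels
  out <- region_histology_summary(list(p = vals), list(a = r1, b = r2))
  expect_equal(out$mean[out$region == "a"], 2)
  expect_equal(out$sd[out$region == "a"], 0)
  # pooled mean over both regions reproduces the hand computation
  pooled <- sum(out$n_voxels * out$mean) / sum(out$n_voxels)
  expect_equal(pooled, (8 * 2 + 8 * 8) / 16)
  # overlap is rejected; empty coverage rows are dropped with a message
  expect_error(region_histology_summary(list(p = vals), list(a = r1, b = r1)),
               "disjoint")
  vals2 <- vals; vals2[r1] <- NaN
  expect_message(out2 <- region_histology_summary(list(p = vals2),
                                                  list(a = r1, b = r2)),
                 "no covered voxels")
  expect_identical(out2$region, "b")
})

test_that("multimodal metrics equal an independent voxel classifier on noisy phantoms", {
  spec <- phantom_spec(seed = 19)
  ph <- generate_phantom(spec, what = "mri")
  contra <- build_contralateral_mask(ph$masks$brain, spec$midline, "left",
                                     ph$masks$ventricle)
  st <- compute_reference_stats(ph$volumes, contra)
  cs <- build_channel_set(ph$volumes, st, k = 1)
  mm <- multimodal_combine(cs, 2)
  gold <- ph$masks$tumor$values
  valid <- ph$masks$brain$values
  r <- report(confusion(mm, gold, valid))
  # independent classifier: count per-voxel threshold crossings from raw data
  cnt <- array(0, spec$geometry$dim)
  ctab <- channel_table()
  for (i in seq_len(nrow(ctab))) {
    v <- ph$volumes[[ctab$modality[i]]]$values
    row <- st[st$modality == ctab$modality[i], ]
    cnt <- cnt + if (ctab$direction[i] == "above")
      (v > row$mean + row$sd) else (v < row$mean - row$sd)
  }
  bf <- brute_metrics(cnt >= 2, gold, valid)
  expect_equal(r$sensitivity, unname(bf["sens"]), tolerance = 1e-12)
  expect_equal(r$specificity, unname(bf["spec"]), tolerance = 1e-12)
})
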