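#!/usr/bin/env Rscript
# Score every delineation method against the histology gold standard on the
# evaluable (histology-covered brain) voxels: sensitivity, specificity,
# accuracy, Jaccard and Youden indices, and volumes; plus interobserver
# agreement among the four observers.

library(multidelin)

seed <- 17
spec <- phantom_spec(seed = seed)
ph <- generate_phantom(spec)
contra <- build_contralateral_mask(ph$masks$brain, spec$midline, "left",
                                   ph$masks$ventricle)
stats <- compute_reference_stats(ph$volumes, contra)
channels <- build_channel_set(ph$volumes, stats, k = 1)

gold <- gold_standard_map(stack_to_volume(ph$stacks$epcam),
                          stack_to_volume(ph$stacks$pimonidazole))
valid <- binary_mask(gold$valid$values & ph$masks$brain$values, ph$geometry,
                     "evaluable")

methods <- list(
  multimodal = multimodal_combine(channels, 2),
  sd2 = sd2_method(ph$volumes$postgd, stats),
  refined = refined_method(ph$volumes$postgd, stats, midline = spec$midline,
                           tumor_side = "left"),
  consensus = observer_consensus(ph$observers))

rows <- lapply(names(methods), function(nm) {
  r <- report(confusion(methods[[nm]], gold, valid), ph$geometry)
  data.frame(method = nm, sensitivity = r$sensitivity,
             specificity = r$specificity, accuracy = r$accuracy,
             jaccard = r$jaccard, youden = r$youden,
             volume_ul = r$pred_volume_ul, gold_volume_ul = r$gold_volume_ul)
})
tab <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.csv(tab, "results/evaluation.csv", row.names = FALSE)

cat(sprintf("Evaluable voxels: %d (%.0f uL)\n", sum(valid$values),
            volume_from_mask(valid)))
print(tab, row.names = FALSE, digits = 3)

io <- interobserver_metrics(ph$observers)
write.csv(io$summary, "results/interobserver.csv", row.names = FALSE)
cat(sprintf("\nInterobserver agreement over %d pairs: Jaccard %.2f +/- %.2f, volume error %.0f%% +/- %.0f%%\n",
            io$summary$n_pairs, io$summary$jaccard_mean, io$summary$jaccard_sd,
            io$summary$volume_error_mean, io$summary$volume_error_sd))
cat("\nExpected pattern: observers and single-modality methods under-segment\n")
cat("(high specificity, low sensitivity); the multimodal map trades a little\n")
cat("specificity for a large sensitivity gain and the best Youden index.\n")
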