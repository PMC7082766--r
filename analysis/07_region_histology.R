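#!/usr/bin/env Rscript
# Characterize the occult rim histologically: stain fractions (hypoxia,
# cellularity) per region (contralateral / observer-identified core / rim
# beyond the core), and vessel morphometry from the per-region collagen-IV
# rasters (area fraction, central diameter, cross-sectional area, density,
# in-plane length).

library(multidelin)

seed <- 17
spec <- phantom_spec(seed = seed)
ph <- generate_phantom(spec)
gold <- gold_standard_map(stack_to_volume(ph$stacks$epcam),
                          stack_to_volume(ph$stacks$pimonidazole))
cons <- observer_consensus(ph$observers)

core <- cons$mask$values & gold$mask$values
rim <- gold$mask$values & !cons$mask$values
contra <- ph$masks$contra_roi$values

stains <- list(pimonidazole = stack_to_volume(ph$stacks$pimonidazole),
               cresyl_violet = stack_to_volume(ph$stacks$cresyl_violet))
reg <- region_histology_summary(
  stains, list(contralateral = contra, core = core, rim = rim))
dir.create("results", showWarnings = FALSE)
write.csv(reg, "results/region_stain_summary.csv", row.names = FALSE)
cat("Stain fractions by region (voxel-weighted mean %):\n")
print(reg, row.names = FALSE, digits = 3)

rows <- lapply(names(ph$vessels), function(rg) {
  v <- ph$vessels[[rg]]
  filt <- preprocess_vessel_mask(v$mask)
  comp <- analyze_components(filt, v$pixel_size_um)
  maps <- vessel_parameter_maps(comp, filt, v$pixel_size_um, window_px = 256)
  data.frame(region = rg,
             n_vessels = nrow(comp),
             area_fraction = mean(maps$area_fraction, na.rm = TRUE),
             central_diameter_um = mean(comp$central_diameter_um),
             cross_sectional_area_um2 = mean(comp$cross_sectional_area_um2),
             density_per_mm2 = mean(maps$density, na.rm = TRUE),
             in_plane_length_um = mean(comp$in_plane_length_um))
})
vt <- do.call(rbind, rows)
write.csv(vt, "results/region_vessel_summary.csv", row.names = FALSE)
cat("\nVessel morphometry by region (means over components/windows):\n")
print(vt, row.names = FALSE, digits = 3)
cat("\nExpected pattern: the rim is hypoxic and hypercellular relative to\n")
cat("normal brain but less extreme than the core; rim vessels are dilated\n")
cat("and sparser than contralateral vessels.\n")
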