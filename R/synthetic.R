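# Phantom generator: emulates the statistical structure of the study data so
# the whole pipeline runs end-to-end against known ground truth.

sub_seed <- function(master, k) {
  as.integer((as.numeric(master) * 1009 + 97 * k) %% 2147483629)
}

ellipsoid_mask <- function(dim, center, radii) {
  r <- array(rep(seq_len(dim[1]), times = dim[2] * dim[3]), dim = dim)
  c_ <- array(rep(rep(seq_len(dim[2]), each = dim[1]), times = dim[3]), dim = dim)
  s <- array(rep(seq_len(dim[3]), each = dim[1] * dim[2]), dim = dim)
  ((r - center[1]) / radii[1])^2 + ((c_ - center[2]) / radii[2])^2 +
    ((s - center[3]) / radii[3])^2 <= 1
}

#' Phantom specification
#'
#' Bundles every parameter of the synthetic study. Defaults mirror the study
#' conditions: a 64 x 64 acquisition matrix over a 32 x 32 mm field of view
#' with 1 mm slices; per-modality contralateral means/SDs in physical units;
#' an ellipsoidal tumor core with directional effect sizes (SD units, signed
#' along each modality's abnormal direction) and a surrounding invasive rim
#' shell with attenuated effects; under-drawing observers; five 200-um
#' histology sections per slice; and region-specific vessel models.
#'
#' Normal-tissue noise has, per modality, a shared heterogeneity component:
#' `noise = lambda * Z + sqrt(1 - lambda^2) * eps`, with one latent `Z` per
#' voxel and loadings oriented along each modality's abnormality direction
#' (coherent tissue-composition variation: a voxel that looks slightly
#' tumor-like on one parameter tends to look so on the others).
#' `heterogeneity` is the shared loading magnitude; 0 makes all modalities
#' independent, which is the configuration used for false-positive
#' calibration checks. Marginal per-modality statistics are unaffected.
#'
#' @param geometry [voxel_geometry()]; default 64 x 64 x 10 at 0.5 x 0.5 x 1 mm.
#' @param normal Data frame with `modality`, `mean`, `sd` (physical units).
#' @param core_center,core_radii Ellipsoid center and radii (voxels).
#' @param core_effects Named numeric: signed shift per modality in SD units.
#' @param rim_thickness Rim shell thickness in voxels (added to all ellipsoid
#'   radii).
#' @param rim_effects Named numeric: attenuated shifts for the rim.
#' @param heterogeneity Shared-noise loading in `[0, 1)`; default 0.9.
#' @param noise_scale Multiplier on all noise; 0 gives a noiseless phantom.
#' @param midline Midline column index; `tumor_side` is `"left"`.
#' @param n_observers,observer_erosion,observer_jitter Observer model:
#'   per-observer 3-D erosion radius of the true extent (observers
#'   under-draw, missing the invasive rim and faint polar slices) and the
#'   probability of flipping a boundary voxel.
#' @param sections_per_slice,section_spacing_um Histology sampling; defaults
#'   5 and 200.
#' @param hist_pixels_per_voxel In-plane histology pixels per MRI voxel.
#' @param stain_levels Named list per stain of `c(core, rim, normal)`
#'   positive-pixel probabilities.
#' @param missing_discs,missing_disc_radius_px Missing-tissue model: number
#'   of missing discs per section and their radius.
#' @param coverage_dilation_px In-plane dilation (voxels) of the true tumor
#'   extent defining the histology-processed neighbourhood.
#' @param contra_roi Contralateral histology ROI as `list(rows, cols, slices)`
#'   index ranges; default ~190 uL, matching reported contralateral ROI size.
#' @param vessel_models Named list (contralateral/core/rim) of vessel-raster
#'   parameters passed to [generate_vessel_raster()].
#' @param seed Master seed; every sub-generator derives from it.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(
    geometry = voxel_geometry(0.5, 1, c(64, 64, 10)),
    normal = data.frame(
      modality = c("postgd", "t1", "t2", "cbv", "cbf", "adc"),
      mean = c(100, 1.8, 0.050, 3.0, 120, 0.75),
      sd   = c(10, 0.10, 0.004, 0.5, 15, 0.05)),
    core_center = c(32, 18, 5.5),
    core_radii = c(6, 6, 2.5),
    core_effects = c(postgd = 3, t1 = 2.5, t2 = -2.5, cbv = -2.5,
                     cbf = -3, adc = 2.5),
    rim_thickness = 2,
    rim_effects = core_effects / 2,
    heterogeneity = 0.9,
    noise_scale = 1,
    midline = 32,
    n_observers = 4,
    observer_erosion = c(1, 1, 1, 0),
    observer_jitter = 0.05,
    sections_per_slice = 5,
    section_spacing_um = 200,
    hist_pixels_per_voxel = 4,
    stain_levels = list(
      epcam = c(core = 0.30, rim = 0.05, normal = 0),
      pimonidazole = c(core = 0.25, rim = 0.15, normal = 0),
      cresyl_violet = c(core = 0.60, rim = 0.40, normal = 0.25)),
    missing_discs = 2,
    missing_disc_radius_px = 6,
    coverage_dilation_px = 2,
    contra_roi = list(rows = 25:40, cols = 42:53, slices = 4:7),
    vessel_models = list(
      contralateral = list(n_tubes = 40, width_range = c(4, 8),
                           length_range = c(30, 80)),
      core = list(n_tubes = 8, width_range = c(10, 20),
                  length_range = c(40, 120)),
      rim = list(n_tubes = 15, width_range = c(8, 16),
                 length_range = c(40, 120))),
    seed = 1) {
  stopifnot(all(core_radii > 0), rim_thickness >= 0,
            heterogeneity >= 0, heterogeneity < 1,
            observer_jitter >= 0, observer_jitter <= 1,
            length(observer_erosion) == n_observers)
  spec <- as.list(environment())
  class(spec) <- "phantom_spec"
  spec
}

# region label array: 0 normal, 1 core, 2 rim
phantom_regions <- function(spec) {
  dm <- spec$geometry$dim
  core <- ellipsoid_mask(dm, spec$core_center, spec$core_radii)
  outer <- ellipsoid_mask(dm, spec$core_center,
                          spec$core_radii + spec$rim_thickness)
  rim <- outer & !core
  list(core = core, rim = rim, tumor = outer)
}

phantom_brain <- function(spec) {
  dm <- spec$geometry$dim
  brain <- ellipsoid_mask(dm, c(dm[1] / 2 + 0.5, dm[2] / 2 + 0.5, dm[3] / 2 + 0.5),
                          c(dm[1] * 0.45, dm[2] * 0.42, dm[3] * 0.62))
  vent <- array(FALSE, dm)
  vr <- intersect(26:38, seq_len(dm[1]))
  vs <- intersect(4:7, seq_len(dm[3]))
  vleft <- intersect(28:30, seq_len(dm[2]))
  vright <- intersect(35:37, seq_len(dm[2]))
  vent[vr, c(vleft, vright), vs] <- TRUE
  vent <- vent & brain
  list(brain = brain, ventricle = vent)
}

#' Generate a complete synthetic study
#'
#' Draws the six parameter volumes (Gaussian contralateral statistics,
#' directional core shifts, attenuated rim shifts), the brain, ventricle and
#' ground-truth masks, under-drawing observer masks, histology stacks for
#' EpCAM, pimonidazole and cresyl violet with limited coverage and missing
#' tissue, and per-region vessel rasters. Fully deterministic under the
#' spec's master seed. The tumor must not intrude on the contralateral
#' hemisphere.
#'
#' @param spec A [phantom_spec()].
#' @param what Character subset of `c("mri", "observers", "histology",
#'   "vessels")` to generate (ground-truth masks always included).
#' @return A `phantom` list: `volumes`, `masks` (brain, ventricle, core, rim,
#'   tumor, coverage), `observers`, `stacks`, `vessels`, `manifest`.
#' @export
generate_phantom <- function(spec,
                             what = c("mri", "observers", "histology", "vessels")) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$geometry
  dm <- g$dim
  reg <- phantom_regions(spec)
  anat <- phantom_brain(spec)
  reg$core <- reg$core & anat$brain
  reg$rim <- reg$rim & anat$brain & !reg$core
  reg$tumor <- reg$core | reg$rim
  cols_arr <- array(rep(seq_len(dm[2]), each = dm[1]), dim = dm)
  if (any(reg$tumor & cols_arr > spec$midline))
    stop("phantom spec error: tumor overlaps the contralateral hemisphere")
  masks <- list(
    brain = binary_mask(anat$brain, g, "brain"),
    ventricle = binary_mask(anat$ventricle, g, "ventricle"),
    core = binary_mask(reg$core, g, "true_core"),
    rim = binary_mask(reg$rim, g, "true_rim"),
    tumor = binary_mask(reg$tumor, g, "true_tumor"))
  out <- list(masks = masks, geometry = g, spec = spec)

  if ("mri" %in% what) {
    set.seed(sub_seed(spec$seed, 1))
    n <- prod(dm)
    Z <- array(stats::rnorm(n), dm)
    lam <- c(postgd = -1, t1 = -1, t2 = 1, cbv = 1, cbf = 1, adc = 1) *
      spec$heterogeneity
    vols <- list()
    for (i in seq_len(nrow(spec$normal))) {
      m <- spec$normal$modality[i]
      mu <- spec$normal$mean[i]; sdv <- spec$normal$sd[i]
      eps <- array(stats::rnorm(n), dm)
      noise <- lam[[m]] * Z + sqrt(1 - lam[[m]]^2) * eps
      shift <- array(0, dm)
      if (!is.null(spec$core_effects[[m]])) {
        shift[reg$core] <- spec$core_effects[[m]]
        shift[reg$rim] <- spec$rim_effects[[m]]
      }
      vals <- mu + sdv * (spec$noise_scale * noise + shift)
      vols[[m]] <- parameter_volume(vals, m, g)
    }
    out$volumes <- vols
  }

  if ("observers" %in% what) {
    obs <- list()
    for (i in seq_len(spec$n_observers)) {
      set.seed(sub_seed(spec$seed, 100 + i))
      base <- reg$tumor
      r <- spec$observer_erosion[i]
      if (r > 0) base <- binary_erode(base, r)
      if (spec$observer_jitter > 0) {
        inner <- base & !binary_erode(base, 1)
        outer <- binary_dilate(base, 1) & !base & anat$brain
        drop <- inner & array(stats::runif(prod(dm)) < spec$observer_jitter, dm)
        add <- outer & array(stats::runif(prod(dm)) < spec$observer_jitter, dm)
        base <- (base & !drop) | add
      }
      obs[[i]] <- binary_mask(base, g, sprintf("observer_%d", i))
    }
    out$observers <- obs
  }

  region_label <- array(0L, dm)
  region_label[reg$rim] <- 2L
  region_label[reg$core] <- 1L
  coverage <- (binary_dilate(reg$tumor, spec$coverage_dilation_px,
                             in_plane = TRUE) & anat$brain)
  cr <- spec$contra_roi
  contra_box <- array(FALSE, dm)
  contra_box[cr$rows, cr$cols, cr$slices] <- TRUE
  coverage <- coverage | (contra_box & anat$brain)
  out$masks$coverage <- binary_mask(coverage, g, "histology_coverage")
  out$masks$contra_roi <- binary_mask(contra_box & anat$brain, g, "contra_roi")

  if ("histology" %in% what) {
    out$stacks <- generate_histology_stacks(spec, region_label, coverage)
  }

  if ("vessels" %in% what) {
    vess <- list()
    for (rg in names(spec$vessel_models)) {
      vm <- spec$vessel_models[[rg]]
      vess[[rg]] <- generate_vessel_raster(
        dim_px = c(512, 512), n_tubes = vm$n_tubes,
        width_range = vm$width_range, length_range = vm$length_range,
        pixel_size_um = 2,
        seed = sub_seed(spec$seed, 500 + match(rg, names(spec$vessel_models))))
    }
    out$vessels <- vess
  }

  out$manifest <- list(seed = spec$seed, geometry = unclass(g),
                       core_center = spec$core_center,
                       core_radii = spec$core_radii,
                       core_effects = as.list(spec$core_effects),
                       rim_effects = as.list(spec$rim_effects),
                       rim_thickness = spec$rim_thickness,
                       heterogeneity = spec$heterogeneity,
                       noise_scale = spec$noise_scale,
                       n_true_tumor_voxels = sum(reg$tumor),
                       observer_erosion = spec$observer_erosion,
                       observer_jitter = spec$observer_jitter)
  class(out) <- "phantom"
  out
}

generate_histology_stacks <- function(spec, region_label, coverage) {
  g <- spec$geometry
  dm <- g$dim
  f <- spec$hist_pixels_per_voxel
  px_um <- g$in_plane * 1000 / f
  thick_um <- g$thickness * 1000
  upscale <- function(m) {
    m[rep(seq_len(nrow(m)), each = f), rep(seq_len(ncol(m)), each = f)]
  }
  covered_slices <- which(apply(coverage, 3, any))
  stacks <- list()
  for (stain in names(spec$stain_levels)) {
    lev <- spec$stain_levels[[stain]]
    sections <- list()
    si <- 0
    for (sl in covered_slices) {
      lab_px <- upscale(region_label[, , sl])
      tis_base <- upscale(coverage[, , sl])
      p_px <- matrix(lev[["normal"]], nrow(lab_px), ncol(lab_px))
      p_px[lab_px == 1] <- lev[["core"]]
      p_px[lab_px == 2] <- lev[["rim"]]
      for (j in seq_len(spec$sections_per_slice)) {
        si <- si + 1
        set.seed(sub_seed(spec$seed,
                          1000 * match(stain, names(spec$stain_levels)) +
                            10 * sl + j))
        pos <- (sl - 1) * thick_um +
          (j - 0.5) * spec$section_spacing_um
        stainpx <- matrix(stats::runif(length(p_px)) < p_px,
                          nrow(p_px))
        tis <- tis_base
        if (spec$missing_discs > 0) {
          for (dsc in seq_len(spec$missing_discs)) {
            ctr <- c(sample.int(nrow(tis), 1), sample.int(ncol(tis), 1))
            rr <- spec$missing_disc_radius_px
            r1 <- max(1, ctr[1] - rr):min(nrow(tis), ctr[1] + rr)
            c1 <- max(1, ctr[2] - rr):min(ncol(tis), ctr[2] + rr)
            tis[r1, c1] <- FALSE
          }
        }
        sections[[si]] <- stain_section(stainpx & tis, tis, stain,
                                        pixel_size_um = px_um,
                                        position_um = pos)
      }
    }
    stacks[[stain]] <- histology_stack(sections, g,
                                       spec$section_spacing_um)
  }
  stacks
}

#' Generate a synthetic vessel raster with known ground truth
#'
#' Places non-overlapping axis-aligned rectangular tubes (half rotated 90
#' degrees) of known width and length, plus sub-threshold speckle noise
#' (components < 5 px), and returns the raster together with a ground-truth
#' component table. Placement retries are bounded; an overfull spec errors.
#'
#' @param dim_px Raster dimensions `(rows, cols)`.
#' @param n_tubes Number of tubes.
#' @param width_range,length_range Inclusive integer ranges in pixels.
#' @param pixel_size_um Pixel edge in micrometres.
#' @param n_speckles Number of 1-4 px noise components; default 30.
#' @param seed Seed.
#' @param max_retries Placement retries per tube before failing.
#' @return List with `mask` (logical matrix), `truth` (data frame: tube,
#'   width_px, length_px, pixel_count, orientation), `pixel_size_um`.
#' @export
generate_vessel_raster <- function(dim_px = c(512, 512), n_tubes = 20,
                                   width_range = c(4, 12),
                                   length_range = c(30, 120),
                                   pixel_size_um = 2, n_speckles = 30,
                                   seed = 1, max_retries = 200) {
  set.seed(seed)
  mask <- matrix(FALSE, dim_px[1], dim_px[2])
  occupied <- matrix(FALSE, dim_px[1], dim_px[2])  # tubes + 1px moat
  truth <- list()
  for (tb in seq_len(n_tubes)) {
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      w <- sample(width_range[1]:width_range[2], 1)
      L <- sample(length_range[1]:length_range[2], 1)
      horiz <- stats::runif(1) < 0.5
      h <- if (horiz) w else L
      wd <- if (horiz) L else w
      if (h + 2 >= dim_px[1] || wd + 2 >= dim_px[2]) next
      r0 <- sample.int(dim_px[1] - h - 2, 1) + 1
      c0 <- sample.int(dim_px[2] - wd - 2, 1) + 1
      rows <- r0:(r0 + h - 1); cols <- c0:(c0 + wd - 1)
      moat_r <- max(1, r0 - 2):min(dim_px[1], r0 + h + 1)
      moat_c <- max(1, c0 - 2):min(dim_px[2], c0 + wd + 1)
      if (any(occupied[moat_r, moat_c])) next
      mask[rows, cols] <- TRUE
      occupied[moat_r, moat_c] <- TRUE
      truth[[tb]] <- data.frame(tube = tb, width_px = w, length_px = L,
                                pixel_count = w * L,
                                orientation = if (horiz) "horizontal" else "vertical")
      placed <- TRUE
      break
    }
    if (!placed) stop("could not place tube ", tb, " after ", max_retries,
                      " retries; reduce density")
  }
  for (sp in seq_len(n_speckles)) {
    for (try in seq_len(max_retries)) {
      npx <- sample(1:4, 1)
      r0 <- sample.int(dim_px[1] - 3, 1) + 1
      c0 <- sample.int(dim_px[2] - 3, 1) + 1
      moat_r <- max(1, r0 - 2):min(dim_px[1], r0 + 3)
      moat_c <- max(1, c0 - 2):min(dim_px[2], c0 + 3)
      if (any(occupied[moat_r, moat_c])) next
      px <- list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))[seq_len(npx)]
      for (p in px) mask[r0 + p[1], c0 + p[2]] <- TRUE
      occupied[moat_r, moat_c] <- TRUE
      break
    }
  }
  list(mask = mask, truth = do.call(rbind, truth), pixel_size_um = pixel_size_um)
}

#' Write a phantom to disk
#'
#' Emits NIfTI volumes and masks, PNG vessel rasters, and a JSON manifest,
#' under `dir`.
#'
#' @param phantom A `phantom` from [generate_phantom()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in names(phantom$volumes))
    write_volume(phantom$volumes[[m]], file.path(dir, paste0(m, ".nii.gz")))
  for (m in names(phantom$masks))
    write_volume(phantom$masks[[m]], file.path(dir, paste0("mask_", m, ".nii.gz")))
  for (i in seq_along(phantom$observers))
    write_volume(phantom$observers[[i]],
                 file.path(dir, sprintf("observer_%d.nii.gz", i)))
  for (rg in names(phantom$vessels))
    write_raster(phantom$vessels[[rg]]$mask,
                 file.path(dir, sprintf("vessels_%s.png", rg)))
  jsonlite::write_json(phantom$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
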