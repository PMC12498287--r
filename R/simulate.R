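#' Specify one planted covariance effect
#'
#' An effect plants group-specific seed-to-voxel covariance: inside a
#' box-shaped blob of voxels, subject GMV receives
#' `slope_group * z(seed volume)`. The blob is deliberately block-shaped
#' (not smoothed) so the planted slopes are exactly recoverable by the GLM.
#'
#' @param subfield Seed subfield name (or `"whole_thalamus"`).
#' @param hemisphere Seed hemisphere: `"ipsi"`, `"contra"`, or `"both"`.
#' @param center 1-based voxel index (i, j, k) of the blob centre.
#' @param halfwidth Box half-width in voxels (0 = single voxel; default 2 =
#'   5x5x5 = 125 voxels, about 0.4 mL at 1.5 mm — the order of magnitude of
#'   a small cortical covariance cluster, and comfortably larger than the
#'   suprathreshold islands 6 mm FWHM noise produces by chance).
#' @param slope_cs,slope_nc Covariance slope (GMV units per SD of seed
#'   volume) for the stroke (CS) and control (NC) groups.
#' @return A list of class `scn_effect`.
#' @export
scn_effect <- function(subfield = "VPL", hemisphere = "ipsi",
                       center = c(3, 7, 7), halfwidth = 2,
                       slope_cs = 2, slope_nc = 1) {
  structure(
    list(
      subfield = subfield, hemisphere = hemisphere,
      center = as.integer(center), halfwidth = as.integer(halfwidth),
      slope_cs = slope_cs, slope_nc = slope_nc
    ),
    class = "scn_effect"
  )
}

#' Simulation design for a synthetic stroke cohort
#'
#' Encodes the data-generating model the SCN GLM assumes: per-voxel GMV is a
#' baseline plus group-specific seed-volume slopes inside effect blobs, plus
#' additive confound effects (age, gender, scanner, TIV), plus spatially
#' smooth Gaussian noise; stroke patients additionally receive a focal
#' right-hemisphere (ipsilesional) lesion that zeroes GMV. Defaults mirror
#' the study conditions: 45 CS vs 93 NC from 3 scanners, 1.5 mm grid,
#' 6 mm FWHM smoothing, one VPL-seeded effect with slopes (2, 1) and unit
#' noise SD — i.e. contrast signal-to-noise (slope_cs - slope_nc) / noise_sd
#' of 1 — and 10% ipsilesional subfield atrophy in patients.
#'
#' @param n_cs,n_nc Group sizes (>= 3 each).
#' @param grid_shape Voxel grid dimensions (default 16^3).
#' @param spacing Voxel size in mm (default 1.5).
#' @param smoothing_fwhm Noise smoothing kernel FWHM in mm (default 6).
#' @param noise_sd Marginal SD of the smoothed noise field in GMV units
#'   (default 1; 0 gives a noise-free cohort for exact-recovery checks).
#' @param baseline Mean GMV level (default 10, keeps GMV positive).
#' @param effects List of [scn_effect()] specs; blobs must not overlap.
#' @param confound_effects Named list of GMV coefficients: `age` (per year),
#'   `gender` (female offset), `scanner` (numeric offset per scanner level),
#'   `tiv` (per mm^3).
#' @param lesion_center,lesion_halfwidth,lesion_jitter Lesion blob base
#'   centre (1-based voxels, right hemisphere), box half-width, and maximum
#'   per-patient uniform integer jitter applied to the centre.
#' @param atrophy Fractional ipsilesional subfield volume reduction in CS
#'   patients (default 0.1).
#' @param volume_cv Coefficient of variation of subfield volumes (default 0.1).
#' @param volume_cor Inter-subfield correlation of volumes within subject,
#'   induced by a shared latent factor (default 0.5).
#' @param clinical_model Tibble describing score generation; see
#'   [default_clinical_model()].
#' @param n_scanners Number of scanner levels (default 3).
#' @param seed Default RNG seed for [simulate_cohort()].
#' @return A list of class `simulation_design`.
#' @export
simulation_design <- function(n_cs = 45, n_nc = 93,
                              grid_shape = c(16, 16, 16), spacing = 1.5,
                              smoothing_fwhm = 6, noise_sd = 1, baseline = 10,
                              effects = list(scn_effect()),
                              confound_effects = list(
                                age = -0.02, gender = 0.3,
                                scanner = c(0, 0.4, -0.2), tiv = 2e-6
                              ),
                              lesion_center = c(12, 8, 8),
                              lesion_halfwidth = 1, lesion_jitter = 1,
                              atrophy = 0.1,
                              volume_cv = 0.1, volume_cor = 0.5,
                              clinical_model = default_clinical_model(),
                              n_scanners = 3, seed = 1L) {
  if (n_cs < 3 || n_nc < 3) abort("Need n_cs, n_nc >= 3.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  grid <- image_grid(grid_shape, spacing = spacing)
  for (e in effects) {
    lo <- e$center - e$halfwidth
    hi <- e$center + e$halfwidth
    if (any(lo < 1L) || any(hi > grid$shape)) {
      abort("Effect blob extends outside the grid.")
    }
  }
  if (length(confound_effects$scanner) < n_scanners) {
    abort("`confound_effects$scanner` must give one offset per scanner level.")
  }
  structure(
    list(
      n_cs = n_cs, n_nc = n_nc, grid = grid, spacing = spacing,
      smoothing_fwhm = smoothing_fwhm, noise_sd = noise_sd,
      baseline = baseline, effects = effects,
      confound_effects = confound_effects,
      lesion_center = as.integer(lesion_center),
      lesion_halfwidth = as.integer(lesion_halfwidth),
      lesion_jitter = as.integer(lesion_jitter),
      atrophy = atrophy, volume_cv = volume_cv, volume_cor = volume_cor,
      clinical_model = clinical_model, n_scanners = n_scanners,
      seed = as.integer(seed)
    ),
    class = "simulation_design"
  )
}

#' Default clinical score model
#'
#' One row per clinical metric with group means/SDs on the instrument's own
#' scale (motor FMA bounded at 100; 1-back accuracies in \[0, 1\]; reaction
#' times in ms, positive) and a `links` list-column of coefficients tying
#' the score to z-scored subfield volumes (named `"hemisphere:subfield"`).
#' Default links are deliberately weak — the emulated cohort shows no
#' FDR-surviving brain-behaviour association, only uncorrected trends.
#'
#' @param link_strength Coefficient applied to the default volume links
#'   (0 severs all brain-behaviour coupling, giving null scores).
#' @return Tibble with columns `metric`, `mean_cs`, `mean_nc`, `sd`,
#'   `lower`, `upper`, `links`.
#' @export
default_clinical_model <- function(link_strength = 1.5) {
  lk <- function(...) {
    v <- c(...)
    if (!length(v)) return(list(numeric(0)))
    list(v * link_strength)
  }
  tibble(
    metric  = c("FMA", "RAVLT_SR", "RAVLT_LR", "N_ACC", "N_RT", "S_ACC", "S_RT"),
    mean_cs = c(92, 42.8, 11, 0.90, 860, 0.90, 880),
    mean_nc = c(100, 49.5, 12, 0.92, 790, 0.92, 800),
    sd      = c(8, 9, 2.5, 0.05, 170, 0.05, 180),
    lower   = c(0, 0, 0, 0, 100, 0, 100),
    upper   = c(100, 75, 15, 1, Inf, 1, Inf),
    links   = c(
      lk("ipsi:VLa" = 1), lk("ipsi:MDm" = 1), lk("ipsi:MDm" = 0.5),
      lk(), lk(), lk("ipsi:L_Sg" = 0.02 / 1.5), lk()
    )
  )
}

# 1-based voxel linear indices of a box blob
blob_indices <- function(grid, center, halfwidth) {
  rng <- function(d) {
    seq(max(1L, center[d] - halfwidth), min(grid$shape[d], center[d] + halfwidth))
  }
  g <- expand.grid(i = rng(1), j = rng(2), k = rng(3))
  ijk_to_index(grid, cbind(g$i - 1L, g$j - 1L, g$k - 1L))
}

# FFT Gaussian smoothing of a 3D array, periodic boundary; kernel normalised
# so a white-noise input keeps unit marginal variance.
smooth_field <- function(x, sigma_vox) {
  if (sigma_vox <= 0) return(x)
  dims <- dim(x)
  k1 <- lapply(dims, function(n) {
    d <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    exp(-d^2 / (2 * sigma_vox^2))
  })
  k <- outer(outer(k1[[1]], k1[[2]]), k1[[3]])
  dim(k) <- dims
  k <- k / sqrt(sum(k^2))
  Re(stats::fft(stats::fft(x) * stats::fft(k), inverse = TRUE)) / prod(dims)
}

# plausible FreeSurfer-scale mean subfield volumes (mm^3)
subfield_base_means <- function() {
  c(
    AV = 130, LD = 25, LP = 120, VA = 400, VAmc = 30, VLa = 600, VLp = 780,
    VPL = 850, VM = 21, CeM = 60, CL = 30, Pc = 4, CM = 240, Pf = 55,
    Pt = 7, MV_re = 12, MDm = 640, MDl = 250, LGN = 120, MGN = 110,
    L_Sg = 27, PuA = 210, PuM = 980, PuL = 170, PuI = 230
  )
}

#' Simulate a complete synthetic stroke cohort
#'
#' Generates every input the SCN pipeline consumes — cohort table with
#' clinical scores, GMV stack, subfield volume table, per-patient lesion
#' masks, a block-parcellated atlas — together with a `truth` record of
#' every planted quantity (effect voxels and slopes, lesion voxels, confound
#' coefficients), so downstream inference can be validated against known
#' ground truth. Identical `(design, seed)` gives bit-identical output.
#'
#' @param design A [simulation_design()].
#' @param seed RNG seed; defaults to `design$seed`.
#' @return A list of class `thalscn_sim` with elements `cohort`, `stack`,
#'   `volumes`, `lesions` (a [lesion_mask_set()]), `atlas`, `truth`,
#'   `design`.
#' @export
simulate_cohort <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "simulation_design"))
  # overlapping effect blobs with conflicting slopes are contradictory specs
  if (length(design$effects) > 1L) {
    ids <- lapply(design$effects, function(e) blob_indices(design$grid, e$center, e$halfwidth))
    for (a in seq_along(ids)[-1]) {
      for (b in seq_len(a - 1)) {
        if (length(intersect(ids[[a]], ids[[b]]))) {
          ea <- design$effects[[a]]; eb <- design$effects[[b]]
          if (!identical(
            c(ea$slope_cs, ea$slope_nc, ea$subfield, ea$hemisphere),
            c(eb$slope_cs, eb$slope_nc, eb$subfield, eb$hemisphere)
          )) {
            abort("Overlapping effect blobs with contradictory specs.")
          }
        }
      }
    }
  }
  set.seed(seed)
  grid <- design$grid
  n <- design$n_cs + design$n_nc
  nv <- prod(grid$shape)

  cohort <- tibble(
    subject_id = sprintf("sub%03d", seq_len(n)),
    group = rep(c("CS", "NC"), c(design$n_cs, design$n_nc)),
    age = round(pmin(80, pmax(30, rnorm(n, 55.5, 7.35))), 1),
    gender = ifelse(runif(n) < 0.56, "male", "female"),
    scanner = paste0("scanner", sample.int(design$n_scanners, n, replace = TRUE)),
    tiv = round(rnorm(n, 1.45e6, 1.3e5))
  )
  cohort <- validate_cohort(cohort)

  volumes <- simulate_subfield_volumes(design, cohort)
  clin <- simulate_clinical_scores(design, cohort, volumes)
  cohort <- dplyr::bind_cols(cohort, clin)

  # GMV = baseline + confounds + planted seed-covariance effects + smooth noise
  ce <- design$confound_effects
  sc_idx <- as.integer(factor(cohort$scanner))
  subject_offset <- design$baseline +
    ce$age * (cohort$age - mean(cohort$age)) +
    ce$gender * (cohort$gender == "female") +
    ce$scanner[sc_idx] +
    ce$tiv * (cohort$tiv - mean(cohort$tiv))
  gmv <- matrix(rep(subject_offset, nv), n, nv)

  truth_effects <- list()
  for (e in design$effects) {
    vox <- blob_indices(grid, e$center, e$halfwidth)
    z <- zscore(seed_volumes(volumes, cohort, e$subfield, e$hemisphere))
    slope <- ifelse(cohort$group == "CS", e$slope_cs, e$slope_nc)
    gmv[, vox] <- gmv[, vox] + (slope * z)
    truth_effects <- c(truth_effects, list(list(
      subfield = e$subfield, hemisphere = e$hemisphere, voxels = vox,
      slope_cs = e$slope_cs, slope_nc = e$slope_nc
    )))
  }

  if (design$noise_sd > 0) {
    sigma_vox <- design$smoothing_fwhm / (2 * sqrt(2 * log(2))) / design$spacing
    for (i in seq_len(n)) {
      w <- array(rnorm(nv), grid$shape)
      gmv[i, ] <- gmv[i, ] + design$noise_sd * as.vector(smooth_field(w, sigma_vox))
    }
  }

  # focal right-hemisphere lesions zero GMV in patients; exclusion is the
  # analysis mask's job downstream
  lesion_masks <- list()
  cs_rows <- which(cohort$group == "CS")
  for (i in cs_rows) {
    jit <- if (design$lesion_jitter > 0) {
      sample(seq(-design$lesion_jitter, design$lesion_jitter), 3, replace = TRUE)
    } else c(0L, 0L, 0L)
    ctr <- design$lesion_center + jit
    vox <- blob_indices(grid, ctr, design$lesion_halfwidth)
    m <- rep(FALSE, nv)
    m[vox] <- TRUE
    lesion_masks[[cohort$subject_id[i]]] <- m
    gmv[i, vox] <- 0
  }
  lesions <- lesion_mask_set(lesion_masks, grid)

  stack <- gmv_stack(gmv, grid, mask = rep(TRUE, nv), subject_id = cohort$subject_id)
  atlas <- block_atlas(grid)

  truth <- list(
    seed = seed, effects = truth_effects,
    lesion_voxels = lapply(lesion_masks, which),
    confound_effects = ce, noise_sd = design$noise_sd,
    baseline = design$baseline, atrophy = design$atrophy
  )
  structure(
    list(
      cohort = cohort, stack = stack, volumes = volumes,
      lesions = lesions, atlas = atlas, truth = truth, design = design
    ),
    class = "thalscn_sim"
  )
}

#' @export
print.thalscn_sim <- function(x, ...) {
  cat(
    "<thalscn_sim> ", x$design$n_cs, " CS + ", x$design$n_nc, " NC on ",
    format(x$stack$grid), "; ", length(x$truth$effects), " planted effect(s)\n",
    sep = ""
  )
  invisible(x)
}

# correlated log-ish normal subfield volumes with CS ipsilesional atrophy
simulate_subfield_volumes <- function(design, cohort) {
  sf <- thalamic_subfields()
  means <- subfield_base_means()[sf]
  n <- nrow(cohort)
  f <- rnorm(n)  # shared latent subject factor -> inter-subfield correlation
  rho <- design$volume_cor
  out <- vector("list", 2L * length(sf))
  idx <- 0L
  for (h in HEMISPHERES) {
    for (s in sf) {
      eps <- rnorm(n)
      rel <- 1 + design$volume_cv * (sqrt(rho) * f + sqrt(1 - rho) * eps)
      vol <- means[[s]] * pmax(rel, 0.2)
      if (h == "ipsi") {
        vol <- vol * ifelse(cohort$group == "CS", 1 - design$atrophy, 1)
      }
      idx <- idx + 1L
      out[[idx]] <- tibble(
        subject_id = cohort$subject_id, hemisphere = h, subfield = s,
        volume = vol
      )
    }
  }
  long <- dplyr::bind_rows(out)
  totals <- dplyr::summarise(
    dplyr::group_by(long, .data$subject_id, .data$hemisphere),
    subfield = "whole_thalamus", volume = sum(.data$volume), .groups = "drop"
  )
  validate_subfield_volumes(dplyr::bind_rows(long, totals))
}

#' Simulate clinical scores from subfield volumes
#'
#' Scores are a group mean plus a linear function of z-scored linked
#' subfield volumes plus Gaussian noise, then clipped to the instrument's
#' range (accuracies to \[0, 1\], reaction times positive, FMA to 100).
#'
#' @param design A [simulation_design()] (supplies `clinical_model`).
#' @param cohort Cohort tibble (group column used for means).
#' @param volumes Subfield volume table the links refer to.
#' @return Tibble of clinical score columns aligned to `cohort` rows.
#' @export
simulate_clinical_scores <- function(design, cohort, volumes) {
  cm <- design$clinical_model
  n <- nrow(cohort)
  out <- vector("list", nrow(cm))
  for (r in seq_len(nrow(cm))) {
    mu <- ifelse(cohort$group == "CS", cm$mean_cs[r], cm$mean_nc[r])
    links <- cm$links[[r]]
    if (length(links)) {
      for (nm in names(links)) {
        part <- strsplit(nm, ":", fixed = TRUE)[[1]]
        z <- zscore(seed_volumes(volumes, cohort, part[2], part[1]))
        mu <- mu + links[[nm]] * z
      }
    }
    val <- mu + rnorm(n, 0, cm$sd[r])
    val <- pmin(cm$upper[r], pmax(cm$lower[r], val))
    out[[r]] <- val
  }
  names(out) <- cm$metric
  as_tibble(out)
}

#' Block-parcellated synthetic atlas
#'
#' Tiles the grid into equal rectangular parcels (default 4 per axis, 64
#' regions on a 16^3 grid), an integer-labelled stand-in for an anatomical
#' parcellation such as AAL3.
#'
#' @param grid An [image_grid()].
#' @param blocks Parcels per axis (length 1 or 3).
#' @return An `atlas_image`.
#' @export
block_atlas <- function(grid, blocks = 4) {
  blocks <- rep_len(as.integer(blocks), 3L)
  cuts <- lapply(1:3, function(d) {
    pmin(blocks[d] - 1L, ((seq_len(grid$shape[d]) - 1L) * blocks[d]) %/% grid$shape[d])
  })
  lab <- array(0L, grid$shape)
  g <- expand.grid(
    i = seq_len(grid$shape[1]), j = seq_len(grid$shape[2]), k = seq_len(grid$shape[3])
  )
  lab[] <- 1L + cuts[[1]][g$i] + blocks[1] * (cuts[[2]][g$j] + blocks[2] * cuts[[3]][g$k])
  atlas_image(lab, grid)
}

#' Write a simulated cohort to disk
#'
#' Produces the on-disk layout a real study would provide: one GMV NIfTI per
#' subject, per-patient lesion masks, the atlas, TSV cohort and subfield
#' volume tables, and a JSON `truth.json` record.
#'
#' @param sim A `thalscn_sim` object.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_simulated_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gmv_stack(sim$stack, file.path(dir, "gmv"))
  les_dir <- file.path(dir, "lesions")
  dir.create(les_dir, showWarnings = FALSE)
  for (id in names(sim$lesions$masks)) {
    write_image(
      array(sim$lesions$masks[[id]], sim$stack$grid$shape),
      sim$stack$grid, file.path(les_dir, paste0(id, "_lesion.nii.gz"))
    )
  }
  write_image(sim$atlas$labels, sim$stack$grid, file.path(dir, "atlas.nii.gz"))
  write_cohort_table(sim$cohort, file.path(dir, "cohort.tsv"))
  utils::write.table(
    sim$volumes, file.path(dir, "subfield_volumes.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      sim$truth, file.path(dir, "truth.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(dir)
}
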