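# Synthetic cohort generator.
#
# Emulates the statistical structure of the study dataset: ~76 patients with
# 1-3 liver lesions each (~93 lesions, ~46:47 dHGP:rHGP), four human-like
# segmentation observers with calibrated Dice agreement plus a CNN-like
# observer that misses ~9% of lesions, multi-scanner intensity batch
# effects, and clinical covariates independent of the class label. The class
# signal is a parameterised texture/rim difference so that effect-size
# sweeps and null calibration (texture_effect = 0) are possible.

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the study cohort: 76 patients, lesion multiplicity with
#' mean ~1.22 (~93 lesions), 49% dHGP, intra-observer Dice 0.80 and mean
#' inter-observer Dice ~0.69, a CNN observer missing 8/93 lesions with the
#' radiologist's mask as fallback, and four scanner manufacturers in
#' proportions 43:16:16:1 (Siemens, Philips, Toshiba, GE).
#'
#' @param n_patients number of patients (>= 2)
#' @param lesions_per_patient named numeric vector of probabilities for the
#'   lesion count per patient (names = counts)
#' @param class_balance fraction of dHGP patients in `[0, 1]`
#' @param texture_effect dimensionless class separation; 0 = no signal
#' @param batch_effects named list `manufacturer -> list(shift, scale)`
#'   applied to voxel intensities (HU)
#' @param manufacturer_probs named sampling probabilities per manufacturer
#' @param observer_dsc_targets named vector of Dice targets. `STUD2` is the
#'   intra-observer repeat and targets Dice vs `STUD1`; all others target
#'   Dice vs the hidden reference mask. Calibrated so the emergent mean
#'   pairwise inter-observer Dice is ~0.69.
#' @param cnn_miss_rate fraction of lesions the CNN observer misses
#' @param volume_dim voxel grid per patient volume
#' @param seed integer RNG seed
#' @param label_association optional strength of a clinical-covariate/label
#'   association (default 0: independent, as observed in the study cohort)
#' @return object of class `cohort_config`
#' @export
cohort_config <- function(n_patients = 76L,
                          lesions_per_patient = c(`1` = 0.80, `2` = 0.17, `3` = 0.03),
                          class_balance = 0.49,
                          texture_effect = 1,
                          batch_effects = list(
                            Siemens = list(shift = 0, scale = 1),
                            Philips = list(shift = 12, scale = 1.06),
                            Toshiba = list(shift = -10, scale = 0.95),
                            GE      = list(shift = 18, scale = 1.10)),
                          manufacturer_probs = c(Siemens = 43, Philips = 16,
                                                 Toshiba = 16, GE = 1) / 76,
                          observer_dsc_targets = c(STUD1 = 0.86, STUD2 = 0.80,
                                                   PhD = 0.82, RAD = 0.82,
                                                   CNN = 0.86),
                          cnn_miss_rate = 8 / 93,
                          volume_dim = c(64L, 64L, 24L),
                          seed = 1L,
                          label_association = 0) {
  cfg <- list(n_patients = as.integer(n_patients),
              lesions_per_patient = lesions_per_patient,
              class_balance = class_balance,
              texture_effect = texture_effect,
              batch_effects = batch_effects,
              manufacturer_probs = manufacturer_probs,
              observer_dsc_targets = observer_dsc_targets,
              cnn_miss_rate = cnn_miss_rate,
              volume_dim = as.integer(volume_dim),
              seed = as.integer(seed),
              label_association = label_association)
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_patients >= 2L,
            cfg$class_balance >= 0, cfg$class_balance <= 1,
            cfg$cnn_miss_rate >= 0, cfg$cnn_miss_rate <= 1,
            abs(sum(cfg$lesions_per_patient) - 1) < 1e-8,
            all(cfg$observer_dsc_targets > 0),
            all(cfg$observer_dsc_targets <= 1),
            length(cfg$volume_dim) == 3L)
  if (any(cfg$volume_dim[1:2] < 16L) || cfg$volume_dim[3] < 8L)
    stop("degenerate grid: in-plane dimensions must be >= 16 and >= 8 slices",
         " (smaller grids cannot hold a lesion plus observer variation)")
  invisible(cfg)
}

# solid ellipsoid mask on the given grid
.ellipsoid_mask <- function(dim3, center, semi) {
  x <- (seq_len(dim3[1]) - center[1]) / semi[1]
  y <- (seq_len(dim3[2]) - center[2]) / semi[2]
  z <- (seq_len(dim3[3]) - center[3]) / semi[3]
  outer(outer(x^2, y^2, `+`), z^2, `+`) <= 1
}

#' Perturb a binary mask to a target Dice agreement
#'
#' Emulates observer variability: the mask indicator is smoothed, a smooth
#' random field is added with magnitude `mag`, and the result re-thresholded.
#' Each voxel flips at most once as `mag` grows, so Dice against the input
#' is monotone non-increasing in `mag`; the magnitude achieving the target
#' is found by bisection.
#'
#' @param mask logical 3-D mask (>= 30 foreground voxels unless target is 1)
#' @param target_dsc target Dice vs `mask`, in `(0, 1]`
#' @param seed optional seed; `NULL` uses the current RNG stream
#' @param bias systematic boundary bias: > 0 looser (dilation-biased),
#'   < 0 conservative (erosion-biased)
#' @return perturbed logical mask; attribute `achieved_dsc`
#' @export
perturb_mask <- function(mask, target_dsc, seed = NULL, bias = 0) {
  stopifnot(target_dsc > 0, target_dsc <= 1)
  mask <- mask != 0
  nfg <- sum(mask)
  if (nfg == 0L) stop("perturb_mask: empty mask")
  if (target_dsc == 1 && bias == 0) {
    out <- mask
    attr(out, "achieved_dsc") <- 1
    return(out)
  }
  if (nfg < 30L)
    stop("perturb_mask: mask too small (", nfg,
         " voxels) to hit a Dice target reliably")
  run <- function() .perturb_mask_impl(mask, target_dsc, bias)
  if (is.null(seed)) run() else with_seed(seed, run())
}

.perturb_mask_impl <- function(mask, target_dsc, bias) {
  d <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  m <- 8L
  lo <- pmax(apply(idx, 2, min) - m, 1L)
  hi <- pmin(apply(idx, 2, max) + m, d)
  sub <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  # half indicator + half smoothed indicator: reproduces the input exactly at
  # zero magnitude (S > 0.5 iff inside) while keeping a soft boundary that
  # lets small noise flip boundary voxels before interior ones
  S <- 0.5 * sub + 0.5 * smooth_gauss_3d(sub * 1.0, c(1.2, 1.2, 0.8))
  N <- array(stats::rnorm(length(sub)), dim(sub))
  N <- smooth_gauss_3d(N, 1.5)
  N <- N / stats::sd(N)
  f <- function(mag) (S + bias + mag * N) > 0.5
  dsc_at <- function(mag) dice(sub, f(mag))
  mag_hi <- 2
  while (dsc_at(mag_hi) > target_dsc && mag_hi < 64) mag_hi <- mag_hi * 2
  if (dsc_at(mag_hi) > target_dsc)
    stop("perturb_mask: target Dice ", target_dsc, " unreachable")
  mag_lo <- 0
  for (it in 1:40) {
    mid <- (mag_lo + mag_hi) / 2
    if (dsc_at(mid) > target_dsc) mag_lo <- mid else mag_hi <- mid
  }
  pert <- f((mag_lo + mag_hi) / 2)
  achieved <- dice(sub, pert)
  if (abs(achieved - target_dsc) > 0.05)
    stop("perturb_mask: could not achieve Dice ", target_dsc,
         " (best ", round(achieved, 3), "); mask too small or bias too strong")
  out <- array(FALSE, d)
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- pert
  attr(out, "achieved_dsc") <- achieved
  out
}

#' Generate a synthetic cohort
#'
#' Builds per-patient volumes (smooth liver-like parenchyma around 100 HU
#' with ellipsoidal hypodense lesions), a hidden reference mask plus four
#' human-like observer masks per lesion, a CNN-like observer (see
#' [simulate_cnn_observer()]), scanner batch effects on intensities, and a
#' lesion-level metadata table. Deterministic given `config$seed`.
#'
#' @param config a [cohort_config()]
#' @return object of class `synthetic_cohort`: list with `config`,
#'   `patients` (each: volume, spacing, liver_mask, acquisition, clinical,
#'   lesions with `reference_mask` and `observer_masks`), and `metadata`
#'   (one row per lesion)
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  with_seed(config$seed, .generate_cohort_impl(config))
}

.generate_cohort_impl <- function(cfg) {
  np <- cfg$n_patients
  d <- cfg$volume_dim
  # patient-level labels: exact fraction, shuffled (lesions inherit)
  n_d <- round(np * cfg$class_balance)
  labels <- sample(c(rep("dHGP", n_d), rep("rHGP", np - n_d)))
  manu <- sample(names(cfg$manufacturer_probs), np, replace = TRUE,
                 prob = cfg$manufacturer_probs)
  counts <- as.integer(names(cfg$lesions_per_patient))
  patients <- vector("list", np)
  names(patients) <- sprintf("P%03d", seq_len(np))
  meta <- list()
  liver_semi <- pmax(c(d[1] * 0.40, d[2] * 0.38, d[3] * 0.42), 3)
  for (p in seq_len(np)) {
    pid <- names(patients)[p]
    acq <- list(
      manufacturer = manu[p],
      slice_thickness = sample(c(2, 2.5, 3, 4, 5), 1,
                               prob = c(.10, .10, .25, .20, .35)),
      pixel_spacing = round(max(0.5, stats::rnorm(1, 0.74, 0.05)), 3),
      tube_current = round(exp(stats::rnorm(1, log(240), 0.3))),
      peak_kilovoltage = sample(c(100, 120, 140), 1, prob = c(.1, .8, .1)))
    spacing <- c(acq$pixel_spacing, acq$pixel_spacing, acq$slice_thickness)
    # smooth parenchyma field ~100 HU
    vol <- array(stats::rnorm(prod(d)), d)
    vol <- smooth_gauss_3d(vol, c(6, 6, 2))
    vol <- 100 + 10 * vol / stats::sd(vol)
    liver <- .ellipsoid_mask(d, center = d / 2 + 0.5, semi = liver_semi)
    nles <- sample(counts, 1, prob = cfg$lesions_per_patient)
    occupied <- array(FALSE, d)
    lesions <- list()
    for (l in seq_len(nles)) {
      ref <- NULL
      for (attempt in 1:25) {
        semi <- c(stats::runif(2, 4.5, 9), stats::runif(1, 2.2, 4))
        ctr <- d / 2 + 0.5 + (stats::runif(3, -1, 1) *
                                pmax(liver_semi - semi - 2, 0))
        cand <- .ellipsoid_mask(d, ctr, semi)
        if (!any(cand & occupied) && all(cand[liver == FALSE] == FALSE) &&
            sum(cand) >= 80L) {
          ref <- cand; break
        }
      }
      if (is.null(ref) && l == 1L) {
        # guarantee at least one lesion per patient: central ellipsoid
        ref <- .ellipsoid_mask(d, d / 2 + 0.5, c(6, 6, 3))
      }
      if (is.null(ref)) next
      occupied <- occupied | mask_dilate(ref, 2)
      # lesion appearance: hypodense core + class-dependent texture and rim
      is_d <- labels[p] == "dHGP"
      eff <- cfg$texture_effect
      sigma_tex <- 1 + if (is_d) 0.8 * eff else 0
      rim_delta <- if (is_d) 15 * eff else 0
      nles_vox <- which(ref)
      tex <- array(stats::rnorm(prod(d)), d)
      tex <- smooth_gauss_3d(tex, c(sigma_tex, sigma_tex, 1))
      tex <- 8 * tex / stats::sd(tex)
      vol[nles_vox] <- 70 + tex[nles_vox]
      rim <- ref & !mask_erode(ref, 2)
      if (rim_delta != 0) vol[rim] <- vol[rim] + rim_delta
      lid <- sprintf("%s_L%d", pid, l)
      lesions[[lid]] <- list(lesion_id = lid, patient_id = pid,
                             label = labels[p], reference_mask = ref)
    }
    # observer masks: STUD1 repeat -> STUD2; PhD/RAD independent of reference
    tg <- cfg$observer_dsc_targets
    for (lid in names(lesions)) {
      ref <- lesions[[lid]]$reference_mask
      stud1 <- perturb_mask(ref, tg[["STUD1"]])
      om <- list(
        STUD1 = stud1,
        STUD2 = perturb_mask(stud1, tg[["STUD2"]]),
        PhD = perturb_mask(ref, tg[["PhD"]]),
        RAD = perturb_mask(ref, tg[["RAD"]], bias = 0.02))
      lesions[[lid]]$observer_masks <- om
    }
    # acquisition batch effect + detector noise
    be <- cfg$batch_effects[[manu[p]]] %||% list(shift = 0, scale = 1)
    vol <- be$shift + be$scale * vol
    vol <- vol + array(stats::rnorm(prod(d), 0, 5), d)
    clinical <- .simulate_clinical(labels[p], cfg$label_association, lesions,
                                   spacing)
    patients[[pid]] <- list(patient_id = pid, volume = vol, spacing = spacing,
                            liver_mask = liver, acquisition = acq,
                            clinical = clinical, lesions = lesions)
  }
  cohort <- structure(list(config = cfg, patients = patients), class = "synthetic_cohort")
  cohort <- simulate_cnn_observer(cohort, cfg$cnn_miss_rate, "RAD")
  cohort$metadata <- .cohort_metadata(cohort)
  cohort
}

.simulate_clinical <- function(label, assoc, lesions, spacing) {
  shift <- if (label == "dHGP") assoc else -assoc
  vols_cm3 <- vapply(lesions, function(l) sum(l$reference_mask) *
                       prod(spacing) / 1000, numeric(1))
  size_cm <- if (length(vols_cm3)) max((6 * vols_cm3 / pi)^(1 / 3)) else NA_real_
  list(age = round(stats::rnorm(1, 68 + 3 * shift, 9)),
       sex = sample(c("male", "female"), 1, prob = c(0.58, 0.42)),
       primary_location = sample(c("right", "left", "rectum"), 1,
                                 prob = c(0.08, 0.54, 0.38)),
       nodal_status = sample(c("N0", "N+"), 1, prob = c(0.46, 0.54)),
       dfi_gt_12mo = stats::runif(1) < 0.51,
       cea_gt_200 = stats::runif(1) < 0.07 + 0.03 * shift,
       n_crlm = length(lesions),
       size_largest_cm = size_cm)
}

#' Add (or re-simulate) the CNN-like observer on a cohort
#'
#' A fraction `miss_rate` of lesions is flagged as missed by the CNN; those
#' lesions receive the fallback observer's mask verbatim (the study used the
#' radiologist's segmentation for the 8/93 lesions the CNN missed). All
#' other lesions get a conservative, erosion-biased perturbation of the
#' reference mask.
#'
#' @param cohort a `synthetic_cohort`
#' @param miss_rate fraction in `[0, 1]`
#' @param fallback_observer observer name whose mask substitutes for misses
#' @param seed optional seed (`NULL`: current RNG stream)
#' @return the cohort with `CNN` observer masks and `cnn_missed` flags
#' @export
simulate_cnn_observer <- function(cohort, miss_rate = 8 / 93,
                                  fallback_observer = "RAD", seed = NULL) {
  run <- function() {
    tg <- cohort$config$observer_dsc_targets
    for (pid in names(cohort$patients)) {
      les <- cohort$patients[[pid]]$lesions
      for (lid in names(les)) {
        fb <- les[[lid]]$observer_masks[[fallback_observer]]
        if (is.null(fb)) stop("fallback observer ", fallback_observer,
                              " missing for lesion ", lid)
        missed <- stats::runif(1) < miss_rate
        cnn <- if (missed) fb else
          perturb_mask(les[[lid]]$reference_mask, tg[["CNN"]], bias = -0.02)
        les[[lid]]$observer_masks$CNN <- cnn
        les[[lid]]$cnn_missed <- missed
      }
      cohort$patients[[pid]]$lesions <- les
    }
    if (!is.null(cohort$metadata)) cohort$metadata <- .cohort_metadata(cohort)
    cohort
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

.cohort_metadata <- function(cohort) {
  rows <- list()
  for (pid in names(cohort$patients)) {
    pt <- cohort$patients[[pid]]
    for (lid in names(pt$lesions)) {
      l <- pt$lesions[[lid]]
      rows[[lid]] <- data.frame(
        patient_id = pid, lesion_id = lid, label = l$label,
        cnn_missed = isTRUE(l$cnn_missed),
        manufacturer = pt$acquisition$manufacturer,
        slice_thickness = pt$acquisition$slice_thickness,
        pixel_spacing = pt$acquisition$pixel_spacing,
        tube_current = pt$acquisition$tube_current,
        peak_kilovoltage = pt$acquisition$peak_kilovoltage,
        age = pt$clinical$age, sex = pt$clinical$sex,
        primary_location = pt$clinical$primary_location,
        nodal_status = pt$clinical$nodal_status,
        dfi_gt_12mo = pt$clinical$dfi_gt_12mo,
        cea_gt_200 = pt$clinical$cea_gt_200,
        n_crlm = pt$clinical$n_crlm,
        size_largest_cm = pt$clinical$size_largest_cm,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  md <- x$metadata
  cat("Synthetic CRLM cohort:", length(x$patients), "patients,",
      nrow(md), "lesions (", sum(md$label == "dHGP"), "dHGP /",
      sum(md$label == "rHGP"), "rHGP )\n")
  cat("  grid:", paste(x$config$volume_dim, collapse = "x"),
      "| texture_effect:", x$config$texture_effect,
      "| seed:", x$config$seed, "\n")
  cat("  CNN missed:", sum(md$cnn_missed), "lesions\n")
  invisible(x)
}

#' Write a cohort to disk (NIfTI volumes/masks + CSV metadata + JSON config)
#'
#' @param cohort a `synthetic_cohort`
#' @param dir output directory (created if needed)
#' @return invisibly, the vector of files written
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (pid in names(cohort$patients)) {
    pt <- cohort$patients[[pid]]
    f <- file.path(dir, paste0(pid, "_volume.nii.gz"))
    nifti_write(pt$volume, f, pt$spacing); files <- c(files, f)
    f <- file.path(dir, paste0(pid, "_liver.nii.gz"))
    nifti_write(pt$liver_mask, f, pt$spacing); files <- c(files, f)
    for (lid in names(pt$lesions)) {
      l <- pt$lesions[[lid]]
      for (obs in names(l$observer_masks)) {
        f <- file.path(dir, paste0(lid, "_", obs, ".nii.gz"))
        nifti_write(l$observer_masks[[obs]], f, pt$spacing)
        files <- c(files, f)
      }
    }
  }
  f <- file.path(dir, "metadata.csv")
  utils::write.csv(cohort$metadata, f, row.names = FALSE); files <- c(files, f)
  f <- file.path(dir, "cohort_config.json")
  jsonlite::write_json(unclass(cohort$config), f, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(files, f)
  invisible(files)
}

#' All lesion masks of a cohort grouped per lesion (observer -> mask)
#'
#' Convenience accessor feeding [pairwise_dice_table()].
#' @param cohort a `synthetic_cohort`
#' @param observers observer subset (default: all present)
#' @return list over lesions of named mask lists
#' @export
cohort_masks_by_lesion <- function(cohort, observers = NULL) {
  out <- list()
  for (pid in names(cohort$patients)) {
    for (lid in names(cohort$patients[[pid]]$lesions)) {
      om <- cohort$patients[[pid]]$lesions[[lid]]$observer_masks
      if (!is.null(observers)) om <- om[intersect(observers, names(om))]
      out[[lid]] <- om
    }
  }
  out
}
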