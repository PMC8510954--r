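test_that("cohort generation is deterministic and respects the config", {
  cfg <- cohort_config(n_patients = 8, volume_dim = c(40L, 40L, 14L), seed = 7)
  co <- tiny_cohort()
  co2 <- generate_cohort(cfg)
  expect_identical(co, co2)                       # byte-identical under seed
  md <- co$metadata
  expect_equal(length(co$patients), 8L)
  expect_true(all(md$label %in% c("dHGP", "rHGP")))
  # patient -> lesion mapping is a function
  expect_false(anyDuplicated(md$lesion_id) > 0)
  split_pat <- vapply(strsplit(md$lesion_id, "_"), `[[`, character(1), 1)
  expect_identical(split_pat, md$patient_id)
  # lesions of one patient share one label, volume and acquisition
  for (pid in names(co$patients)) {
    pt <- co$patients[[pid]]
    labs <- unique(md$label[md$patient_id == pid])
    if (length(pt$lesions)) expect_length(labs, 1L)
    for (l in pt$lesions) {
      expect_identical(dim(l$reference_mask), dim(pt$volume))
      for (om in l$observer_masks)
        expect_identical(dim(om), dim(pt$volume))
    }
  }
})

test_that("study-scale config reproduces the cohort structure", {
  cfg <- cohort_config(n_patients = 76, class_balance = 0.49, seed = 1)
  md <- generate_cohort(cfg)$metadata
  expect_equal(length(unique(md$patient_id)), 76L)
  expect_gt(nrow(md), 80)            # ~93 lesions
  expect_lt(nrow(md), 110)
  frac_d <- mean(md$label == "dHGP")
  expect_gt(frac_d, 0.38)            # ~46/93
  expect_lt(frac_d, 0.60)
  # CNN misses ~9% of lesions, substituted by the radiologist mask
  expect_gt(sum(md$cnn_missed), 0)
  expect_lt(mean(md$cnn_missed), 0.25)
})

test_that("degenerate grids are rejected", {
  expect_error(cohort_config(volume_dim = c(8L, 8L, 4L)), "degenerate")
  expect_error(cohort_config(n_patients = 1L))
  expect_error(cohort_config(class_balance = 1.2))
})

test_that("perturb_mask hits its Dice target and handles edge cases", {
  m <- ball_mask(c(40, 40, 20), radius = c(9, 9, 6))
  p1 <- perturb_mask(m, 1.0, seed = 1)
  expect_identical(as.vector(p1), as.vector(m))   # identity at target 1
  p <- perturb_mask(m, 0.69, seed = 2)
  expect_gte(dice(m, p), 0.64)
  expect_lte(dice(m, p), 0.74)
  tiny <- array(FALSE, c(12, 12, 6)); tiny[6:7, 6:7, 3] <- TRUE
  expect_error(perturb_mask(tiny, 0.7, seed = 1), "small")
  expect_error(perturb_mask(array(FALSE, c(8, 8, 4)), 0.9), "empty")
})

test_that("perturbation magnitude monotonically degrades Dice", {
  # same noise field, growing magnitude: each voxel flips at most once,
  # so Dice against the input is non-increasing
  m <- ball_mask(c(40, 40, 20), radius = c(9, 9, 6))
  d <- withr::with_seed(11, {
    S <- 0.5 * m + 0.5 * hgpradiomics:::smooth_gauss_3d(m * 1.0, c(1.2, 1.2, 0.8))
    N <- hgpradiomics:::smooth_gauss_3d(array(stats::rnorm(length(m)), dim(m)), 1.5)
    N <- N / stats::sd(N)
    vapply(seq(0, 2, by = 0.1), function(mag)
      dice(m, (S + mag * N) > 0.5), numeric(1))
  })
  expect_true(all(diff(d) <= 1e-12))
})

test_that("simulated observers reproduce the intra/inter Dice structure", {
  # >= 50 lesions for a stable mean pairwise estimate
  co <- generate_cohort(cohort_config(n_patients = 52,
                                      volume_dim = c(44L, 44L, 16L),
                                      seed = 13))
  expect_gte(nrow(co$metadata), 50)
  tab <- pairwise_dice_table(cohort_masks_by_lesion(co))
  # intra-observer repeat (STUD1 vs STUD2): stated-world target 0.80
  expect_equal(tab$mean["STUD1", "STUD2"], 0.80, tolerance = 0.05)
  # mean pairwise Dice among the other human observer pairs: target 0.69
  hum <- c("STUD1", "STUD2", "PhD", "RAD")
  pairs <- utils::combn(hum, 2, simplify = FALSE)
  pairs <- Filter(function(p) !setequal(p, c("STUD1", "STUD2")), pairs)
  inter <- mean(vapply(pairs, function(p) tab$mean[p[1], p[2]], numeric(1)))
  expect_equal(inter, 0.69, tolerance = 0.05)
})

test_that("the CNN observer misses lesions and substitutes the fallback", {
  co <- tiny_cohort()
  co0 <- simulate_cnn_observer(co, miss_rate = 0, seed = 3)
  for (pid in names(co0$patients)) for (l in co0$patients[[pid]]$lesions) {
    expect_false(l$cnn_missed)
    expect_false(identical(l$observer_masks$CNN, l$observer_masks$RAD))
  }
  co1 <- simulate_cnn_observer(co, miss_rate = 1, seed = 3)
  for (pid in names(co1$patients)) for (l in co1$patients[[pid]]$lesions) {
    expect_true(l$cnn_missed)
    expect_identical(l$observer_masks$CNN, l$observer_masks$RAD)
  }
})

test_that("batch effects are detectable on a null cohort (ANOVA)", {
  co <- generate_cohort(cohort_config(n_patients = 16, texture_effect = 0,
                                      volume_dim = c(40L, 40L, 14L),
                                      seed = 21))
  md <- co$metadata
  expect_gte(length(unique(md$manufacturer)), 2)
  # mean lesion intensity per lesion (CNN mask), in metadata row order
  vals <- unlist(lapply(names(co$patients), function(pid) {
    pt <- co$patients[[pid]]
    vapply(pt$lesions, function(l) mean(pt$volume[l$observer_masks$CNN]),
           numeric(1))
  }))
  keep <- table(md$manufacturer) >= 2
  ok <- md$manufacturer %in% names(keep)[keep]
  p <- stats::anova(stats::lm(vals[ok] ~ md$manufacturer[ok]))$`Pr(>F)`[1]
  expect_lt(p, 0.05)
})

test_that("cohort round-trips through NIfTI and CSV", {
  co <- tiny_cohort()
  dir <- withr::local_tempdir()
  files <- write_cohort(co, dir)
  expect_true(all(file.exists(files)))
  pid <- names(co$patients)[1]
  vol <- nifti_read(file.path(dir, paste0(pid, "_volume.nii.gz")))
  expect_equal(dim(vol), dim(co$patients[[pid]]$volume))
  # float32 storage: relative tolerance
  expect_equal(as.vector(vol), as.vector(co$patients[[pid]]$volume),
               tolerance = 1e-6)
  lid <- names(co$patients[[pid]]$lesions)[1]
  m <- nifti_read(file.path(dir, paste0(lid, "_RAD.nii.gz")))
  expect_identical(as.vector(m != 0),
                   as.vector(co$patients[[pid]]$lesions[[lid]]$observer_masks$RAD))
})
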