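# Shared fixtures, all generated in code.

ball_mask <- function(dim3 = c(40, 40, 20), center = dim3 / 2 + 0.5,
                      radius = c(8, 8, 5)) {
  x <- (seq_len(dim3[1]) - center[1]) / radius[1]
  y <- (seq_len(dim3[2]) - center[2]) / radius[2]
  z <- (seq_len(dim3[3]) - center[3]) / radius[3]
  outer(outer(x^2, y^2, `+`), z^2, `+`) <= 1
}

noise_volume <- function(dim3 = c(40, 40, 20), mean = 100, sd = 10,
                         seed = 1) {
  withr::with_seed(seed, array(stats::rnorm(prod(dim3), mean, sd), dim3))
}

# a tiny cohort reused by several test files (cached per session)
.tiny_cohort_env <- new.env()
tiny_cohort <- function() {
  if (is.null(.tiny_cohort_env$cohort))
    .tiny_cohort_env$cohort <- generate_cohort(
      cohort_config(n_patients = 8, volume_dim = c(40L, 40L, 14L), seed = 7))
  .tiny_cohort_env$cohort
}

# lesion-roi features of the tiny cohort (expensive; cached)
tiny_features <- function() {
  if (is.null(.tiny_cohort_env$features))
    .tiny_cohort_env$features <- extract_cohort_features(tiny_cohort())
  .tiny_cohort_env$features
}

# quick synthetic FeatureTable-shaped frame for model-search tests
fake_rows <- function(n_patients = 40, per_patient = 2, p = 25,
                      effect = 1.5, seed = 1) {
  withr::with_seed(seed, {
    n <- n_patients * per_patient
    lab_p <- rep(c("dHGP", "rHGP"), length.out = n_patients)
    df <- data.frame(
      patient_id = rep(sprintf("P%03d", seq_len(n_patients)),
                       each = per_patient),
      lesion_id = sprintf("L%03d", seq_len(n)),
      observer = "CNN",
      label = rep(lab_p, each = per_patient))
    X <- matrix(stats::rnorm(n * p), n, p)
    X[df$label == "dHGP", 1] <- X[df$label == "dHGP", 1] + effect
    X[df$label == "dHGP", 2] <- X[df$label == "dHGP", 2] + effect / 2
    colnames(X) <- paste0("V", seq_len(p))
    cbind(df, as.data.frame(X))
  })
}

fake_cols <- function(rows) grep("^V", names(rows), value = TRUE)
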