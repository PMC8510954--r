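test_that("workflow draws cover all classifiers, validate, and are
           reproducible", {
  draws <- withr::with_seed(2, lapply(1:400, sample_workflow))
  cls <- vapply(draws, `[[`, character(1), "classifier")
  expect_setequal(unique(cls), workflow_priors()$classifiers)
  expect_length(workflow_priors()$classifiers, 8L)
  for (cfg in draws[1:50]) expect_silent(validate_workflow(cfg))
  draws2 <- withr::with_seed(2, lapply(1:400, sample_workflow))
  expect_identical(draws, draws2)
})

test_that("every classifier fits and predicts probabilities", {
  rows <- fake_rows(n_patients = 30, p = 12, effect = 2)
  X <- as.matrix(rows[, fake_cols(rows)])
  y <- as.integer(rows$label == "dHGP")
  for (clf in workflow_priors()$classifiers) {
    m <- withr::with_seed(4, fit_classifier(clf, X, y))
    p <- predict_classifier(m, X)
    expect_length(p, nrow(X))
    expect_true(all(p >= 0 & p <= 1), info = clf)
    # trains well above chance on separable data
    expect_gt(hgpradiomics:::.auc_rank(p, y), 0.8)
  }
  # degenerate single-class input falls back to a constant model
  m0 <- fit_classifier("logistic", X[y == 1, ], y[y == 1])
  expect_equal(predict_classifier(m0, X[1:3, ]), rep(1, 3))
})

test_that("evaluate_workflow separates signal from permutation null", {
  rows <- fake_rows(n_patients = 40, p = 20, effect = 2, seed = 3)
  fc <- fake_cols(rows)
  ctx <- make_internal_context(rows, fc, seed = 9)
  cfg <- withr::with_seed(5, sample_workflow(1L))
  s1 <- evaluate_workflow(cfg, ctx = ctx, metric = "f1_weighted")
  s1b <- evaluate_workflow(cfg, ctx = ctx, metric = "f1_weighted")
  expect_identical(s1, s1b)                        # fixed seeds -> identical
  rows_null <- rows
  rows_null$label <- withr::with_seed(7, {
    pl <- unique(rows[, c("patient_id", "label")])
    perm <- stats::setNames(sample(pl$label), pl$patient_id)
    unname(perm[rows_null$patient_id])
  })
  ctx0 <- make_internal_context(rows_null, fc, seed = 9)
  cfgs <- withr::with_seed(11, lapply(1:12, sample_workflow))
  sig <- vapply(cfgs, evaluate_workflow, numeric(1), ctx = ctx,
                metric = "auc")
  nul <- vapply(cfgs, evaluate_workflow, numeric(1), ctx = ctx0,
                metric = "auc")
  expect_gt(max(sig, na.rm = TRUE), 0.9)           # separable -> near max
  expect_lt(abs(mean(nul, na.rm = TRUE) - 0.5), 0.15)  # permuted -> chance
})

test_that("internal splits are patient-grouped and stratified", {
  rows <- fake_rows(n_patients = 40, p = 5)
  ctx <- make_internal_context(rows, fake_cols(rows), seed = 2)
  for (sp in ctx$splits) {
    tr_p <- unique(rows$patient_id[sp$train])
    va_p <- unique(rows$patient_id[sp$valid])
    expect_length(intersect(tr_p, va_p), 0L)
    expect_gte(length(unique(rows$label[sp$valid])), 2L)
  }
})

test_that("search_and_ensemble ranks, refits, and k=1 equals the best
           workflow", {
  rows <- fake_rows(n_patients = 36, p = 15, effect = 2, seed = 8)
  fc <- fake_cols(rows)
  ens <- search_and_ensemble(rows, fc, n_candidates = 40, k = 5, seed = 21)
  expect_length(ens$members, 5L)
  expect_true(all(diff(ens$scores) <= 0))          # sorted by score
  p5 <- predict_ensemble(ens, rows)
  expect_true(all(p5 >= 0 & p5 <= 1))
  ens1 <- search_and_ensemble(rows, fc, n_candidates = 40, k = 1, seed = 21)
  p1 <- predict_ensemble(ens1, rows)
  m1 <- with(ens1, hgpradiomics:::.predict_workflow_matrix(
    members[[1]], as.matrix(rows[, fc])))
  expect_identical(p1, m1)                         # k=1 is the single best
  expect_error(search_and_ensemble(rows, fc, n_candidates = 3, k = 5), "k")
})

test_that("no training-time state leaks from the test rows (sentinel probe)", {
  # Build a FeatureTable-shaped frame with four observers, corrupt the
  # test-side (CNN) rows two different ways, and verify the fitted
  # per-iteration ensembles are unchanged: scaling, selection, ComBat and
  # the search may only ever see training rows.
  base <- fake_rows(n_patients = 24, per_patient = 1, p = 12, seed = 10)
  fc <- fake_cols(base)
  mk <- function(corrupt) {
    obs_rows <- lapply(c("STUD2", "PhD", "RAD", "CNN"), function(o) {
      r <- base
      r$observer <- o
      if (o == "CNN") r[, fc] <- r[, fc] + corrupt
      r
    })
    out <- do.call(rbind, obs_rows)
    out$roi <- "lesion"
    out$manufacturer <- rep(c("Siemens", "Philips"),
                            length.out = nrow(out))
    out$slice_thickness <- rep(c(3, 5), length.out = nrow(out))
    attr(out, "feature_cols") <- fc
    out
  }
  splits <- make_splits(base, n_iterations = 2L, seed = 5)
  run <- function(features, robustness)
    run_experiment(features, experiment_design("multi",
                                               robustness = robustness),
                   splits, n_candidates = 8L, k = 2L, seed = 17,
                   return_models = TRUE)
  for (rob in c("none", "combat-manufacturer")) {
    r1 <- run(mk(corrupt = 1e6), rob)
    r2 <- run(mk(corrupt = -31415), rob)
    for (i in 1:2) {
      e1 <- r1$ensembles[[i]]; e2 <- r2$ensembles[[i]]
      expect_identical(e1$scores, e2$scores)
      # identical fitted members: same predictions on a clean probe set
      probe <- base
      probe$observer <- "CNN"
      expect_equal(predict_ensemble(e1, probe), predict_ensemble(e2, probe),
                   tolerance = 1e-12)
    }
  }
})
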