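# Random search over preprocessing+classifier workflows, ranked on internal
# random-split validation and ensembled (the "best k of n candidates"
# strategy; study-scale defaults n = 100,000 / k = 50, desk-scale defaults
# n = 1,000 / k = 10).

.classifier_set <- c("logistic", "svm", "random_forest", "naive_bayes",
                     "lda", "qda", "adaboost", "gradient_boosting")

#' Declared hyperparameter priors of the workflow search
#'
#' One place defines every random choice: scaler, feature selector,
#' class-imbalance handling, classifier and its hyperparameters.
#' @return list describing the priors
#' @export
workflow_priors <- function() {
  list(
    scaler = c("zscore", "robust", "minmax", "none"),
    selector_p_none = 0.2,
    selector_k_range = c(5L, 60L),       # log-uniform
    imbalance = c(none = 0.7, oversample = 0.3),
    classifiers = .classifier_set,
    logistic = list(alpha = c(0, 1), log10_lambda = c(-4, 0)),
    svm = list(kernel = c("linear", "rbf"), log10_C = c(-2, 2),
               log10_gamma = c(-3, 0)),
    random_forest = list(ntree = c(20L, 100L), mtry_sqrt_mult = c(0.5, 2),
                         max_depth = c(2L, 8L), min_leaf = c(1L, 5L)),
    adaboost = list(n_rounds = c(20L, 60L), max_depth = c(1L, 2L)),
    gradient_boosting = list(n_rounds = c(20L, 60L), max_depth = c(1L, 3L),
                             log10_lr = c(-2, -0.5)))
}

#' Draw one candidate workflow from the priors
#'
#' Uses the current RNG stream; wrap in a seeded context for reproducible
#' draw sequences.
#'
#' @param draw_index bookkeeping index used for deterministic tie-breaking
#' @return object of class `workflow_config`
#' @export
sample_workflow <- function(draw_index = NA_integer_) {
  pr <- workflow_priors()
  scaler <- sample(pr$scaler, 1)
  selector <- if (stats::runif(1) < pr$selector_p_none) {
    list(method = "none", k = NA_integer_)
  } else {
    lk <- log(pr$selector_k_range)
    list(method = "topk", k = as.integer(round(exp(stats::runif(1, lk[1], lk[2])))))
  }
  imbalance <- sample(names(pr$imbalance), 1, prob = pr$imbalance)
  clf <- sample(pr$classifiers, 1)
  params <- switch(clf,
    logistic = list(alpha = stats::runif(1, pr$logistic$alpha[1], pr$logistic$alpha[2]),
                    lambda = 10^stats::runif(1, pr$logistic$log10_lambda[1],
                                             pr$logistic$log10_lambda[2])),
    svm = list(kernel = sample(pr$svm$kernel, 1),
               C = 10^stats::runif(1, pr$svm$log10_C[1], pr$svm$log10_C[2]),
               gamma = 10^stats::runif(1, pr$svm$log10_gamma[1], pr$svm$log10_gamma[2])),
    random_forest = list(
      ntree = sample(pr$random_forest$ntree[1]:pr$random_forest$ntree[2], 1),
      mtry_sqrt_mult = stats::runif(1, pr$random_forest$mtry_sqrt_mult[1],
                                    pr$random_forest$mtry_sqrt_mult[2]),
      max_depth = sample(pr$random_forest$max_depth[1]:pr$random_forest$max_depth[2], 1),
      min_leaf = sample(pr$random_forest$min_leaf[1]:pr$random_forest$min_leaf[2], 1)),
    adaboost = list(n_rounds = sample(pr$adaboost$n_rounds[1]:pr$adaboost$n_rounds[2], 1),
                    max_depth = sample(pr$adaboost$max_depth[1]:pr$adaboost$max_depth[2], 1)),
    gradient_boosting = list(
      n_rounds = sample(pr$gradient_boosting$n_rounds[1]:pr$gradient_boosting$n_rounds[2], 1),
      max_depth = sample(pr$gradient_boosting$max_depth[1]:pr$gradient_boosting$max_depth[2], 1),
      learning_rate = 10^stats::runif(1, pr$gradient_boosting$log10_lr[1],
                                      pr$gradient_boosting$log10_lr[2])),
    list())
  cfg <- structure(list(scaler = scaler, selector = selector,
                        imbalance = imbalance, classifier = clf,
                        params = params, draw_index = draw_index,
                        seed = sample.int(.Machine$integer.max - 1L, 1)),
                   class = "workflow_config")
  validate_workflow(cfg)
  cfg
}

#' @export
validate_workflow <- function(cfg) {
  pr <- workflow_priors()
  stopifnot(cfg$classifier %in% pr$classifiers,
            cfg$scaler %in% pr$scaler,
            cfg$selector$method %in% c("none", "topk"),
            cfg$imbalance %in% names(pr$imbalance))
  if (cfg$selector$method == "topk")
    stopifnot(cfg$selector$k >= pr$selector_k_range[1],
              cfg$selector$k <= pr$selector_k_range[2])
  invisible(cfg)
}

# ---- preprocessing pieces --------------------------------------------------

.scaler_fit <- function(X, kind) {
  switch(kind,
    none = list(kind = kind),
    zscore = list(kind = kind, c = colMeans(X),
                  s = pmax(apply(X, 2, stats::sd), 1e-12)),
    robust = list(kind = kind, c = apply(X, 2, stats::median),
                  s = pmax(apply(X, 2, stats::IQR), 1e-12)),
    minmax = {
      mn <- apply(X, 2, min); mx <- apply(X, 2, max)
      list(kind = kind, c = mn, s = pmax(mx - mn, 1e-12))
    })
}

.scaler_apply <- function(X, sc) {
  if (sc$kind == "none") return(X)
  sweep(sweep(X, 2, sc$c), 2, sc$s, `/`)
}

# univariate rank score per feature: |AUC - 0.5| from the rank-sum statistic
.univariate_scores <- function(X, y01) {
  n1 <- sum(y01 == 1); n0 <- sum(y01 == 0)
  if (n1 == 0 || n0 == 0) return(rep(0, ncol(X)))
  scores <- vapply(seq_len(ncol(X)), function(j) {
    r <- rank(X[, j])
    auc <- (sum(r[y01 == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    abs(auc - 0.5)
  }, numeric(1))
  scores
}

# Shared training-side preprocessing state: imputation medians, zero-variance
# filter, lazily-memoised scaled matrices and the univariate feature order.
# All of it is a function of the training rows only; candidates sharing an
# internal split reuse one prep environment (monotone scalers leave the
# rank-based univariate ordering unchanged, so it is scaler-independent).
.workflow_prep <- function(X, y01) {
  prep <- new.env(parent = emptyenv())
  med <- apply(X, 2, function(col) stats::median(col, na.rm = TRUE))
  med[!is.finite(med)] <- 0
  for (j in seq_len(ncol(X))) {
    bad <- !is.finite(X[, j])
    if (any(bad)) X[bad, j] <- med[j]
  }
  keep <- which(apply(X, 2, stats::sd) > 1e-12)
  if (!length(keep)) keep <- 1L
  prep$impute <- med
  prep$keep <- keep
  prep$Ximp <- X[, keep, drop = FALSE]
  prep$y01 <- y01
  prep$scalers <- list()
  prep$scaled <- list()
  prep$ord <- NULL
  prep
}

.prep_scaled <- function(prep, kind) {
  if (is.null(prep$scaled[[kind]])) {
    sc <- .scaler_fit(prep$Ximp, kind)
    prep$scalers[[kind]] <- sc
    prep$scaled[[kind]] <- .scaler_apply(prep$Ximp, sc)
  }
  prep$scaled[[kind]]
}

.prep_order <- function(prep) {
  if (is.null(prep$ord))
    prep$ord <- order(.univariate_scores(prep$Ximp, prep$y01),
                      decreasing = TRUE)
  prep$ord
}

# fit the full preprocessing+classifier pipeline on training rows
.fit_workflow_matrix <- function(cfg, X, y01, prep = NULL) {
  if (is.null(prep)) prep <- .workflow_prep(X, y01)
  Xs <- .prep_scaled(prep, cfg$scaler)
  sel <- seq_len(ncol(Xs))
  if (cfg$selector$method == "topk" && cfg$selector$k < ncol(Xs))
    sel <- .prep_order(prep)[seq_len(cfg$selector$k)]
  Xsel <- Xs[, sel, drop = FALSE]
  rows <- seq_len(nrow(Xsel))
  if (cfg$imbalance == "oversample") {
    tab <- table(y01)
    if (length(tab) == 2L && tab[1] != tab[2]) {
      minority <- as.integer(names(tab)[which.min(tab)])
      extra <- sample(which(y01 == minority), max(tab) - min(tab),
                      replace = TRUE)
      rows <- c(rows, extra)
    }
  }
  model <- fit_classifier(cfg$classifier, Xsel[rows, , drop = FALSE],
                          y01[rows], cfg$params)
  list(config = cfg, impute = prep$impute, keep = prep$keep,
       scaler = prep$scalers[[cfg$scaler]], selected = sel, model = model)
}

.predict_workflow_matrix <- function(wf, X) {
  for (j in seq_len(ncol(X))) {
    bad <- !is.finite(X[, j])
    if (any(bad)) X[bad, j] <- wf$impute[j]
  }
  X <- X[, wf$keep, drop = FALSE]
  X <- .scaler_apply(X, wf$scaler)
  predict_classifier(wf$model, X[, wf$selected, drop = FALSE])
}

# ---- internal validation ---------------------------------------------------

#' Internal random-split validation context
#'
#' Precomputes the patient-grouped stratified 85/15 internal splits shared
#' by every candidate workflow of one search, so candidate evaluation only
#' pays for classifier fitting.
#'
#' @param rows FeatureTable rows (training portion of an outer split)
#' @param feature_cols feature column names
#' @param n_splits number of internal splits (study value 5)
#' @param valid_frac validation fraction (study value 0.15)
#' @param seed RNG seed for the splits
#' @return internal context list
#' @export
make_internal_context <- function(rows, feature_cols, n_splits = 5L,
                                  valid_frac = 0.15, seed = 1L) {
  X <- as.matrix(rows[, feature_cols, drop = FALSE])
  y01 <- as.integer(rows$label == "dHGP")
  pat <- rows$patient_id
  plab <- tapply(y01, pat, function(v) v[1])
  pids <- names(plab)
  splits <- with_seed(seed, lapply(seq_len(n_splits), function(i) {
    va <- character(0)
    for (cl in unique(plab)) {
      p_cl <- pids[plab == cl]
      n_va <- max(1L, round(valid_frac * length(p_cl)))
      va <- c(va, sample(p_cl, n_va))
    }
    list(train = which(!(pat %in% va)), valid = which(pat %in% va))
  }))
  ctx <- list(X = X, y01 = y01, splits = splits, cache = new.env(parent = emptyenv()))
  ctx
}

#' Evaluate one candidate workflow on the internal splits
#'
#' Imputation, scaling and selection are fitted on each internal training
#' part only. Returns the mean validation metric over the splits;
#' workflows failing on any split score `NA`.
#'
#' @param config `workflow_config`
#' @param rows training rows (used when `ctx` not supplied)
#' @param feature_cols feature column names
#' @param ctx precomputed [make_internal_context()]
#' @param metric `"f1_weighted"` (default) or `"auc"`
#' @return numeric validation score
#' @export
evaluate_workflow <- function(config, rows = NULL, feature_cols = NULL,
                              ctx = NULL, metric = "f1_weighted") {
  if (is.null(ctx))
    ctx <- make_internal_context(rows, feature_cols, seed = config$seed)
  scores <- numeric(length(ctx$splits))
  for (i in seq_along(ctx$splits)) {
    sp <- ctx$splits[[i]]
    ytr <- ctx$y01[sp$train]
    if (length(unique(ytr)) < 2L || length(unique(ctx$y01[sp$valid])) < 2L)
      return(NA_real_)
    key <- paste0("prep", i)
    if (is.null(ctx$cache[[key]]))
      ctx$cache[[key]] <- .workflow_prep(ctx$X[sp$train, , drop = FALSE], ytr)
    wf <- tryCatch(
      with_seed(config$seed + i,
                .fit_workflow_matrix(config, NULL, ytr, prep = ctx$cache[[key]])),
      error = function(e) NULL)
    if (is.null(wf)) return(NA_real_)
    pv <- tryCatch(.predict_workflow_matrix(wf, ctx$X[sp$valid, , drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(pv) || anyNA(pv)) return(NA_real_)
    yv <- ctx$y01[sp$valid]
    scores[i] <- if (metric == "auc") .auc_rank(pv, yv) else .f1_weighted(pv, yv)
  }
  mean(scores)
}

.auc_rank <- function(scores, y01) {
  n1 <- sum(y01 == 1); n0 <- sum(y01 == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y01 == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.f1_weighted <- function(scores, y01, threshold = 0.5) {
  pred <- as.integer(scores >= threshold)
  f1 <- function(cl) {
    tp <- sum(pred == cl & y01 == cl)
    fp <- sum(pred == cl & y01 != cl)
    fn <- sum(pred != cl & y01 == cl)
    if (2 * tp + fp + fn == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }
  w1 <- mean(y01 == 1)
  w1 * f1(1) + (1 - w1) * f1(0)
}

# ---- search + ensemble -----------------------------------------------------

#' Random search over workflows with top-k ensembling
#'
#' Draws `n_candidates` workflows, scores each by internal random-split
#' validation on the training rows, refits the best `k` on the full
#' training rows, and averages their class probabilities. Ties in the
#' validation score are broken by draw index.
#'
#' @param rows training FeatureTable rows
#' @param feature_cols feature column names
#' @param n_candidates candidates to draw (study-scale 100,000; desk-scale
#'   default 1,000)
#' @param k ensemble size (study-scale 50; desk-scale default 10)
#' @param metric internal validation metric (`"f1_weighted"` or `"auc"`)
#' @param n_internal internal splits (study value 5)
#' @param seed RNG seed
#' @return object of class `ensemble_model`
#' @export
search_and_ensemble <- function(rows, feature_cols, n_candidates = 1000L,
                                k = 10L, metric = "f1_weighted",
                                n_internal = 5L, seed = 1L) {
  stopifnot(n_candidates >= k)
  configs <- with_seed(seed, lapply(seq_len(n_candidates), sample_workflow))
  ctx <- make_internal_context(rows, feature_cols, n_splits = n_internal,
                               seed = seed + 104729L)
  scores <- vapply(configs, evaluate_workflow, numeric(1), ctx = ctx,
                   metric = metric)
  if (all(is.na(scores)))
    stop("search_and_ensemble: all candidate workflows failed")
  ord <- order(-scores, vapply(configs, `[[`, numeric(1), "draw_index"),
               na.last = TRUE)
  top <- ord[seq_len(k)]
  top <- top[!is.na(scores[top])]
  X <- as.matrix(rows[, feature_cols, drop = FALSE])
  y01 <- as.integer(rows$label == "dHGP")
  members <- lapply(top, function(i)
    with_seed(configs[[i]]$seed, .fit_workflow_matrix(configs[[i]], X, y01)))
  structure(list(members = members, scores = scores[top],
                 configs = configs[top], feature_cols = feature_cols,
                 metric = metric, n_candidates = n_candidates, k = k),
            class = "ensemble_model")
}

#' Ensemble class-probability predictions (mean over members)
#' @param ensemble `ensemble_model`
#' @param rows FeatureTable rows
#' @return probability of the positive class (dHGP) per row
#' @export
predict_ensemble <- function(ensemble, rows) {
  Xm <- as.matrix(rows[, ensemble$feature_cols, drop = FALSE])
  p <- vapply(ensemble$members, function(m) .predict_workflow_matrix(m, Xm),
              numeric(nrow(Xm)))
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  rowMeans(p)
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat("Workflow ensemble:", length(x$members), "members (from",
      x$n_candidates, "candidates), metric:", x$metric, "\n")
  cat("  validation scores:", paste(round(x$scores, 3), collapse = ", "), "\n")
  cat("  classifiers:", paste(vapply(x$configs, `[[`, character(1),
                                     "classifier"), collapse = ", "), "\n")
  invisible(x)
}
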