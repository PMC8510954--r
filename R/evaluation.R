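# Outer evaluation: patient-grouped stratified random splits, single- and
# multi-observer designs, per-iteration metrics with corrected resampled
# t-test confidence intervals, fixed-width ROC bands, and the univariate
# statistics used for the cohort table.

#' Patient-grouped stratified random-split plan
#'
#' Each iteration draws `train_frac` of the patients per class (so the
#' dHGP:rHGP ratio is preserved within one patient); lesions always follow
#' their patient. Deterministic under `seed`.
#'
#' @param metadata lesion-level metadata (needs `patient_id`, `label`)
#' @param n_iterations number of outer iterations (study value 100)
#' @param train_frac training fraction (study value 0.8)
#' @param seed RNG seed
#' @return object of class `split_plan`: list of
#'   `list(train = patient ids, test = patient ids)`
#' @export
make_splits <- function(metadata, n_iterations = 100L, train_frac = 0.8,
                        seed = 1L) {
  pl <- unique(metadata[, c("patient_id", "label")])
  if (anyDuplicated(pl$patient_id))
    stop("make_splits: a patient has lesions with conflicting labels")
  plan <- with_seed(seed, lapply(seq_len(n_iterations), function(i) {
    tr <- character(0)
    for (cl in unique(pl$label)) {
      p_cl <- pl$patient_id[pl$label == cl]
      n_tr <- round(train_frac * length(p_cl))
      n_tr <- min(max(n_tr, 1L), length(p_cl) - 1L)
      tr <- c(tr, sample(p_cl, n_tr))
    }
    list(train = sort(tr), test = sort(setdiff(pl$patient_id, tr)))
  }))
  structure(plan, class = "split_plan", train_frac = train_frac, seed = seed)
}

#' Multi-observer training augmentation
#'
#' Returns the training rows replicated once per observer segmentation:
#' each training lesion appears `length(observers)` times (threefold for
#' the study's STUD2/PhD/RAD setting); labels and patient grouping are
#' preserved. Test rows are never augmented.
#'
#' @param rows FeatureTable rows restricted to training patients (all
#'   observers present)
#' @param observers training observers
#' @return the subset of `rows` with `observer` in `observers`
#' @export
augment_multiobserver <- function(rows, observers = c("STUD2", "PhD", "RAD")) {
  out <- rows[rows$observer %in% observers, , drop = FALSE]
  n_les <- length(unique(out$lesion_id))
  if (nrow(out) != n_les * length(observers))
    stop("augment_multiobserver: not every training lesion has every observer")
  out
}

#' Classification metrics for one iteration
#'
#' AUC from the rank statistic; accuracy, sensitivity and specificity at
#' probability threshold 0.5. The positive class is dHGP.
#'
#' @param scores class-1 probabilities
#' @param labels `"dHGP"`/`"rHGP"` vector or 0/1
#' @return named vector (auc, accuracy, sensitivity, specificity)
#' @export
compute_metrics <- function(scores, labels) {
  y01 <- if (is.numeric(labels)) as.integer(labels) else
    as.integer(labels == "dHGP")
  pred <- as.integer(scores >= 0.5)
  n1 <- sum(y01 == 1); n0 <- sum(y01 == 0)
  c(auc = .auc_rank(scores, y01),
    accuracy = mean(pred == y01),
    sensitivity = if (n1 > 0) sum(pred == 1 & y01 == 1) / n1 else NA_real_,
    specificity = if (n0 > 0) sum(pred == 0 & y01 == 0) / n0 else NA_real_)
}

#' Corrected resampled t-test confidence interval
#'
#' For k overlapping random train/test splits the per-iteration metric
#' values are positively correlated; the naive t-interval is too narrow.
#' The corrected interval inflates the variance by
#' `(1/k + n_test/n_train)` instead of `1/k`:
#' `mean +/- t_{(1+level)/2, k-1} * s * sqrt(1/k + n_test/n_train)`.
#'
#' @param values per-iteration metric values (NA allowed, dropped)
#' @param n_train,n_test training and test sample counts per iteration
#' @param level confidence level
#' @return named vector (mean, lo, hi)
#' @export
corrected_resampled_ci <- function(values, n_train, n_test, level = 0.95) {
  values <- values[!is.na(values)]
  k <- length(values)
  if (k < 2L) stop("corrected_resampled_ci: need >= 2 iterations")
  m <- mean(values)
  s <- stats::sd(values)
  half <- stats::qt((1 + level) / 2, df = k - 1) *
    s * sqrt(1 / k + n_test / n_train)
  c(mean = m, lo = m - half, hi = m + half)
}

#' Vertically averaged ROC curve with a fixed-width confidence band
#'
#' Each iteration's ROC curve is interpolated onto a common
#' false-positive-rate grid; the band half-width `w` is the smallest value
#' such that at least `level` of the curves lie inside
#' `[mean - w, mean + w]` everywhere.
#'
#' @param roc_list list of `list(scores=, labels=)` per iteration
#' @param level coverage level of the band
#' @param grid FPR grid
#' @return list with `fpr`, `tpr_mean`, `w`, and the interpolated
#'   per-iteration curve matrix
#' @export
roc_band <- function(roc_list, level = 0.95, grid = seq(0, 1, by = 0.02)) {
  curves <- vapply(roc_list, function(it) {
    y01 <- if (is.numeric(it$labels)) as.integer(it$labels) else
      as.integer(it$labels == "dHGP")
    .roc_interp(it$scores, y01, grid)
  }, numeric(length(grid)))
  if (is.null(dim(curves))) curves <- matrix(curves, ncol = 1)
  tpr_mean <- rowMeans(curves)
  dev <- apply(abs(curves - tpr_mean), 2, max)
  w <- stats::quantile(dev, level, type = 1, names = FALSE)
  list(fpr = grid, tpr_mean = tpr_mean, w = w, curves = curves)
}

# step-function ROC: TPR at each grid FPR
.roc_interp <- function(scores, y01, grid) {
  n1 <- sum(y01 == 1); n0 <- sum(y01 == 0)
  if (n1 == 0 || n0 == 0) return(rep(NA_real_, length(grid)))
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(y01[ord] == 1) / n1
  fp <- cumsum(y01[ord] == 0) / n0
  # ensure (0,0) start and tie handling: keep last point per fp value
  vapply(grid, function(g) {
    ok <- fp <= g + 1e-12
    if (!any(ok)) 0 else max(tp[ok])
  }, numeric(1))
}

#' Pearson chi-square test for a 2 x k contingency table
#'
#' No continuity correction (matches the cohort-table p-values).
#' @param counts matrix of counts
#' @return p-value
#' @export
chi_square_2xk <- function(counts) {
  counts <- as.matrix(counts)
  if (all(counts == counts[1])) return(1)
  stats::chisq.test(counts, correct = FALSE)$p.value
}

#' Two-sided Mann-Whitney U test
#' @param values_a,values_b samples from the two groups
#' @return p-value
#' @export
mann_whitney <- function(values_a, values_b) {
  stats::wilcox.test(values_a, values_b, alternative = "two.sided")$p.value
}

#' Bonferroni adjustment: p * m, capped at 1
#' @param p_values raw p-values
#' @param m number of tests (default: number of p-values)
#' @return adjusted p-values
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  pmin(p_values * m, 1)
}

# ---- experiment designs ----------------------------------------------------

#' Construct an experiment design
#'
#' Single-observer: the same observer's segmentation is used for training
#' and testing. Multi-observer: training rows carry the three human
#' observers (STUD2, PhD, RAD) and testing uses the CNN observer, mirroring
#' deployment on automated segmentations.
#'
#' @param mode `"single"` or `"multi"`
#' @param observer observer for single-observer mode
#' @param roi one of `"lesion"`, `"nlp"`, `"nlp_plus_lesion"`, `"ring"`
#' @param feature_source `"imaging"`, `"clinical"`, or
#'   `"imaging+clinical"`
#' @param robustness `"none"`, `"icc0.75"`, `"icc0.90"`,
#'   `"combat-manufacturer"`, or `"combat-protocol"`
#' @return `experiment_design` object
#' @export
experiment_design <- function(mode = c("multi", "single"), observer = "CNN",
                              roi = "lesion", feature_source = "imaging",
                              robustness = "none") {
  mode <- match.arg(mode)
  stopifnot(roi %in% c("lesion", "nlp", "nlp_plus_lesion", "ring"),
            feature_source %in% c("imaging", "clinical", "imaging+clinical"),
            robustness %in% c("none", "icc0.75", "icc0.90",
                              "combat-manufacturer", "combat-protocol"))
  if (mode == "single" && robustness %in% c("icc0.75", "icc0.90"))
    stop("ICC-based selection needs the multi-observer design")
  structure(list(mode = mode, observer = observer,
                 train_observers = if (mode == "multi")
                   c("STUD2", "PhD", "RAD") else observer,
                 test_observer = if (mode == "multi") "CNN" else observer,
                 roi = roi, feature_source = feature_source,
                 robustness = robustness),
            class = "experiment_design")
}

#' Run one experiment over a split plan
#'
#' Per outer iteration: assemble train/test rows for the design, apply the
#' robustness option (ICC filtering / ComBat fitted on the training rows
#' only), run the workflow search on the training rows, score the test
#' rows, and compute metrics. Iterations whose test set is single-class
#' have no defined AUC and are excluded from averaging (counted in the
#' result).
#'
#' @param features FeatureTable from [extract_cohort_features()]
#' @param design [experiment_design()]
#' @param splits [make_splits()] plan
#' @param n_candidates,k,metric,n_internal workflow-search budget
#' @param seed RNG seed
#' @param verbose print per-iteration progress
#' @param return_models keep the fitted per-iteration ensembles in the
#'   result (memory-heavy; used by leakage probes)
#' @return object of class `metric_summary`
#' @export
run_experiment <- function(features, design, splits, n_candidates = 1000L,
                           k = 10L, metric = "f1_weighted", n_internal = 5L,
                           seed = 1L, verbose = FALSE, return_models = FALSE) {
  rows_roi <- features[features$roi == design$roi, , drop = FALSE]
  fcols <- .design_feature_cols(features, design)
  metrics <- c("auc", "accuracy", "sensitivity", "specificity")
  per_iter <- matrix(NA_real_, length(splits), length(metrics),
                     dimnames = list(NULL, metrics))
  roc_list <- vector("list", length(splits))
  ens_list <- if (return_models) vector("list", length(splits))
  n_tr_les <- n_te_les <- numeric(length(splits))
  degenerate <- 0L
  for (i in seq_along(splits)) {
    sp <- splits[[i]]
    tr_rows <- rows_roi[rows_roi$patient_id %in% sp$train &
                          rows_roi$observer %in% design$train_observers, ,
                        drop = FALSE]
    if (design$mode == "multi")
      tr_rows <- augment_multiobserver(tr_rows, design$train_observers)
    te_rows <- rows_roi[rows_roi$patient_id %in% sp$test &
                          rows_roi$observer == design$test_observer, ,
                        drop = FALSE]
    n_tr_les[i] <- length(unique(tr_rows$lesion_id))
    n_te_les[i] <- length(unique(te_rows$lesion_id))
    use_cols <- fcols
    if (design$robustness %in% c("icc0.75", "icc0.90")) {
      thr <- if (design$robustness == "icc0.75") 0.75 else 0.90
      icc_rec <- icc_table(
        features[features$roi == design$roi &
                   features$patient_id %in% sp$train, , drop = FALSE],
        observers = design$train_observers)
      rel <- select_reliable(icc_rec, thr)
      use_cols <- intersect(use_cols, rel)
      if (length(use_cols) < 2L) use_cols <- fcols
    }
    if (design$robustness %in% c("combat-manufacturer", "combat-protocol")) {
      mode <- if (design$robustness == "combat-manufacturer") "manufacturer"
              else "protocol"
      ba_tr <- define_batches(tr_rows, mode)
      cp <- combat_fit(as.matrix(tr_rows[, use_cols, drop = FALSE]), ba_tr)
      tr_rows[, use_cols] <- combat_apply(
        as.matrix(tr_rows[, use_cols, drop = FALSE]), cp, ba_tr)
      ba_te <- list(batch = stats::setNames(
        if (mode == "manufacturer") te_rows$manufacturer else
          paste0(te_rows$manufacturer, "_",
                 ifelse(te_rows$slice_thickness > ba_tr$thickness_median,
                        "thick", "thin")),
        te_rows$lesion_id), excluded = ba_tr$excluded)
      te_rows[, use_cols] <- combat_apply(
        as.matrix(te_rows[, use_cols, drop = FALSE]), cp, ba_te)
    }
    ens <- search_and_ensemble(tr_rows, use_cols, n_candidates = n_candidates,
                               k = k, metric = metric,
                               n_internal = n_internal, seed = seed + i)
    if (return_models) ens_list[[i]] <- ens
    pv <- predict_ensemble(ens, te_rows)
    if (length(unique(te_rows$label)) < 2L) {
      degenerate <- degenerate + 1L
      next
    }
    per_iter[i, ] <- compute_metrics(pv, te_rows$label)
    roc_list[[i]] <- list(scores = pv, labels = te_rows$label)
    if (verbose)
      message(sprintf("iteration %d/%d: test AUC %.3f", i, length(splits),
                      per_iter[i, "auc"]))
  }
  summary <- do.call(rbind, lapply(metrics, function(mt) {
    ci <- corrected_resampled_ci(per_iter[, mt], mean(n_tr_les),
                                 mean(n_te_les))
    data.frame(metric = mt, mean = ci["mean"], ci_lo = ci["lo"],
               ci_hi = ci["hi"], row.names = NULL)
  }))
  structure(list(design = design, summary = summary, per_iteration = per_iter,
                 roc = roc_list[!vapply(roc_list, is.null, logical(1))],
                 n_train_lesions = mean(n_tr_les),
                 n_test_lesions = mean(n_te_les),
                 degenerate_iterations = degenerate,
                 ensembles = if (return_models) ens_list),
            class = "metric_summary")
}

.design_feature_cols <- function(features, design) {
  fc <- attr(features, "feature_cols") %||%
    intersect(feature_names(), names(features))
  cc <- grep("^clin_", names(features), value = TRUE)
  switch(design$feature_source,
         imaging = fc,
         clinical = cc,
         `imaging+clinical` = c(fc, cc))
}

#' @export
print.metric_summary <- function(x, ...) {
  cat("Design:", x$design$mode, "| roi:", x$design$roi, "| features:",
      x$design$feature_source, "| robustness:", x$design$robustness, "\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s %.2f [%.2f, %.2f]\n", s$metric[i], s$mean[i],
                s$ci_lo[i], s$ci_hi[i]))
  if (x$degenerate_iterations > 0)
    cat("  (", x$degenerate_iterations, "degenerate iterations excluded )\n")
  invisible(x)
}
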