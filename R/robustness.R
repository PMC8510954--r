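# Feature reliability across observers (ICC) and acquisition harmonization
# (ComBat).

#' Intraclass correlation coefficient, two-way random effects, absolute
#' agreement, single measurement (ICC(2,1))
#'
#' Computed from the mean squares of the lesion x observer ANOVA
#' decomposition. A matrix with zero total variance returns 1 (perfect
#' agreement on a constant).
#'
#' @param x numeric matrix, lesions (rows) x observers (columns), no missing
#'   cells
#' @return ICC value (<= 1)
#' @export
icc <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) stop("icc: need >= 2 lesions and >= 2 observers")
  if (anyNA(x)) stop("icc: missing cells not supported")
  if (stats::var(as.vector(x)) == 0) return(1)
  grand <- mean(x)
  rm_ <- rowMeans(x); cm_ <- colMeans(x)
  ssr <- k * sum((rm_ - grand)^2)
  ssc <- n * sum((cm_ - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Per-feature ICC across observers for a feature table
#'
#' @param feature_table data.frame from [extract_cohort_features()] with one
#'   row per (lesion, observer)
#' @param observers observers entering the reliability analysis; default the
#'   three human observers used for multi-observer training
#' @return data.frame (feature, icc, reliability) with reliability
#'   `excellent` (> 0.90), `good` (> 0.75) or `below-good`
#' @export
icc_table <- function(feature_table,
                      observers = c("STUD2", "PhD", "RAD")) {
  ft <- feature_table[feature_table$observer %in% observers, , drop = FALSE]
  lesions <- sort(unique(ft$lesion_id))
  fn <- intersect(feature_names(), names(ft))
  out <- data.frame(feature = fn, icc = NA_real_,
                    reliability = NA_character_, stringsAsFactors = FALSE)
  # build lesion x observer matrices feature by feature
  key <- paste(ft$lesion_id, ft$observer)
  ord <- order(match(ft$lesion_id, lesions), match(ft$observer, observers))
  ft <- ft[ord, , drop = FALSE]
  counts <- table(ft$lesion_id)
  if (length(unique(counts)) != 1L)
    stop("icc_table: unbalanced observers per lesion")
  k <- length(observers); n <- length(lesions)
  for (i in seq_along(fn)) {
    m <- matrix(ft[[fn[i]]], nrow = n, ncol = k, byrow = TRUE)
    out$icc[i] <- icc(m)
  }
  out$reliability <- ifelse(out$icc > 0.90, "excellent",
                            ifelse(out$icc > 0.75, "good", "below-good"))
  out
}

#' Select features above an ICC threshold
#'
#' @param icc_records data.frame from [icc_table()] (needs `feature`, `icc`)
#' @param threshold strict lower bound (conventional thresholds: 0.75 good,
#'   0.90 excellent)
#' @return character vector of feature names in manifest order
#' @export
select_reliable <- function(icc_records, threshold = 0.75) {
  sel <- icc_records$feature[icc_records$icc > threshold]
  intersect(feature_names(), sel)
}

#' Batch assignment for harmonization
#'
#' `mode = "manufacturer"` groups scans by manufacturer;
#' `mode = "protocol"` crosses manufacturer with slice thickness above vs
#' at-or-below the cohort median. Batches with fewer than 2 members cannot
#' support parameter estimation and are moved to `excluded` (the study's
#' single GE scan was omitted from harmonization this way).
#'
#' @param metadata data.frame with `lesion_id`, `manufacturer`,
#'   `slice_thickness`
#' @param mode `"manufacturer"` or `"protocol"`
#' @return list with `batch` (named character vector, lesion -> batch id),
#'   `excluded` (batch ids), `mode`, `thickness_median`
#' @export
define_batches <- function(metadata, mode = c("manufacturer", "protocol")) {
  mode <- match.arg(mode)
  med <- stats::median(metadata$slice_thickness)
  batch <- if (mode == "manufacturer") metadata$manufacturer else
    paste0(metadata$manufacturer, "_",
           ifelse(metadata$slice_thickness > med, "thick", "thin"))
  names(batch) <- metadata$lesion_id
  tab <- table(batch)
  excluded <- names(tab)[tab < 2L]
  list(batch = batch, excluded = excluded, mode = mode,
       thickness_median = med)
}

#' Fit ComBat harmonization parameters
#'
#' Standard parametric empirical-Bayes location/scale harmonization without
#' covariates: per-feature standardization against the pooled mean/variance,
#' per-batch location (gamma) and scale (delta) estimates shrunk towards
#' normal / inverse-gamma priors, solved by the usual iterative scheme.
#' Samples in excluded batches take no part in estimation and pass through
#' [combat_apply()] unchanged. Features with zero within-batch variance are
#' flagged and passed through.
#'
#' @param features numeric matrix (samples x features)
#' @param batches `BatchAssignment`-style list from [define_batches()], or a
#'   vector of batch labels aligned with the rows
#' @param eb use empirical-Bayes shrinkage (default). `eb = FALSE` subtracts
#'   the direct per-batch estimates, which equalizes batch means exactly.
#' @return object of class `combat_params`
#' @export
combat_fit <- function(features, batches, eb = TRUE) {
  X <- as.matrix(features)
  batch <- if (is.list(batches)) batches$batch else batches
  excluded <- if (is.list(batches)) batches$excluded else character(0)
  if (length(batch) != nrow(X)) stop("combat_fit: batch/rows mismatch")
  use <- !(batch %in% excluded)
  Xu <- X[use, , drop = FALSE]
  bu <- factor(batch[use])
  levs <- levels(bu)
  if (any(table(bu) < 2L)) stop("combat_fit: every batch needs >= 2 samples")
  nb <- length(levs)
  n <- nrow(Xu); p <- ncol(Xu)
  ni <- as.vector(table(bu))

  # feature-wise grand mean weighted by batch proportions, pooled variance
  batch_means <- apply(Xu, 2, function(col) tapply(col, bu, mean))
  if (nb == 1L) batch_means <- matrix(batch_means, nrow = 1)
  grand <- colSums(batch_means * ni / n)
  fitted <- batch_means[as.integer(bu), , drop = FALSE]
  pooled_var <- colSums((Xu - fitted)^2) / n
  degenerate <- pooled_var <= .Machine$double.eps
  pooled_var[degenerate] <- 1

  Z <- sweep(sweep(Xu, 2, grand), 2, sqrt(pooled_var), `/`)
  gamma_hat <- apply(Z, 2, function(col) tapply(col, bu, mean))
  if (nb == 1L) gamma_hat <- matrix(gamma_hat, nrow = 1)
  delta_hat <- apply(Z, 2, function(col) tapply(col, bu, stats::var))
  if (nb == 1L) delta_hat <- matrix(delta_hat, nrow = 1)
  delta_hat[!is.finite(delta_hat) | delta_hat <= 0] <- 1

  # parametric EB priors per batch (across features)
  gamma_bar <- rowMeans(gamma_hat)
  tau2 <- apply(gamma_hat, 1, stats::var)
  tau2[!is.finite(tau2) | tau2 <= 0] <- 1e-8
  a_prior <- apply(delta_hat, 1, function(d) (2 * stats::var(d) + mean(d)^2) /
                     max(stats::var(d), 1e-12))
  b_prior <- apply(delta_hat, 1, function(d) (mean(d) * stats::var(d) + mean(d)^3) /
                     max(stats::var(d), 1e-12))

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  if (nb == 1L) {
    # a single batch carries no batch effect: exact pass-through
    gamma_star[] <- 0
    delta_star[] <- 1
    eb <- FALSE
  }
  if (eb) for (i in seq_len(nb)) {
    idx <- bu == levs[i]
    zi <- Z[idx, , drop = FALSE]
    g <- gamma_hat[i, ]; d <- delta_hat[i, ]
    for (it in 1:100) {
      g_new <- (ni[i] * tau2[i] * colMeans(zi) + d * gamma_bar[i]) /
        (ni[i] * tau2[i] + d)
      sum2 <- colSums(sweep(zi, 2, g_new)^2)
      d_new <- (0.5 * sum2 + b_prior[i]) / (ni[i] / 2 + a_prior[i] - 1)
      d_new[!is.finite(d_new) | d_new <= 0] <- d[!is.finite(d_new) | d_new <= 0]
      if (max(abs(g_new - g), abs(d_new - d)) < 1e-8) { g <- g_new; d <- d_new; break }
      g <- g_new; d <- d_new
    }
    gamma_star[i, ] <- g
    delta_star[i, ] <- d
  }
  structure(list(levels = levs, excluded = excluded, grand = grand,
                 pooled_var = pooled_var, degenerate = degenerate,
                 gamma_star = gamma_star, delta_star = delta_star,
                 gamma_hat = gamma_hat, delta_hat = delta_hat,
                 feature_names = colnames(X)),
            class = "combat_params")
}

#' Apply fitted ComBat parameters
#'
#' @param features samples x features matrix (columns as in the fit)
#' @param params `combat_params` from [combat_fit()]
#' @param batches batch assignment for these rows (list or vector)
#' @return harmonized matrix, same dimensions and row order; rows in
#'   excluded or unseen batches and degenerate features pass through
#' @export
combat_apply <- function(features, params, batches) {
  X <- as.matrix(features)
  batch <- if (is.list(batches)) batches$batch else batches
  if (length(batch) != nrow(X)) stop("combat_apply: batch/rows mismatch")
  out <- X
  for (i in seq_along(params$levels)) {
    lev <- params$levels[i]
    idx <- which(batch == lev)
    if (!length(idx)) next
    Z <- sweep(sweep(X[idx, , drop = FALSE], 2, params$grand), 2,
               sqrt(params$pooled_var), `/`)
    Zs <- sweep(sweep(Z, 2, params$gamma_star[i, ]), 2,
                sqrt(params$delta_star[i, ]), `/`)
    Xs <- sweep(sweep(Zs, 2, sqrt(params$pooled_var), `*`), 2,
                params$grand, `+`)
    Xs[, params$degenerate] <- X[idx, params$degenerate, drop = FALSE]
    out[idx, ] <- Xs
  }
  out
}
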