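# The eight-member classifier set behind the workflow search. All fitters
# take a numeric matrix X and a 0/1 response (1 = positive class, dHGP) and
# return a model whose predict_classifier() yields class-1 probabilities.

sigmoid <- function(z) 1 / (1 + exp(-pmin(pmax(z, -30), 30)))

#' Fit one of the eight workflow classifiers
#'
#' @param name one of `"logistic"`, `"svm"`, `"random_forest"`,
#'   `"naive_bayes"`, `"lda"`, `"qda"`, `"adaboost"`, `"gradient_boosting"`
#' @param X numeric matrix (samples x features)
#' @param y01 0/1 response (1 = dHGP)
#' @param params named list of hyperparameters (see [workflow_priors()])
#' @return classifier model object for [predict_classifier()]
#' @export
fit_classifier <- function(name, X, y01, params = list()) {
  X <- as.matrix(X)
  if (length(unique(y01)) < 2L)
    return(structure(list(name = "constant", p = mean(y01)),
                     class = "hgp_classifier"))
  fit <- switch(name,
    logistic = .fit_logistic(X, y01, params),
    svm = .fit_lssvm(X, y01, params),
    random_forest = .fit_rf(X, y01, params),
    naive_bayes = .fit_gnb(X, y01, params),
    lda = .fit_da(X, y01, params, quadratic = FALSE),
    qda = .fit_da(X, y01, params, quadratic = TRUE),
    adaboost = .fit_adaboost(X, y01, params),
    gradient_boosting = .fit_gbm(X, y01, params),
    stop("unknown classifier: ", name))
  fit$name <- name
  structure(fit, class = "hgp_classifier")
}

#' Class-1 probability predictions
#' @param model from [fit_classifier()]
#' @param X samples x features matrix
#' @return numeric vector of probabilities
#' @export
predict_classifier <- function(model, X) {
  X <- as.matrix(X)
  switch(model$name,
    constant = rep(model$p, nrow(X)),
    logistic = .pred_logistic(model, X),
    svm = .pred_lssvm(model, X),
    random_forest = pmin(pmax(cpp_predict_forest(model$forest, X), 0), 1),
    naive_bayes = .pred_gnb(model, X),
    lda = ,
    qda = .pred_da(model, X),
    adaboost = .pred_adaboost(model, X),
    gradient_boosting = .pred_gbm(model, X),
    stop("unknown model"))
}

# ---- logistic regression (elastic net via glmnet) -------------------------

.fit_logistic <- function(X, y, p) {
  alpha <- p$alpha %||% 0
  lambda <- p$lambda %||% 0.01
  if (ncol(X) < 2L) {
    df <- data.frame(y = y, x = X[, 1])
    return(list(glm = stats::glm(y ~ x, df, family = stats::binomial())))
  }
  # glmnet warns when a class has < 8 observations; routine at desk scale
  fit <- suppressWarnings(
    glmnet::glmnet(X, factor(y), family = "binomial", alpha = alpha,
                   lambda = lambda, standardize = FALSE))
  list(glmnet = fit, lambda = lambda)
}

.pred_logistic <- function(m, X) {
  if (!is.null(m[["glm"]]))
    return(as.vector(stats::predict(m$glm, data.frame(x = X[, 1]),
                                    type = "response")))
  as.vector(stats::predict(m$glmnet, X, s = m$lambda, type = "response"))
}

# ---- least-squares SVM (kernel ridge on +/-1 labels, Platt-style
#      probability calibration on the training decision values) ------------

.kernel_mat <- function(A, B, kernel, gamma) {
  if (kernel == "linear") return(A %*% t(B))
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, `+`) - 2 * A %*% t(B)
  exp(-gamma * pmax(d2, 0))
}

.fit_lssvm <- function(X, y, p) {
  kernel <- p$kernel %||% "rbf"
  gamma <- p$gamma %||% (1 / ncol(X))
  C <- p$C %||% 1
  ypm <- 2 * y - 1
  n <- nrow(X)
  K <- .kernel_mat(X, X, kernel, gamma)
  A <- rbind(c(0, rep(1, n)), cbind(1, K + diag(n) / C))
  sol <- tryCatch(solve(A, c(0, ypm)),
                  error = function(e) qr.solve(A, c(0, ypm), tol = 1e-12))
  b <- sol[1]; alpha <- sol[-1]
  f <- as.vector(K %*% alpha + b)
  platt <- tryCatch(
    stats::glm(y ~ f, data.frame(y = y, f = f), family = stats::binomial()),
    warning = function(w) NULL, error = function(e) NULL)
  list(Xtr = X, alpha = alpha, b = b, kernel = kernel, gamma = gamma,
       platt = platt)
}

.pred_lssvm <- function(m, X) {
  K <- .kernel_mat(X, m$Xtr, m$kernel, m$gamma)
  f <- as.vector(K %*% m$alpha + m$b)
  if (!is.null(m$platt))
    as.vector(stats::predict(m$platt, data.frame(f = f), type = "response"))
  else sigmoid(2 * f)
}

# ---- random forest ---------------------------------------------------------

.fit_rf <- function(X, y, p) {
  ntree <- p$ntree %||% 50L
  mtry <- max(1L, round((p$mtry_sqrt_mult %||% 1) * sqrt(ncol(X))))
  list(forest = cpp_fit_forest(X, as.numeric(y), as.integer(ntree),
                               as.integer(mtry),
                               as.integer(p$max_depth %||% 6L),
                               as.integer(p$min_leaf %||% 2L),
                               p$sample_frac %||% 1))
}

# ---- Gaussian naive Bayes --------------------------------------------------

.fit_gnb <- function(X, y, p) {
  col_var <- function(M) {
    n <- nrow(M)
    (colSums(M^2) - n * colMeans(M)^2) / max(n - 1, 1)
  }
  eps <- 1e-9 * max(col_var(X), 1e-12)
  stats_by <- lapply(c(0, 1), function(cl) {
    Xi <- X[y == cl, , drop = FALSE]
    list(mu = colMeans(Xi), var = col_var(Xi) + eps, prior = mean(y == cl))
  })
  list(cls = stats_by)
}

.pred_gnb <- function(m, X) {
  ll <- vapply(m$cls, function(s) {
    lv <- sweep(sweep(X, 2, s$mu)^2, 2, 2 * s$var, `/`)
    -rowSums(lv) - 0.5 * sum(log(2 * pi * s$var)) + log(s$prior)
  }, numeric(nrow(X)))
  if (is.null(dim(ll))) ll <- matrix(ll, 1)
  1 / (1 + exp(pmin(pmax(ll[, 1] - ll[, 2], -700), 700)))
}

# ---- linear / quadratic discriminant analysis -----------------------------

.fit_da <- function(X, y, p, quadratic) {
  colnames(X) <- paste0("V", seq_len(ncol(X)))
  rot <- NULL
  if (ncol(X) > nrow(X) - 5L) {
    # p ~ n makes the within-class covariance singular; project onto the
    # leading principal components first
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE,
                        rank. = max(2L, nrow(X) - 5L))
    rot <- list(center = pc$center, rotation = pc$rotation)
    X <- pc$x
    colnames(X) <- paste0("V", seq_len(ncol(X)))
  }
  # trailing principal components can be near-constant; MASS then warns
  # about collinearity, which is expected here
  fit <- suppressWarnings(
    if (quadratic) MASS::qda(X, grouping = factor(y))
    else MASS::lda(X, grouping = factor(y)))
  list(da = fit, cols = colnames(X), rot = rot)
}

.pred_da <- function(m, X) {
  if (!is.null(m$rot))
    X <- sweep(X, 2, m$rot$center) %*% m$rot$rotation
  colnames(X) <- m$cols
  pr <- stats::predict(m$da, X)$posterior
  as.vector(pr[, "1"])
}

# ---- AdaBoost (discrete, shallow trees; C++ loop) -------------------------

.fit_adaboost <- function(X, y, p) {
  M <- p$n_rounds %||% 50L
  depth <- p$max_depth %||% 1L
  mtry <- min(ncol(X), 64L)  # feature subsampling keeps wide inputs cheap
  fit <- cpp_fit_adaboost(X, as.numeric(y), as.integer(M),
                          as.integer(depth), as.integer(mtry))
  list(trees = fit$trees, alphas = fit$alphas)
}

.pred_adaboost <- function(m, X) {
  F <- rep(0, nrow(X))
  for (i in seq_along(m$trees)) {
    pred <- ifelse(cpp_predict_tree(m$trees[[i]], X) >= 0.5, 1, -1)
    F <- F + m$alphas[i] * pred
  }
  sigmoid(2 * F)
}

# ---- gradient boosting (logistic loss, per-leaf Newton steps; C++ loop) ---

.fit_gbm <- function(X, y, p) {
  M <- p$n_rounds %||% 50L
  depth <- p$max_depth %||% 2L
  nu <- p$learning_rate %||% 0.1
  mtry <- min(ncol(X), 64L)
  fit <- cpp_fit_gbm(X, as.numeric(y), as.integer(M), as.integer(depth),
                     nu, as.integer(mtry))
  list(trees = fit$trees, F0 = fit$F0, nu = nu)
}

.pred_gbm <- function(m, X) {
  F <- rep(m$F0, nrow(X))
  for (tr in m$trees) F <- F + m$nu * cpp_predict_tree(tr, X)
  sigmoid(F)
}
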