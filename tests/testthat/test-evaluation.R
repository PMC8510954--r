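test_that("make_splits is patient-disjoint, stratified and deterministic", {
  md <- data.frame(patient_id = sprintf("P%03d", 1:76),
                   label = rep(c("dHGP", "rHGP"), c(37, 39)))
  md <- md[rep(seq_len(76), times = rep(c(1, 2), length.out = 76)), ]
  md$lesion_id <- sprintf("L%03d", seq_len(nrow(md)))
  sp <- make_splits(md, n_iterations = 100L, train_frac = 0.8, seed = 4)
  expect_length(sp, 100L)
  glob_ratio <- 37 / 76
  for (it in sp) {
    expect_length(intersect(it$train, it$test), 0L)
    expect_setequal(c(it$train, it$test), unique(md$patient_id))
    # round(0.8 * n) per class: 30 + 31 train patients
    expect_equal(length(it$train), round(0.8 * 37) + round(0.8 * 39))
    n_d <- sum(it$test %in% md$patient_id[md$label == "dHGP"])
    expect_lte(abs(n_d / length(it$test) - glob_ratio) * length(it$test), 1.5)
  }
  expect_identical(sp, make_splits(md, 100L, 0.8, seed = 4))
  expect_error(make_splits(data.frame(patient_id = c("a", "a"),
                                      label = c("dHGP", "rHGP"))),
               "conflicting")
})

test_that("multi-observer augmentation triples training rows and leaves
           test rows to the CNN", {
  base <- fake_rows(n_patients = 10, per_patient = 1, p = 3)
  rows <- do.call(rbind, lapply(c("STUD2", "PhD", "RAD", "CNN"), function(o) {
    r <- base; r$observer <- o; r
  }))
  aug <- augment_multiobserver(rows)
  expect_equal(nrow(aug), 3 * length(unique(rows$lesion_id)))
  per_lesion <- tapply(aug$observer, aug$lesion_id, sort)
  for (obs in per_lesion)
    expect_identical(unname(obs), c("PhD", "RAD", "STUD2"))
  expect_false(any(aug$observer == "CNN"))
  # single-observer mode: identity on the rows of that observer
  single <- augment_multiobserver(rows, "CNN")
  expect_identical(single, rows[rows$observer == "CNN", ])
  expect_error(augment_multiobserver(rows[-1, ]), "every training lesion")
})

test_that("compute_metrics matches the exhaustive concordant-pair oracle", {
  auc_oracle <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    conc <- 0
    for (a in pos) for (b in neg)
      conc <- conc + (a > b) + 0.5 * (a == b)
    conc / (length(pos) * length(neg))
  }
  withr::with_seed(6, for (i in 1:40) {
    y <- sample(0:1, 10, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- round(stats::runif(10), 2)   # rounded to force some ties
    m <- compute_metrics(s, y)
    expect_equal(unname(m["auc"]), auc_oracle(s, y), tolerance = 1e-12)
    expect_equal(unname(m["accuracy"]), mean((s >= 0.5) == y))
  })
  m <- compute_metrics(c(0.9, 0.8, 0.2, 0.1), c("dHGP", "dHGP", "rHGP", "rHGP"))
  expect_identical(unname(m), c(1, 1, 1, 1))      # perfect separation
})

test_that("random scores give AUC near 0.5 at large n", {
  withr::with_seed(12, {
    y <- rep(0:1, each = 2500)
    s <- stats::runif(5000)
    expect_equal(unname(compute_metrics(s, y)["auc"]), 0.5, tolerance = 0.03)
  })
})

test_that("corrected resampled CI matches the closed form", {
  # independent re-implementation of the formula
  oracle <- function(v, ntr, nte, level = 0.95) {
    k <- length(v)
    mean(v) + c(-1, 1) * stats::qt((1 + level) / 2, k - 1) * stats::sd(v) *
      sqrt(1 / k + nte / ntr)
  }
  withr::with_seed(2, for (i in 1:10) {
    v <- stats::runif(100, 0.5, 0.9)
    ci <- corrected_resampled_ci(v, n_train = 80, n_test = 20)
    expect_equal(unname(ci[c("lo", "hi")]), oracle(v, 80, 20),
                 tolerance = 1e-12)
    # corrected CI strictly wider than the naive t interval
    naive_half <- stats::qt(0.975, 99) * stats::sd(v) / sqrt(100)
    expect_gt(ci["hi"] - ci["mean"], naive_half)
  })
  # k=100, n_test/n_train = 0.25: half-width ratio = sqrt(26) ~ 5.10
  v <- withr::with_seed(3, stats::runif(100))
  ci <- corrected_resampled_ci(v, n_train = 100, n_test = 25)
  naive_half <- stats::qt(0.975, 99) * stats::sd(v) * sqrt(1 / 100)
  expect_equal(unname((ci["hi"] - ci["mean"]) / naive_half), sqrt(26),
               tolerance = 1e-12)
  # all-equal values: zero-width interval at the value
  ci0 <- corrected_resampled_ci(rep(0.7, 50), 80, 20)
  expect_identical(unname(ci0), c(0.7, 0.7, 0.7))
  expect_error(corrected_resampled_ci(0.5, 80, 20), "2 iterations")
})

test_that("roc_band covers its inputs and degenerates to zero width", {
  mk <- function(auc_ish, seed) withr::with_seed(seed, {
    y <- rep(0:1, each = 30)
    s <- stats::rnorm(60, mean = y * auc_ish)
    list(scores = s, labels = y)
  })
  rl <- lapply(1:20, function(i) mk(1.2, i))
  rb <- roc_band(rl)
  # by construction at least 95% of curves lie fully inside the band
  inside <- vapply(seq_len(ncol(rb$curves)), function(j)
    all(abs(rb$curves[, j] - rb$tpr_mean) <= rb$w + 1e-12), logical(1))
  expect_gte(mean(inside), 0.95)
  # monotone mean curve from monotone step inputs
  expect_true(all(diff(rb$tpr_mean) >= -1e-12))
  # identical iterations: w = 0
  rb0 <- roc_band(rep(list(mk(1, 99)), 10))
  expect_equal(rb0$w, 0)
})

test_that("chi-square p-values reproduce the cohort-table values", {
  expect_equal(chi_square_2xk(matrix(c(24, 13, 20, 19), 2)), 0.23,
               tolerance = 0.005)
  expect_equal(chi_square_2xk(matrix(c(18, 19, 17, 22), 2)), 0.66,
               tolerance = 0.005)
  expect_equal(chi_square_2xk(matrix(c(10, 10, 5, 5), 2)), 1)
  expect_equal(chi_square_2xk(matrix(c(5, 5, 5, 5, 5, 5), 2)), 1)
})

test_that("mann_whitney matches exhaustive permutation enumeration at 3v3", {
  a <- c(1.3, 2.1, 0.4); b <- c(3.0, 2.6, 1.9)
  p <- mann_whitney(a, b)
  # enumerate all 20 assignments of 6 values into two groups of 3
  vals <- c(a, b)
  u_stat <- function(x, y) sum(outer(x, y, `>`)) + 0.5 * sum(outer(x, y, `==`))
  obs <- u_stat(a, b)
  n1 <- length(a)
  combs <- utils::combn(6, 3)
  us <- apply(combs, 2, function(ix) u_stat(vals[ix], vals[-ix]))
  mu <- n1 * n1 / 2
  p_exact <- mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
  expect_equal(p, p_exact, tolerance = 1e-12)
  # identical large samples -> p ~ 1
  z <- stats::rnorm(200)
  expect_gt(mann_whitney(z, z), 0.99)
  # shifted alternative is detected
  withr::with_seed(4, {
    x <- stats::rnorm(200); y <- stats::rnorm(200, 1)
    expect_lt(mann_whitney(x, y), 1e-3)
  })
})

test_that("bonferroni multiplies and caps", {
  expect_equal(bonferroni(0.001, m = 564), 0.564)
  expect_equal(bonferroni(0.01, m = 564), 1)
  expect_identical(bonferroni(c(0.2, 0.9)), pmin(c(0.2, 0.9) * 2, 1))
  expect_equal(bonferroni(0.03, m = 1), 0.03)
})
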