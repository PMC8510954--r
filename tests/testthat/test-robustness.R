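test_that("icc matches the ANOVA mean-squares oracle to 1e-10", {
  icc_oracle <- function(x) {
    n <- nrow(x); k <- ncol(x)
    df <- data.frame(y = as.vector(x),
                     r = factor(rep(seq_len(n), k)),
                     c = factor(rep(seq_len(k), each = n)))
    ms <- summary(stats::aov(y ~ r + c, df))[[1]][["Mean Sq"]]
    (ms[1] - ms[3]) / (ms[1] + (k - 1) * ms[3] + k * (ms[2] - ms[3]) / n)
  }
  withr::with_seed(5, for (i in 1:25) {
    x <- matrix(stats::rnorm(15), 5, 3)
    expect_lt(abs(icc(x) - icc_oracle(x)), 1e-10)
  })
})

test_that("icc recovers known variance components and edge cases", {
  withr::with_seed(8, {
    les <- stats::rnorm(200, 0, sqrt(3))
    x <- vapply(1:3, function(o) les + stats::rnorm(200), numeric(200))
  })
  expect_equal(icc(x), 0.75, tolerance = 0.05)   # 3 / (3 + 1)
  # identical observers, varying lesions
  same <- matrix(rep(stats::rnorm(10), 3), 10, 3)
  expect_equal(icc(same), 1)
  # constant matrix: perfect agreement by convention
  expect_equal(icc(matrix(2, 6, 3)), 1)
  # column permutation invariance
  expect_equal(icc(x), icc(x[, c(3, 1, 2)]))
  expect_error(icc(matrix(1, 1, 3)), "need")
})

test_that("select_reliable thresholds strictly and nests", {
  rec <- data.frame(feature = feature_names()[1:4],
                    icc = c(0.96, 0.80, 0.75, 0.40))
  expect_identical(select_reliable(rec, 0.75), feature_names()[1:2])
  expect_identical(select_reliable(rec, 0.90), feature_names()[1])
  expect_true(all(select_reliable(rec, 0.90) %in% select_reliable(rec, 0.75)))
})

test_that("icc_table recovers a constructed two-tier reliability split", {
  withr::with_seed(3, {
    n_les <- 60
    fn <- feature_names()
    reliable <- fn[1:5]; noisy <- fn[6:10]
    les_eff <- matrix(stats::rnorm(n_les * 10), n_les, 10)
    rows <- list()
    for (obs in c("STUD2", "PhD", "RAD")) {
      X <- les_eff + cbind(matrix(stats::rnorm(n_les * 5, 0, 0.1), n_les, 5),
                           matrix(stats::rnorm(n_les * 5, 0, 3), n_les, 5))
      df <- data.frame(lesion_id = sprintf("L%02d", 1:n_les), observer = obs)
      colnames(X) <- fn[1:10]
      rows[[obs]] <- cbind(df, as.data.frame(X))
    }
    ft <- do.call(rbind, rows)
  })
  rec <- icc_table(ft)
  expect_identical(rec$feature, fn[1:10])
  expect_true(all(rec$icc[rec$feature %in% reliable] > 0.9))
  expect_true(all(rec$icc[rec$feature %in% noisy] < 0.75))
  expect_identical(select_reliable(rec, 0.90), reliable)
})

test_that("define_batches handles the manufacturer distribution and
           singleton exclusion", {
  md <- data.frame(
    lesion_id = sprintf("L%02d", 1:76),
    manufacturer = rep(c("Siemens", "Philips", "Toshiba", "GE"),
                       c(43, 16, 16, 1)),
    slice_thickness = rep(c(3, 5), length.out = 76))
  ba <- define_batches(md, "manufacturer")
  expect_identical(ba$excluded, "GE")             # the single GE scan
  expect_identical(unname(ba$batch[1]), "Siemens")
  bp <- define_batches(md, "protocol")
  expect_identical(bp$thickness_median, stats::median(md$slice_thickness))
  expect_true(all(grepl("_(thick|thin)$", bp$batch)))
  # thickness above the median -> "thick"
  expect_identical(unname(bp$batch[md$slice_thickness > bp$thickness_median][1]),
                   paste0(md$manufacturer[md$slice_thickness >
                                            bp$thickness_median][1], "_thick"))
})

test_that("ComBat removes an additive offset and passes through degenerate
           cases", {
  withr::with_seed(7, {
    X <- matrix(stats::rnorm(200 * 20), 200, 20)
    b <- rep(c("A", "B"), each = 100)
    X[b == "B", ] <- X[b == "B", ] + 5
  })
  # direct adjustment equalises batch means exactly
  pf <- combat_fit(X, b, eb = FALSE)
  Xh <- combat_apply(X, pf, b)
  expect_lt(max(abs(colMeans(Xh[b == "A", ]) - colMeans(Xh[b == "B", ]))),
            1e-6)
  expect_identical(dim(Xh), dim(X))
  # EB estimates recover the injected location shift on the standardised
  # scale (offset 5 / pooled sd ~ sqrt(1 + 25/4) ... measured directly:
  # gamma separation times pooled sd equals ~5 in raw units)
  pe <- combat_fit(X, b, eb = TRUE)
  raw_sep <- mean((pe$gamma_hat[2, ] - pe$gamma_hat[1, ]) *
                    sqrt(pe$pooled_var))
  expect_equal(raw_sep, 5, tolerance = 0.2)
  # single batch: exact pass-through
  p1 <- combat_fit(X[b == "A", ], rep("A", 100))
  expect_equal(combat_apply(X[b == "A", ], p1, rep("A", 100)), X[b == "A", ],
               tolerance = 1e-12)
  # zero-variance feature passes through
  X2 <- X; X2[, 3] <- 7
  p2 <- combat_fit(X2, b)
  expect_true(p2$degenerate[3])
  expect_identical(combat_apply(X2, p2, b)[, 3], X2[, 3])
  # excluded batches pass through unchanged
  md <- data.frame(lesion_id = sprintf("L%03d", 1:201),
                   manufacturer = c(rep(c("A", "B"), each = 100), "GE"),
                   slice_thickness = 3)
  X3 <- rbind(X, stats::rnorm(20))
  ba <- define_batches(md, "manufacturer")
  p3 <- combat_fit(X3, ba)
  X3h <- combat_apply(X3, p3, ba)
  expect_identical(X3h[201, ], X3[201, ])
  expect_error(combat_fit(X3[1:3, ], c("A", "A", "B")), ">= 2")
})

test_that("after harmonization, null-class between-batch F-tests lose
           significance", {
  withr::with_seed(19, {
    n <- 150; p <- 40
    X <- matrix(stats::rnorm(n * p), n, p)
    b <- sample(c("A", "B", "C"), n, replace = TRUE)
    shift <- c(A = 0, B = 3, C = -2)
    X <- X + matrix(shift[b], n, p)
  })
  pvals_of <- function(M) vapply(seq_len(ncol(M)), function(j)
    stats::anova(stats::lm(M[, j] ~ b))$`Pr(>F)`[1], numeric(1))
  expect_lt(stats::median(pvals_of(X)), 1e-6)     # batch clearly present
  Xh <- combat_apply(X, combat_fit(X, b), b)
  expect_gt(stats::median(pvals_of(Xh)), 0.05)    # removed
})
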