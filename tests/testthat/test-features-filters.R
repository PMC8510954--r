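test_that("LBP codes are invariant to intensity offset and match a
           hand-enumerated bright-pixel neighbourhood", {
  sl <- matrix(0, 24, 24)
  sl[12, 12] <- 10
  code <- hgpradiomics:::lbp_slice(sl, radius = 1, n_neighbours = 8L)
  inner <- code[!is.na(code)]
  # flat field: every sampled neighbour equals the centre -> all bits set
  expect_true(all(inner %in% c(0, 255)))
  expect_equal(sum(inner == 0), 1)            # only the bright pixel itself
  expect_equal(code[12, 12], 0)
  # constant offset leaves every code unchanged (sign-based coding)
  code2 <- hgpradiomics:::lbp_slice(sl + 42, 1, 8L)
  expect_identical(code, code2)
})

test_that("Gabor responses are orientation-selective and permute under
           rotation", {
  d <- c(48, 48, 5)
  sl <- matrix(sin(2 * pi * 0.2 * (1:48)), 48, 48, byrow = TRUE)  # along cols
  vol <- array(rep(sl, d[3]), d)
  msk <- array(FALSE, d); msk[13:36, 13:36, 2:4] <- TRUE
  fv <- gabor_features(vol, msk)
  expect_gt(fv["gabor_f0.2_a0_mean_mean"], 2 * fv["gabor_f0.2_a90_mean_mean"])
  # transposing each slice maps angle 0 <-> 90
  volT <- aperm(vol, c(2, 1, 3))
  mskT <- aperm(msk, c(2, 1, 3))
  fvT <- gabor_features(volT, mskT)
  expect_equal(unname(fvT["gabor_f0.2_a90_mean_mean"]),
               unname(fv["gabor_f0.2_a0_mean_mean"]), tolerance = 1e-8)
  # constant image: zero-DC kernels give (near) zero band-pass response
  fc <- gabor_features(array(5, d), msk)
  expect_lt(max(abs(fc[grep("_mean_mean$", names(fc))])), 1e-8)
})

test_that("LoG responses match the analytic kernel and select scale", {
  for (sg in c(1, 5)) {
    d <- 2 * ceiling(3 * sg) + 15
    sl <- matrix(0, d, d); sl[(d + 1) / 2, (d + 1) / 2] <- 1
    resp <- hgpradiomics:::conv2_fft(sl, hgpradiomics:::log_kernel(sg))
    analytic <- -1 / (pi * sg^2)  # scale-normalised LoG at the origin
    expect_equal(resp[(d + 1) / 2, (d + 1) / 2], analytic, tolerance = 5e-3)
  }
  # a disc of radius R maximises |response| near sigma = R/sqrt(2)
  d <- c(70, 70, 3)
  vol <- array(0, d)
  cc <- 35.5
  for (z in 1:3) vol[, , z] <- outer(1:70, 1:70, function(i, j)
    as.numeric((i - cc)^2 + (j - cc)^2 <= 7^2))
  msk <- array(FALSE, d); msk[33:38, 33:38, 2] <- TRUE
  fv <- log_features(vol, msk)
  peak <- abs(c(s1 = fv[["log_sigma1_mean_mean"]],
                s5 = fv[["log_sigma5_mean_mean"]],
                s10 = fv[["log_sigma10_mean_mean"]]))
  expect_identical(names(which.max(peak)), "s5")   # 7 / sqrt(2) ~ 4.9
  # constant image -> exactly zero response
  fz <- log_features(array(3, c(40, 40, 6)),
                     ball_mask(c(40, 40, 6), radius = c(8, 8, 2)))
  expect_lt(max(abs(fz[grep("_mean_mean$", names(fz))])), 1e-10)
})

test_that("vesselness highlights a bright tube and the edge/inner split
           partitions the mask", {
  d <- c(40, 40, 6)
  vol <- array(0, d)
  vol[, 19:20, ] <- 10                      # bright vertical tube
  msk <- array(FALSE, d); msk[8:32, 8:32, 2:5] <- TRUE
  fv <- vessel_features(vol, msk)
  expect_gt(fv[["vessel_full_mean_mean"]], 0)
  flat <- vessel_features(array(1, d), msk)
  expect_equal(unname(flat[["vessel_full_mean_mean"]]), 0)
  # partition: edge and inner are disjoint and cover the slice mask
  ms <- msk[, , 3]
  inner <- hgpradiomics:::.erode2d(ms, 2L)
  edge <- ms & !inner
  expect_identical(edge | inner, ms)
  expect_false(any(edge & inner))
})

test_that("local phase is contrast-invariant and flags a step edge", {
  sl <- matrix(0, 48, 48); sl[, 25:48] <- 10   # vertical step edge
  ph1 <- hgpradiomics:::monogenic_slice(sl)
  ph5 <- hgpradiomics:::monogenic_slice(5 * sl)
  for (nm in c("phase", "congruency", "symmetry"))
    expect_equal(ph1[[nm]], ph5[[nm]], tolerance = 1e-9)
  # congruency concentrates at the edge; symmetry is low there (odd-dominant)
  edge_cols <- 23:26; far_cols <- c(5:12, 37:44)
  expect_gt(mean(ph1$congruency[10:39, edge_cols]),
            mean(ph1$congruency[10:39, far_cols]))
  expect_lt(mean(ph1$symmetry[10:39, edge_cols]),
            mean(ph1$symmetry[10:39, far_cols]))
  # degenerate constant input stays finite
  ph0 <- hgpradiomics:::monogenic_slice(matrix(2, 32, 32))
  expect_true(all(vapply(ph0, function(m) all(is.finite(m)), logical(1))))
})

test_that("first-order and shape features behave under shift and scaling", {
  vol <- noise_volume(c(40, 40, 16))
  msk <- ball_mask(c(40, 40, 16), radius = c(9, 9, 5))
  sp <- c(0.7, 0.7, 3)
  f0 <- histogram_shape_features(vol, msk, sp)
  f1 <- histogram_shape_features(vol + 25, msk, sp)
  expect_equal(f1[["intensity_mean"]], f0[["intensity_mean"]] + 25)
  expect_equal(f1[["intensity_sd"]], f0[["intensity_sd"]])
  shape_cols <- grep("^shape_", names(f0), value = TRUE)
  expect_equal(f1[shape_cols], f0[shape_cols])     # shape ignores intensity
  expect_equal(f0[["shape_n_voxels"]], sum(msk))
  expect_equal(f0[["shape_volume_mm3"]], sum(msk) * prod(sp))
  # a ball is more compact than an elongated box of similar volume
  box <- array(FALSE, c(40, 40, 16)); box[5:36, 18:22, 4:13] <- TRUE
  fb <- histogram_shape_features(vol, box, sp)
  expect_gt(f0[["shape_sphericity"]], fb[["shape_sphericity"]])
  # with isotropic spacing the in-plane symmetric ball has equal leading axes
  f_iso <- histogram_shape_features(vol, msk, c(1, 1, 1))
  expect_equal(f_iso[["shape_elongation"]], 1, tolerance = 1e-6)
})

test_that("extract_all returns 564 deterministic, translation-invariant
           features", {
  d <- c(72, 72, 12)
  vol <- array(100, d)
  content <- noise_volume(c(20, 20, 6), seed = 4)
  vol[27:46, 27:46, 4:9] <- content
  msk <- array(FALSE, d)
  msk[30:43, 30:43, 5:8] <- ball_mask(c(14, 14, 4), radius = c(6, 6, 2))
  sp <- c(0.74, 0.74, 5)
  fv <- extract_all(vol, msk, sp)
  expect_length(fv, 564L)
  expect_identical(names(fv), feature_names())
  expect_true(all(is.finite(fv)))
  expect_identical(fv, extract_all(vol, msk, sp))      # deterministic
  # whole-voxel translation of image and mask inside the constant background
  sh <- c(2, 3, 1)
  volS <- array(100, d); mskS <- array(FALSE, d)
  volS[27:46 + sh[1], 27:46 + sh[2], 4:9 + sh[3]] <- content
  mskS[(30:43) + sh[1], (30:43) + sh[2], (5:8) + sh[3]] <-
    ball_mask(c(14, 14, 4), radius = c(6, 6, 2))
  fvS <- extract_all(volS, mskS, sp)
  # shape bbox etc are position-independent; filters see identical context
  expect_equal(fvS, fv, tolerance = 1e-6)
  expect_error(extract_all(vol, array(FALSE, d)), "empty")
})
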