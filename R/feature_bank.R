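# Radiomics feature bank.
#
# Texture/filter features are computed in 2-D per axial slice intersecting
# the mask and aggregated over slices (mean, sd), matching segmentations
# drawn per transverse slice and the anisotropic CT spacing; first-order
# intensity and shape features are computed on the full 3-D ROI.

# ---- quantization ---------------------------------------------------------

#' Equal-width gray-level quantization
#'
#' Bins `[min, max]` of the ROI intensities into `n_levels` levels,
#' returning 0-based integer levels. A constant ROI maps to level 0.
#'
#' @param roi_intensities numeric vector/array of intensities within the ROI
#' @param n_levels number of gray levels (>= 2)
#' @return integer array/vector of levels in `0 .. n_levels-1`
#' @export
quantize <- function(roi_intensities, n_levels = 16L) {
  stopifnot(n_levels >= 2L, length(roi_intensities) > 0L)
  r <- range(roi_intensities)
  if (r[1] == r[2]) {
    out <- roi_intensities
    out[] <- 0L
    return(out)
  }
  q <- floor((roi_intensities - r[1]) / (r[2] - r[1]) * n_levels)
  q[q >= n_levels] <- n_levels - 1L
  storage.mode(q) <- "integer"
  q
}

# ---- response-map statistics ----------------------------------------------

# the 9 per-map statistics used by all filter families
map_stat_vec <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L)
    return(stats::setNames(rep(0, length(.map_stats)), .map_stats))
  out <- c(mean = mean(x), sd = if (length(x) > 1L) stats::sd(x) else 0,
           min = min(x), max = max(x), median = stats::median(x),
           skewness = .skewness(x), kurtosis = .kurtosis(x),
           entropy = .hist_entropy(x), energy = mean(x^2))
  .finite_or_zero(out)
}

# aggregate a (n_slices x n_stats) matrix over slices into mean/sd pairs,
# named <prefix>_<stat>_<agg>
.agg_slices <- function(mat, prefix) {
  if (is.null(mat) || nrow(mat) == 0L) {
    nm <- as.vector(outer(.map_stats, .slice_aggs,
                          function(s, g) paste0(prefix, "_", s, "_", g)))
    return(stats::setNames(rep(0, length(nm)), nm))
  }
  mn <- colMeans(mat)
  sdv <- if (nrow(mat) > 1L) apply(mat, 2, stats::sd) else rep(0, ncol(mat))
  out <- c(rbind(mn, sdv))
  names(out) <- as.vector(vapply(colnames(mat), function(s)
    c(paste0(prefix, "_", s, "_mean"), paste0(prefix, "_", s, "_sd")),
    character(2)))
  .finite_or_zero(out)
}

# ---- kernels ---------------------------------------------------------------

.kernel_cache <- new.env(parent = emptyenv())

.cached <- function(key, build) {
  if (is.null(.kernel_cache[[key]])) .kernel_cache[[key]] <- build()
  .kernel_cache[[key]]
}

gabor_kernel <- function(freq, angle_deg) .cached(
  sprintf("gab_%g_%g", freq, angle_deg), function() {
  sigma <- 0.56 / freq
  r <- ceiling(2.5 * sigma)
  cc <- matrix(-r:r, 2 * r + 1, 2 * r + 1, byrow = TRUE)  # column offset
  rr <- matrix(-r:r, 2 * r + 1, 2 * r + 1)                # row offset
  th <- angle_deg * pi / 180
  xr <- cc * cos(th) + rr * sin(th)
  yr <- -cc * sin(th) + rr * cos(th)
  env <- exp(-(xr^2 + yr^2) / (2 * sigma^2))
  re <- env * cos(2 * pi * freq * xr)
  im <- env * sin(2 * pi * freq * xr)
  re <- re - mean(re)  # zero DC so a constant image gives zero response
  (re + 1i * im) / sum(env)
})

log_kernel <- function(sigma) .cached(sprintf("log_%g", sigma), function() {
  r <- ceiling(3 * sigma)
  cc <- matrix(-r:r, 2 * r + 1, 2 * r + 1, byrow = TRUE)
  rr <- matrix(-r:r, 2 * r + 1, 2 * r + 1)
  s2 <- sigma^2
  g <- exp(-(cc^2 + rr^2) / (2 * s2)) / (2 * pi * s2)
  k <- s2 * g * ((cc^2 + rr^2) - 2 * s2) / s2^2  # scale-normalised LoG
  k - mean(k)
})

gauss_deriv_kernels <- function(sigma) .cached(
  sprintf("gd_%g", sigma), function() {
  r <- ceiling(3 * sigma)
  cc <- matrix(-r:r, 2 * r + 1, 2 * r + 1, byrow = TRUE)
  rr <- matrix(-r:r, 2 * r + 1, 2 * r + 1)
  s2 <- sigma^2
  g <- exp(-(cc^2 + rr^2) / (2 * s2)) / (2 * pi * s2)
  list(xx = g * (cc^2 - s2) / s2^2,
       yy = g * (rr^2 - s2) / s2^2,
       xy = g * cc * rr / s2^2)
})

# ---- per-slice map computation --------------------------------------------

# All filter-response maps for one axial slice. Expensive; callers cache per
# (volume, z) so that observers/ROIs sharing slices reuse the maps.
compute_slice_maps <- function(slice) {
  maps <- list()
  for (f in .gabor_freqs) for (a in .tex_angles) {
    k <- gabor_kernel(f, a)
    resp <- conv2_fft(slice, k, tag = sprintf("gab_%s_%d", sprintf("%g", f), a))
    maps[[sprintf("gabor_f%s_a%d", sprintf("%g", f), a)]] <- Mod(resp)
  }
  for (sg in .log_sigmas) {
    maps[[sprintf("log_sigma%g", sg)]] <-
      conv2_fft(slice, log_kernel(sg), tag = paste0("log_", sg))
  }
  maps$vessel <- frangi_slice(slice)
  ph <- monogenic_slice(slice)
  maps$phase_monogenic <- ph$phase
  maps$phase_congruency <- ph$congruency
  maps$phase_symmetry <- ph$symmetry
  for (p in .lbp_params) {
    maps[[sprintf("lbp_r%dn%d", p[["r"]], p[["n"]])]] <-
      lbp_slice(slice, p[["r"]], p[["n"]])
  }
  maps
}

# 2-D Frangi vesselness (single scale, bright tubular structures)
frangi_slice <- function(slice, sigma = 1.5, beta = 0.5) {
  if (diff(range(slice)) <= 1e-12 * max(1, max(abs(slice))))
    return(slice * 0)  # constant slice: avoid amplifying FFT noise
  ks <- gauss_deriv_kernels(sigma)
  hxx <- conv2_fft(slice, sigma^2 * ks$xx, tag = "fr_xx")
  hyy <- conv2_fft(slice, sigma^2 * ks$yy, tag = "fr_yy")
  hxy <- conv2_fft(slice, sigma^2 * ks$xy, tag = "fr_xy")
  tmp <- sqrt((hxx - hyy)^2 + 4 * hxy^2)
  l1 <- (hxx + hyy + tmp) / 2
  l2 <- (hxx + hyy - tmp) / 2
  # order |lam1| <= |lam2|
  swap <- abs(l1) > abs(l2)
  lam1 <- ifelse(swap, l2, l1)
  lam2 <- ifelse(swap, l1, l2)
  S <- sqrt(lam1^2 + lam2^2)
  c2 <- (max(S) / 2)^2
  if (c2 == 0) return(slice * 0)
  rb2 <- ifelse(lam2 != 0, (lam1 / lam2)^2, 0)
  v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-S^2 / (2 * c2)))
  v[lam2 >= 0] <- 0  # bright structures only
  v
}

# monogenic signal over 3 log-Gabor scales: phase (mid scale), simplified
# phase congruency (energy over summed amplitude) and phase symmetry
monogenic_slice <- function(slice, omega0 = c(0.25, 0.10, 0.04),
                            sigma_ratio = 0.55) {
  d <- dim(slice)
  Fc <- stats::fft(slice)
  fr <- fft_freq_grid(d[1], d[2])
  w <- sqrt(fr$u^2 + fr$v^2)
  w[1, 1] <- 1
  ru <- fr$v / w   # Riesz: column frequency is the x-axis
  rv <- fr$u / w
  sum_even <- sum_o1 <- sum_o2 <- sum_amp <- sum_sym <- matrix(0, d[1], d[2])
  phase_mid <- NULL
  for (s in seq_along(omega0)) {
    lg <- exp(-(log(w / omega0[s]))^2 / (2 * log(sigma_ratio)^2))
    lg[1, 1] <- 0
    even <- Re(stats::fft(Fc * lg, inverse = TRUE)) / prod(d)
    o1 <- Re(stats::fft(Fc * lg * (1i * ru), inverse = TRUE)) / prod(d)
    o2 <- Re(stats::fft(Fc * lg * (1i * rv), inverse = TRUE)) / prod(d)
    odd <- sqrt(o1^2 + o2^2)
    amp <- sqrt(even^2 + odd^2)
    sum_even <- sum_even + even
    sum_o1 <- sum_o1 + o1; sum_o2 <- sum_o2 + o2
    sum_amp <- sum_amp + amp
    sum_sym <- sum_sym + (abs(even) - odd)
    if (s == 2L) phase_mid <- atan2(odd, even)
  }
  eps <- 1e-8 * mean(sum_amp) + 1e-300
  list(phase = phase_mid,
       congruency = sqrt(sum_even^2 + sum_o1^2 + sum_o2^2) / (sum_amp + eps),
       symmetry = sum_sym / (sum_amp + eps))
}

# local binary pattern code image (bilinear-interpolated circular neighbours);
# pixels whose neighbourhood leaves the slice are NA
lbp_slice <- function(slice, radius, n_neighbours) {
  d <- dim(slice)
  rc <- ceiling(radius) + 1L  # +1 margin for the bilinear upper neighbour
  if (any(d < 2 * rc + 2)) return(matrix(NA_real_, d[1], d[2]))
  rows <- (rc + 1):(d[1] - rc)
  cols <- (rc + 1):(d[2] - rc)
  centre <- slice[rows, cols, drop = FALSE]
  code <- matrix(0, length(rows), length(cols))
  for (k in 0:(n_neighbours - 1L)) {
    ang <- 2 * pi * k / n_neighbours
    dr <- radius * sin(ang); dc <- radius * cos(ang)
    r0 <- floor(dr); c0 <- floor(dc)
    fr <- dr - r0; fc <- dc - c0
    samp <- (1 - fr) * (1 - fc) * slice[rows + r0, cols + c0, drop = FALSE] +
            (1 - fr) * fc       * slice[rows + r0, cols + c0 + 1L, drop = FALSE] +
            fr * (1 - fc)       * slice[rows + r0 + 1L, cols + c0, drop = FALSE] +
            fr * fc             * slice[rows + r0 + 1L, cols + c0 + 1L, drop = FALSE]
    code <- code + 2^k * (samp >= centre - 1e-9)
  }
  out <- matrix(NA_real_, d[1], d[2])
  out[rows, cols] <- code
  out
}

# ---- GLCM ------------------------------------------------------------------

.glcm_offsets <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L),
                      `90` = c(-1L, 0L), `135` = c(-1L, -1L))

# symmetric normalised co-occurrence matrix of a quantised slice within a
# mask, for one (distance, angle); NULL when no valid pair exists
glcm_matrix <- function(q_slice, mask_slice, distance, angle,
                        levels = .n_gray_levels) {
  off <- .glcm_offsets[[as.character(angle)]] * distance
  d <- dim(q_slice)
  r1 <- max(1L, 1L - off[1]):min(d[1], d[1] - off[1])
  c1 <- max(1L, 1L - off[2]):min(d[2], d[2] - off[2])
  if (length(r1) < 1L || length(c1) < 1L) return(NULL)
  a <- q_slice[r1, c1, drop = FALSE]
  b <- q_slice[r1 + off[1], c1 + off[2], drop = FALSE]
  ok <- mask_slice[r1, c1, drop = FALSE] & mask_slice[r1 + off[1], c1 + off[2], drop = FALSE]
  if (!any(ok)) return(NULL)
  ia <- a[ok] + 1L; ib <- b[ok] + 1L
  cnt <- tabulate((ia - 1L) * levels + ib, levels * levels)
  P <- matrix(cnt, levels, levels, byrow = TRUE)
  P <- P + t(P)
  P / sum(P)
}

glcm_props_of <- function(P, levels = .n_gray_levels) {
  if (is.null(P))
    return(stats::setNames(rep(0, length(.glcm_props)), .glcm_props))
  i <- matrix(seq_len(levels), levels, levels)
  j <- t(i)
  pi_ <- rowSums(P)
  mu_i <- sum(i[, 1] * pi_)
  sd_i <- sqrt(sum((i[, 1] - mu_i)^2 * pi_))
  corr <- if (sd_i == 0) 1 else (sum(P * i * j) - mu_i^2) / sd_i^2
  pnz <- P[P > 0]
  c(contrast = sum(P * (i - j)^2),
    dissimilarity = sum(P * abs(i - j)),
    homogeneity = sum(P / (1 + (i - j)^2)),
    energy = sum(P^2),
    correlation = corr,
    entropy = -sum(pnz * log2(pnz)))
}

# ---- slice bookkeeping -----------------------------------------------------

.mask_slices <- function(mask, min_pixels = 5L) {
  cnt <- apply(mask, 3, sum)
  which(cnt >= min_pixels)
}

# per-slice 4-connected 2-D erosion (for the vessel edge/inner split)
.erode2d <- function(m, w = 2L) {
  for (i in seq_len(w)) {
    d <- dim(m)
    grown <- !m
    grown[-1, ] <- grown[-1, ] | !m[-d[1], ]
    grown[-d[1], ] <- grown[-d[1], ] | !m[-1, ]
    grown[, -1] <- grown[, -1] | !m[, -d[2]]
    grown[, -d[2]] <- grown[, -d[2]] | !m[, -1]
    m <- !grown
  }
  m
}

# shared driver: stats of one cached map family over mask, per slice
.family_from_maps <- function(volume, mask, map_names, prefixes, provider,
                              min_pixels = 5L) {
  zs <- .mask_slices(mask, min_pixels)
  out <- list()
  for (mi in seq_along(map_names)) {
    mat <- NULL
    if (length(zs)) {
      mat <- matrix(0, length(zs), length(.map_stats),
                    dimnames = list(NULL, .map_stats))
      for (k in seq_along(zs)) {
        z <- zs[k]
        mp <- provider(z)[[map_names[mi]]]
        mat[k, ] <- map_stat_vec(mp[mask[, , z]])
      }
    }
    out[[mi]] <- .agg_slices(mat, prefixes[mi])
  }
  unlist(out)
}

.default_provider <- function(volume) {
  cache <- new.env(parent = emptyenv())
  function(z) {
    key <- as.character(z)
    if (is.null(cache[[key]])) cache[[key]] <- compute_slice_maps(volume[, , z])
    cache[[key]]
  }
}

# ---- exported per-family operations ---------------------------------------

#' Gray-level co-occurrence matrix features
#'
#' Symmetric, normalised GLCMs per (distance, angle) on 16 equal-width gray
#' levels, computed per axial slice within the mask and aggregated over
#' slices (mean, sd). Matrices with no valid pixel pair (mask thinner than
#' the offset) are zero-filled.
#'
#' @param volume 3-D numeric array
#' @param mask logical 3-D mask
#' @param distances,angles,levels co-occurrence parameters
#' @return named numeric vector (96 values at the defaults)
#' @export
glcm_features <- function(volume, mask, distances = .glcm_distances,
                          angles = .tex_angles, levels = .n_gray_levels) {
  stopifnot(any(mask))
  q <- volume
  q[] <- NA_integer_
  q[mask] <- quantize(volume[mask], levels)
  zs <- .mask_slices(mask)
  out <- list()
  for (dd in distances) for (aa in angles) {
    mat <- NULL
    if (length(zs)) {
      mat <- matrix(0, length(zs), length(.glcm_props),
                    dimnames = list(NULL, .glcm_props))
      for (k in seq_along(zs)) {
        z <- zs[k]
        qs <- q[, , z]
        qs[is.na(qs)] <- 0L
        mat[k, ] <- glcm_props_of(glcm_matrix(qs, mask[, , z], dd, aa, levels),
                                  levels)
      }
    }
    out[[sprintf("d%d_a%d", dd, aa)]] <-
      .agg_slices(mat, sprintf("glcm_d%d_a%d", dd, aa))
  }
  unlist(unname(out))
}

#' Local binary pattern features
#' @inheritParams glcm_features
#' @param params list of `c(r=, n=)` radius/neighbour settings
#' @param .provider internal slice-map cache
#' @return named numeric vector (54 values at the defaults)
#' @export
lbp_features <- function(volume, mask, params = .lbp_params,
                         .provider = NULL) {
  stopifnot(any(mask))
  provider <- .provider %||% .default_provider(volume)
  nm <- vapply(params, function(p) sprintf("lbp_r%dn%d", p[["r"]], p[["n"]]),
               character(1))
  .family_from_maps(volume, mask, nm, nm, provider)
}

#' Gabor filter-bank features
#' @inheritParams lbp_features
#' @param freqs frequencies in cycles/pixel
#' @param angles orientations in degrees
#' @return named numeric vector (216 values at the defaults)
#' @export
gabor_features <- function(volume, mask, freqs = .gabor_freqs,
                           angles = .tex_angles, .provider = NULL) {
  stopifnot(any(mask))
  provider <- .provider %||% .default_provider(volume)
  nm <- as.vector(t(outer(freqs, angles, function(f, a)
    sprintf("gabor_f%s_a%d", sprintf("%g", f), a))))
  .family_from_maps(volume, mask, nm, nm, provider)
}

#' Laplacian-of-Gaussian features
#' @inheritParams lbp_features
#' @param sigmas Gaussian widths in pixels
#' @return named numeric vector (54 values at the defaults)
#' @export
log_features <- function(volume, mask, sigmas = .log_sigmas,
                         .provider = NULL) {
  stopifnot(any(mask))
  provider <- .provider %||% .default_provider(volume)
  nm <- sprintf("log_sigma%g", sigmas)
  .family_from_maps(volume, mask, nm, nm, provider)
}

#' Vesselness features over the full mask, its edge and its inner region
#'
#' Single-scale 2-D Frangi response; edge/inner split by a fixed-width
#' (2-pixel) in-plane erosion.
#'
#' @inheritParams lbp_features
#' @return named numeric vector (54 values)
#' @export
vessel_features <- function(volume, mask, .provider = NULL) {
  stopifnot(any(mask))
  provider <- .provider %||% .default_provider(volume)
  zs <- .mask_slices(mask)
  regions <- .vessel_regions
  mats <- stats::setNames(vector("list", length(regions)), regions)
  for (r in regions)
    mats[[r]] <- if (length(zs)) matrix(0, length(zs), length(.map_stats),
                                        dimnames = list(NULL, .map_stats))
  for (k in seq_along(zs)) {
    z <- zs[k]
    v <- provider(z)$vessel
    ms <- mask[, , z]
    inner <- .erode2d(ms, 2L)
    edge <- ms & !inner
    vals <- list(full = v[ms], edge = v[edge], inner = v[inner])
    for (r in regions) mats[[r]][k, ] <- map_stat_vec(vals[[r]])
  }
  unlist(lapply(regions, function(r)
    .agg_slices(mats[[r]], paste0("vessel_", r))))
}

#' Local phase features (monogenic phase, phase congruency, phase symmetry)
#' @inheritParams lbp_features
#' @return named numeric vector (54 values)
#' @export
local_phase_features <- function(volume, mask, .provider = NULL) {
  stopifnot(any(mask))
  provider <- .provider %||% .default_provider(volume)
  nm <- paste0("phase_", .phase_maps)
  .family_from_maps(volume, mask, nm, nm, provider)
}

#' First-order intensity and 3-D shape features
#'
#' @param volume 3-D numeric array
#' @param mask logical 3-D mask
#' @param spacing voxel spacing in mm per axis
#' @return named numeric vector (15 intensity + 21 shape values)
#' @export
histogram_shape_features <- function(volume, mask, spacing = c(1, 1, 1)) {
  stopifnot(any(mask))
  x <- volume[mask]
  q <- stats::quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE)
  hb <- tabulate(quantize(x, 16L) + 1L, 16L) / length(x)
  intensity <- c(mean = mean(x), median = stats::median(x),
                 sd = if (length(x) > 1) stats::sd(x) else 0,
                 mad = stats::mad(x), min = min(x), max = max(x),
                 range = diff(range(x)), p10 = q[1], p90 = q[4],
                 iqr = q[3] - q[2], skewness = .skewness(x),
                 kurtosis = .kurtosis(x), entropy = .hist_entropy(x),
                 uniformity = sum(hb^2), rms = sqrt(mean(x^2)))
  names(intensity) <- paste0("intensity_", .intensity_stats)

  vox_vol <- prod(spacing)
  n <- sum(mask)
  V <- n * vox_vol
  # surface area from exposed voxel faces
  d <- dim(mask)
  # exposed voxel faces: mask/non-mask transitions plus array-border faces
  faces <- 0
  ax_area <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
               spacing[1] * spacing[2])
  for (ax in 1:3) {
    nb <- array(FALSE, d)  # forward-shifted mask along axis
    if (ax == 1) nb[-d[1], , ] <- mask[-1, , ]
    if (ax == 2) nb[, -d[2], ] <- mask[, -1, ]
    if (ax == 3) nb[, , -d[3]] <- mask[, , -1]
    n_faces <- sum(mask & !nb) + sum(nb & !mask) +
      switch(ax, sum(mask[1, , ]), sum(mask[, 1, ]), sum(mask[, , 1]))
    faces <- faces + ax_area[ax] * n_faces
  }
  S <- faces
  R <- (3 * V / (4 * pi))^(1 / 3)
  idx <- which(mask, arr.ind = TRUE)
  mmc <- sweep(idx, 2, spacing, `*`)
  bbox <- apply(idx, 2, function(v) diff(range(v)) + 1) * spacing
  ev <- if (n > 3) {
    e <- eigen(stats::cov(mmc), symmetric = TRUE, only.values = TRUE)$values
    pmax(e, 0)
  } else c(0, 0, 0)
  axlen <- 4 * sqrt(ev)
  zs <- unique(idx[, 3])
  max_diam2d <- 0
  for (z in zs) {
    sub <- idx[idx[, 3] == z, , drop = FALSE]
    dx <- diff(range(sub[, 1])) * spacing[1]
    dy <- diff(range(sub[, 2])) * spacing[2]
    max_diam2d <- max(max_diam2d, sqrt(dx^2 + dy^2))
  }
  shape <- c(n_voxels = n, volume_mm3 = V, surface_area_mm2 = S,
             surface_to_volume = S / V,
             compactness1 = V / (sqrt(pi) * S^1.5),
             compactness2 = 36 * pi * V^2 / S^3,
             sphericity = (36 * pi * V^2)^(1 / 3) / S,
             spherical_disproportion = S / (4 * pi * R^2),
             equivalent_diameter_mm = 2 * R,
             bbox_x_mm = bbox[1], bbox_y_mm = bbox[2], bbox_z_mm = bbox[3],
             bbox_volume_mm3 = prod(bbox), extent = V / prod(bbox),
             axis_major_mm = axlen[1], axis_minor_mm = axlen[2],
             axis_least_mm = axlen[3],
             elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,
             flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0,
             n_slices = length(zs),
             max_inplane_diameter_mm = max_diam2d)
  names(shape) <- paste0("shape_", .shape_feats)
  .finite_or_zero(c(intensity, shape))
}

#' Extract the full 564-feature vector for one ROI
#'
#' Deterministic; exactly 564 finite values in manifest order.
#'
#' @param volume 3-D numeric array
#' @param mask logical 3-D mask (non-empty)
#' @param spacing mm per axis
#' @param .provider optional shared slice-map cache (see
#'   [make_slice_map_provider()])
#' @return named numeric vector of length 564
#' @export
extract_all <- function(volume, mask, spacing = c(1, 1, 1), .provider = NULL) {
  mask <- mask != 0
  if (!any(mask)) stop("extract_all: empty mask")
  provider <- .provider %||% .default_provider(volume)
  v <- c(histogram_shape_features(volume, mask, spacing),
         glcm_features(volume, mask),
         lbp_features(volume, mask, .provider = provider),
         gabor_features(volume, mask, .provider = provider),
         log_features(volume, mask, .provider = provider),
         vessel_features(volume, mask, .provider = provider),
         local_phase_features(volume, mask, .provider = provider))
  nm <- feature_names()
  if (!identical(names(v), nm)) v <- v[nm]
  if (anyNA(v)) stop("extract_all: internal error, features missing vs manifest")
  stopifnot(length(v) == 564L)
  .finite_or_zero(v)
}

#' Shared slice-map cache for repeated extraction from one volume
#'
#' Filter-response maps depend only on the image, not the mask; when many
#' ROIs/observers index the same volume, pass one provider to
#' [extract_all()] to compute each slice's maps once.
#'
#' @param volume 3-D numeric array
#' @return memoised function `z -> named list of maps`
#' @export
make_slice_map_provider <- function(volume) .default_provider(volume)
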