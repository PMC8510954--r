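# The 564-feature manifest: the single source of truth for feature names,
# families, parameters and order. Changing it is a breaking change; every
# extracted vector is checked against it.

.map_stats <- c("mean", "sd", "min", "max", "median",
                "skewness", "kurtosis", "entropy", "energy")
.slice_aggs <- c("mean", "sd")
.glcm_props <- c("contrast", "dissimilarity", "homogeneity",
                 "energy", "correlation", "entropy")
.glcm_distances <- c(1L, 3L)
.tex_angles <- c(0L, 45L, 90L, 135L)
.lbp_params <- list(c(r = 1, n = 8), c(r = 2, n = 12), c(r = 3, n = 16))
.gabor_freqs <- c(0.05, 0.2, 0.5)
.log_sigmas <- c(1, 5, 10)
.vessel_regions <- c("full", "edge", "inner")
.phase_maps <- c("monogenic", "congruency", "symmetry")
.n_gray_levels <- 16L

.intensity_stats <- c("mean", "median", "sd", "mad", "min", "max", "range",
                      "p10", "p90", "iqr", "skewness", "kurtosis",
                      "entropy", "uniformity", "rms")
.shape_feats <- c("n_voxels", "volume_mm3", "surface_area_mm2",
                  "surface_to_volume", "compactness1", "compactness2",
                  "sphericity", "spherical_disproportion",
                  "equivalent_diameter_mm", "bbox_x_mm", "bbox_y_mm",
                  "bbox_z_mm", "bbox_volume_mm3", "extent",
                  "axis_major_mm", "axis_minor_mm", "axis_least_mm",
                  "elongation", "flatness", "n_slices",
                  "max_inplane_diameter_mm")

#' The radiomics feature manifest
#'
#' 564 features: 15 first-order intensity, 21 shape, 96 GLCM (2 distances x
#' 4 angles x 6 matrix statistics x mean/sd over slices), 54 LBP (3
#' radius/neighbour settings), 216 Gabor (3 frequencies x 4 angles), 54 LoG
#' (3 Gaussian widths), 54 vesselness (full/edge/inner region), 54 local
#' phase (monogenic phase, phase congruency, phase symmetry); the filter
#' families use 9 response-map statistics aggregated over axial slices by
#' mean and sd.
#'
#' @return data.frame with columns `name`, `family`, `params`, `stat`, `agg`
#' @export
feature_manifest <- function() {
  if (!is.null(.manifest_cache$df)) return(.manifest_cache$df)
  rows <- list()
  add <- function(name, family, params, stat, agg = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, family = family, params = params, stat = stat, agg = agg,
      stringsAsFactors = FALSE)
  }
  for (s in .intensity_stats)
    add(paste0("intensity_", s), "intensity", "", s)
  for (s in .shape_feats)
    add(paste0("shape_", s), "shape", "", s)
  for (d in .glcm_distances) for (a in .tex_angles)
    for (s in .glcm_props) for (g in .slice_aggs)
      add(sprintf("glcm_d%d_a%d_%s_%s", d, a, s, g), "glcm",
          sprintf("d%d_a%d", d, a), s, g)
  for (p in .lbp_params) for (s in .map_stats) for (g in .slice_aggs)
    add(sprintf("lbp_r%dn%d_%s_%s", p[["r"]], p[["n"]], s, g), "lbp",
        sprintf("r%dn%d", p[["r"]], p[["n"]]), s, g)
  for (f in .gabor_freqs) for (a in .tex_angles)
    for (s in .map_stats) for (g in .slice_aggs)
      add(sprintf("gabor_f%s_a%d_%s_%s", sprintf("%g", f), a, s, g), "gabor",
          sprintf("f%s_a%d", sprintf("%g", f), a), s, g)
  for (sg in .log_sigmas) for (s in .map_stats) for (g in .slice_aggs)
    add(sprintf("log_sigma%g_%s_%s", sg, s, g), "log",
        sprintf("sigma%g", sg), s, g)
  for (r in .vessel_regions) for (s in .map_stats) for (g in .slice_aggs)
    add(sprintf("vessel_%s_%s_%s", r, s, g), "vessel", r, s, g)
  for (mp in .phase_maps) for (s in .map_stats) for (g in .slice_aggs)
    add(sprintf("phase_%s_%s_%s", mp, s, g), "phase", mp, s, g)
  out <- do.call(rbind, rows)
  stopifnot(nrow(out) == 564L, !anyDuplicated(out$name))
  .manifest_cache$df <- out
  out
}

.manifest_cache <- new.env(parent = emptyenv())

#' Feature names in manifest order
#' @return character vector of length 564
#' @export
feature_names <- function() feature_manifest()$name

#' Write the manifest as a sidecar JSON
#' @param path output path
#' @export
write_feature_manifest <- function(path) {
  jsonlite::write_json(feature_manifest(), path, digits = NA, pretty = TRUE)
  invisible(path)
}
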