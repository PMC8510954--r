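# Cohort-level feature extraction: one row per (lesion, observer, ROI) with
# the 564 imaging features, label, acquisition/batch metadata and one-hot
# encoded clinical covariates.

#' Extract a FeatureTable from a synthetic cohort
#'
#' Filter-response maps are cached per patient volume so observers and ROIs
#' sharing slices are extracted cheaply. For `roi = "nlp"` the region
#' (liver minus all CNN lesion masks, the automated segmentation) is
#' observer-independent: its features are computed once per patient and
#' replicated across the requested observers. `nlp_plus_lesion` unions the
#' NLP with each observer's lesion mask; `ring` is each observer's lesion
#' border shell.
#'
#' @param cohort `synthetic_cohort`
#' @param rois subset of `c("lesion", "nlp", "nlp_plus_lesion", "ring")`
#' @param observers observers to extract
#' @param ring_width ring half-width in voxels
#' @param verbose print progress per patient
#' @return data.frame with attribute `feature_cols`
#' @export
extract_cohort_features <- function(cohort, rois = "lesion",
                                    observers = c("STUD2", "PhD", "RAD", "CNN"),
                                    ring_width = 2L, verbose = FALSE) {
  stopifnot(all(rois %in% c("lesion", "nlp", "nlp_plus_lesion", "ring")))
  fn <- feature_names()
  md <- cohort$metadata
  chunks <- list()
  for (pid in names(cohort$patients)) {
    pt <- cohort$patients[[pid]]
    if (!length(pt$lesions)) next
    provider <- make_slice_map_provider(pt$volume)
    nlp_mask <- NULL
    nlp_fv <- NULL
    if (any(rois %in% c("nlp", "nlp_plus_lesion"))) {
      cnn_masks <- lapply(pt$lesions, function(l) l$observer_masks$CNN)
      nlp_mask <- derive_nlp(pt$liver_mask, cnn_masks)
      if ("nlp" %in% rois)
        nlp_fv <- extract_all(pt$volume, nlp_mask, pt$spacing,
                              .provider = provider)
    }
    for (lid in names(pt$lesions)) {
      l <- pt$lesions[[lid]]
      mrow <- md[md$lesion_id == lid, , drop = FALSE]
      for (obs in observers) {
        om <- l$observer_masks[[obs]]
        if (is.null(om)) next
        for (roi in rois) {
          fv <- switch(roi,
            lesion = extract_all(pt$volume, om, pt$spacing,
                                 .provider = provider),
            ring = extract_all(pt$volume, make_ring(om, ring_width),
                               pt$spacing, .provider = provider),
            nlp = nlp_fv,
            nlp_plus_lesion = extract_all(pt$volume, nlp_mask | om,
                                          pt$spacing, .provider = provider))
          chunks[[length(chunks) + 1L]] <- cbind(
            data.frame(patient_id = pid, lesion_id = lid, observer = obs,
                       roi = roi, stringsAsFactors = FALSE),
            mrow[, setdiff(names(mrow), c("patient_id", "lesion_id")),
                 drop = FALSE],
            as.data.frame(as.list(fv)),
            row.names = NULL)
        }
      }
    }
    if (verbose) message("extracted ", pid)
  }
  out <- do.call(rbind, chunks)
  out <- cbind(out, clinical_features(out))
  attr(out, "feature_cols") <- fn
  out
}

#' One-hot encoded clinical covariates (prefix `clin_`)
#'
#' @param metadata rows carrying the clinical columns of the cohort
#'   metadata
#' @return data.frame of numeric `clin_*` columns
#' @export
clinical_features <- function(metadata) {
  data.frame(
    clin_age = metadata$age,
    clin_sex_male = as.numeric(metadata$sex == "male"),
    clin_loc_right = as.numeric(metadata$primary_location == "right"),
    clin_loc_left = as.numeric(metadata$primary_location == "left"),
    clin_loc_rectum = as.numeric(metadata$primary_location == "rectum"),
    clin_nodal_pos = as.numeric(metadata$nodal_status == "N+"),
    clin_dfi_gt_12mo = as.numeric(metadata$dfi_gt_12mo),
    clin_cea_gt_200 = as.numeric(metadata$cea_gt_200),
    clin_n_crlm = metadata$n_crlm,
    clin_size_largest_cm = metadata$size_largest_cm)
}

#' Write a FeatureTable (CSV) with its sidecar feature manifest (JSON)
#' @param features FeatureTable
#' @param path CSV path; the manifest is written next to it
#' @export
write_feature_table <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  write_feature_manifest(sub("\\.csv$", "_manifest.json", path))
  invisible(path)
}
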