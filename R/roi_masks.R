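# Mask algebra: Dice agreement and derivation of the four regions of
# interest used by the models (lesion, normal liver parenchyma (NLP),
# NLP + lesion, border ring).

#' Dice similarity coefficient of two binary masks
#'
#' `2|A∩B| / (|A|+|B|)`. Two empty masks are defined to agree perfectly
#' (DSC = 1): agreement on absence.
#'
#' @param a,b logical/0-1 arrays on the same grid
#' @return value in `[0, 1]`
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("dice: masks are on different grids")
  sa <- sum(a != 0); sb <- sum(b != 0)
  if (sa + sb == 0L) return(1)
  2 * sum(a != 0 & b != 0) / (sa + sb)
}

# one morphological step with the 3-D 6-connected structuring element,
# implemented by axis shifts (cheap at phantom scale)
.shift_or <- function(m) {
  d <- dim(m); out <- m
  out[-1, , ] <- out[-1, , ] | m[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | m[-1, , ]
  out[, -1, ] <- out[, -1, ] | m[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | m[, -1, ]
  if (d[3] > 1L) {
    out[, , -1] <- out[, , -1] | m[, , -d[3]]
    out[, , -d[3]] <- out[, , -d[3]] | m[, , -1]
  }
  out
}

#' Binary dilation / erosion (6-connected, voxel units)
#'
#' @param m logical 3-D array
#' @param w number of morphological steps
#' @return logical array of the same shape
#' @export
mask_dilate <- function(m, w = 1L) {
  m <- m != 0
  for (i in seq_len(w)) m <- .shift_or(m)
  m
}

#' @rdname mask_dilate
#' @export
mask_erode <- function(m, w = 1L) {
  m <- m != 0
  for (i in seq_len(w)) m <- !.shift_or(!m)
  m
}

#' Border ring of a lesion mask
#'
#' Morphological shell straddling the lesion boundary:
#' `dilate(lesion, w) \\ erode(lesion, w)`. When the lesion is too small to
#' survive the erosion, the degenerate rule `dilate(lesion, w) \\ lesion`
#' is used and flagged via the `"degenerate"` attribute.
#'
#' @param lesion logical 3-D mask
#' @param width_voxels ring half-width in voxels (>= 1), applied on each side
#' @return logical mask
#' @export
make_ring <- function(lesion, width_voxels = 2L) {
  stopifnot(width_voxels >= 1L)
  lesion <- lesion != 0
  dil <- mask_dilate(lesion, width_voxels)
  ero <- mask_erode(lesion, width_voxels)
  if (!any(ero)) {
    ring <- dil & !lesion
    attr(ring, "degenerate") <- TRUE
    return(ring)
  }
  ring <- dil & !ero
  attr(ring, "degenerate") <- FALSE
  ring
}

#' Normal liver parenchyma mask
#'
#' Liver minus the union of all lesion masks.
#'
#' @param liver_mask logical 3-D liver mask (non-empty)
#' @param lesion_masks list of logical masks on the same grid
#' @return logical mask
#' @export
derive_nlp <- function(liver_mask, lesion_masks = list()) {
  if (!any(liver_mask != 0)) stop("derive_nlp: liver mask is empty")
  nlp <- liver_mask != 0
  for (lm in lesion_masks) {
    if (!identical(dim(lm), dim(nlp))) stop("derive_nlp: grid mismatch")
    nlp <- nlp & !(lm != 0)
  }
  if (!any(nlp)) stop("derive_nlp: lesions cover the whole liver; NLP is empty")
  nlp
}

#' Derive the four-ROI set for one lesion
#'
#' @param liver_mask liver mask
#' @param lesion_mask this lesion's mask
#' @param all_lesion_masks all lesion masks of the patient (for NLP removal);
#'   defaults to just `lesion_mask`
#' @param ring_width ring half-width in voxels
#' @return list with elements `lesion`, `nlp`, `nlp_plus_lesion`, `ring`
#' @export
roi_set <- function(liver_mask, lesion_mask, all_lesion_masks = NULL,
                    ring_width = 2L) {
  if (is.null(all_lesion_masks)) all_lesion_masks <- list(lesion_mask)
  nlp <- derive_nlp(liver_mask, all_lesion_masks)
  list(lesion = lesion_mask != 0,
       nlp = nlp,
       nlp_plus_lesion = nlp | (lesion_mask != 0),
       ring = make_ring(lesion_mask, ring_width))
}

#' Pairwise Dice agreement table between observers
#'
#' For each observer pair, the mean (and sd) DSC over the lesions both
#' segmented. Pairs sharing no lesion get `NA`.
#'
#' @param masks_by_lesion list over lesions; each element a named list
#'   `observer -> mask` (observers may be missing per lesion)
#' @return object of class `dsc_table`: list with symmetric `mean`, `sd`,
#'   `n` matrices (diagonal = 1, 0, lesion count)
#' @export
pairwise_dice_table <- function(masks_by_lesion) {
  obs <- unique(unlist(lapply(masks_by_lesion, names)))
  if (length(obs) < 2L) stop("need at least 2 observers")
  k <- length(obs)
  vals <- array(list(), c(k, k))
  acc <- matrix(vector("list", k * k), k, k)
  for (les in masks_by_lesion) {
    present <- intersect(obs, names(les))
    if (length(present) < 2L) next
    for (i in seq_along(present)) for (j in seq_along(present)) {
      if (i >= j) next
      a <- match(present[i], obs); b <- match(present[j], obs)
      d <- dice(les[[present[i]]], les[[present[j]]])
      acc[[a, b]] <- c(acc[[a, b]], d)
    }
  }
  mn <- sdm <- nm <- matrix(NA_real_, k, k, dimnames = list(obs, obs))
  diag(mn) <- 1; diag(sdm) <- 0
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (a >= b) next
    v <- acc[[a, b]]
    if (!is.null(v)) {
      mn[a, b] <- mn[b, a] <- mean(v)
      sdm[a, b] <- sdm[b, a] <- if (length(v) > 1L) stats::sd(v) else 0
      nm[a, b] <- nm[b, a] <- length(v)
    }
  }
  diag(nm) <- length(masks_by_lesion)
  structure(list(mean = mn, sd = sdm, n = nm), class = "dsc_table")
}

#' @export
print.dsc_table <- function(x, digits = 2, ...) {
  k <- nrow(x$mean)
  out <- matrix("", k, k, dimnames = dimnames(x$mean))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    out[i, j] <- if (is.na(x$mean[i, j])) "-" else
      sprintf("%.*f (%.*f)", digits, x$mean[i, j], digits, x$sd[i, j])
  }
  cat("Pairwise Dice agreement, mean (sd):\n")
  print(out, quote = FALSE)
  invisible(x)
}

#' Write a Dice table as CSV
#' @param x `dsc_table`
#' @param path output CSV path
#' @export
write_dsc_table <- function(x, path) {
  df <- data.frame(observer = rownames(x$mean), x$mean, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
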