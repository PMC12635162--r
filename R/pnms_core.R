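#' Binarize a personalized neurometabolic signature (pNMS) mask
#'
#' The pNMS is the set of voxels, within one hemisphere, whose asymmetry
#' index falls at or below a threshold (the hypometabolic direction:
#' ipsilateral intensity lower than the contralateral homologue).
#'
#' @param ai a `pnms_ai_map` from [asymmetry_index_map()].
#' @param threshold AI cut-off; default -0.06.
#' @param hemisphere_mask logical array lying strictly on one side of the
#'   midsagittal plane.
#' @param source_modality label stored with the mask ("PET", "T1GM",
#'   "FLAIR").
#' @return An object of class `pnms_mask`: fields `mask` (logical array),
#'   `threshold`, `hemisphere`, `source_modality`, `n_vox`.
#' @export
binarize_pnms <- function(ai, threshold = -0.06, hemisphere_mask,
                          source_modality = "PET") {
  stopifnot(inherits(ai, "pnms_ai_map"))
  d <- dim(ai$values)
  hm <- as_mask(hemisphere_mask, d)
  nx <- d[1]
  if (nx %% 2L != 0L) stop("asymmetric grid")
  xs <- which(apply(hm, 1, any))
  left <- any(xs <= nx / 2L); right <- any(xs > nx / 2L)
  if (left && right) stop("hemisphere_mask straddles the midsagittal plane")
  hemi <- if (left) "left" else "right"
  m <- hm & ai$valid_mask & !is.na(ai$values) & (ai$values <= threshold)
  if (!any(m)) warning("empty pNMS mask at threshold ", threshold)
  structure(
    list(mask = m, threshold = threshold, hemisphere = hemi,
         source_modality = source_modality, n_vox = sum(m)),
    class = "pnms_mask"
  )
}

#' @export
print.pnms_mask <- function(x, ...) {
  cat(sprintf("<pnms_mask %s %s, threshold %.3g, %d voxels>\n",
              x$source_modality, x$hemisphere, x$threshold, x$n_vox))
  invisible(x)
}

#' Ablative rate of a pNMS within a region of interest
#'
#' Fraction of the patient-specific signature, restricted to a region of
#' interest, that falls inside the ablation cavity:
#' `|pNMS & roi & ablation| / |pNMS & roi|`.
#'
#' If the signature does not intersect the region the rate is undefined and
#' returned as `NA` (propagated as missing, never as zero).
#'
#' @param pnms a `pnms_mask` (or logical array).
#' @param ablation logical array, ablation cavity.
#' @param roi logical array, region of interest (e.g. ipsilateral
#'   hippocampus); defaults to everywhere.
#' @return A fraction in `[0, 1]`, or `NA` if `pnms & roi` is empty.
#' @export
ablative_rate <- function(pnms, ablation, roi = NULL) {
  m <- if (inherits(pnms, "pnms_mask")) pnms$mask else pnms != 0
  d <- dim(m)
  abl <- as_mask(ablation, d)
  r <- if (is.null(roi)) array(TRUE, d) else as_mask(roi, d)
  denom <- sum(m & r)
  if (denom == 0) return(NA_real_)
  sum(m & r & abl) / denom
}

#' Dice overlap coefficient between two masks
#'
#' `Dice(A, B) = 2 |A & B| / (|A| + |B|)`.
#'
#' @param a,b logical arrays (or 0/1 volumes) on the same lattice.
#' @return A fraction in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (is_volume(a)) a <- a$values
  if (is_volume(b)) b <- b$values
  a <- as.array(a) != 0; b <- as.array(b) != 0
  if (!identical(dim(a), dim(b))) stop("masks differ in shape")
  s <- sum(a) + sum(b)
  if (s == 0) stop("both masks empty")
  2 * sum(a & b) / s
}

#' Mean (or median) asymmetry index within a mask
#'
#' Aggregates an AI map over a mask, e.g. the ablation cavity, giving the
#' per-patient scalar feature used in all regressions.
#'
#' @param ai a `pnms_ai_map`.
#' @param mask logical array.
#' @param aggregate `"mean"` (default) or `"median"`.
#' @return A scalar, or `NA` if the mask does not meet the valid AI region.
#' @export
mean_ai_within_mask <- function(ai, mask, aggregate = c("mean", "median")) {
  stopifnot(inherits(ai, "pnms_ai_map"))
  aggregate <- match.arg(aggregate)
  m <- as_mask(mask, dim(ai$values)) & ai$valid_mask
  if (!any(m)) return(NA_real_)
  if (aggregate == "mean") mean(ai$values[m]) else stats::median(ai$values[m])
}
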