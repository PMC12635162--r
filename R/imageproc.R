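#' Z-standardize a volume within a brain mask
#'
#' Subtracts the within-mask mean and divides by the within-mask sample
#' standard deviation (denominator n-1). Voxels outside the mask are set to
#' zero and should be excluded from downstream masks.
#'
#' @param vol a [volume()].
#' @param mask logical 3D array (or 0/1 volume) of in-brain voxels.
#' @return A [volume()] with within-mask mean 0 and sample SD 1.
#' @export
zscore_within_mask <- function(vol, mask) {
  stopifnot(is_volume(vol))
  mask <- as_mask(mask, dim(vol$values))
  if (!any(mask)) stop("empty mask")
  v <- vol$values[mask]
  s <- stats::sd(v)
  if (!is.finite(s) || s <= 0) stop("constant image")
  out <- array(0, dim(vol$values))
  out[mask] <- (v - mean(v)) / s
  with_values(vol, out)
}

# coerce logical array / 0-1 volume to a logical array of the right shape
as_mask <- function(mask, dims) {
  if (is_volume(mask)) mask <- mask$values
  mask <- as.array(mask)
  if (!identical(dim(mask), as.integer(dims)) && !identical(dim(mask), dims))
    stop("mask shape does not match volume")
  mask != 0 & !is.na(mask)
}

# 1D convolution matrix with half-sample (edge-mirror) reflection.
# The matrix is symmetric and doubly stochastic for a symmetric normalized
# kernel, so total intensity is conserved exactly.
conv_matrix_reflect <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  C <- matrix(0, n, n)
  reflect <- function(i) {              # 0-based index -> 0-based in range
    i <- ifelse(i < 0L, -1L - i, i)
    ifelse(i >= n, 2L * n - 1L - i, i)
  }
  for (t in seq(-r, r)) {
    src <- reflect(seq_len(n) - 1L + t) + 1L
    w <- kernel[t + r + 1L]
    for (j in seq_len(n)) C[j, src[j]] <- C[j, src[j]] + w
  }
  C
}

apply_along_axis <- function(arr, C, axis) {
  d <- dim(arr)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  a <- aperm(arr, perm)
  dp <- dim(a)
  m <- C %*% matrix(a, dp[1], dp[2] * dp[3])
  a <- array(m, dp)
  aperm(a, order(perm))
}

#' Separable Gaussian smoothing
#'
#' Smooths with per-axis sigma `fwhm_mm / (2 sqrt(2 ln 2)) / voxel_mm[axis]`
#' voxels, using half-sample reflective boundaries. The discrete kernel is
#' sampled from the Gaussian density, truncated at 4 sigma and renormalized,
#' so the filter conserves total intensity.
#'
#' @param vol a [volume()].
#' @param fwhm_mm full width at half maximum in mm; 0 is the identity.
#' @return The smoothed [volume()].
#' @export
gaussian_smooth <- function(vol, fwhm_mm) {
  stopifnot(is_volume(vol))
  if (!is.finite(fwhm_mm) || fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  if (fwhm_mm == 0) return(vol)
  out <- vol$values
  for (axis in 1:3) {
    sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / vol$voxel_mm[axis]
    r <- max(1L, as.integer(ceiling(4 * sigma)))
    k <- stats::dnorm(seq(-r, r), sd = sigma)
    k <- k / sum(k)
    C <- conv_matrix_reflect(dim(out)[axis], k)
    out <- apply_along_axis(out, C, axis)
  }
  with_values(vol, out)
}

# one 6-neighbourhood erosion of a logical mask
erode_mask <- function(mask) {
  d <- dim(mask)
  shift <- function(m, axis, by) {
    out <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[axis]
    if (by > 0) { idx_dst[[axis]] <- 2:n; idx_src[[axis]] <- 1:(n - 1) }
    else { idx_dst[[axis]] <- 1:(n - 1); idx_src[[axis]] <- 2:n }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  out <- mask
  for (axis in 1:3) for (by in c(-1, 1)) out <- out & shift(mask, axis, by)
  out
}

#' Mueller-Gaertner partial volume correction
#'
#' Three-compartment voxel-wise correction of PET for the scanner point
#' spread function (PSF): spill-in from white matter and CSF is removed
#' using their PSF-smoothed tissue maps and reference activities, and the
#' result is divided by the PSF-smoothed gray-matter map,
#' `GM_corr = (PET - mu_WM G(wm) - mu_CSF G(csf)) / G(gm)`.
#' Reference activities `mu_WM`, `mu_CSF` are mean PET over voxels with
#' compartment probability >= 0.9 after one erosion. The correction is only
#' defined where `G(gm) >= gm_floor`; other voxels are returned as `NA`.
#'
#' @param pet PET [volume()].
#' @param gm,wm,csf tissue probability [volume()]s in `[0, 1]`.
#' @param fwhm_mm PSF full width at half maximum in mm (default 6).
#' @param gm_floor minimum smoothed GM fraction for a defined correction,
#'   in (0, 1); default 0.3.
#' @return A [volume()] of corrected GM activity, `NA` where undefined.
#' @export
muller_gartner_pvc <- function(pet, gm, wm, csf, fwhm_mm = 6, gm_floor = 0.3) {
  for (v in list(pet, gm, wm, csf)) stopifnot(is_volume(v))
  check_same_lattice(pet, gm); check_same_lattice(pet, wm)
  check_same_lattice(pet, csf)
  if (!is.finite(fwhm_mm) || fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  if (gm_floor <= 0 || gm_floor >= 1) stop("gm_floor must be in (0, 1)")
  if (all(gm$values == 0)) stop("all-zero GM map")

  mu_ref <- function(prob, act) {
    core <- erode_mask(prob$values >= 0.9)
    if (!any(core)) core <- prob$values >= 0.9
    if (!any(core)) return(0)
    mean(act$values[core])
  }
  mu_wm <- mu_ref(wm, pet)
  mu_csf <- mu_ref(csf, pet)

  g_gm <- gaussian_smooth(gm, fwhm_mm)$values
  g_wm <- gaussian_smooth(wm, fwhm_mm)$values
  g_csf <- gaussian_smooth(csf, fwhm_mm)$values

  out <- (pet$values - mu_wm * g_wm - mu_csf * g_csf) / g_gm
  out[g_gm < gm_floor] <- NA_real_
  res <- with_values(pet, out)
  attr(res, "mu_wm") <- mu_wm
  attr(res, "mu_csf") <- mu_csf
  res
}

#' Voxel-wise interhemispheric asymmetry-index map
#'
#' Computes `AI = (i1 - i2) / ((i1 + i2) * 0.5)` where `i2` is the
#' midsagittal flip of `i1`. For nonnegative images the AI is bounded in
#' `[-2, 2]` and antisymmetric under the flip. Standardized images can be
#' negative, which breaks the formula's premise, so by default (`shift =
#' "auto"`) any image with negative within-mask values is first shifted so
#' its within-mask minimum equals 1% of its range; the shift is a global
#' scalar and therefore preserves antisymmetry.
#'
#' @param vol a [volume()] in symmetric space.
#' @param eps denominator guard: voxels with `|(i1+i2)/2| < eps` are invalid.
#' @param mask optional logical array restricting where the AI is defined
#'   (intersected with its own flip so homologous voxels are both in-brain);
#'   `NA` voxels in `vol` are likewise invalid.
#' @param shift `"auto"`, `"none"`, or `"minmax"` (always shift).
#' @return An object of class `pnms_ai_map` with fields `values` (AI, `NA`
#'   where invalid), `valid_mask`, `voxel_mm`.
#' @export
asymmetry_index_map <- function(vol, eps = 1e-6, mask = NULL,
                                shift = c("auto", "none", "minmax")) {
  stopifnot(is_volume(vol))
  shift <- match.arg(shift)
  if (!is.finite(eps) || eps <= 0) stop("eps must be > 0")
  if (!vol$symmetric_space) stop("volume not in symmetric space")
  d <- dim(vol$values)
  msk <- if (is.null(mask)) array(TRUE, d) else as_mask(mask, d)
  msk <- msk & !is.na(vol$values)

  v <- vol$values
  inmask <- v[msk]
  do_shift <- shift == "minmax" ||
    (shift == "auto" && length(inmask) > 0 && any(inmask < 0))
  if (do_shift) {
    rng <- range(inmask)
    v <- v - rng[1] + 0.01 * (rng[2] - rng[1])
  }
  v[!msk] <- NA_real_

  vwork <- with_values(vol, v)
  i2 <- midsagittal_flip(vwork)$values
  denom <- (v + i2) * 0.5
  valid <- msk & !is.na(i2) & abs(denom) >= eps
  ai <- array(NA_real_, d)
  ai[valid] <- (v[valid] - i2[valid]) / denom[valid]
  structure(
    list(values = ai, valid_mask = valid, voxel_mm = vol$voxel_mm,
         shifted = do_shift, eps = eps),
    class = "pnms_ai_map"
  )
}

#' @export
print.pnms_ai_map <- function(x, ...) {
  cat(sprintf("<pnms_ai_map %s, %d valid voxels, shifted=%s>\n",
              paste(dim(x$values), collapse = "x"), sum(x$valid_mask),
              x$shifted))
  invisible(x)
}

#' Proportional scaling normalization
#'
#' Divides by the within-mask mean (global-mean scaling to 1), an
#' alternative to [zscore_within_mask()] for interindividual intensity
#' normalization.
#'
#' @inheritParams zscore_within_mask
#' @return A [volume()] with within-mask mean 1; outside-mask voxels 0.
#' @export
proportional_scale <- function(vol, mask) {
  stopifnot(is_volume(vol))
  mask <- as_mask(mask, dim(vol$values))
  if (!any(mask)) stop("empty mask")
  m <- mean(vol$values[mask])
  if (!is.finite(m) || abs(m) < .Machine$double.eps) stop("zero-mean image")
  out <- array(0, dim(vol$values))
  out[mask] <- vol$values[mask] / m
  with_values(vol, out)
}
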