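# Synthetic mTLE phantom cohort ------------------------------------------
#
# Aligned multimodal phantom subjects with the statistical structure the
# asymmetry analysis assumes: lateralized hippocampal PET hypometabolism
# whose severity correlates with hippocampal atrophy, an ablation cavity
# covering a controllable fraction of the hypometabolic region, and a
# 1-year seizure-freedom outcome driven by that coverage through a
# logistic link calibrated to a target seizure-free prevalence.

#' Phantom generator specification
#'
#' @param grid_shape integer triple; the x dimension must be even so the
#'   midsagittal plane falls between voxel columns. Default `c(48,48,48)`.
#' @param voxel_mm voxel size in mm, default `c(2,2,2)`.
#' @param roi_radius_vox hippocampal sphere radius in voxels (default 5);
#'   the amygdala uses `amyg_radius_vox` (default 3).
#' @param amyg_radius_vox amygdala sphere radius in voxels.
#' @param hypometabolism_depth mean fractional PET reduction in the
#'   ipsilateral hippocampus, in `[0,1]` (default 0.30).
#' @param atrophy_fraction mean fractional gray-matter/volume loss in the
#'   ipsilateral hippocampus, in `[0,1]` (default 0.15).
#' @param noise_sd additive Gaussian voxel noise SD (default 0.05).
#' @param ablation_coverage fraction of the subject's hypometabolic region
#'   covered by the ablation cavity, in `[0,1]` (default 0.6; per-subject
#'   draws in [make_cohort()] come from `Beta(coverage_shape1,
#'   coverage_shape2)`).
#' @param outcome_beta logistic slope linking true ablative coverage to
#'   seizure freedom (default 6).
#' @param planted_threshold AI value defining the "true" hypometabolic
#'   region used to place the ablation cavity (default -0.06).
#' @param prevalence target expected seizure-free fraction (default 0.70).
#' @param coverage_shape1,coverage_shape2 Beta parameters for per-subject
#'   coverage draws (default 2.5, 1.8; mean ~0.58).
#' @param depth_sd,atrophy_sd per-subject SDs of depth and atrophy draws.
#' @param depth_atrophy_cor correlation between per-subject depth and
#'   atrophy draws (default 0.5).
#' @param p_left probability of a left-sided epileptogenic zone (default
#'   0.6).
#' @param seed base RNG seed (default 1).
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(48L, 48L, 48L), voxel_mm = c(2, 2, 2),
                         roi_radius_vox = 5L, amyg_radius_vox = 3L,
                         hypometabolism_depth = 0.30, atrophy_fraction = 0.15,
                         noise_sd = 0.05, ablation_coverage = 0.6,
                         outcome_beta = 6, planted_threshold = -0.06,
                         prevalence = 0.70,
                         coverage_shape1 = 2.5, coverage_shape2 = 1.8,
                         depth_sd = 0.10, atrophy_sd = 0.06,
                         depth_atrophy_cor = 0.5, p_left = 0.6, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (grid_shape[1] %% 2L != 0L) stop("asymmetric grid")
  fracs <- c(hypometabolism_depth, atrophy_fraction, ablation_coverage,
             prevalence, p_left)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (roi_radius_vox <= 0 || amyg_radius_vox <= 0) stop("ROI radii must be positive")
  structure(as.list(environment()), class = "phantom_spec")
}

combine_seeds <- function(a, b) {
  ((as.integer(a) %% 46337L) * 46337L + as.integer(b) %% 46337L) %% 2147483647L
}

# squared-distance field (in voxels) from a center, plus sphere helper;
# brain_scale scales the whole (symmetric) ellipsoid so total intracranial
# volume varies across subjects
phantom_geometry <- function(spec, brain_scale = 1) {
  d <- spec$grid_shape
  ii <- array(rep(seq_len(d[1]), times = d[2] * d[3]), d)
  jj <- array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), d)
  kk <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
  cx <- d[1] / 2 + 0.5; cy <- (d[2] + 1) / 2; cz <- (d[3] + 1) / 2
  rho2 <- ((ii - cx) / (0.42 * d[1] * brain_scale))^2 +
    ((jj - cy) / (0.44 * d[2] * brain_scale))^2 +
    ((kk - cz) / (0.40 * d[3] * brain_scale))^2
  sphere <- function(center, r)
    (ii - center[1])^2 + (jj - center[2])^2 + (kk - center[3])^2 <= r^2
  dist_from <- function(center)
    sqrt((ii - center[1])^2 + (jj - center[2])^2 + (kk - center[3])^2)
  off <- max(6, round(0.2 * d[1]))
  centers <- list(
    hippo_l = c(cx - off, cy + 2, cz - 2), hippo_r = c(cx + off, cy + 2, cz - 2),
    amyg_l = c(cx - off, cy - 7, cz - 1), amyg_r = c(cx + off, cy - 7, cz - 1)
  )
  # mirror a left-hemisphere point into the right hemisphere
  mirror <- function(p) c(2 * cx - p[1], p[2], p[3])
  list(rho = sqrt(rho2), sphere = sphere, dist_from = dist_from,
       centers = centers, mirror = mirror, dims = d)
}

#' Generate one aligned multimodal phantom subject
#'
#' Builds symmetric tissue maps (ellipsoidal brain with a gray-matter
#' shell, white-matter core, CSF rim, and mirrored spherical hippocampus /
#' amygdala ROIs), then plants the disease effects: ipsilateral
#' hippocampal PET activity multiplied by `1 - depth`, gray-matter density
#' multiplied by `1 - atrophy` with the ipsilateral hippocampal label
#' eroded to `(1 - atrophy)` of its volume, FLAIR mildly increased, and an
#' ablation cavity covering `coverage` of the voxels whose noiseless PET
#' asymmetry index falls at or below the planted threshold. Additive
#' Gaussian noise is applied after effect insertion. The output is
#' bit-identical for identical `(spec$seed, subject_seed)`.
#'
#' @param spec a [phantom_spec()].
#' @param subject_seed integer distinguishing subjects.
#' @param ez_side `"left"` or `"right"` epileptogenic zone; default drawn
#'   from `spec$p_left`.
#' @param depth,atrophy,coverage optional per-subject overrides of the
#'   spec's mean effect sizes.
#' @return A `subject_images` list: `pet`, `gm_density`, `flair`,
#'   `tissue_gm`, `tissue_wm`, `tissue_csf`, `roi_labels`, `ablation_mask`,
#'   `brain_mask`, `ez_side`, `outcome` (NA here; assigned by
#'   [make_cohort()]), and `truth` (planted parameters).
#' @export
make_phantom_subject <- function(spec, subject_seed, ez_side = NULL,
                                 depth = NULL, atrophy = NULL,
                                 coverage = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$grid_shape[1] %% 2L != 0L) stop("asymmetric grid")
  d <- spec$grid_shape
  vol0 <- function(v) volume(array(v, d), spec$voxel_mm, TRUE)

  out <- withr::with_seed(combine_seeds(spec$seed, subject_seed), {
    if (is.null(ez_side))
      ez_side <- if (stats::runif(1) < spec$p_left) "left" else "right"
    if (is.null(depth)) depth <- spec$hypometabolism_depth
    if (is.null(atrophy)) atrophy <- spec$atrophy_fraction
    if (is.null(coverage)) coverage <- spec$ablation_coverage
    if (coverage < 0 || coverage > 1) stop("coverage outside [0, 1]")
    if (depth < 0 || depth > 1) stop("depth outside [0, 1]")

    # per-subject anatomy: head size, mirrored sub-voxel ROI-centre jitter,
    # per-side segmentation-label radius variation, amygdalar atrophy
    brain_scale <- 1 + 0.03 * stats::rnorm(1)
    jit <- stats::runif(3, -0.5, 0.5)
    rad_jit <- 1 + 0.02 * stats::rnorm(4)      # Lh, Rh, La, Ra label radii
    amyg_atrophy <- min(max(0.4 * atrophy + 0.03 * stats::rnorm(1), 0), 0.5)
    geo <- phantom_geometry(spec, brain_scale)

    brain <- geo$rho <= 1
    csf_rim <- brain & geo$rho > 0.92
    gm_shell <- brain & geo$rho > 0.72 & geo$rho <= 0.92
    wm_core <- brain & geo$rho <= 0.72

    rois <- list(
      hippo_l = geo$sphere(geo$centers$hippo_l, spec$roi_radius_vox),
      hippo_r = geo$sphere(geo$centers$hippo_r, spec$roi_radius_vox),
      amyg_l = geo$sphere(geo$centers$amyg_l, spec$amyg_radius_vox),
      amyg_r = geo$sphere(geo$centers$amyg_r, spec$amyg_radius_vox)
    )
    roi_any <- Reduce(`|`, rois)

    gm <- array(0, d); wm <- array(0, d); csf <- array(0, d)
    gm[gm_shell] <- 0.85; wm[gm_shell] <- 0.05; csf[gm_shell] <- 0.02
    wm[wm_core] <- 0.85; gm[wm_core] <- 0.10
    csf[csf_rim] <- 0.85; gm[csf_rim] <- 0.05
    gm[roi_any] <- 0.90; wm[roi_any] <- 0.05; csf[roi_any] <- 0

    # segmentation labels: independent of the symmetric intensity geometry
    # (as anatomical labels are in practice), with per-side radius
    # variation, mirrored centre jitter, and the ipsilateral structures
    # eroded so label volume is reduced by ~atrophy (hippocampus) and
    # ~amyg_atrophy (amygdala)
    hc <- geo$centers[[if (ez_side == "left") "hippo_l" else "hippo_r"]]
    lab_centers <- list(
      hippo_l = geo$centers$hippo_l + jit,
      hippo_r = geo$mirror(geo$centers$hippo_l + jit),
      amyg_l = geo$centers$amyg_l + jit,
      amyg_r = geo$mirror(geo$centers$amyg_l + jit)
    )
    shrink_h <- (1 - atrophy)^(1 / 3)
    shrink_a <- (1 - amyg_atrophy)^(1 / 3)
    lab_r <- c(
      hippo_l = spec$roi_radius_vox * rad_jit[1] *
        if (ez_side == "left") shrink_h else 1,
      hippo_r = spec$roi_radius_vox * rad_jit[2] *
        if (ez_side == "right") shrink_h else 1,
      amyg_l = spec$amyg_radius_vox * rad_jit[3] *
        if (ez_side == "left") shrink_a else 1,
      amyg_r = spec$amyg_radius_vox * rad_jit[4] *
        if (ez_side == "right") shrink_a else 1
    )
    labels <- array(0L, d)
    labels[geo$sphere(lab_centers$hippo_l, lab_r["hippo_l"])] <- 1L
    labels[geo$sphere(lab_centers$hippo_r, lab_r["hippo_r"])] <- 2L
    labels[geo$sphere(lab_centers$amyg_l, lab_r["amyg_l"])] <- 3L
    labels[geo$sphere(lab_centers$amyg_r, lab_r["amyg_r"])] <- 4L

    # disease effects cover the ipsilateral structure as segmented (label)
    # together with the symmetric intensity sphere, so every labelled voxel
    # carries the full planted effect; the amygdalar effect excludes any
    # hippocampal-effect voxel so the two factors never compound
    ipsi_h <- (if (ez_side == "left") rois$hippo_l else rois$hippo_r) |
      labels == (if (ez_side == "left") 1L else 2L)
    ipsi_a <- ((if (ez_side == "left") rois$amyg_l else rois$amyg_r) |
                 labels == (if (ez_side == "left") 3L else 4L)) & !ipsi_h

    pet_true <- 1.0 * gm + 0.5 * wm + 0.05 * csf
    pet_true[ipsi_h] <- pet_true[ipsi_h] * (1 - depth)
    pet_true[ipsi_a] <- pet_true[ipsi_a] * (1 - 0.4 * depth)

    gmdens_true <- gm
    gmdens_true[ipsi_h] <- gmdens_true[ipsi_h] * (1 - atrophy)
    flair_true <- 0.8 * gm + 0.6 * wm + 0.2 * csf
    flair_true[ipsi_h] <- flair_true[ipsi_h] * (1 + 0.5 * atrophy)

    # ablation cavity over the true hypometabolic region
    ai_true <- asymmetry_index_map(vol0(pet_true), eps = 1e-6, mask = brain,
                                   shift = "none")
    hemi <- hemisphere_mask(vol0(0), ez_side)
    cand <- hemi & ai_true$valid_mask & !is.na(ai_true$values) &
      ai_true$values <= spec$planted_threshold &
      geo$dist_from(hc) <= 2.5 * spec$roi_radius_vox
    if (!any(cand)) cand <- ipsi_h & brain
    idx <- which(cand)
    ord <- order(geo$dist_from(hc)[idx], idx)     # deterministic, center-out
    take <- idx[ord][seq_len(round(coverage * length(idx)))]
    ablation <- array(FALSE, d)
    ablation[take] <- TRUE
    ablation <- ablation & brain

    noisy <- function(v) {
      v[brain] <- v[brain] + stats::rnorm(sum(brain), 0, spec$noise_sd)
      v
    }
    list(
      pet = vol0(noisy(pet_true)), gm_density = vol0(noisy(gmdens_true)),
      flair = vol0(noisy(flair_true)),
      tissue_gm = vol0(gm), tissue_wm = vol0(wm), tissue_csf = vol0(csf),
      roi_labels = vol0(labels), ablation_mask = vol0(ablation * 1),
      brain_mask = vol0(brain * 1), ez_side = ez_side, outcome = NA_character_,
      truth = list(depth = depth, atrophy = atrophy, coverage = coverage,
                   realized_coverage = sum(ablation) / max(1L, length(idx)),
                   planted_threshold = spec$planted_threshold,
                   ez_side = ez_side, subject_seed = subject_seed,
                   pet_noiseless = pet_true)
    )
  })
  class(out) <- "subject_images"
  out
}

#' @export
print.subject_images <- function(x, ...) {
  cat(sprintf("<subject_images %s EZ, depth %.2f, atrophy %.2f, coverage %.2f, outcome %s>\n",
              x$ez_side, x$truth$depth, x$truth$atrophy, x$truth$coverage,
              x$outcome))
  invisible(x)
}

#' Calibrate the outcome-model intercept to a target prevalence
#'
#' Solves for the intercept `alpha` such that the expected seizure-free
#' fraction `E[plogis(alpha + beta * coverage)]` over the coverage
#' distribution `Beta(shape1, shape2)` equals the target prevalence.
#'
#' @param beta logistic slope on coverage.
#' @param prevalence target seizure-free fraction.
#' @param shape1,shape2 Beta parameters of the coverage distribution.
#' @return The intercept `alpha`.
#' @export
calibrate_outcome_intercept <- local({
  cache <- new.env(parent = emptyenv())
  function(beta, prevalence = 0.70, shape1 = 2.5, shape2 = 1.8) {
    key <- paste(beta, prevalence, shape1, shape2, sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    f <- function(a)
      stats::integrate(function(c) stats::plogis(a + beta * c) *
                         stats::dbeta(c, shape1, shape2), 0, 1,
                       rel.tol = 1e-10)$value - prevalence
    cache[[key]] <- stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
    cache[[key]]
  }
})

#' Generate a phantom cohort with outcomes
#'
#' Draws per-subject hypometabolism depth and atrophy from a correlated
#' bivariate normal (correlation `spec$depth_atrophy_cor`, clamped to
#' plausible ranges), ablative coverage from
#' `Beta(coverage_shape1, coverage_shape2)`, and the seizure-freedom
#' outcome from `Bernoulli(plogis(alpha + outcome_beta * coverage))` with
#' `alpha` calibrated so the expected seizure-free fraction equals
#' `spec$prevalence`. Clinical covariates (side of the epileptogenic zone,
#' SEEG implantation, age at onset, epilepsy duration) are drawn to match
#' the emulated cohort's demographics.
#'
#' @param n number of subjects (>= 2), default 30.
#' @param spec a [phantom_spec()]; its `seed` is replaced by `seed`.
#' @param seed integer cohort seed.
#' @param images if `FALSE`, skip image synthesis and return only the
#'   truth/covariate table (fast path for calibration studies).
#' @return List: `subjects` (list of `subject_images`, or `NULL`),
#'   `table` (data.frame: `subject_id`, `ez_side`, `seeg`, `age_onset`,
#'   `duration`, `depth`, `atrophy`, `coverage`, `outcome` "SF"/"NSF").
#' @export
make_cohort <- function(n = 30, spec = phantom_spec(), seed = 1,
                        images = TRUE) {
  if (n < 2) stop("need n >= 2 subjects")
  spec$seed <- as.integer(seed)
  alpha <- calibrate_outcome_intercept(spec$outcome_beta, spec$prevalence,
                                       spec$coverage_shape1,
                                       spec$coverage_shape2)
  tab <- withr::with_seed(combine_seeds(seed, 7919L), {
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    rho <- spec$depth_atrophy_cor
    depth <- pmin(pmax(spec$hypometabolism_depth + spec$depth_sd * z1,
                       0.05), 0.60)
    atrophy <- pmin(pmax(spec$atrophy_fraction +
                           spec$atrophy_sd * (rho * z1 + sqrt(1 - rho^2) * z2),
                         0.02), 0.45)
    coverage <- stats::rbeta(n, spec$coverage_shape1, spec$coverage_shape2)
    outcome <- stats::rbinom(n, 1, stats::plogis(alpha + spec$outcome_beta * coverage))
    data.frame(
      subject_id = sprintf("sub%03d", seq_len(n)),
      ez_side = ifelse(stats::runif(n) < spec$p_left, "left", "right"),
      seeg = stats::rbinom(n, 1, 8 / 30),
      age_onset = round(stats::rnorm(n, 21.84, 8.63), 1),
      duration = round(exp(stats::rnorm(n, log(10), 0.7)), 1),
      depth = depth, atrophy = atrophy, coverage = coverage,
      outcome = ifelse(outcome == 1, "SF", "NSF"),
      stringsAsFactors = FALSE
    )
  })
  subjects <- NULL
  if (images) {
    subjects <- lapply(seq_len(n), function(i) {
      s <- make_phantom_subject(spec, subject_seed = i,
                                ez_side = tab$ez_side[i],
                                depth = tab$depth[i],
                                atrophy = tab$atrophy[i],
                                coverage = tab$coverage[i])
      s$outcome <- tab$outcome[i]
      s
    })
  }
  list(subjects = subjects, table = tab, alpha = alpha, spec = spec)
}

#' Simulate an AI/outcome cohort with a planted dose-response threshold
#'
#' Table-level generator for threshold-recovery studies: per-subject PET
#' asymmetry indices `x ~ N(x_mean, x_sd)` and a binary outcome from a
#' logistic model whose log-odds change direction (shape `"U"`, a
#' quadratic with its vertex at the threshold) or change slope (shape
#' `"L"`, flat below the threshold, rising above) exactly at `threshold`.
#'
#' @param n subjects.
#' @param threshold planted reference value (default -0.06).
#' @param shape `"U"` or `"L"`.
#' @param seed RNG seed.
#' @param x_mean,x_sd AI distribution (defaults `threshold`, 0.10).
#' @param eta0 log-odds at the threshold (default 1.5 for `"U"`, 0 for
#'   `"L"`).
#' @param curvature quadratic coefficient for `"U"` (default 50).
#' @param slope hinge slope for `"L"` (default 12).
#' @return data.frame `ai`, `outcome` (0/1), `eta`.
#' @export
simulate_threshold_cohort <- function(n, threshold = -0.06,
                                      shape = c("U", "L"), seed = 1,
                                      x_mean = threshold, x_sd = 0.10,
                                      eta0 = NULL, curvature = 50,
                                      slope = 12) {
  shape <- match.arg(shape)
  if (is.null(eta0)) eta0 <- if (shape == "U") 1.5 else 0
  withr::with_seed(as.integer(seed) %% 2147483647L, {
    x <- stats::rnorm(n, x_mean, x_sd)
    eta <- if (shape == "U") eta0 - curvature * (x - threshold)^2
           else eta0 + slope * pmax(x - threshold, 0)
    y <- stats::rbinom(n, 1, stats::plogis(eta))
    data.frame(ai = x, outcome = y, eta = eta)
  })
}

#' Simulate a structural-features cohort with hippocampal-volume coupling
#'
#' Table-level generator for the interpretation stage: total intracranial
#' volume, ipsilateral hippocampal and amygdalar volumes (mm^3), their
#' volumetric asymmetry indices, and a per-patient PET asymmetry index
#' driven most strongly by hippocampal volume (coefficient 0.045 AI per SD
#' of hippocampal volume, vs <= 0.020 for every other feature), with
#' residual noise SD 0.03.
#'
#' @param n subjects (default 30).
#' @param seed RNG seed.
#' @param hippo_beta AI change per SD of hippocampal volume (default
#'   0.045; smaller volume means more negative AI).
#' @return data.frame: `tiv`, `hippo_volume_ipsi`, `amyg_volume_ipsi`,
#'   `hippo_vai`, `amyg_vai`, `pet_ai`.
#' @export
simulate_structural_cohort <- function(n = 30, seed = 1, hippo_beta = 0.045) {
  withr::with_seed(as.integer(seed) %% 2147483647L, {
    zt <- stats::rnorm(n)
    zh <- 0.4 * zt + sqrt(1 - 0.16) * stats::rnorm(n)
    za <- 0.3 * zt + sqrt(1 - 0.09) * stats::rnorm(n)
    zvh <- 0.5 * zh + sqrt(1 - 0.25) * stats::rnorm(n)
    zva <- 0.4 * za + sqrt(1 - 0.16) * stats::rnorm(n)
    pet_ai <- -0.10 + hippo_beta * zh + 0.020 * zvh + 0.012 * zt +
      0.008 * za + 0.005 * zva + stats::rnorm(n, 0, 0.03)
    data.frame(
      tiv = 1.45e6 + 1.2e5 * zt,
      hippo_volume_ipsi = 3200 + 450 * zh,
      amyg_volume_ipsi = 1600 + 250 * za,
      hippo_vai = -0.06 + 0.03 * zvh,
      amyg_vai = -0.03 + 0.02 * zva,
      pet_ai = pet_ai
    )
  })
}

# piecewise-linear quantile-function draws matching printed quartiles
quantile_match_draws <- function(n, qs, lo, hi) {
  p <- (seq_len(n) - 0.5) / n
  round(stats::approx(c(0, 0.25, 0.5, 0.75, 1), c(lo, qs, hi), xout = p)$y, 1)
}

# z-scored draws rescaled so the sample mean/SD match exactly
moment_match_draws <- function(n, mean, sd, seed_offset) {
  z <- withr::with_seed(combine_seeds(20240101L, seed_offset),
                        stats::rnorm(n))
  round(mean + sd * (z - base::mean(z)) / stats::sd(z), 1)
}

#' Packaged 30-patient demographic fixture (synthetic)
#'
#' A deterministic 30-row cohort table reproducing the marginal counts of
#' the emulated mTLE cohort's demographic table: 21 seizure-free / 9 not
#' seizure-free, 16 female, 18 left-sided epileptogenic zones, 8 SEEG
#' implantations, and all other categorical fields with their per-group
#' counts. Continuous fields are synthetic draws whose group sample
#' mean/SD (ages) match the printed summaries exactly, and whose epilepsy
#' durations are drawn from a piecewise-linear quantile function through
#' the printed median and quartiles. Individual rows are synthetic; only
#' the summaries are meaningful.
#'
#' @return data.frame with attribute `synthetic = TRUE`.
#' @export
table1_fixture <- function() {
  n_sf <- 21L; n_nsf <- 9L
  field_no <- 0L
  grp <- function(yes_sf, yes_nsf, levels = c("no", "yes")) {
    field_no <<- field_no + 1L
    pick <- function(n, k, off) {
      v <- rep(levels[1], n)
      sel <- withr::with_seed(combine_seeds(20240101L, off),
                              sample.int(n, k))
      v[sel] <- levels[2]
      v
    }
    c(pick(n_nsf, yes_nsf, 1000L + field_no),
      pick(n_sf, yes_sf, 2000L + field_no))
  }
  df <- data.frame(
    subject_id = sprintf("sub%03d", 1:30),
    outcome = c(rep("NSF", n_nsf), rep("SF", n_sf)),
    gender = grp(12, 4, c("male", "female")),
    ez_side = grp(12, 6, c("right", "left")),
    age_onset = c(moment_match_draws(n_nsf, 23.76, 11.80, 11L),
                  moment_match_draws(n_sf, 21.01, 7.07, 12L)),
    duration = c(quantile_match_draws(n_nsf, c(7, 11, 20), 2, 30),
                 quantile_match_draws(n_sf, c(5, 7, 18), 1, 35)),
    age_surgery = c(moment_match_draws(n_nsf, 37.67, 12.67, 13L),
                    moment_match_draws(n_sf, 32.24, 10.41, 14L)),
    iid = grp(10, 4, c("bilateral_diffuse", "focal_regional")),
    id = grp(14, 7, c("bilateral_diffuse", "focal_regional")),
    aura = grp(16, 7),
    loc = grp(21, 8),
    automatism = grp(19, 7),
    icdp = grp(7, 2),
    f2btcs = grp(9, 6),
    hippocampal_atrophy = grp(16, 6),
    ihi = grp(8, 2),
    tp_atrophy = grp(13, 5),
    flair_increase = grp(20, 9),
    pet_hypometabolism = grp(20, 9),
    seeg = grp(4, 4),
    stringsAsFactors = FALSE
  )
  attr(df, "synthetic") <- TRUE
  df
}

#' Write a phantom subject to disk
#'
#' One NIfTI file per map plus a JSON truth sidecar.
#'
#' @param subject a `subject_images`.
#' @param dir output directory (created if needed).
#' @param id subject identifier used as the filename stem.
#' @return The directory, invisibly.
#' @export
write_subject <- function(subject, dir, id = "subject") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  maps <- c("pet", "gm_density", "flair", "tissue_gm", "tissue_wm",
            "tissue_csf", "roi_labels", "ablation_mask", "brain_mask")
  for (m in maps)
    write_volume(subject[[m]], file.path(dir, paste0(id, "_", m, ".nii.gz")))
  truth <- subject$truth
  truth$pet_noiseless <- NULL
  jsonlite::write_json(
    c(truth, list(ez_side = subject$ez_side, outcome = subject$outcome)),
    file.path(dir, paste0(id, "_truth.json")), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
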