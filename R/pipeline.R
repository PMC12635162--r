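# End-to-end driver: simulate -> preprocess -> pNMS -> stats -> interpret.
# All numeric outputs are plain CSV/JSON so a rerun with the same config is
# byte-identical.

#' Pipeline run configuration
#'
#' @param seed integer master seed for the synthetic cohort and the
#'   cross-validation partitions.
#' @param n cohort size (default 30).
#' @param fwhm_mm Gaussian smoothing / PSF width in mm (default 6).
#' @param pvc apply Mueller-Gaertner partial volume correction to PET
#'   (default `TRUE`).
#' @param eps AI denominator guard (default 1e-6).
#' @param gm_floor minimum smoothed GM fraction for a defined PVC value.
#' @param threshold pNMS asymmetry-index threshold (default -0.06).
#' @param knot_probs spline knot percentiles.
#' @param or_scale odds-ratio unit for continuous AI features (default
#'   0.01 AI).
#' @param cv_k,cv_iterations cross-validation folds and repetitions.
#' @param grid_n dose-response curve grid size.
#' @param order preprocessing order tag recorded with every run.
#' @param out_dir optional output directory; `NULL` keeps results in
#'   memory only.
#' @return A named list (class `pnms_config`).
#' @export
run_config <- function(seed = 1L, n = 30L, fwhm_mm = 6, pvc = TRUE,
                       eps = 1e-6, gm_floor = 0.3, threshold = -0.06,
                       knot_probs = c(0.10, 0.50, 0.90), or_scale = 0.01,
                       cv_k = 5L, cv_iterations = 1000L, grid_n = 200L,
                       order = c("smooth", "pvc", "zscore", "ai"),
                       out_dir = NULL) {
  cfg <- list(seed = as.integer(seed), n = as.integer(n), fwhm_mm = fwhm_mm,
              pvc = isTRUE(pvc), eps = eps, gm_floor = gm_floor,
              threshold = threshold, knot_probs = knot_probs,
              or_scale = or_scale, cv_k = as.integer(cv_k),
              cv_iterations = as.integer(cv_iterations),
              grid_n = as.integer(grid_n), order = order, out_dir = out_dir)
  class(cfg) <- c("pnms_config", "list")
  cfg
}

#' Serialize / restore a run configuration
#'
#' JSON round trip: `read_config(write_config(cfg, path))` reproduces the
#' configuration exactly.
#'
#' @param cfg a [run_config()].
#' @param path file path.
#' @return `write_config` returns `path`; `read_config` returns the
#'   configuration.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw[!vapply(raw, is.null, logical(1))])
}

#' Preprocess one subject into asymmetry-index maps
#'
#' PET: Gaussian smoothing (`fwhm_mm`), optional Mueller-Gaertner partial
#' volume correction, z-standardization within the brain mask, and AI
#' mapping. Gray-matter density and FLAIR: standardization and AI mapping.
#'
#' @param subject a `subject_images`.
#' @param config a [run_config()].
#' @return List of `pnms_ai_map`s: `pet`, `gm`, `flair`, plus `brain`
#'   (logical array).
#' @export
preprocess_subject <- function(subject, config = run_config()) {
  brain <- subject$brain_mask$values != 0
  pet <- gaussian_smooth(subject$pet, config$fwhm_mm)
  if (config$pvc) {
    pet <- muller_gartner_pvc(pet, subject$tissue_gm, subject$tissue_wm,
                              subject$tissue_csf, fwhm_mm = config$fwhm_mm,
                              gm_floor = config$gm_floor)
  }
  ai_for <- function(vol) {
    ok <- brain & !is.na(vol$values)
    z <- zscore_within_mask(with_values(vol, ifelse(is.na(vol$values), 0,
                                                    vol$values)), ok)
    z$values[!ok] <- NA_real_
    asymmetry_index_map(z, eps = config$eps, mask = ok, shift = "auto")
  }
  list(pet = ai_for(pet), gm = ai_for(subject$gm_density),
       flair = ai_for(subject$flair), brain = brain)
}

#' Per-subject imaging features
#'
#' Mean AI of each modality within the ablation cavity, structural volumes
#' (total intracranial, ipsilateral hippocampus and amygdala, in mm^3),
#' volumetric asymmetry indices, and pNMS ablative rates within the
#' ipsilateral hippocampus and amygdala.
#'
#' @param subject a `subject_images`.
#' @param ai output of [preprocess_subject()].
#' @param config a [run_config()].
#' @return One-row data.frame.
#' @export
subject_features <- function(subject, ai, config = run_config()) {
  voxvol <- prod(subject$pet$voxel_mm)
  lab <- subject$roi_labels$values
  abl <- subject$ablation_mask$values != 0
  side <- subject$ez_side
  hip <- list(left = lab == 1L, right = lab == 2L)
  amy <- list(left = lab == 3L, right = lab == 4L)
  contra <- if (side == "left") "right" else "left"
  vai <- function(ipsi_n, contra_n) {
    m <- (ipsi_n + contra_n) / 2
    if (m == 0) return(NA_real_)
    (ipsi_n - contra_n) / m
  }
  hemi <- hemisphere_mask(subject$pet, side)
  pnms <- suppressWarnings(
    binarize_pnms(ai$pet, config$threshold, hemi, "PET"))
  data.frame(
    pet_ai = mean_ai_within_mask(ai$pet, abl),
    gm_ai = mean_ai_within_mask(ai$gm, abl),
    flair_ai = mean_ai_within_mask(ai$flair, abl),
    tiv = sum(ai$brain) * voxvol,
    hippo_volume_ipsi = sum(hip[[side]]) * voxvol,
    amyg_volume_ipsi = sum(amy[[side]]) * voxvol,
    hippo_vai = vai(sum(hip[[side]]), sum(hip[[contra]])),
    amyg_vai = vai(sum(amy[[side]]), sum(amy[[contra]])),
    ablation_volume = sum(abl) * voxvol,
    pnms_volume_vox = pnms$n_vox,
    rate_hippo = ablative_rate(pnms, abl, hip[[side]]),
    rate_amyg = ablative_rate(pnms, abl, amy[[side]])
  )
}

#' Run the full synthetic-cohort analysis
#'
#' Simulates a phantom cohort, preprocesses every subject into AI maps,
#' assembles the cohort feature table, and runs the three analysis stages:
#' group comparisons and odds ratios per modality, spline dose-response
#' threshold discovery, pNMS ablative-rate evaluation (spline inflection,
#' Youden/ROC, chi-squared at both thresholds), and structural
#' interpretation (additive model, repeated cross-validation, Shapley
#' attribution, partial dependence, actual-vs-predicted correlation).
#' Deterministic given `config$seed`; if `config$out_dir` is set, all
#' tables are written as CSV and the report as JSON.
#'
#' @param config a [run_config()].
#' @return A `pnms_report` list with elements `cohort`, `group_comparisons`,
#'   `or_table`, `rcs`, `ablative`, `interpret`, `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  spec <- phantom_spec(seed = config$seed)
  cohort <- make_cohort(config$n, spec, seed = config$seed)
  feats <- do.call(rbind, lapply(cohort$subjects, function(s) {
    ai <- preprocess_subject(s, config)
    subject_features(s, ai, config)
  }))
  tab <- cbind(cohort$table, feats)
  y <- as.integer(tab$outcome == "SF")
  covars <- cbind(ez_left = as.integer(tab$ez_side == "left"),
                  seeg = tab$seeg, age_onset = tab$age_onset)

  modalities <- c(pet = "pet_ai", gm = "gm_ai", flair = "flair_ai")
  group_comparisons <- do.call(rbind, lapply(names(modalities), function(m) {
    x <- tab[[modalities[m]]]
    tt <- compare_groups(x, tab$outcome, "t")
    ww <- compare_groups(x, tab$outcome, "wilcoxon")
    data.frame(modality = m, mean_sf = unname(tt$means["SF"]),
               mean_nsf = unname(tt$means["NSF"]),
               t = tt$statistic, p_t = tt$p, w = ww$statistic, p_w = ww$p)
  }))

  or_table <- do.call(rbind, lapply(names(modalities), function(m) {
    r <- suppressWarnings(odds_ratio_report(tab[[modalities[m]]], y,
                                            scale = config$or_scale))
    cbind(data.frame(feature = paste0(m, "_ai")), r)
  }))

  rcs <- lapply(names(modalities), function(m) {
    fit <- suppressWarnings(
      rcs_logistic_curve(tab[[modalities[m]]], y, covariates = covars,
                         knot_probs = config$knot_probs,
                         grid_n = config$grid_n))
    list(modality = m, fit = fit, inflection = find_inflection(fit),
         bic_rcs = fit$bic, bic_linear = fit$linear_fit$bic)
  })
  names(rcs) <- names(modalities)

  # ablative-rate analysis (hippocampus), rates in percent
  keep <- !is.na(tab$rate_hippo)
  n_missing <- sum(!keep)
  rate_pct <- tab$rate_hippo[keep] * 100
  y_k <- y[keep]
  rate_fit <- suppressWarnings(
    rcs_logistic_curve(rate_pct, y_k, covariates = NULL,
                       knot_probs = config$knot_probs,
                       grid_n = config$grid_n))
  rate_infl <- find_inflection(rate_fit)
  roc <- roc_youden(rate_pct, y_k, weights = mean(y_k))
  chi2_at <- function(cut) {
    hi <- rate_pct >= cut
    tabm <- rbind(c(sum(hi & y_k == 1), sum(hi & y_k == 0)),
                  c(sum(!hi & y_k == 1), sum(!hi & y_k == 0)))
    if (any(rowSums(tabm) == 0) || any(colSums(tabm) == 0))
      return(list(statistic = NA_real_, p = NA_real_, df = 1))
    pearson_chi2(tabm)
  }
  ablative <- list(
    n_used = sum(keep), n_missing_rate = n_missing,
    t_test = compare_groups(rate_pct, tab$outcome[keep], "t"),
    rcs_fit = rate_fit, inflection = rate_infl,
    roc = roc,
    chi2_youden = chi2_at(roc$threshold),
    chi2_inflection = if (is.na(rate_infl$primary)) NULL
                      else chi2_at(rate_infl$primary)
  )

  features <- c("tiv", "hippo_volume_ipsi", "amyg_volume_ipsi",
                "hippo_vai", "amyg_vai")
  fdat <- tab[keep <- stats::complete.cases(tab[features]) &
                !is.na(tab$pet_ai), , drop = FALSE]
  target <- fdat$pet_ai
  gam_fit <- fit_additive_model(fdat[features], target, features,
                                config$knot_probs)
  cv <- cross_validate(fdat[features], target, features, k = config$cv_k,
                       iterations = config$cv_iterations,
                       seed = combine_seeds(config$seed, 1234L),
                       knot_probs = config$knot_probs)
  shap <- shapley_importance(fdat[features], target, features,
                             config$knot_probs)
  pd <- partial_dependence(gam_fit, fdat[features], "hippo_volume_ipsi")
  pc <- prediction_correlation(target, cv$prediction)
  interpret <- list(fit = gam_fit, cv = cv, shapley = shap, pd = pd,
                    correlation = pc)

  report <- structure(
    list(cohort = tab, group_comparisons = group_comparisons,
         or_table = or_table, rcs = rcs, ablative = ablative,
         interpret = interpret, config = config),
    class = "pnms_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.pnms_report <- function(x, ...) {
  cat(sprintf("<pnms_report n=%d, seed=%d>\n", nrow(x$cohort),
              x$config$seed))
  cat(sprintf("  PET AI inflection: %.4f (%s)\n",
              x$rcs$pet$inflection$primary, x$rcs$pet$inflection$shape))
  cat(sprintf("  ablative-rate Youden cutoff: %.2f%%, AUC %.3f\n",
              x$ablative$roc$threshold, x$ablative$roc$auc))
  cat(sprintf("  actual-vs-predicted r = %.3f (P = %.3g)\n",
              x$interpret$correlation$r, x$interpret$correlation$p))
  invisible(x)
}

write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a pipeline report to disk
#'
#' Writes the cohort table, the per-stage result tables, the fitted curves
#' and interpretation outputs as CSV, the resolved configuration and a
#' numeric summary as JSON. All files are plain text and a rerun with the
#' same configuration reproduces them byte for byte.
#'
#' @param report a `pnms_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_csv_plain(report$cohort, file.path(dir, "cohort.csv"))
  write_csv_plain(report$group_comparisons,
                  file.path(dir, "group_comparisons.csv"))
  write_csv_plain(report$or_table, file.path(dir, "or_table.csv"))
  for (m in names(report$rcs))
    write_csv_plain(report$rcs[[m]]$fit$curve,
                    file.path(dir, sprintf("rcs_curve_%s.csv", m)))
  write_csv_plain(report$ablative$rcs_fit$curve,
                  file.path(dir, "rcs_curve_ablative_rate.csv"))
  shap <- report$interpret$shapley
  write_csv_plain(
    data.frame(feature = colnames(shap$phi),
               mean_signed = unname(shap$mean_signed),
               mean_abs = unname(shap$mean_abs)),
    file.path(dir, "shapley.csv"))
  write_csv_plain(report$interpret$pd, file.path(dir, "pd_hippo_volume.csv"))
  cv <- report$interpret$cv
  write_csv_plain(
    data.frame(actual = report$interpret$fit$fitted + report$interpret$fit$residuals,
               predicted = cv$prediction, ci_lo = cv$ci_lo, ci_hi = cv$ci_hi),
    file.path(dir, "cv_predictions.csv"))
  cfg <- report$config
  cfg$out_dir <- NULL            # a path, not part of the analysis identity
  write_config(cfg, file.path(dir, "config.json"))
  jsonlite::write_json(report_summary(report),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Numeric summary of a pipeline report
#'
#' The headline quantities of each stage as a flat named list, suitable
#' for JSON serialization.
#'
#' @param report a `pnms_report`.
#' @return Named list of scalars.
#' @export
report_summary <- function(report) {
  roc <- report$ablative$roc
  shap <- report$interpret$shapley
  top <- names(which.max(shap$mean_abs))
  list(
    seed = report$config$seed,
    n = nrow(report$cohort),
    sf_fraction = mean(report$cohort$outcome == "SF"),
    pet_ai_t = report$group_comparisons$t[report$group_comparisons$modality == "pet"],
    pet_ai_or = report$or_table$or[report$or_table$feature == "pet_ai"],
    pet_ai_or_scale = report$config$or_scale,
    pet_ai_inflection = report$rcs$pet$inflection$primary,
    pet_ai_shape = report$rcs$pet$inflection$shape,
    pet_ai_p_nonlinearity = report$rcs$pet$fit$p_nonlinearity,
    rate_inflection_pct = report$ablative$inflection$primary,
    rate_youden_cutoff_pct = roc$threshold,
    rate_auc = roc$auc,
    rate_sensitivity = roc$sensitivity,
    rate_specificity = roc$specificity,
    rate_balanced_accuracy = roc$balanced_accuracy,
    rate_weighted_accuracy = roc$weighted_accuracy,
    rate_chi2_youden = report$ablative$chi2_youden$statistic,
    shapley_top_feature = top,
    shapley_top_mean_abs = unname(shap$mean_abs[top]),
    shapley_hippo_signed = unname(shap$mean_signed["hippo_volume_ipsi"]),
    prediction_r = report$interpret$correlation$r,
    prediction_p = report$interpret$correlation$p
  )
}
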