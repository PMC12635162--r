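#' Restricted cubic spline basis (3 knots)
#'
#' Harrell's restricted basis: columns `[x, s(x)]` with
#' `s(x) = [(x-t1)+^3 - (x-t2)+^3 (t3-t1)/(t3-t2) + (x-t3)+^3 (t2-t1)/(t3-t2)] / (t3-t1)^2`,
#' which is a cubic on `[t1, t3]` and linear (zero second derivative)
#' outside the boundary knots. The `(t3-t1)^2` normalization puts both
#' columns on the scale of `x`.
#'
#' @param x numeric vector.
#' @param knots three strictly increasing knot locations.
#' @return A numeric matrix with columns `x` and `x_nl`.
#' @export
rcs_basis <- function(x, knots) {
  if (length(knots) != 3L) stop("exactly 3 knots required")
  if (any(diff(knots) <= 0)) stop("knots must be strictly increasing")
  if (any(!is.finite(x))) stop("x must be finite")
  t1 <- knots[1]; t2 <- knots[2]; t3 <- knots[3]
  p3 <- function(u) pmax(u, 0)^3
  s <- (p3(x - t1) - p3(x - t2) * (t3 - t1) / (t3 - t2) +
          p3(x - t3) * (t2 - t1) / (t3 - t2)) / (t3 - t1)^2
  cbind(x = x, x_nl = s)
}

#' Knot locations from empirical percentiles
#'
#' Type-7 (linear interpolation) quantiles at the given probabilities,
#' default the 10th, 50th and 90th percentiles.
#'
#' @param x numeric vector with at least 10 distinct values.
#' @param probs quantile probabilities, default `c(0.10, 0.50, 0.90)`.
#' @return Strictly increasing knots.
#' @export
knots_from_percentiles <- function(x, probs = c(0.10, 0.50, 0.90)) {
  x <- x[is.finite(x)]
  if (length(unique(x)) < 10L) stop("need at least 10 distinct values for knot placement")
  k <- unname(stats::quantile(x, probs = probs, type = 7))
  if (any(diff(k) <= 0))
    stop("ties collapse the knots; percentile knots are not strictly increasing")
  k
}

#' Maximum-likelihood logistic regression on a design matrix
#'
#' Thin wrapper around [stats::glm()] (binomial, logit) returning the
#' quantities the spline machinery needs: coefficients, covariance,
#' log-likelihood, and `BIC = -2 loglik + k ln n`. Quasi-complete
#' separation is detected (fitted probabilities numerically 0/1) and
#' flagged with a warning rather than silently returning diverging
#' coefficients.
#'
#' @param X numeric design matrix (no intercept column; one is added).
#' @param y binary 0/1 response.
#' @return List with `coef`, `vcov`, `loglik`, `bic`, `n`, `k`,
#'   `converged`, `separation`, and the underlying `glm` object.
#' @export
fit_logistic <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (length(unique(y)) < 2L) stop("y has a single class")
  if (ncol(X) > 0L && nrow(X) != length(y)) stop("X and y sizes differ")
  if (nrow(X) <= ncol(X) + 1L) stop("more parameters than observations")
  df <- if (ncol(X) > 0L) data.frame(y = y, X) else data.frame(y = y)
  fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
  p <- stats::fitted(fit)
  sep <- any(p < 1e-8 | p > 1 - 1e-8) || any(abs(stats::coef(fit)) > 15)
  if (sep) warning("possible (quasi-)separation: fitted probabilities near 0/1")
  ll <- as.numeric(stats::logLik(fit))
  k <- length(stats::coef(fit))
  list(coef = stats::coef(fit), vcov = stats::vcov(fit), loglik = ll,
       bic = -2 * ll + k * log(length(y)), n = length(y), k = k,
       converged = fit$converged, separation = sep, glm = fit)
}

#' Univariate odds ratio with Wald confidence interval
#'
#' Fits `y ~ feature` by logistic regression and reports the odds ratio per
#' `scale` units of the feature, `OR = exp(beta * scale)`, with a Wald 95%
#' CI and P value. For continuous asymmetry-index features the default
#' scale is 0.01 AI units; the scale used is carried in the output so the
#' unit behind the OR is always explicit.
#'
#' @param feature numeric predictor.
#' @param y binary 0/1 outcome.
#' @param scale units per odds-ratio step (default 0.01).
#' @param conf confidence level (default 0.95).
#' @return A one-row data.frame: `or`, `ci_lo`, `ci_hi`, `p`, `beta`, `se`,
#'   `scale`.
#' @export
odds_ratio_report <- function(feature, y, scale = 0.01, conf = 0.95) {
  fit <- fit_logistic(matrix(feature, ncol = 1, dimnames = list(NULL, "x")), y)
  b <- fit$coef[["x"]]
  se <- sqrt(fit$vcov["x", "x"])
  z <- stats::qnorm(1 - (1 - conf) / 2)
  data.frame(
    or = exp(b * scale),
    ci_lo = exp((b - z * se) * scale),
    ci_hi = exp((b + z * se) * scale),
    p = 2 * stats::pnorm(-abs(b / se)),
    beta = b, se = se, scale = scale
  )
}

#' Restricted-cubic-spline logistic dose-response curve
#'
#' Fits `y ~ rcs(x) + covariates` with 3 knots at configurable percentiles
#' of `x`. The nonlinearity P value is a 1-df likelihood-ratio test of the
#' nonlinear spline column; the overall P is a 2-df LR test of both `x`
#' columns. The fitted log-odds curve is evaluated on a grid spanning the
#' 2.5th-97.5th percentiles of `x`, with covariates held at their means,
#' and odds ratios are referenced at `reference_x` (default the median),
#' with delta-method Wald CIs.
#'
#' @param x continuous exposure.
#' @param y binary 0/1 outcome.
#' @param covariates optional numeric matrix / data.frame of adjustment
#'   covariates.
#' @param knot_probs knot percentiles, default `c(0.10, 0.50, 0.90)`.
#' @param grid_n number of grid points for the fitted curve (default 200).
#' @param reference_x reference for OR = 1 (default `median(x)`).
#' @return An object of class `rcs_fit`: knots, coefficients, covariance,
#'   `loglik`, `bic`, `curve` (data.frame `x`, `logodds`, `or`, `ci_lo`,
#'   `ci_hi`), `p_nonlinearity`, `p_overall`, `reference_x`, `n`, `k`.
#' @export
rcs_logistic_curve <- function(x, y, covariates = NULL,
                               knot_probs = c(0.10, 0.50, 0.90),
                               grid_n = 200, reference_x = NULL) {
  knots <- knots_from_percentiles(x, knot_probs)
  B <- rcs_basis(x, knots)
  Z <- if (is.null(covariates)) NULL else as.matrix(covariates)
  X_full <- if (is.null(Z)) B else cbind(B, Z)
  fit_full <- fit_logistic(X_full, y)

  X_lin <- if (is.null(Z)) B[, "x", drop = FALSE] else cbind(B[, "x", drop = FALSE], Z)
  fit_lin <- fit_logistic(X_lin, y)
  fit_null <- if (is.null(Z)) {
    fit0 <- suppressWarnings(stats::glm(y ~ 1, family = stats::binomial()))
    list(loglik = as.numeric(stats::logLik(fit0)))
  } else fit_logistic(Z, y)

  lr <- function(l1, l0, df) stats::pchisq(2 * (l1 - l0), df, lower.tail = FALSE)
  p_nl <- lr(fit_full$loglik, fit_lin$loglik, 1)
  p_all <- lr(fit_full$loglik, fit_null$loglik, 2)

  if (is.null(reference_x)) reference_x <- stats::median(x)
  qs <- stats::quantile(x, c(0.025, 0.975), type = 7)
  grid <- seq(qs[1], qs[2], length.out = grid_n)
  Bg <- rcs_basis(grid, knots)
  Br <- rcs_basis(reference_x, knots)
  zbar <- if (is.null(Z)) NULL else colMeans(Z)
  cf <- fit_full$coef
  lp <- function(B1) {
    out <- cf[["(Intercept)"]] + B1[, 1] * cf[["x"]] + B1[, 2] * cf[["x_nl"]]
    if (!is.null(zbar)) out <- out + sum(zbar * cf[-(1:3)])
    out
  }
  logodds <- lp(Bg)
  # OR(x) vs reference: contrast only involves the two spline coefficients
  D <- cbind(Bg[, 1] - Br[1, 1], Bg[, 2] - Br[1, 2])
  V <- fit_full$vcov[c("x", "x_nl"), c("x", "x_nl")]
  delta <- D %*% cf[c("x", "x_nl")]
  se <- sqrt(rowSums((D %*% V) * D))
  z <- stats::qnorm(0.975)
  structure(
    list(knots = knots, coef = cf, vcov = fit_full$vcov,
         loglik = fit_full$loglik, bic = fit_full$bic,
         curve = data.frame(x = grid, logodds = logodds,
                            or = exp(delta), ci_lo = exp(delta - z * se),
                            ci_hi = exp(delta + z * se)),
         p_nonlinearity = p_nl, p_overall = p_all,
         reference_x = reference_x, n = fit_full$n, k = fit_full$k,
         separation = fit_full$separation,
         linear_fit = list(coef = fit_lin$coef, loglik = fit_lin$loglik,
                           bic = fit_lin$bic, k = fit_lin$k, n = fit_lin$n)),
    class = "rcs_fit"
  )
}

#' @export
print.rcs_fit <- function(x, ...) {
  cat(sprintf(paste0("<rcs_fit n=%d, knots %s, BIC %.2f, ",
                     "P nonlinearity %.3g, P overall %.3g>\n"),
              x$n, paste(signif(x$knots, 4), collapse = "/"), x$bic,
              x$p_nonlinearity, x$p_overall))
  invisible(x)
}

#' Select among candidate fits by BIC
#'
#' Returns the fit with the lowest `BIC = -2 loglik + k ln n`; ties are
#' broken in favour of fewer parameters. All candidates must be fitted to
#' the same number of observations.
#'
#' @param fits list of fit objects, each with `bic`, `k`, `n` fields.
#' @return The selected element, with attribute `index`.
#' @export
select_rcs_by_bic <- function(fits) {
  if (length(fits) < 1L) stop("need at least one candidate")
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) != 1L) stop("candidates fitted on differing n")
  bics <- vapply(fits, function(f) f$bic, numeric(1))
  ks <- vapply(fits, function(f) f$k, numeric(1))
  best <- order(bics, ks)[1]
  out <- fits[[best]]
  attr(out, "index") <- best
  out
}

#' Inflection / reference points of a fitted dose-response curve
#'
#' Scans the fitted log-odds over the grid for interior direction changes
#' (sign changes of the first difference): the curve is classified as
#' `"monotone"` (no change), `"U"` (one interior extremum, either
#' orientation), `"N"` (two), or `"flat"` when the curve's total range is
#' below `flat_tol`. When no strict direction change exists, the point of
#' maximum absolute second difference is returned as a curvature elbow and
#' labelled `"elbow"`; if the slope on one side of the elbow is much
#' smaller than on the other (ratio below `l_ratio`) the shape is reported
#' as `"L"`. The primary reference value is the first extremum if one
#' exists, otherwise the elbow.
#'
#' @param fit an `rcs_fit`, or any list with a `curve` data.frame holding
#'   columns `x` and `logodds`.
#' @param flat_tol total log-odds range below which the curve is "flat".
#' @param l_ratio slope-ratio threshold separating "L" from "monotone".
#' @return List: `shape`, `points` (x values), `labels` (`"extremum"` /
#'   `"elbow"`), `primary` (reference x, `NA` when flat).
#' @export
find_inflection <- function(fit, flat_tol = 1e-6, l_ratio = 0.2) {
  cv <- fit$curve
  xg <- cv$x; f <- cv$logodds
  if (diff(range(f)) < flat_tol)
    return(list(shape = "flat", points = numeric(0), labels = character(0),
                primary = NA_real_))
  d <- diff(f)
  s <- sign(d)
  s[s == 0] <- NA
  s <- zoo_locf(s)
  changes <- which(s[-1] * s[-length(s)] < 0)
  if (length(changes) > 0) {
    pts <- xg[changes + 1L]                       # grid point of the extremum
    shape <- if (length(changes) == 1L) "U" else if (length(changes) == 2L) "N"
             else "wiggly"
    return(list(shape = shape, points = pts,
                labels = rep("extremum", length(pts)), primary = pts[1]))
  }
  d2 <- diff(d)
  i <- which.max(abs(d2)) + 1L                    # interior grid index
  elbow <- xg[i]
  left_slope <- mean(abs(d[seq_len(i - 1L)]))
  right_slope <- mean(abs(d[i:length(d)]))
  ratio <- min(left_slope, right_slope) / max(left_slope, right_slope)
  shape <- if (is.finite(ratio) && ratio < l_ratio) "L" else "monotone"
  list(shape = shape, points = elbow, labels = "elbow", primary = elbow)
}

# last-observation-carried-forward for the sign vector (then backward for
# any leading NAs); avoids calling zoo for one tiny utility
zoo_locf <- function(x) {
  if (all(is.na(x))) return(x)
  for (i in seq_along(x)[-1]) if (is.na(x[i])) x[i] <- x[i - 1]
  for (i in rev(seq_along(x))[-1]) if (is.na(x[i])) x[i] <- x[i + 1]
  x
}

#' ROC analysis with Youden-optimal threshold
#'
#' Scores are classified positive when `score >= threshold`. All empirical
#' cut points (midpoints between consecutive distinct scores, plus
#' sentinels below and above the data) are evaluated; the optimal threshold
#' maximizes Youden's `J = sensitivity + specificity - 1`, ties broken by
#' the lower threshold. The AUC is the trapezoidal area under the empirical
#' ROC curve (equivalently the tie-corrected rank statistic).
#'
#' @param score numeric predictor (higher = more likely positive).
#' @param y binary 0/1 outcome (1 = positive class).
#' @param weights optional `w` for weighted accuracy `w*sens + (1-w)*spec`;
#'   default the positive-class prevalence.
#' @return An object of class `classifier_eval`: `threshold`, `tp`, `fp`,
#'   `fn`, `tn`, `sensitivity`, `specificity`, `youden_j`, `auc`,
#'   `balanced_accuracy`, `weighted_accuracy`, `accuracy`, `n`.
#' @export
roc_youden <- function(score, y, weights = NULL) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (length(score) != length(y)) stop("score and y sizes differ")
  n1 <- sum(y == 1); n0 <- sum(y == 0)

  # tie-corrected rank AUC == trapezoid over the empirical ROC
  r <- rank(score)
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  u <- sort(unique(score))
  if (length(u) < 2L) {
    ev <- confusion_metrics(tp = n1, fp = n0, fn = 0, tn = 0, weights = weights)
    ev$threshold <- NA_real_
    ev$auc <- 0.5
    ev$youden_j <- 0
    class(ev) <- "classifier_eval"
    warning("constant score: threshold undefined")
    return(ev)
  }
  thr <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  best <- NULL
  for (t in thr) {
    pred <- score >= t
    tp <- sum(pred & y == 1); fp <- sum(pred & y == 0)
    fn <- n1 - tp; tn <- n0 - fp
    j <- tp / n1 + tn / n0 - 1
    if (is.null(best) || j > best$j + 1e-12) best <- list(t = t, j = j)
  }
  pred <- score >= best$t
  tp <- sum(pred & y == 1); fp <- sum(pred & y == 0)
  ev <- confusion_metrics(tp = tp, fp = fp, fn = n1 - tp, tn = n0 - fp,
                          weights = weights)
  ev$threshold <- best$t
  ev$auc <- auc
  class(ev) <- "classifier_eval"
  ev
}

#' @export
print.classifier_eval <- function(x, ...) {
  cat(sprintf(paste0("<classifier_eval thr=%.4g sens=%.3f spec=%.3f ",
                     "J=%.3f AUC=%.3f BAcc=%.3f>\n"),
              x$threshold, x$sensitivity, x$specificity, x$youden_j,
              if (is.null(x$auc)) NA else x$auc, x$balanced_accuracy))
  invisible(x)
}

#' Classification metrics from a confusion table
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, Youden's J,
#' balanced accuracy (their unweighted mean), a prevalence- or
#' user-weighted accuracy `w*sens + (1-w)*spec`, and overall accuracy
#' `(tp+tn)/n`. A zero margin makes the affected metric `NA`.
#'
#' @param tp,fp,fn,tn nonnegative counts.
#' @param weights weight `w` on sensitivity for the weighted accuracy;
#'   default the positive-class prevalence `(tp+fn)/n`.
#' @return A list of metrics (class `classifier_eval`).
#' @export
confusion_metrics <- function(tp, fp, fn, tn, weights = NULL) {
  cnt <- c(tp, fp, fn, tn)
  if (any(cnt < 0) || any(cnt != round(cnt))) stop("counts must be nonnegative integers")
  n <- sum(cnt)
  if (n == 0) stop("empty table")
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  w <- if (is.null(weights)) (tp + fn) / n else weights[1]
  structure(
    list(tp = tp, fp = fp, fn = fn, tn = tn, n = n,
         sensitivity = sens, specificity = spec,
         youden_j = sens + spec - 1,
         balanced_accuracy = (sens + spec) / 2,
         weighted_accuracy = w * sens + (1 - w) * spec,
         weight = w,
         accuracy = (tp + tn) / n,
         threshold = NA_real_, auc = NULL),
    class = "classifier_eval"
  )
}

#' Pearson chi-squared test for a 2x2 table
#'
#' Uncorrected by default: `chi2 = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`;
#' the Yates continuity correction is available via `correction = TRUE`.
#' P value from the chi-squared distribution with 1 df.
#'
#' @param tab 2x2 matrix of counts `rbind(c(a, b), c(c, d))`.
#' @param correction apply Yates continuity correction (default `FALSE`).
#' @return List `statistic`, `p`, `df`.
#' @export
pearson_chi2 <- function(tab, correction = FALSE) {
  tab <- as.matrix(tab)
  if (!identical(dim(tab), c(2L, 2L))) stop("2x2 table required")
  if (any(tab < 0)) stop("negative counts")
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + cc + d
  marg <- c(a + b, cc + d, a + cc, b + d)
  if (any(marg == 0)) stop("zero margin")
  num <- abs(a * d - b * cc)
  if (correction) num <- max(0, num - n / 2)
  stat <- n * num^2 / prod(marg)
  list(statistic = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE), df = 1)
}

#' Likelihood-ratio G-squared test of independence
#'
#' `G2 = 2 sum O log(O / E)` over nonzero cells, with
#' `(r-1)(c-1)` degrees of freedom.
#'
#' @param tab matrix of counts.
#' @return List `statistic`, `p`, `df`.
#' @export
g2_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("negative counts")
  n <- sum(tab)
  if (n == 0) stop("empty table")
  E <- outer(rowSums(tab), colSums(tab)) / n
  if (any(E == 0)) stop("zero margin")
  nz <- tab > 0
  stat <- 2 * sum(tab[nz] * log(tab[nz] / E[nz]))
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, p = stats::pchisq(stat, df, lower.tail = FALSE), df = df)
}

#' Two-group comparison of a continuous variable
#'
#' Dispatches to the two-sided Student (pooled or Welch) t test or the
#' Wilcoxon rank-sum (Mann-Whitney) test.
#'
#' @param x numeric values.
#' @param g two-level grouping factor/vector.
#' @param method `"t"`, `"welch"`, or `"wilcoxon"`.
#' @return List `statistic`, `p`, `method`, group means.
#' @export
compare_groups <- function(x, g, method = c("t", "welch", "wilcoxon")) {
  method <- match.arg(method)
  g <- as.factor(g)
  if (nlevels(g) != 2L) stop("exactly two groups required")
  res <- switch(method,
    t = stats::t.test(x ~ g, var.equal = TRUE),
    welch = stats::t.test(x ~ g, var.equal = FALSE),
    wilcoxon = stats::wilcox.test(x ~ g, exact = FALSE, correct = FALSE)
  )
  list(statistic = unname(res$statistic), p = res$p.value, method = method,
       means = tapply(x, g, mean))
}

#' One-covariate ANCOVA group F test
#'
#' Compares group means adjusted for a single covariate via the linear
#' model `y ~ covariate + group`; the group effect is the sequential F for
#' `group` after the covariate.
#'
#' @param y response.
#' @param group grouping factor.
#' @param covariate numeric covariate.
#' @return List `f`, `p`, `df`.
#' @export
ancova_group_test <- function(y, group, covariate) {
  group <- as.factor(group)
  fit <- stats::lm(y ~ covariate + group)
  an <- stats::anova(fit)
  i <- which(rownames(an) == "group")
  list(f = an$`F value`[i], p = an$`Pr(>F)`[i],
       df = c(an$Df[i], an$Df[nrow(an)]))
}
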