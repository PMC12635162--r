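# Additive spline model: one unpenalized 3-knot restricted cubic spline per
# feature, least-squares fit. The same basis as the logistic spline module,
# so the dose-response machinery and the interpretation stage share one
# notion of "smooth". Features whose distribution cannot support 3 distinct
# percentile knots (heavy ties) fall back to a linear term.

# build the per-feature bases; knots fixed at training time
build_additive_design <- function(data, feature_knots) {
  cols <- lapply(names(feature_knots), function(f) {
    k <- feature_knots[[f]]
    x <- data[[f]]
    if (is.null(k)) {
      m <- matrix(x, ncol = 1); colnames(m) <- f; m
    } else {
      m <- rcs_basis(x, k); colnames(m) <- paste0(f, c("", "_nl")); m
    }
  })
  do.call(cbind, cols)
}

feature_knot_set <- function(data, features, knot_probs) {
  out <- stats::setNames(vector("list", length(features)), features)
  for (f in features) {
    out[f] <- list(tryCatch(knots_from_percentiles(data[[f]], knot_probs),
                            error = function(e) NULL))
  }
  out
}

#' Fit an additive spline model
#'
#' Gaussian additive model with one restricted-cubic-spline smooth (3 knots
#' at the 10th/50th/90th percentiles) per feature, fitted by least squares.
#'
#' @param data data.frame of numeric features.
#' @param target numeric response (e.g. per-patient PET asymmetry index).
#' @param features character vector of feature columns; default all columns
#'   of `data`.
#' @param knot_probs knot percentiles, default `c(0.10, 0.50, 0.90)`.
#' @return An object of class `additive_fit`: `coef`, `feature_knots`,
#'   `features`, `fitted`, `residuals`, `target_mean`, `n`.
#' @export
fit_additive_model <- function(data, target, features = names(data),
                               knot_probs = c(0.10, 0.50, 0.90)) {
  data <- as.data.frame(data)
  if (anyNA(data[features]) || anyNA(target)) stop("missing values in model input")
  n <- nrow(data)
  if (n <= 10L && length(features) > 0L && n <= 2L * length(features) + 1L)
    stop("too few observations for the additive model")
  fk <- feature_knot_set(data, features, knot_probs)
  X <- if (length(features)) build_additive_design(data, fk) else
    matrix(numeric(0), n, 0)
  Xd <- cbind(`(Intercept)` = 1, X)
  q <- qr(Xd)
  if (q$rank < ncol(Xd)) {
    bad <- colnames(Xd)[q$pivot[(q$rank + 1):ncol(Xd)]]
    stop("rank-deficient design; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  cf <- qr.coef(q, target)
  fitted <- as.numeric(Xd %*% cf)
  structure(
    list(coef = cf, feature_knots = fk, features = features,
         knot_probs = knot_probs, fitted = fitted,
         residuals = target - fitted, target_mean = mean(target), n = n),
    class = "additive_fit"
  )
}

#' @export
predict.additive_fit <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  if (length(object$features) == 0L)
    return(rep(object$coef[["(Intercept)"]], nrow(newdata)))
  X <- build_additive_design(newdata, object$feature_knots)
  as.numeric(cbind(1, X) %*% object$coef)
}

#' @export
print.additive_fit <- function(x, ...) {
  cat(sprintf("<additive_fit n=%d, %d feature smooth(s): %s>\n", x$n,
              length(x$features), paste(x$features, collapse = ", ")))
  invisible(x)
}

#' Repeated k-fold cross-validated predictions
#'
#' Each iteration draws a fresh seeded k-fold partition (fold sizes differ
#' by at most one; every subject is out-of-fold exactly once per
#' iteration), refits the additive model on the in-fold subjects, and
#' predicts the held-out ones. Per-subject point predictions are the mean
#' across iterations; the interval is the 2.5th/97.5th percentile of the
#' per-iteration out-of-fold predictions.
#'
#' @param data feature data.frame.
#' @param target numeric response.
#' @param features feature columns; default all.
#' @param k folds (default 5).
#' @param iterations repetitions (default 1000).
#' @param seed integer RNG seed for the partitions.
#' @param knot_probs passed to [fit_additive_model()].
#' @return List: `prediction` (length n), `ci_lo`, `ci_hi`, `matrix`
#'   (n x iterations), `k`, `iterations`, `seed`.
#' @export
cross_validate <- function(data, target, features = names(data), k = 5,
                           iterations = 1000, seed = 1,
                           knot_probs = c(0.10, 0.50, 0.90)) {
  data <- as.data.frame(data)
  n <- nrow(data)
  if (k > n) stop("k exceeds the number of subjects")
  preds <- matrix(NA_real_, n, iterations)
  withr::with_seed(as.integer(seed) %% 2147483647L, {
    for (it in seq_len(iterations)) {
      fold <- sample(rep_len(seq_len(k), n))
      for (f in seq_len(k)) {
        test <- fold == f
        fit <- fit_additive_model(data[!test, , drop = FALSE], target[!test],
                                  features, knot_probs)
        preds[test, it] <- predict(fit, data[test, , drop = FALSE])
      }
    }
  })
  list(prediction = rowMeans(preds),
       ci_lo = apply(preds, 1, stats::quantile, probs = 0.025, type = 7),
       ci_hi = apply(preds, 1, stats::quantile, probs = 0.975, type = 7),
       matrix = preds, k = k, iterations = iterations, seed = seed)
}

#' Exact Shapley feature attribution by subset retraining
#'
#' For each subject and feature, the exact Shapley value over all feature
#' coalitions: the payoff of coalition `S` is the prediction of the
#' additive model retrained on the features in `S` (the empty coalition
#' predicts the target mean). With `p` features this fits `2^p` models, so
#' `p <= 12` is enforced. Per subject the contributions telescope to
#' `full-model prediction - mean(target)` (efficiency).
#'
#' @inheritParams fit_additive_model
#' @return An object of class `shapley_report`: `phi` (n x p matrix of
#'   per-subject values), `mean_signed` and `mean_abs` per feature,
#'   `baseline` (target mean), `full_prediction`.
#' @export
shapley_importance <- function(data, target, features = names(data),
                               knot_probs = c(0.10, 0.50, 0.90)) {
  data <- as.data.frame(data)
  p <- length(features)
  if (p > 12L) stop("more than 12 features: exact enumeration infeasible; ",
                    "use a sampling approximation (not implemented)")
  n <- nrow(data)
  # Coalition payoff = in-sample prediction of the model retrained on the
  # subset. The projection onto the subset's column space is unique even
  # when features are collinear (e.g. duplicates), so a pivoted QR fit is
  # used here instead of the strict user-facing fitter: this is what makes
  # the symmetry axiom hold exactly for duplicated features.
  pay <- vector("list", 2^p)
  pay[[1]] <- rep(mean(target), n)
  fk_all <- feature_knot_set(data, features, knot_probs)
  for (m in seq_len(2^p - 1)) {
    S <- features[bitwAnd(m, bitwShiftL(1L, seq_len(p) - 1L)) != 0L]
    Xd <- cbind(1, build_additive_design(data, fk_all[S]))
    pay[[m + 1]] <- qr.fitted(qr(Xd), target)
  }
  fact <- factorial(0:p)
  phi <- matrix(0, n, p, dimnames = list(NULL, features))
  for (j in seq_len(p)) {
    bitj <- bitwShiftL(1L, j - 1L)
    for (m in 0:(2^p - 1)) {
      if (bitwAnd(m, bitj) != 0L) next
      s <- sum(bitwAnd(m, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
      w <- fact[s + 1] * fact[p - s] / fact[p + 1]
      phi[, j] <- phi[, j] + w * (pay[[m + bitj + 1]] - pay[[m + 1]])
    }
  }
  structure(
    list(phi = phi,
         mean_signed = colMeans(phi),
         mean_abs = colMeans(abs(phi)),
         baseline = mean(target),
         full_prediction = pay[[2^p]]),
    class = "shapley_report"
  )
}

#' @export
print.shapley_report <- function(x, ...) {
  ord <- order(-x$mean_abs)
  cat("<shapley_report> mean |value| by feature:\n")
  for (i in ord)
    cat(sprintf("  %-18s %+.5f (signed %+.5f)\n", colnames(x$phi)[i],
                x$mean_abs[i], x$mean_signed[i]))
  invisible(x)
}

#' Partial dependence of the additive model on one feature
#'
#' `PD(v)` is the mean prediction over subjects after setting the feature
#' to `v`. For an additive model this equals the feature's fitted smooth
#' plus a constant.
#'
#' @param fit an `additive_fit`.
#' @param data the feature data.frame the model was fitted to.
#' @param feature feature name.
#' @param grid evaluation points; default 50 points over the observed
#'   range. Points outside the observed range trigger an extrapolation
#'   warning.
#' @return data.frame with columns `x` and `pd`.
#' @export
partial_dependence <- function(fit, data, feature, grid = NULL) {
  stopifnot(inherits(fit, "additive_fit"))
  data <- as.data.frame(data)
  if (!feature %in% fit$features) stop("unknown feature: ", feature)
  rng <- range(data[[feature]])
  if (is.null(grid)) grid <- seq(rng[1], rng[2], length.out = 50)
  if (any(grid < rng[1] - 1e-12) || any(grid > rng[2] + 1e-12))
    warning("grid extends beyond the observed range of ", feature,
            ": extrapolating")
  pd <- vapply(grid, function(v) {
    d <- data
    d[[feature]] <- v
    mean(predict(fit, d))
  }, numeric(1))
  data.frame(x = grid, pd = pd)
}

#' Correlation between actual and predicted values
#'
#' Two-sided Pearson correlation with a t-based P value, used as the
#' predictive-accuracy summary for cross-validated predictions.
#'
#' @param actual,predicted numeric vectors of equal length (n >= 3).
#' @return List `r`, `p`, `n`.
#' @export
prediction_correlation <- function(actual, predicted) {
  if (length(actual) != length(predicted)) stop("lengths differ")
  if (length(actual) < 3L) stop("need at least 3 pairs")
  if (stats::sd(actual) == 0 || stats::sd(predicted) == 0)
    stop("zero variance")
  ct <- stats::cor.test(actual, predicted, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(actual))
}
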