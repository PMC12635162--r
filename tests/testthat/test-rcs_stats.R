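test_that("restricted spline basis matches the closed form and is linear in the tails", {
  knots <- c(-1, 0.2, 2)
  withr::with_seed(3, x <- runif(20, -4, 5))
  B <- rcs_basis(x, knots)
  t1 <- knots[1]; t2 <- knots[2]; t3 <- knots[3]
  p3 <- function(u) pmax(u, 0)^3
  s_direct <- (p3(x - t1) - p3(x - t2) * (t3 - t1) / (t3 - t2) +
                 p3(x - t3) * (t2 - t1) / (t3 - t2)) / (t3 - t1)^2
  expect_equal(unname(B[, 2]), s_direct, tolerance = 1e-12)
  expect_equal(unname(B[, 1]), x)

  expect_equal(unname(rcs_basis(c(-5, -1.2, t1), knots)[, 2]), c(0, 0, 0))

  # zero numeric second derivative far beyond the last knot
  x0 <- t3 + 5 * (t3 - t1); h <- 1e-3
  sv <- rcs_basis(c(x0 - h, x0, x0 + h), knots)[, 2]
  expect_lt(abs(sv[1] - 2 * sv[2] + sv[3]) / h^2, 1e-6)

  expect_error(rcs_basis(x, c(0, 0, 1)), "strictly increasing")
  expect_error(rcs_basis(x, c(0, 1)), "3 knots")
})

test_that("percentile knots use type-7 quantiles and reject degenerate samples", {
  expect_equal(knots_from_percentiles(1:100), c(10.9, 50.5, 90.1))
  expect_error(knots_from_percentiles(rep(1, 50)), "distinct")
  withr::with_seed(4, x <- rnorm(201))
  expect_equal(knots_from_percentiles(x)[2], median(x))
})

test_that("logistic ML fit matches closed forms and detects separation", {
  withr::with_seed(9, y <- rbinom(200, 1, 0.3))
  f0 <- fit_logistic(matrix(numeric(0), 200, 0), y)
  expect_equal(unname(f0$coef[1]), qlogis(mean(y)), tolerance = 1e-8)
  expect_equal(f0$bic, -2 * f0$loglik + 1 * log(200))

  withr::with_seed(10, {
    x <- rnorm(5000)
    yy <- rbinom(5000, 1, plogis(-0.5 + 1.0 * x))
  })
  f1 <- fit_logistic(cbind(x = x), yy)
  expect_true(f1$coef[["x"]] > 0.9 && f1$coef[["x"]] < 1.1)

  # binary predictor: OR equals the 2x2 cross-product ratio (20*5)/(4*1)
  xb <- c(rep(1, 24), rep(0, 6))
  yb <- c(rep(1, 20), rep(0, 4), rep(1, 1), rep(0, 5))
  orr <- odds_ratio_report(xb, yb, scale = 1)
  expect_equal(orr$or, 25.0, tolerance = 1e-6)

  expect_error(fit_logistic(cbind(x = x), rep(1, 5000)), "single class")
  xs <- c(rnorm(20, -3), rnorm(20, 3))
  ys <- rep(c(0, 1), each = 20)
  expect_warning(fit_logistic(cbind(x = xs), ys), "separation")
})

test_that("odds-ratio scale is an explicit reparameterization with calibrated coverage", {
  withr::with_seed(11, {
    x <- rnorm(300)
    y <- rbinom(300, 1, plogis(0.4 + 0.8 * x))
  })
  r1 <- odds_ratio_report(x, y, scale = 1)
  r2 <- odds_ratio_report(x, y, scale = 0.5)
  expect_equal(log(r2$or), 0.5 * log(r1$or), tolerance = 1e-10)
  r3 <- odds_ratio_report(x * 2, y, scale = 1)
  expect_equal(log(r3$or), 0.5 * log(r1$or), tolerance = 1e-6)

  # null predictor: Wald CI covers OR = 1 about 95% of the time
  cover <- vapply(1:500, function(s) {
    withr::with_seed(1000 + s, {
      xx <- rnorm(150)
      yy <- rbinom(150, 1, 0.5)
    })
    r <- odds_ratio_report(xx, yy, scale = 1)
    r$ci_lo <= 1 && r$ci_hi >= 1
  }, logical(1))
  expect_gt(mean(cover), 0.92)
  expect_lt(mean(cover), 0.985)
})

test_that("spline logistic curve detects planted nonlinearity and prefers the simpler truth", {
  # planted U-shaped log-odds: nonlinearity flagged in nearly every replicate
  power <- vapply(1:25, function(s) {
    d <- simulate_threshold_cohort(2000, shape = "U", seed = 200 + s)
    f <- suppressWarnings(rcs_logistic_curve(d$ai, d$outcome, grid_n = 60))
    f$p_nonlinearity < 0.05
  }, logical(1))
  expect_gte(mean(power), 0.9)

  # linear truth: BIC favours the linear nested model most of the time
  lin_wins <- vapply(1:20, function(s) {
    withr::with_seed(300 + s, {
      x <- rnorm(500)
      y <- rbinom(500, 1, plogis(0.2 + 0.7 * x))
    })
    f <- suppressWarnings(rcs_logistic_curve(x, y, grid_n = 30))
    f$linear_fit$bic < f$bic
  }, logical(1))
  expect_gte(mean(lin_wins), 0.8)

  d <- simulate_threshold_cohort(800, shape = "U", seed = 77)
  f <- suppressWarnings(rcs_logistic_curve(d$ai, d$outcome))
  expect_equal(f$bic, -2 * f$loglik + f$k * log(f$n))
  expect_equal(nrow(f$curve), 200)
  # OR referenced at reference_x equals 1 there
  i_ref <- which.min(abs(f$curve$x - f$reference_x))
  expect_equal(f$curve$or[i_ref], 1, tolerance = 0.05)
})

test_that("BIC selection picks the lowest-BIC candidate with ties to fewer parameters", {
  a <- list(bic = 10, k = 3, n = 100)
  b <- list(bic = 10, k = 2, n = 100)
  cc <- list(bic = 12, k = 1, n = 100)
  expect_identical(select_rcs_by_bic(list(a))$k, 3)
  sel <- select_rcs_by_bic(list(a, b, cc))
  expect_equal(sel$k, 2)
  expect_error(select_rcs_by_bic(list(a, list(bic = 1, k = 1, n = 99))),
               "differing n")
})

test_that("inflection detection recovers planted vertices and labels shapes", {
  # quadratic log-odds with vertex at 0.3
  withr::with_seed(21, {
    x <- rnorm(4000, 0.3, 1)
    y <- rbinom(4000, 1, plogis(1 - 2 * (x - 0.3)^2))
  })
  f <- suppressWarnings(rcs_logistic_curve(x, y))
  inf <- find_inflection(f)
  expect_equal(inf$shape, "U")
  step <- diff(f$curve$x[1:2])
  expect_lt(abs(inf$primary - 0.3), 3 * step + 0.02)

  # strictly linear logit: monotone, elbow flagged but not an extremum
  withr::with_seed(22, {
    xl <- rnorm(2000)
    yl <- rbinom(2000, 1, plogis(0.5 * xl))
  })
  fl <- suppressWarnings(rcs_logistic_curve(xl, yl))
  il <- find_inflection(fl)
  expect_true(il$shape %in% c("monotone", "L"))
  expect_identical(il$labels, "elbow")

  flat <- list(curve = data.frame(x = seq(0, 1, length.out = 50),
                                  logodds = rep(0.2, 50)))
  expect_equal(find_inflection(flat)$shape, "flat")
  expect_true(is.na(find_inflection(flat)$primary))
})

test_that("Youden threshold search matches exhaustive enumeration and pROC's AUC", {
  # perfect separation
  ev <- roc_youden(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1))
  expect_equal(ev$auc, 1.0)
  expect_equal(ev$youden_j, 1.0)

  brute <- function(score, y) {
    u <- sort(unique(score))
    cand <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
    js <- sapply(cand, function(t) {
      mean(score[y == 1] >= t) + mean(score[y == 0] < t) - 1
    })
    cand[which.max(js)]   # which.max takes the first (lowest) maximizer
  }
  for (s in 1:20) {
    withr::with_seed(400 + s, {
      y <- rbinom(50, 1, 0.5)
      if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
      score <- rnorm(50) + 0.8 * y
    })
    ev <- roc_youden(score, y)
    expect_equal(ev$threshold, brute(score, y))
    pr <- pROC::roc(y, score, quiet = TRUE, direction = "<")
    expect_equal(ev$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
    flip <- roc_youden(-score, y)
    expect_equal(flip$auc, 1 - ev$auc, tolerance = 1e-12)
  }
  expect_warning(ev0 <- roc_youden(rep(1, 10), rep(c(0, 1), 5)), "constant")
  expect_equal(ev0$auc, 0.5)
  expect_true(is.na(ev0$threshold))
})

test_that("confusion metrics reproduce the reconstructed outcome table", {
  m <- confusion_metrics(20, 4, 1, 5)
  expect_equal(m$sensitivity, 20 / 21, tolerance = 1e-4)   # 0.9524
  expect_equal(m$specificity, 5 / 9, tolerance = 1e-4)     # 0.5556
  expect_equal(m$accuracy, 25 / 30)                        # 0.8333
  expect_equal(m$balanced_accuracy, (20 / 21 + 5 / 9) / 2) # 0.7540
  expect_equal(round(m$balanced_accuracy, 4), 0.754)
  expect_equal(m$weighted_accuracy, 0.7 * 20 / 21 + 0.3 * 5 / 9)

  perfect <- confusion_metrics(10, 0, 0, 10)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$youden_j, 1)

  zero_margin <- confusion_metrics(0, 3, 0, 7)
  expect_true(is.na(zero_margin$sensitivity))
  expect_error(confusion_metrics(-1, 0, 0, 1), "nonnegative")
})

test_that("Pearson chi-squared matches the formula oracle and chisq.test", {
  res <- pearson_chi2(rbind(c(20, 4), c(1, 5)))
  expect_equal(round(res$statistic, 2), 10.16)
  expect_lt(res$p, 0.0015)

  expect_equal(pearson_chi2(rbind(c(10, 10), c(10, 10)))$statistic, 0)

  withr::with_seed(31, {
    for (i in 1:100) {
      tab <- matrix(rpois(4, 12) + 1, 2, 2)
      ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
      expect_equal(pearson_chi2(tab)$statistic, unname(ref$statistic),
                   tolerance = 1e-10)
      refy <- suppressWarnings(chisq.test(tab, correct = TRUE))
      expect_equal(pearson_chi2(tab, correction = TRUE)$statistic,
                   unname(refy$statistic), tolerance = 1e-10)
    }
  })
  expect_error(pearson_chi2(rbind(c(0, 0), c(1, 2))), "zero margin")
})

test_that("auxiliary tests agree with enumeration and model-based oracles", {
  # G-squared equals the LR statistic from the log-linear independence fit
  withr::with_seed(33, tab <- matrix(rpois(4, 15) + 1, 2, 2))
  ref <- stats::loglin(tab, margin = list(1, 2), print = FALSE)
  expect_equal(g2_test(tab)$statistic, ref$lrt, tolerance = 1e-8)

  # Fisher exact on the reconstructed table vs hypergeometric enumeration
  ft <- fisher.test(rbind(c(20, 4), c(1, 5)))
  m <- 21; nn <- 9; k <- 24
  probs <- dhyper(max(0, k - nn):min(m, k), m, nn, k)
  p_enum <- sum(probs[probs <= dhyper(20, m, nn, k) * (1 + 1e-7)])
  expect_equal(ft$p.value, p_enum, tolerance = 1e-8)

  g <- rep(c("a", "b"), each = 10)
  x <- rep(1:10, 2)
  same <- compare_groups(x, g, "t")
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  # ANCOVA recovers a planted adjusted group difference
  withr::with_seed(34, {
    cov <- rnorm(60)
    grp <- rep(c(0, 1), each = 30)
    yy <- 2 * cov + 0.9 * grp + rnorm(60, 0, 0.5)
  })
  an <- ancova_group_test(yy, grp, cov)
  expect_lt(an$p, 1e-4)
})
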