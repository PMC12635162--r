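test_that("phantom subjects carry the planted asymmetry exactly when noiseless", {
  spec <- small_spec(noise_sd = 0, seed = 5)
  s <- make_phantom_subject(spec, 1, ez_side = "left", depth = 0.2,
                            atrophy = 0.1, coverage = 0.5)
  ai <- asymmetry_index_map(s$pet, mask = s$brain_mask$values != 0,
                            shift = "none")
  lab <- s$roi_labels$values == 1
  vals <- ai$values[lab & ai$valid_mask]
  # (0.8 - 1) / 0.9 at every ipsilateral hippocampal voxel
  expect_equal(vals, rep(-2 * 0.2 / (2 - 0.2), length(vals)), tolerance = 1e-12)

  # no planted effect: hippocampal AI is zero without noise, and small
  # relative to its standard error with noise
  s0 <- make_phantom_subject(small_spec(noise_sd = 0, seed = 5), 2,
                             ez_side = "left", depth = 0, atrophy = 0,
                             coverage = 0.5)
  ai0 <- asymmetry_index_map(s0$pet, mask = s0$brain_mask$values != 0,
                             shift = "none")
  expect_lt(max(abs(ai0$values[lab & ai0$valid_mask])), 1e-12)
  sn <- make_phantom_subject(small_spec(noise_sd = 0.05, seed = 5), 3,
                             ez_side = "left", depth = 0, atrophy = 0,
                             coverage = 0.5)
  ain <- asymmetry_index_map(sn$pet, mask = sn$brain_mask$values != 0,
                             shift = "none")
  roi_n <- sn$roi_labels$values == 1 & ain$valid_mask
  vals_n <- ain$values[roi_n]
  expect_lt(abs(mean(vals_n)), 3 * sd(vals_n) / sqrt(length(vals_n)))
})

test_that("phantom generation is deterministic and validates its inputs", {
  spec <- small_spec(seed = 9)
  a <- make_phantom_subject(spec, 4)
  b <- make_phantom_subject(spec, 4)
  expect_identical(a$pet$values, b$pet$values)
  expect_identical(a$roi_labels$values, b$roi_labels$values)
  expect_identical(a$ablation_mask$values, b$ablation_mask$values)
  cc <- make_phantom_subject(spec, 5)
  expect_false(identical(a$pet$values, cc$pet$values))

  expect_error(phantom_spec(grid_shape = c(47, 48, 48)), "asymmetric grid")
  expect_error(phantom_spec(ablation_coverage = 1.2), "\\[0, 1\\]")
  expect_error(phantom_spec(noise_sd = -1), "noise_sd")
  expect_error(make_phantom_subject(spec, 6, coverage = 2), "coverage")
})

test_that("phantom invariants: tissue budget, disjoint labels, cavity inside brain", {
  s <- make_phantom_subject(small_spec(seed = 2), 1)
  tsum <- s$tissue_gm$values + s$tissue_wm$values + s$tissue_csf$values
  expect_true(all(tsum <= 1 + 1e-12))
  expect_true(all(s$tissue_gm$values >= 0 & s$tissue_gm$values <= 1))
  expect_true(all(s$roi_labels$values %in% 0:4))
  expect_true(all(s$ablation_mask$values[s$brain_mask$values == 0] == 0))

  # ablation covers the requested fraction of the hypometabolic region
  sp <- small_spec(noise_sd = 0, seed = 2)
  s2 <- make_phantom_subject(sp, 1, ez_side = "right", depth = 0.3,
                             atrophy = 0.15, coverage = 0.4)
  expect_equal(s2$truth$realized_coverage, 0.4, tolerance = 0.05)
})

test_that("deepening hypometabolism strictly lowers the noiseless hippocampal AI", {
  sp <- small_spec(noise_sd = 0, seed = 3)
  means <- sapply(c(0.05, 0.15, 0.25, 0.35), function(dep) {
    s <- make_phantom_subject(sp, 1, ez_side = "left", depth = dep,
                              atrophy = 0.1, coverage = 0.5)
    ai <- asymmetry_index_map(s$pet, mask = s$brain_mask$values != 0,
                              shift = "none")
    mean(ai$values[s$roi_labels$values == 1 & ai$valid_mask])
  })
  expect_true(all(diff(means) < 0))
})

test_that("cohorts are reproducible and calibrated to the target prevalence", {
  c1 <- make_cohort(10, small_spec(), seed = 21, images = FALSE)
  c2 <- make_cohort(10, small_spec(), seed = 21, images = FALSE)
  expect_identical(c1$table, c2$table)
  expect_error(make_cohort(1, small_spec(), seed = 1), "n >= 2")

  # alpha solves E[plogis(alpha + beta C)] = prevalence under the Beta law
  a <- calibrate_outcome_intercept(6, 0.70, 2.5, 1.8)
  ev <- integrate(function(c) plogis(a + 6 * c) * dbeta(c, 2.5, 1.8), 0, 1)$value
  expect_equal(ev, 0.70, tolerance = 1e-6)

  # over many simulated cohorts the mean seizure-free fraction hits 0.70
  sf <- vapply(1:1000, function(s)
    mean(make_cohort(30, seed = s, images = FALSE)$table$outcome == "SF"),
    numeric(1))
  expect_lt(abs(mean(sf) - 0.70), 0.02)

  # a dominant coverage effect makes extreme coverages decide the outcome
  strong <- make_cohort(200, phantom_spec(outcome_beta = 60), seed = 8,
                        images = FALSE)$table
  lo <- strong$coverage < quantile(strong$coverage, 0.05)
  hi <- strong$coverage > quantile(strong$coverage, 0.95)
  expect_true(mean(strong$outcome[hi] == "SF") >
                mean(strong$outcome[lo] == "SF"))
  expect_gte(mean(strong$outcome[hi] == "SF"), 0.9)
})

test_that("the packaged demographic fixture reproduces every categorical margin", {
  t1 <- table1_fixture()
  expect_equal(nrow(t1), 30)
  expect_true(isTRUE(attr(t1, "synthetic")))
  expect_identical(t1, table1_fixture())   # deterministic

  sf <- t1$outcome == "SF"
  expect_equal(sum(sf), 21)
  expect_equal(sum(t1$gender == "female"), 16)
  expect_equal(sum(t1$ez_side == "left"), 18)
  expect_equal(sum(t1$seeg == "yes"), 8)
  # per-group margins
  expect_equal(sum(t1$gender[sf] == "female"), 12)
  expect_equal(sum(t1$gender[!sf] == "female"), 4)
  expect_equal(sum(t1$ez_side[sf] == "left"), 12)
  expect_equal(sum(t1$seeg[!sf] == "yes"), 4)
  expect_equal(sum(t1$loc == "yes"), 29)
  expect_equal(sum(t1$pet_hypometabolism == "yes"), 29)
  expect_equal(sum(t1$f2btcs == "yes"), 15)
  expect_equal(sum(t1$hippocampal_atrophy == "yes"), 22)

  # continuous fields match the printed group summaries
  expect_equal(mean(t1$age_onset[sf]), 21.01, tolerance = 0.02)
  expect_equal(sd(t1$age_onset[sf]), 7.07, tolerance = 0.02)
  expect_equal(mean(t1$age_onset[!sf]), 23.76, tolerance = 0.02)
  expect_equal(median(t1$duration[sf]), 7, tolerance = 0.5)
  expect_equal(median(t1$duration[!sf]), 11, tolerance = 0.5)
})

test_that("table-level generators plant their advertised structure", {
  d <- simulate_threshold_cohort(5000, threshold = -0.06, shape = "U", seed = 1)
  expect_identical(d, simulate_threshold_cohort(5000, threshold = -0.06,
                                                shape = "U", seed = 1))
  # log-odds peak at the planted threshold
  expect_equal(d$eta[which.max(d$eta)],
               max(1.5 - 50 * (d$ai - (-0.06))^2), tolerance = 1e-12)
  dl <- simulate_threshold_cohort(5000, shape = "L", seed = 2)
  below <- dl$ai <= -0.06
  expect_true(all(dl$eta[below] == dl$eta[below][1]))   # flat below threshold

  sc <- simulate_structural_cohort(500, seed = 3)
  expect_true(all(sc$tiv > 0) && all(sc$hippo_volume_ipsi > 0))
  # hippocampal volume is the strongest single correlate of the PET AI
  cors <- abs(cor(sc[c("tiv", "hippo_volume_ipsi", "amyg_volume_ipsi",
                       "hippo_vai", "amyg_vai")], sc$pet_ai))
  expect_equal(rownames(cors)[which.max(cors)], "hippo_volume_ipsi")
})

test_that("subjects write to disk as NIfTI plus a truth sidecar", {
  s <- make_phantom_subject(small_spec(seed = 12), 1)
  dir <- file.path(tempdir(), "pnms_subj")
  write_subject(s, dir, "demo")
  expect_true(file.exists(file.path(dir, "demo_pet.nii.gz")))
  expect_true(file.exists(file.path(dir, "demo_truth.json")))
  truth <- jsonlite::read_json(file.path(dir, "demo_truth.json"))
  expect_equal(truth$ez_side, s$ez_side)
  back <- read_volume(file.path(dir, "demo_pet.nii.gz"))
  expect_lt(max(abs(back$values - s$pet$values)), 1e-5)
  unlink(dir, recursive = TRUE)
})
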