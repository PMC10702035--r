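params_obs <- default_generation_params("observed")

test_that("closed-form intercept for a slope-free dependent mechanism", {
  cfg <- missingness_config("dependent", "low")
  cfg$slopes <- lapply(cfg$slopes, function(x) x * 0)
  cfg$targets <- list(
    p_conf_any = 0.30, p_exposure = 0.10, p_any = 0.35,
    p_petown = 0.25, p_ante = 0.125
  )
  cal <- calibrate_intercepts(params_obs, cfg, n_ref = 20000)
  # slope-free marginal target 0.25 has the closed-form intercept logit(0.25)
  expect_equal(unname(round(cal$intercepts["nu0"], 4)), -1.0986)
})

test_that("infeasible compound targets are rejected", {
  cfg <- missingness_config("independent", "low")
  cfg$targets$p_any <- 0.05 # any-incomplete below the exposure component
  expect_error(calibrate_intercepts(params_obs, cfg), "infeasible")
  cfg2 <- missingness_config("independent", "low")
  cfg2$targets$p_petown <- 0.01
  cfg2$targets$p_ante <- 0.01
  expect_error(calibrate_intercepts(params_obs, cfg2), "infeasible")
})

test_that("low independent mechanism hits the stated compound proportions", {
  cal <- calibrate_intercepts(params_obs, missingness_config("independent", "low"))
  co <- generate_cohort(params_obs, 100000, seed = 21)
  co <- induce_unintended(co, cal, seed = 22)
  m <- attr(co, "mask_unintended")
  mc3 <- function(p) 3 * sqrt(p * (1 - p) / 100000)
  expect_lt(abs(mean(m[, "PetOwn"] | m[, "AnteVD"]) - 0.20), mc3(0.20))
  expect_lt(abs(mean(m[, "VDI"]) - 0.10), mc3(0.10))
  expect_lt(abs(mean(rowSums(m) > 0) - 0.25), mc3(0.25))
})

test_that("calibrated dependent mechanism achieves its targets on fresh data", {
  cal <- calibrate_intercepts(params_obs, missingness_config("dependent", "low"),
    tol = 0.005, seed = 31
  )
  expect_true(cal$calibrated)
  # analytic achieved proportions recorded at calibration
  expect_lt(abs(cal$achieved$p_conf_any - 0.20), 0.005)
  expect_lt(abs(cal$achieved$p_exposure - 0.10), 0.005)
  expect_lt(abs(cal$achieved$p_any - 0.25), 0.005)
  # re-simulated on an independent validation cohort
  co <- generate_cohort(params_obs, 100000, seed = 32)
  co <- induce_unintended(co, cal, seed = 33)
  m <- attr(co, "mask_unintended")
  expect_lt(abs(mean(m[, "VDI"]) - 0.10), 0.006)
  expect_lt(abs(mean(m[, "PetOwn"] | m[, "AnteVD"]) - 0.20), 0.007)
  expect_lt(abs(mean(rowSums(m) > 0) - 0.25), 0.008)
})

test_that("high level doubles the component proportions", {
  for (mech in c("independent", "dependent")) {
    cal <- calibrate_intercepts(params_obs, missingness_config(mech, "high"))
    expect_lt(abs(cal$achieved$p_conf_any - 0.40), 0.005, label = mech)
    expect_lt(abs(cal$achieved$p_exposure - 0.20), 0.005, label = mech)
  }
})

test_that("intercept-only mechanism yields the plain Bernoulli rates", {
  cfg <- missingness_config("dependent", "low")
  cfg$slopes <- lapply(cfg$slopes, function(x) x * 0)
  cal <- calibrate_intercepts(params_obs, cfg, n_ref = 20000)
  co <- generate_cohort(params_obs, 100000, seed = 41)
  co <- induce_unintended(co, cal, seed = 42)
  m <- attr(co, "mask_unintended")
  expect_lt(abs(mean(m[, "PetOwn"]) - 0.10), 0.004)
  expect_lt(abs(mean(m[, "AnteVD"]) - 0.125), 0.004)
  expect_lt(abs(mean(m[, "VDI"]) - 0.10), 0.004)
})

test_that("independent masks do not depend on the outcome; dependent slopes are recoverable", {
  n <- 150000
  co <- generate_cohort(params_obs, n, seed = 51)
  cal_i <- calibrate_intercepts(params_obs, missingness_config("independent", "low"))
  ci <- induce_unintended(co, cal_i, seed = 52)
  mi <- attr(ci, "mask_unintended")
  for (v in colnames(mi)) {
    f <- glm(mi[, v] ~ co$FoodAllergy + co$Eth + co$MAge, family = binomial())
    z <- summary(f)$coefficients[-1, "z value"]
    expect_lt(max(abs(z)), 4, label = paste("independent", v))
  }
  cal_d <- calibrate_intercepts(params_obs, missingness_config("dependent", "low"))
  cd <- induce_unintended(co, cal_d, seed = 53)
  md <- attr(cd, "mask_unintended")
  f <- summary(glm(md[, "PetOwn"] ~ co$FoodAllergy + co$Eth + co$MAge,
    family = binomial()
  ))$coefficients
  truth <- cal_d$slopes$nu
  expect_lt(max(abs(f[-1, "Estimate"] - truth) / f[-1, "Std. Error"]), 4)
})

test_that("subset selection follows the case-cohort design", {
  co <- generate_cohort(params_obs, 100000, seed = 61)
  s1 <- select_subset(co, design_config(100000, 1), seed = 62)
  expect_true(all(s1$in_subset))
  expect_false(anyNA(s1$VDI))

  s3 <- select_subset(co, design_config(100000, 0.3), seed = 63)
  expect_lt(abs(mean(s3$in_subcohort) - 0.3), 3 * sqrt(0.3 * 0.7 / 100000))
  expect_true(all(s3$in_subset[s3$is_case]))
  # a non-case, non-subcohort record loses its exposure by design
  out_row <- which(!s3$is_case & !s3$in_subcohort)[1]
  expect_false(is.na(co$VDI[out_row]))
  expect_true(is.na(s3$VDI[out_row]))
  # intended and unintended masks tracked separately
  expect_identical(attr(s3, "mask_intended"), !s3$in_subset)
  expect_true(all(!attr(s3, "mask_unintended")))
})

test_that("a subset member's exposure can still be missing by chance", {
  co <- make_study_cohort(n = 20000, selection = 0.3, mechanism = "independent", seed = 71)
  m <- attr(co, "mask_unintended")
  expect_gt(sum(co$in_subset & m[, "VDI"]), 0)
  expect_true(all(is.na(co$VDI[m[, "VDI"]])))
  # induced before selection: unintended exposure masking is independent of subset
  expect_lt(
    abs(mean(m[co$in_subset, "VDI"]) - mean(m[!co$in_subset, "VDI"])),
    4 * sqrt(0.1 * 0.9 / sum(co$in_subset))
  )
})

test_that("missingness requires calibration and a fully observed cohort", {
  co <- generate_cohort(params_obs, 100, seed = 81)
  expect_error(
    induce_unintended(co, missingness_config("independent", "low")),
    "calibrated"
  )
  cal <- calibrate_intercepts(params_obs, missingness_config("independent", "low"))
  co2 <- induce_unintended(co, cal, seed = 82)
  expect_error(induce_unintended(co2, cal), "already")
})

test_that("calibrated configs serialize with their achieved proportions", {
  cal <- calibrate_intercepts(params_obs, missingness_config("dependent", "low"))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_missingness_config(cal, path)
  back <- read_missingness_config(path)
  expect_equal(back$intercepts, cal$intercepts, tolerance = 1e-8)
  expect_equal(back$achieved$p_any, cal$achieved$p_any, tolerance = 1e-8)
  expect_true(back$calibrated)
})
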