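test_that("imputing a complete dataset returns identical copies", {
  co <- make_clean_cohort(n = 300, selection = 1, seed = 1)
  view <- scope_view(co, "full")
  imp <- impute(view, imputation_spec(m = 3, cycles = 2, seed = 9))
  expect_length(imp$imputations, 3)
  for (k in 1:3) expect_identical(imp$imputations[[k]], view)
  expect_length(imp$n_missing, 0)
})

test_that("observed cells are identical across imputations; only missing cells differ", {
  co <- make_study_cohort(n = 3000, selection = 0.3, mechanism = "independent", seed = 2)
  view <- scope_view(co, "subset")
  imp <- impute(view, imputation_spec(m = 4, cycles = 3, seed = 10))
  miss <- is.na(view$VDI)
  for (k in 1:4) {
    d <- imp$imputations[[k]]
    expect_identical(d$VDI[!miss], view$VDI[!miss])
    expect_false(anyNA(d[, c("VDI", "PetOwn", "AnteVD")]))
  }
  # between-imputation variance of a fully observed variable's mean is zero
  means <- vapply(imp$imputations, function(d) mean(d$Eth), numeric(1))
  expect_equal(var(means), 0)
  # imputed cells genuinely vary across copies
  imputed_vdi <- vapply(imp$imputations, function(d) sum(d$VDI[miss]), numeric(1))
  expect_gt(length(unique(imputed_vdi)), 1)
})

test_that("MCAR margin is recovered by an intercept-only imputation model", {
  set.seed(11)
  n <- 20000
  x <- rbinom(n, 1, 0.5)
  dat <- data.frame(
    FoodAllergy = rbinom(n, 1, 0.1), VDI = x, Eth = rbinom(n, 1, 0.7),
    MAge = rnorm(n, 32, 5)
  )
  dat$VDI[sample(n, n / 2)] <- NA
  imp <- impute(dat, imputation_spec(
    m = 5, cycles = 1, seed = 12,
    predictors = list(VDI = character(0))
  ))
  miss <- is.na(dat$VDI)
  pooled <- mean(vapply(imp$imputations, function(d) mean(d$VDI[miss]), numeric(1)))
  expect_lt(abs(pooled - 0.5), 3 * sqrt(0.25 / sum(miss)) + 0.01)
})

test_that("a deterministic copy is recovered through the separation fallback", {
  set.seed(13)
  n <- 2000
  eth <- rbinom(n, 1, 0.5)
  dat <- data.frame(
    FoodAllergy = rbinom(n, 1, 0.1), VDI = eth, Eth = eth,
    MAge = rnorm(n, 32, 5)
  )
  miss <- sample(n, n / 2)
  dat$VDI[miss] <- NA
  imp <- impute(dat, imputation_spec(m = 2, cycles = 2, seed = 14))
  for (k in 1:2) {
    agree <- mean(imp$imputations[[k]]$VDI[miss] == eth[miss])
    expect_gte(agree, 0.99)
  }
})

test_that("imputation is deterministic given the seed and rejects bad input", {
  co <- make_study_cohort(n = 1500, selection = 0.3, seed = 3)
  view <- scope_view(co, "subset")
  a <- impute(view, imputation_spec(m = 2, cycles = 2, seed = 15))
  b <- impute(view, imputation_spec(m = 2, cycles = 2, seed = 15))
  expect_identical(a$imputations, b$imputations)

  bad <- view
  bad$VDI <- NA_real_
  expect_error(impute(bad, imputation_spec(m = 2, seed = 1)), "100% missing")
  bad2 <- view
  bad2$FoodAllergy[1] <- NA
  expect_error(impute(bad2, imputation_spec(m = 2, seed = 1)), "outcome")
  expect_error(imputation_spec(m = 1), "m must be")
})

test_that("scope views expose the intended-missingness structure correctly", {
  co <- make_study_cohort(n = 8000, selection = 0.3, mechanism = "independent", seed = 4)
  sub <- scope_view(co, "subset")
  full <- scope_view(co, "full")
  expect_equal(nrow(sub), sum(co$in_subset))
  expect_equal(nrow(full), nrow(co))
  # subset scope: exposure missingness is the unintended-only rate
  m <- attr(co, "mask_unintended")
  expect_equal(mean(is.na(sub$VDI)), mean(m[co$in_subset, "VDI"]))
  # full scope: by-design plus unintended missingness
  expect_equal(
    sum(is.na(full$VDI)),
    sum(!co$in_subset) + sum(m[co$in_subset, "VDI"])
  )

  co1 <- make_clean_cohort(n = 400, selection = 1, seed = 5)
  expect_identical(scope_view(co1, "subset"), scope_view(co1, "full"))
})

test_that("pooled estimates are stable in m beyond Monte-Carlo error", {
  co <- make_study_cohort(n = 2500, selection = 0.3, seed = 6)
  w <- unclass(sampling_weights(co))
  view <- scope_view(co, "subset")
  wv <- w[view$id]
  fit_m <- function(m, seed) {
    imp <- impute(view, imputation_spec(m = m, cycles = 5, seed = seed))
    pool_rubin(lapply(imp$imputations, fit_modified_poisson, weights = wv))
  }
  p10 <- fit_m(10, 16)
  p50 <- fit_m(50, 17)
  # point estimates agree within the between-imputation MC error of each run
  tol <- 3 * sqrt(p10$B / 10 + p50$B / 50)
  expect_lt(abs(p10$estimate - p50$estimate), tol)
})
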