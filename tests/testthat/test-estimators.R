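test_that("saturated modified Poisson equals the closed-form log risk ratio", {
  dat <- expand_2x2(a = 20, b = 80, c = 10, d = 90)
  fit <- fit_modified_poisson(dat, terms = "VDI")
  expect_equal(unname(fit$coef["VDI"]), log(2), tolerance = 1e-7)
  expect_equal(unname(fit$coef["(Intercept)"]), log(0.1), tolerance = 1e-7)

  # constant weights cancel in a saturated model
  fit_w <- fit_modified_poisson(dat, weights = rep(3.7, nrow(dat)), terms = "VDI")
  expect_equal(fit_w$coef, fit$coef, tolerance = 1e-7)
})

test_that("robust sandwich variance matches an independently coded oracle", {
  dat <- expand_2x2(a = 20, b = 80, c = 10, d = 90)
  w <- rep(c(1, 2.5), length.out = nrow(dat))
  fit <- fit_modified_poisson(dat, weights = w, terms = "VDI")

  # brute-force oracle: bread = inverse weighted Fisher information,
  # meat = sum of weighted score outer products, assembled longhand
  X <- cbind(1, dat$VDI)
  mu <- exp(drop(X %*% unname(fit$coef)))
  bread <- matrix(0, 2, 2)
  meat <- matrix(0, 2, 2)
  for (i in seq_len(nrow(dat))) {
    xi <- X[i, ]
    bread <- bread + w[i] * mu[i] * tcrossprod(xi)
    si <- w[i] * (dat$FoodAllergy[i] - mu[i]) * xi
    meat <- meat + tcrossprod(si)
  }
  V_oracle <- solve(bread) %*% meat %*% solve(bread)
  expect_equal(unname(fit$vcov), unname(V_oracle), tolerance = 1e-6)
})

test_that("unweighted sandwich agrees with the sandwich package on a glm", {
  skip_if_not_installed("sandwich")
  co <- make_clean_cohort(n = 2000, selection = 1, seed = 21)
  fit <- fit_modified_poisson(as.data.frame(co))
  g <- suppressWarnings(glm(
    FoodAllergy ~ VDI + Eth + FamHx + PetOwn + AnteVD +
      I(NSib == 1) + I(NSib == 2),
    data = as.data.frame(co), family = poisson(link = "log")
  ))
  V <- sandwich::vcovHC(g, type = "HC0")
  expect_equal(unname(fit$coef), unname(coef(g)), tolerance = 1e-6)
  expect_equal(unname(fit$vcov), unname(V), tolerance = 1e-6)
})

test_that("rank-deficient or incomplete designs are rejected", {
  dat <- expand_2x2(20, 80, 10, 90)
  expect_error(fit_modified_poisson(dat), "rank-deficient") # constant covariates
  dat2 <- expand_2x2(20, 80, 10, 90)
  dat2$VDI[1] <- NA
  expect_error(fit_modified_poisson(dat2, terms = "VDI"), "complete")
  expect_error(
    fit_modified_poisson(dat, weights = rep(1, 5), terms = "VDI"),
    "weights"
  )
})

test_that("Rubin's rules reproduce the hand-computed pooling identities", {
  mk_fit <- function(est, v) {
    structure(
      list(
        coef = c(`(Intercept)` = 0, VDI = est),
        vcov = matrix(c(1, 0, 0, v), 2, dimnames = list(
          c("(Intercept)", "VDI"), c("(Intercept)", "VDI")
        )),
        n = 10, converged = TRUE, weights_kind = "none"
      ),
      class = "cc_fit"
    )
  }
  # m identical fits: B = 0, total variance = W, normal quantile
  p <- pool_rubin(rep(list(mk_fit(0.5, 0.04)), 5))
  expect_equal(p$estimate, 0.5)
  expect_equal(p$B, 0)
  expect_equal(p$total_var, 0.04)
  expect_equal(p$df, Inf)
  expect_equal(unname(p$ci[2] - p$ci[1]), 2 * qnorm(0.975) * 0.2)

  # m = 2, estimates {0, 1}, variances {0.1, 0.1}
  p2 <- pool_rubin(list(mk_fit(0, 0.1), mk_fit(1, 0.1)))
  expect_equal(p2$estimate, 0.5)
  expect_equal(p2$W, 0.1)
  expect_equal(p2$B, 0.5)
  expect_equal(p2$total_var, 0.1 + 1.5 * 0.5)
  expect_equal(p2$df, (2 - 1) * (1 + 0.1 / (1.5 * 0.5))^2)

  # total variance never falls below the within-imputation variance
  set.seed(22)
  fits <- lapply(rnorm(7, 0.3, 0.2), mk_fit, v = 0.05)
  p3 <- pool_rubin(fits)
  expect_gte(p3$total_var, p3$W)
  expect_true(p3$ci[1] <= p3$estimate && p3$estimate <= p3$ci[2])

  bad <- mk_fit(0.1, 0.1)
  bad$converged <- FALSE
  expect_error(pool_rubin(list(mk_fit(0, 0.1), bad)), "converge")
  expect_error(pool_rubin(list(mk_fit(0, 0.1))), "at least 2")
})

test_that("all approaches coincide when nothing is missing and selection is 1", {
  co <- make_clean_cohort(n = 2500, selection = 1, seed = 23)
  spec <- imputation_spec(m = 2, cycles = 1, seed = 24)
  ests <- vapply(
    c("complete-data", "CCA", "IPW-only", "MI-IPW-Sub", "MI-IPW-Int", "MI-only"),
    function(a) tidy_estimate(run_approach(co, a, spec = spec))$estimate,
    numeric(1)
  )
  expect_true(all(abs(ests - ests[1]) < 1e-6))
})

test_that("CCA and IPW-only coincide exactly without unintended missingness", {
  co <- make_clean_cohort(n = 4000, selection = 0.3, seed = 25)
  cca <- run_approach(co, "CCA")
  ipw <- run_approach(co, "IPW-only")
  expect_equal(cca$coef, ipw$coef, tolerance = 1e-12)
  expect_equal(cca$vcov, ipw$vcov, tolerance = 1e-12)
})

test_that("approach errors carry their approach context", {
  co <- generate_cohort(default_generation_params(), 100, seed = 26)
  expect_error(run_approach(co, "CCA"), "CCA:")
})
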