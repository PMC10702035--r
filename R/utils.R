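# Internal numerical helpers shared across modules.

#' Deterministic seed derivation
#'
#' Derives a child seed from a master seed, a string key and an index, so that
#' every replication (and every imputation within a replication) has its own
#' reproducible random stream regardless of execution order.
#'
#' @param master integer master seed.
#' @param key character key (e.g. a scenario id).
#' @param index non-negative integer (e.g. replication number).
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, key = "", index = 0L) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (ch in utf8ToInt(as.character(key))) h <- (h * 31 + ch) %% m
  s <- (as.numeric(master) %% m) * 48271 + h * 16807 + as.numeric(index) * 69621
  s <- s %% m
  as.integer(s) + 1L
}

# Iteratively reweighted least squares for logistic regression on a raw
# design matrix. A small ridge penalty (excluding the intercept) is the
# fallback for separation/collinearity; `ridge = 0` first, then
# `ridge_fallback` if the unpenalized fit diverges.
.fit_logistic <- function(X, y, ridge = 0, maxit = 100, tol = 1e-10) {
  p <- ncol(X)
  pen <- rep(ridge, p)
  pen[1] <- 0 # never penalize the intercept
  beta <- numeric(p)
  pbar <- min(max(mean(y), 1e-6), 1 - 1e-6)
  beta[1] <- stats::qlogis(pbar)
  info <- NULL
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    score <- drop(crossprod(X, y - mu)) - pen * beta
    info <- crossprod(X * w, X)
    diag(info) <- diag(info) + pen
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      return(list(coef = beta, cov = NULL, converged = FALSE))
    }
    # step-halving to keep the likelihood ascent stable
    if (max(abs(step)) > 5) step <- step * (5 / max(abs(step)))
    beta <- beta + step
    if (any(!is.finite(beta)) || max(abs(beta)) > 1e3) {
      return(list(coef = beta, cov = NULL, converged = FALSE))
    }
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
  }
  cov <- tryCatch(solve(info), error = function(e) NULL)
  list(coef = beta, cov = cov, converged = converged && !is.null(cov))
}

# Logistic fit with automatic ridge fallback; errors only if the penalized
# fit is still unusable.
.fit_logistic_safe <- function(X, y, ridge_fallback = 0.1, context = "logistic model") {
  fit <- .fit_logistic(X, y)
  fit$penalized <- FALSE
  if (!fit$converged || is.null(fit$cov) ||
    max(abs(fit$coef)) > 25 || any(!is.finite(diag(fit$cov)))) {
    fit <- .fit_logistic(X, y, ridge = ridge_fallback)
    fit$penalized <- TRUE
  }
  if (!fit$converged || is.null(fit$cov)) {
    stop(context, ": fit failed even with ridge penalty (separation or rank deficiency)")
  }
  fit
}

# Draw from the approximate multivariate-normal posterior N(coef, cov).
.draw_coef <- function(fit) {
  L <- tryCatch(chol(fit$cov), error = function(e) {
    # tiny jitter for numerically semi-definite covariances
    chol(fit$cov + diag(1e-10, nrow(fit$cov)))
  })
  drop(fit$coef + t(L) %*% stats::rnorm(length(fit$coef)))
}

# Vectorized draw from a 3-category distribution with per-record
# probabilities p0, p1, p2 (columns); returns values in {0, 1, 2}.
.rcat3 <- function(p0, p1, p2) {
  u <- stats::runif(length(p0))
  (u > p0) + (u > p0 + p1)
}

# Half-up rounding to `digits` decimals (the tabulation convention used for
# the descriptive tables; R's round() is round-half-even).
.round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

# Multinomial-logit category probabilities for a 3-level variable with
# linear predictors lp1 = log(P1/P0), lp2 = log(P2/P0). Rows sum to 1.
.mlogit3_probs <- function(lp1, lp2) {
  den <- 1 + exp(lp1) + exp(lp2)
  cbind(p0 = 1 / den, p1 = exp(lp1) / den, p2 = exp(lp2) / den)
}
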