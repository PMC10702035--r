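# Target-model estimation: modified Poisson regression (log link, robust
# sandwich variance, optionally weighted) for the risk ratio, Rubin's-rules
# pooling across imputations, and the five missing-data analysis approaches
# plus the complete-data benchmark.

.cc_model_terms <- c("VDI", "Eth", "FamHx", "PetOwn", "AnteVD", "NSib")

.cc_design_matrix <- function(data, terms = .cc_model_terms) {
  cols <- list(`(Intercept)` = rep(1, nrow(data)))
  for (tm in terms) {
    if (tm == "NSib") {
      cols$NSib1 <- as.numeric(data$NSib == 1)
      cols$NSib2 <- as.numeric(data$NSib == 2)
    } else {
      cols[[tm]] <- as.numeric(data[[tm]])
    }
  }
  do.call(cbind, cols)
}

#' Modified Poisson regression for the risk ratio
#'
#' Fits the target log-link model for the binary outcome — intercept,
#' exposure (`VDI`), `Eth`, `FamHx`, `PetOwn`, `AnteVD` and two
#' number-of-siblings indicators — by maximizing the (optionally weighted)
#' Poisson log-likelihood, the standard device for estimating risk ratios
#' directly while avoiding the convergence problems of log-binomial
#' regression. The variance is a weight-aware sandwich estimator (HC0 by
#' default) treating the weights as fixed: bread = inverse weighted Fisher
#' information, meat = sum of weighted score outer products.
#'
#' @param data data.frame with complete values for the model variables.
#' @param weights optional per-record weights (a [sampling_weights()] /
#'   [combined_weights()] vector aligned with `data` rows, or plain
#'   numeric); `NULL` for an unweighted fit.
#' @param hc `"HC0"` (default) or `"HC1"` (multiplies the meat by
#'   `n/(n - p)`).
#' @param terms model terms on the right-hand side; defaults to the full
#'   target model (`VDI` plus the five confounders, `NSib` entering as two
#'   indicators). Reduced term sets support saturated closed-form checks.
#' @return a `cc_fit`: list with `coef` (log-RR scale, named), `vcov`
#'   (robust), `n`, `converged`, `weights_kind`.
#' @export
fit_modified_poisson <- function(data, weights = NULL, hc = c("HC0", "HC1"),
                                 terms = .cc_model_terms) {
  hc <- match.arg(hc)
  X <- .cc_design_matrix(data, terms)
  y <- as.numeric(data$FoodAllergy)
  if (anyNA(X) || anyNA(y)) stop("model variables must be complete")
  w <- if (is.null(weights)) rep(1, length(y)) else as.numeric(weights)
  if (length(w) != length(y) || anyNA(w)) {
    stop("weights must be defined for every record in the data")
  }
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design matrix")

  start <- c(log(max(stats::weighted.mean(y, w), 1e-8)), rep(0, ncol(X) - 1))
  fit <- suppressWarnings(stats::glm.fit(X, y,
    weights = w, family = stats::poisson(link = "log"), start = start,
    control = stats::glm.control(maxit = 100)
  ))
  if (!fit$converged) {
    # retry from a flat start
    fit <- suppressWarnings(stats::glm.fit(X, y,
      weights = w, family = stats::poisson(link = "log"),
      control = stats::glm.control(maxit = 200)
    ))
  }
  if (!fit$converged) stop("modified Poisson fit did not converge")
  beta <- stats::setNames(fit$coefficients, colnames(X))
  mu <- drop(exp(X %*% beta))
  A <- crossprod(X, X * (w * mu)) # weighted Fisher information
  U <- X * (w * (y - mu)) # weighted scores
  meat <- crossprod(U)
  if (hc == "HC1") meat <- meat * length(y) / (length(y) - ncol(X))
  Ainv <- solve(A)
  V <- Ainv %*% meat %*% Ainv
  dimnames(V) <- list(colnames(X), colnames(X))
  structure(
    list(
      coef = beta, vcov = V, n = length(y), converged = TRUE,
      weights_kind = if (is.null(weights)) "none" else attr(weights, "kind") %||% "numeric"
    ),
    class = "cc_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cc_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  cat("<cc_fit> modified Poisson, n =", x$n, ", weights =", x$weights_kind, "\n")
  print(.round_half_up(cbind(logRR = x$coef, robust_se = se, RR = exp(x$coef)), 4))
  invisible(x)
}

# 95% Wald CI on the log-RR scale for one coefficient of a single fit.
.fit_ci <- function(fit, parameter = "VDI", level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- fit$coef[[parameter]]
  se <- sqrt(fit$vcov[parameter, parameter])
  c(estimate = est, se = se, lower = est - z * se, upper = est + z * se)
}

#' Pool fits across imputations by Rubin's rules
#'
#' Pools the exposure coefficient across `m` completed-data fits: the
#' pooled estimate is the mean; the total variance is the mean
#' within-imputation (robust) variance `W` plus `(1 + 1/m)` times the
#' between-imputation variance `B`; degrees of freedom follow the classic
#' formula `(m - 1) * (1 + W / ((1 + 1/m) B))^2`, with `B = 0` handled by
#' a normal quantile.
#'
#' @param fits list of `cc_fit` objects from the same model.
#' @param parameter coefficient to pool (default the exposure, `"VDI"`).
#' @param level confidence level.
#' @return a `cc_pooled`: list with `estimate`, `W`, `B`, `total_var`,
#'   `df`, `se`, `ci` (length-2), `m`.
#' @export
pool_rubin <- function(fits, parameter = "VDI", level = 0.95) {
  m <- length(fits)
  if (m < 2) stop("need at least 2 fits to pool")
  if (any(!vapply(fits, function(f) isTRUE(f$converged), logical(1)))) {
    stop("cannot pool: at least one fit did not converge")
  }
  est <- vapply(fits, function(f) f$coef[[parameter]], numeric(1))
  vars <- vapply(fits, function(f) f$vcov[parameter, parameter], numeric(1))
  qbar <- mean(est)
  W <- mean(vars)
  B <- stats::var(est)
  total <- W + (1 + 1 / m) * B
  if (B > 0) {
    df <- (m - 1) * (1 + W / ((1 + 1 / m) * B))^2
    q <- stats::qt(1 - (1 - level) / 2, df)
  } else {
    df <- Inf
    q <- stats::qnorm(1 - (1 - level) / 2)
  }
  se <- sqrt(total)
  structure(
    list(
      estimate = qbar, W = W, B = B, total_var = total, df = df, se = se,
      ci = c(lower = qbar - q * se, upper = qbar + q * se), m = m,
      parameter = parameter
    ),
    class = "cc_pooled"
  )
}

#' @export
print.cc_pooled <- function(x, ...) {
  cat(
    "<cc_pooled> ", x$parameter, ": ", .round_half_up(x$estimate, 4),
    " (RR ", .round_half_up(exp(x$estimate), 3), "), 95% CI [",
    .round_half_up(x$ci[1], 4), ", ", .round_half_up(x$ci[2], 4),
    "], m = ", x$m, "\n",
    sep = ""
  )
  invisible(x)
}

.cc_approaches <- c(
  "CCA", "IPW-only", "MI-IPW-Sub", "MI-IPW-Int", "MI-only", "complete-data"
)

#' Run one missing-data analysis approach on a cohort
#'
#' The approaches compared in the study:
#' * `CCA` — delete records with unintended missingness, analyse complete
#'   subset records with sampling weights;
#' * `IPW-only` — analyse complete subset records with combined
#'   selection-by-response weights;
#' * `MI-IPW-Sub` — impute within the subset, sampling-weighted analysis of
#'   each completed subset, Rubin pooling;
#' * `MI-IPW-Int` — impute the full cohort, discard non-subset records,
#'   sampling-weighted analysis, Rubin pooling;
#' * `MI-only` — impute the full cohort (including the by-design missing
#'   exposure), unweighted analysis of the full cohort, Rubin pooling;
#' * `complete-data` — unweighted fit to the pre-missingness cohort (the
#'   data-generation benchmark).
#'
#' @param cohort a `cc_cohort` with design indicators and masks set.
#' @param approach one of the names above.
#' @param spec an [imputation_spec()] for the MI approaches (its scope is
#'   set by the approach).
#' @param selection_probability optional known selection probability passed
#'   to [sampling_weights()].
#' @param response_predictors predictors for the IPW-only response model.
#' @return a `cc_fit` (CCA, IPW-only, complete-data) or `cc_pooled` (MI
#'   approaches).
#' @export
run_approach <- function(cohort, approach = .cc_approaches, spec = NULL,
                         selection_probability = NULL,
                         response_predictors = c("Eth", "MAge")) {
  approach <- match.arg(approach)
  tryCatch(
    switch(approach,
      "complete-data" = fit_modified_poisson(complete_view(cohort)),
      "CCA" = {
        w <- sampling_weights(cohort, selection_probability)
        keep <- cohort$in_subset & cohort$is_complete
        fit_modified_poisson(as.data.frame(cohort)[keep, ], unclass(w)[keep])
      },
      "IPW-only" = {
        u <- combined_weights(cohort, response_predictors)
        if (!is.null(selection_probability)) {
          # rescale the sampling component to the known design probability
          w_known <- sampling_weights(cohort, selection_probability)
          w_est <- sampling_weights(cohort)
          u <- unclass(u) * unclass(w_known) / unclass(w_est)
        }
        keep <- cohort$in_subset & cohort$is_complete
        fit_modified_poisson(as.data.frame(cohort)[keep, ], unclass(u)[keep])
      },
      "MI-IPW-Sub" = {
        spec <- spec %||% imputation_spec()
        spec$scope <- "subset"
        view <- scope_view(cohort, "subset")
        w <- unclass(sampling_weights(cohort, selection_probability))[view$id]
        imp <- impute(view, spec)
        pool_rubin(lapply(imp$imputations, fit_modified_poisson, weights = w))
      },
      "MI-IPW-Int" = {
        spec <- spec %||% imputation_spec()
        spec$scope <- "full"
        view <- scope_view(cohort, "full")
        w_all <- unclass(sampling_weights(cohort, selection_probability))
        imp <- impute(view, spec)
        fits <- lapply(imp$imputations, function(d) {
          keep <- d$in_subset
          fit_modified_poisson(d[keep, ], w_all[d$id[keep]])
        })
        pool_rubin(fits)
      },
      "MI-only" = {
        spec <- spec %||% imputation_spec()
        spec$scope <- "full"
        imp <- impute(scope_view(cohort, "full"), spec)
        pool_rubin(lapply(imp$imputations, fit_modified_poisson))
      }
    ),
    error = function(e) {
      stop(approach, ": ", conditionMessage(e), call. = FALSE)
    }
  )
}

#' Extract a one-row summary from a fit or pooled estimate
#'
#' @param x a `cc_fit` or `cc_pooled`.
#' @param parameter coefficient of interest.
#' @return data.frame with `estimate`, `se`, `ci_lower`, `ci_upper`,
#'   `converged`.
#' @export
tidy_estimate <- function(x, parameter = "VDI") {
  if (inherits(x, "cc_pooled")) {
    data.frame(
      estimate = x$estimate, se = x$se,
      ci_lower = unname(x$ci[1]), ci_upper = unname(x$ci[2]), converged = TRUE
    )
  } else {
    ci <- .fit_ci(x, parameter)
    data.frame(
      estimate = unname(ci["estimate"]), se = unname(ci["se"]),
      ci_lower = unname(ci["lower"]), ci_upper = unname(ci["upper"]),
      converged = x$converged
    )
  }
}
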