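# Inverse-probability weights: sampling weights for the case-cohort design
# and combined selection-by-response weights for the fully weighted analysis.

#' Sampling weights for the case-cohort subset
#'
#' The weight is the inverse probability of selection into the subset given
#' the outcome: 1 for cases (all cases are selected), and `(m0/n0)^-1` for
#' non-case subcohort members, where `n0` is the number of non-cases in the
#' full cohort and `m0` the number of non-cases in the subcohort. Weights
#' are undefined (`NA`) for non-subset records.
#'
#' @param cohort a `cc_cohort` with the subset defined ([select_subset()]).
#' @param selection_probability optional known selection probability; if
#'   supplied, the non-case weight is `1/selection_probability` instead of
#'   the `(m0/n0)^-1` estimate (as done in the case study, where the design
#'   probability 0.30 is known).
#' @return a numeric vector of per-record weights (class `cc_weights`) with
#'   attributes `kind = "sampling"`, `m0`, `n0`.
#' @export
sampling_weights <- function(cohort, selection_probability = NULL) {
  if (anyNA(cohort$in_subset)) stop("subset must be defined before computing weights")
  n0 <- sum(!cohort$is_case)
  m0 <- sum(!cohort$is_case & cohort$in_subcohort)
  if (is.null(selection_probability)) {
    if (m0 == 0) stop("no non-cases in the subcohort: sampling weight undefined")
    w_noncase <- n0 / m0
  } else {
    w_noncase <- 1 / selection_probability
  }
  w <- ifelse(cohort$is_case, 1, w_noncase)
  w[!cohort$in_subset] <- NA
  structure(w, kind = "sampling", m0 = m0, n0 = n0, class = "cc_weights")
}

#' Combined selection-by-response weights
#'
#' For the fully weighted (IPW-only) analysis the weight is the inverse
#' probability of being an analyzed complete record: the sampling weight
#' divided by the estimated probability of having no unintended missingness
#' in any analysis variable. That response probability is estimated by a
#' logistic regression of the complete-record indicator on fully observed
#' predictors of missingness, fitted among subset members (the records for
#' which completeness is at stake; configurable). If no subset record has
#' unintended missingness the response model is degenerate and all response
#' probabilities are taken to be 1.
#'
#' @param cohort a `cc_cohort` with subset defined.
#' @param response_predictors names of fully observed predictor columns for
#'   the response model; the outcome is always included first.
#' @return a numeric vector (class `cc_weights`, kind `"combined"`) defined
#'   for complete subset records, `NA` elsewhere, with the fitted response
#'   model coefficients in attribute `response_model`.
#' @export
combined_weights <- function(cohort, response_predictors = c("Eth", "MAge")) {
  w <- sampling_weights(cohort)
  sub <- which(cohort$in_subset)
  if (length(sub) == 0) stop("empty subset")
  r <- as.numeric(cohort$is_complete[sub])
  preds <- unique(c("FoodAllergy", response_predictors))
  Z <- as.matrix(as.data.frame(cohort)[sub, preds, drop = FALSE])
  if (anyNA(Z)) stop("response predictors must be fully observed on the subset")
  coefs <- NULL
  if (all(r == 1)) {
    p_complete <- rep(1, length(sub))
  } else {
    X <- cbind(`(Intercept)` = 1, Z)
    fit <- .fit_logistic_safe(X, r, context = "response model")
    p_complete <- stats::plogis(drop(X %*% fit$coef))
    if (any(p_complete <= 0)) stop("fitted response probability <= 0")
    coefs <- stats::setNames(fit$coef, colnames(X))
  }
  u <- rep(NA_real_, nrow(cohort))
  u[sub] <- unclass(w)[sub] / p_complete
  u[!cohort$is_complete | !cohort$in_subset] <- NA
  structure(u,
    kind = "combined", m0 = attr(w, "m0"), n0 = attr(w, "n0"),
    response_model = coefs, class = "cc_weights"
  )
}

#' @export
print.cc_weights <- function(x, ...) {
  cat(
    "<cc_weights> kind =", attr(x, "kind"), "; defined for",
    sum(!is.na(x)), "of", length(x), "records\n"
  )
  invisible(x)
}
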