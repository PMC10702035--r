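# Synthetic cohort generation: variables drawn sequentially
# Eth -> MAge -> SEIFA -> FamHx -> NSib -> PetOwn -> AnteVD -> VDI -> outcome.

.cc_analysis_vars <- c(
  "FoodAllergy", "VDI", "Eth", "PetOwn", "AnteVD", "FamHx", "NSib"
)
.cc_all_vars <- c(.cc_analysis_vars, "MAge", "SEIFA")
.cc_maskable <- c("VDI", "PetOwn", "AnteVD")

#' Outcome probability under the log-link risk model
#'
#' Computes `exp(theta0 + theta1*VDI + theta2*Eth + theta3*FamHx +
#' theta4*PetOwn + theta5*AnteVD + theta6*I[NSib=1] + theta7*I[NSib=2] +
#' theta_int*VDI*Eth)`. Because the link is the log of a probability, the
#' result must lie strictly inside (0, 1); values outside that range are a
#' validity violation of the generating model and raise an error rather
#' than being truncated (truncation would silently change the estimand).
#'
#' @param record a list or data.frame with fields `VDI`, `Eth`, `FamHx`,
#'   `PetOwn`, `AnteVD`, `NSib` (NSib coded 0/1/2). Vectorized over rows.
#' @param theta numeric vector of length 8 (intercept first).
#' @param theta_int optional exposure-by-ethnicity interaction coefficient.
#' @return numeric vector of outcome probabilities in (0, 1).
#' @export
outcome_probability <- function(record, theta, theta_int = 0) {
  if (length(theta) != 8 || any(!is.finite(theta))) {
    stop("theta must be a finite vector of length 8")
  }
  lp <- theta[1] + theta[2] * record$VDI + theta[3] * record$Eth +
    theta[4] * record$FamHx + theta[5] * record$PetOwn +
    theta[6] * record$AnteVD + theta[7] * (record$NSib == 1) +
    theta[8] * (record$NSib == 2) + theta_int * record$VDI * record$Eth
  p <- exp(lp)
  if (any(!is.finite(p)) || any(p >= 1) || any(p <= 0)) {
    stop(
      "log-link validity violation: outcome probability outside (0, 1) ",
      "for at least one record"
    )
  }
  p
}

#' Generate a complete synthetic source cohort
#'
#' Draws `n` records sequentially from the generation models described in
#' [default_generation_params()]: binary variables from logistic models,
#' three-level variables from multinomial-logit models, maternal age from a
#' linear model with Gaussian error, and the outcome from the log-link risk
#' model. The returned cohort is fully observed; missingness and the
#' case-cohort design are imposed afterwards by [induce_unintended()] and
#' [select_subset()].
#'
#' @param params a `cc_generation_params` object.
#' @param n number of records (>= 1).
#' @param seed optional integer seed; given the seed the cohort is
#'   bit-for-bit reproducible.
#' @return an object of class `cc_cohort`: a data.frame with the analysis
#'   and auxiliary variables plus design indicator columns (`is_case`,
#'   `in_subcohort`, `in_subset`, `is_complete`; the latter three are `NA`
#'   until [select_subset()] is called). The pre-missingness values and the
#'   missingness masks are carried in attributes.
#' @export
generate_cohort <- function(params, n, seed = NULL) {
  validate_generation_params(params)
  if (!is.numeric(n) || length(n) != 1 || n < 1) stop("n must be a count >= 1")
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)

  Eth <- stats::rbinom(n, 1, params$p_eth)
  MAge <- params$delta[1] + params$delta[2] * Eth +
    stats::rnorm(n, 0, params$sigma)

  pr_seifa <- .mlogit3_probs(
    params$zeta[1] + params$zeta[2] * MAge + params$zeta[3] * Eth,
    params$eta[1] + params$eta[2] * MAge + params$eta[3] * Eth
  )
  SEIFA <- .rcat3(pr_seifa[, 1], pr_seifa[, 2], pr_seifa[, 3])

  FamHx <- stats::rbinom(n, 1, stats::plogis(params$iota[1] + params$iota[2] * Eth))

  S1 <- as.numeric(SEIFA == 1)
  S2 <- as.numeric(SEIFA == 2)
  pr_nsib <- .mlogit3_probs(
    params$kappa[1] + params$kappa[2] * MAge + params$kappa[3] * Eth +
      params$kappa[4] * S1 + params$kappa[5] * S2 + params$kappa[6] * FamHx,
    params$lambda[1] + params$lambda[2] * MAge + params$lambda[3] * Eth +
      params$lambda[4] * S1 + params$lambda[5] * S2 + params$lambda[6] * FamHx
  )
  NSib <- .rcat3(pr_nsib[, 1], pr_nsib[, 2], pr_nsib[, 3])
  N1 <- as.numeric(NSib == 1)
  N2 <- as.numeric(NSib == 2)

  lp8 <- function(b) {
    b[1] + b[2] * MAge + b[3] * Eth + b[4] * S1 + b[5] * S2 +
      b[6] * FamHx + b[7] * N1 + b[8] * N2
  }
  PetOwn <- stats::rbinom(n, 1, stats::plogis(lp8(params$rho)))
  AnteVD <- stats::rbinom(n, 1, stats::plogis(lp8(params$psi)))
  VDI <- stats::rbinom(n, 1, stats::plogis(
    lp8(params$phi) + params$phi[9] * PetOwn + params$phi[10] * AnteVD
  ))

  p_y <- outcome_probability(
    list(VDI = VDI, Eth = Eth, FamHx = FamHx, PetOwn = PetOwn, AnteVD = AnteVD, NSib = NSib),
    params$theta, params$theta_int
  )
  FoodAllergy <- stats::rbinom(n, 1, p_y)

  cohort <- data.frame(
    id = seq_len(n),
    FoodAllergy = FoodAllergy, VDI = VDI, Eth = Eth, PetOwn = PetOwn,
    AnteVD = AnteVD, FamHx = FamHx, NSib = NSib, SEIFA = SEIFA, MAge = MAge,
    is_case = FoodAllergy == 1,
    in_subcohort = NA, in_subset = NA, is_complete = NA
  )
  attr(cohort, "complete") <- cohort[, .cc_all_vars]
  attr(cohort, "mask_unintended") <- matrix(
    FALSE, n, length(.cc_maskable),
    dimnames = list(NULL, .cc_maskable)
  )
  attr(cohort, "mask_intended") <- rep(FALSE, n)
  attr(cohort, "params") <- params
  class(cohort) <- c("cc_cohort", "data.frame")
  cohort
}

#' Pre-missingness view of a cohort
#'
#' Returns the cohort with the originally generated (complete) values
#' restored, as used by the complete-data benchmark analysis. Cells that
#' were never generated (e.g. genuinely unknown values in the synthetic
#' case-study fixture) stay `NA`.
#'
#' @param cohort a `cc_cohort`.
#' @return a data.frame with the same rows and the complete variables.
#' @export
complete_view <- function(cohort) {
  out <- as.data.frame(cohort)
  comp <- attr(cohort, "complete")
  out[, .cc_all_vars] <- comp[, .cc_all_vars]
  out
}

# Masks accessors (internal).
.unintended_mask <- function(cohort) attr(cohort, "mask_unintended")
.intended_mask <- function(cohort) attr(cohort, "mask_intended")

#' @export
print.cc_cohort <- function(x, ...) {
  n <- nrow(x)
  cat("<cc_cohort> ", n, " records, ", sum(x$is_case), " cases", sep = "")
  if (!anyNA(x$in_subset)) {
    cat(", subset ", sum(x$in_subset), sep = "")
  }
  nmiss <- colSums(is.na(as.data.frame(x)[, .cc_all_vars, drop = FALSE]))
  nmiss <- nmiss[nmiss > 0]
  if (length(nmiss)) {
    cat("\n  missing: ", paste0(names(nmiss), "=", nmiss, collapse = ", "), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Export a cohort's visible data as CSV
#'
#' Writes one row per record with the analysis/auxiliary variables (missing
#' cells empty) and the design indicator columns.
#'
#' @param cohort a `cc_cohort`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}
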