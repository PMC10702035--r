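# Unintended missingness mechanisms (independent and outcome-dependent),
# calibration of their intercepts, and case-cohort subset selection.

#' Missingness mechanism configuration
#'
#' Describes how unintended missingness is induced in the exposure (`VDI`)
#' and the two incomplete confounders (`PetOwn`, `AnteVD`).
#'
#' Two mechanisms are supported. Under the *independent* mechanism the masks
#' are independent of every generated variable: the two confounder masks are
#' independent Bernoulli draws, and the exposure mask is Bernoulli with a
#' rate that may differ according to whether a confounder is already masked
#' (this overlap tilt is what makes the three stated compound proportions
#' jointly attainable; see the methods vignette). Under the *dependent*
#' mechanism the masks follow sequential logistic models in the outcome,
#' ethnicity and maternal age, with the pet-ownership mask feeding the
#' antenatal-vitamin-D mask and the union of the two confounder masks
#' feeding the exposure mask.
#'
#' Target proportions at the `"low"` level: 20% of records with at least
#' one confounder missing, 10% with the exposure missing, 25% with at least
#' one of the three incomplete. At the `"high"` level the component
#' percentages are doubled; the any-incomplete proportion is then whatever
#' results.
#'
#' @param mechanism `"independent"` or `"dependent"`.
#' @param level `"low"` or `"high"`.
#' @param setting `"observed"` uses the default dependence slopes;
#'   `"enhanced"` doubles them. Ignored by the independent mechanism.
#' @return an (uncalibrated) object of class `cc_missingness_config`. Pass
#'   it to [calibrate_intercepts()] before use.
#' @export
missingness_config <- function(mechanism = c("independent", "dependent"),
                               level = c("low", "high"),
                               setting = c("observed", "enhanced")) {
  mechanism <- match.arg(mechanism)
  level <- match.arg(level)
  setting <- match.arg(setting)
  f <- if (level == "high") 2 else 1
  targets <- list(
    p_conf_any = 0.20 * f,
    p_exposure = 0.10 * f,
    p_any = if (level == "low") 0.25 else NA_real_,
    # component split of the confounder union (chosen; union is what the
    # study conditions state)
    p_petown = 0.10 * f,
    p_ante = 0.125 * f
  )
  s <- if (setting == "enhanced") 2 else 1
  slopes <- list(
    # FoodAllergy, Eth, MAge
    nu = s * c(0.5, -0.3, -0.03),
    tau = s * c(0.5, -0.3, -0.03),
    omega = s * c(0.5, -0.3, -0.03)
  )
  structure(
    list(
      mechanism = mechanism, level = level, setting = setting,
      targets = targets, slopes = slopes,
      intercepts = NULL, rates = NULL, calibrated = FALSE,
      achieved = NULL, calibration = NULL
    ),
    class = "cc_missingness_config"
  )
}

#' @export
print.cc_missingness_config <- function(x, ...) {
  cat(
    "<cc_missingness_config>", x$mechanism, "/", x$level, "/", x$setting,
    if (x$calibrated) "(calibrated)" else "(uncalibrated)", "\n"
  )
  if (x$calibrated && !is.null(x$achieved)) {
    cat(
      "  achieved: conf-any ", .round_half_up(100 * x$achieved$p_conf_any, 2),
      "%, exposure ", .round_half_up(100 * x$achieved$p_exposure, 2),
      "%, any ", .round_half_up(100 * x$achieved$p_any, 2), "%\n",
      sep = ""
    )
  }
  invisible(x)
}

# Per-record dependent-mechanism mask probabilities, computed exactly
# (expectations over the mask randomness) for calibration.
.dep_lp <- function(cohort, slopes) {
  slopes[1] * cohort$FoodAllergy + slopes[2] * cohort$Eth + slopes[3] * cohort$MAge
}

#' Calibrate missingness-mechanism intercepts
#'
#' Chooses the free intercept-like parameters of a missingness mechanism so
#' that the target proportions are achieved on a large reference cohort.
#' For the dependent mechanism this solves, in the causal order of the
#' three mask models, for `nu0` (pet-ownership mask marginal), `tau0` and
#' `tau4` (antenatal-vitamin-D mask marginal and the confounder-mask union),
#' and `omega0` and `omega4` (exposure-mask marginal and the any-incomplete
#' proportion), using per-record closed-form mask probabilities averaged
#' over the reference cohort, with nested root finding. For the independent
#' mechanism the per-variable rates have closed forms. At the `"high"`
#' level, where the any-incomplete proportion is not a stated target,
#' `omega4` (and the independent mechanism's conditional-rate ratio) is
#' carried over from the `"low"` calibration.
#'
#' @param params generation parameters used to simulate the reference
#'   cohort (a `cc_generation_params`), or an existing `cc_cohort` to use
#'   directly as the reference.
#' @param config an uncalibrated [missingness_config()].
#' @param tol required absolute tolerance on achieved proportions
#'   (default 0.005).
#' @param seed seed for the reference cohort simulation.
#' @param n_ref reference cohort size.
#' @return the config with intercepts/rates filled in, `calibrated = TRUE`,
#'   and the achieved proportions recorded.
#' @export
calibrate_intercepts <- function(params, config, tol = 0.005, seed = 1L,
                                 n_ref = 200000) {
  t <- config$targets
  # feasibility: the overlap implied by the three compound targets must be
  # a valid probability
  if (!is.na(t$p_any)) {
    overlap <- t$p_conf_any + t$p_exposure - t$p_any
    if (overlap < 0 || overlap > min(t$p_conf_any, t$p_exposure) ||
      t$p_any < t$p_exposure || t$p_any < t$p_conf_any) {
      stop("infeasible missingness targets: implied mask overlap is not a probability")
    }
  }
  if (t$p_petown + t$p_ante < t$p_conf_any) {
    stop("infeasible missingness targets: component rates cannot reach the union")
  }

  if (config$mechanism == "independent") {
    config <- .calibrate_independent(config)
  } else {
    ref <- if (inherits(params, "cc_cohort")) {
      params
    } else {
      generate_cohort(params, n_ref, seed = seed)
    }
    config <- .calibrate_dependent(config, ref, tol)
  }
  config$calibrated <- TRUE
  config$calibration <- list(tol = tol, seed = seed, n_ref = n_ref)
  # record achieved proportions (exact expectations on the reference)
  ach <- config$achieved
  if (any(abs(unlist(ach[c("p_conf_any", "p_exposure")]) -
    c(t$p_conf_any, t$p_exposure)) > tol)) {
    stop("calibration failed to reach the target proportions within tolerance")
  }
  config
}

.calibrate_independent <- function(config) {
  t <- config$targets
  if (config$level == "low") {
    p_conf <- 1 - sqrt(1 - t$p_conf_any) # equal per-confounder rates
    overlap <- t$p_conf_any + t$p_exposure - t$p_any
    p_vdi_conf <- overlap / t$p_conf_any
    p_vdi_noconf <- (t$p_exposure - overlap) / (1 - t$p_conf_any)
  } else {
    p_conf <- 1 - sqrt(1 - t$p_conf_any)
    # preserve the low-level conditional-rate ratio for the exposure mask
    low <- .calibrate_independent(missingness_config("independent", "low", config$setting))
    r <- low$rates$p_vdi_conf / low$rates$p_vdi_noconf
    q <- t$p_exposure / (t$p_conf_any * r + 1 - t$p_conf_any)
    p_vdi_conf <- r * q
    p_vdi_noconf <- q
  }
  if (any(c(p_vdi_conf, p_vdi_noconf, p_conf) < 0 |
    c(p_vdi_conf, p_vdi_noconf, p_conf) > 1)) {
    stop("infeasible independent-mechanism targets")
  }
  config$rates <- list(
    p_petown = p_conf, p_ante = p_conf,
    p_vdi_conf = p_vdi_conf, p_vdi_noconf = p_vdi_noconf
  )
  p_any <- t$p_conf_any * p_vdi_conf + (1 - t$p_conf_any) * p_vdi_noconf +
    t$p_conf_any * (1 - p_vdi_conf)
  config$achieved <- list(
    p_conf_any = 1 - (1 - p_conf)^2, p_exposure = t$p_conf_any * p_vdi_conf +
      (1 - t$p_conf_any) * p_vdi_noconf, p_any = p_any
  )
  config
}

.calibrate_dependent <- function(config, ref, tol) {
  t <- config$targets
  sl <- config$slopes
  lp_pet <- .dep_lp(ref, sl$nu)
  lp_ante <- .dep_lp(ref, sl$tau)
  lp_vdi <- .dep_lp(ref, sl$omega)

  solve1 <- function(f, target, lower = -25, upper = 25) {
    stats::uniroot(function(b) f(b) - target, c(lower, upper), tol = 1e-10)$root
  }

  nu0 <- solve1(function(b) mean(stats::plogis(b + lp_pet)), t$p_petown)
  p_pet <- stats::plogis(nu0 + lp_pet)

  # tau0 (ante marginal) nested inside tau4 (confounder-mask union)
  ante_marg <- function(t0, t4) {
    mean(p_pet * stats::plogis(t0 + lp_ante + t4) +
      (1 - p_pet) * stats::plogis(t0 + lp_ante))
  }
  conf_union <- function(t0, t4) {
    mean(1 - (1 - p_pet) * (1 - stats::plogis(t0 + lp_ante)))
  }
  union_at <- function(t4) {
    t0 <- solve1(function(b) ante_marg(b, t4), t$p_ante)
    c(union = conf_union(t0, t4), t0 = t0)
  }
  tau4 <- tryCatch(
    stats::uniroot(function(t4) union_at(t4)["union"] - t$p_conf_any,
      c(-15, 15),
      tol = 1e-9
    )$root,
    error = function(e) {
      stop("calibration failed: no tau4 achieves the confounder union target")
    }
  )
  tau0 <- unname(union_at(tau4)["t0"])

  p_ante_pet1 <- stats::plogis(tau0 + lp_ante + tau4)
  p_ante_pet0 <- stats::plogis(tau0 + lp_ante)
  p_conf_any <- 1 - (1 - p_pet) * (1 - p_ante_pet0)
  # distribution of the confounder-any indicator per record
  # (needed for the exposure-mask expectations)
  vdi_marg <- function(w0, w4) {
    mean(p_conf_any * stats::plogis(w0 + lp_vdi + w4) +
      (1 - p_conf_any) * stats::plogis(w0 + lp_vdi))
  }
  any_prop <- function(w0, w4) {
    mean(p_conf_any + (1 - p_conf_any) * stats::plogis(w0 + lp_vdi))
  }
  if (config$level == "low") {
    vdi_at <- function(w4) {
      w0 <- solve1(function(b) vdi_marg(b, w4), t$p_exposure)
      c(any = any_prop(w0, w4), w0 = w0)
    }
    omega4 <- tryCatch(
      stats::uniroot(function(w4) vdi_at(w4)["any"] - t$p_any,
        c(-15, 15),
        tol = 1e-9
      )$root,
      error = function(e) {
        stop("calibration failed: no omega4 achieves the any-incomplete target")
      }
    )
    omega0 <- unname(vdi_at(omega4)["w0"])
  } else {
    low <- .calibrate_dependent(
      missingness_config("dependent", "low", config$setting), ref, tol
    )
    omega4 <- low$intercepts["omega4"]
    omega0 <- solve1(function(b) vdi_marg(b, omega4), t$p_exposure)
  }

  config$intercepts <- c(
    nu0 = nu0, tau0 = tau0, tau4 = tau4,
    omega0 = unname(omega0), omega4 = unname(omega4)
  )
  p_vdi <- p_conf_any * stats::plogis(omega0 + lp_vdi + omega4) +
    (1 - p_conf_any) * stats::plogis(omega0 + lp_vdi)
  config$achieved <- list(
    p_conf_any = mean(p_conf_any), p_exposure = mean(p_vdi),
    p_any = any_prop(omega0, omega4)
  )
  config
}

#' Induce unintended missingness
#'
#' Applies a calibrated missingness mechanism to a fully observed cohort,
#' masking values of `PetOwn`, `AnteVD` and `VDI`. The underlying values
#' remain available internally (for the complete-data benchmark) but are
#' hidden from every analysis operation. Must be called before
#' [select_subset()].
#'
#' @param cohort a fully observed `cc_cohort`.
#' @param config a calibrated [missingness_config()].
#' @param seed optional integer seed.
#' @return the cohort with unintended masks set and masked cells `NA`.
#' @export
induce_unintended <- function(cohort, config, seed = NULL) {
  if (!inherits(config, "cc_missingness_config") || !isTRUE(config$calibrated)) {
    stop("config must be a calibrated cc_missingness_config (see calibrate_intercepts)")
  }
  if (any(.unintended_mask(cohort))) stop("cohort already has unintended missingness")
  if (anyNA(as.data.frame(cohort)[, .cc_all_vars])) {
    stop("cohort must be fully observed before inducing missingness")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cohort)

  if (config$mechanism == "independent") {
    r <- config$rates
    m_pet <- stats::runif(n) < r$p_petown
    m_ante <- stats::runif(n) < r$p_ante
    conf_any <- m_pet | m_ante
    m_vdi <- stats::runif(n) < ifelse(conf_any, r$p_vdi_conf, r$p_vdi_noconf)
  } else {
    ic <- config$intercepts
    sl <- config$slopes
    m_pet <- stats::runif(n) < stats::plogis(ic["nu0"] + .dep_lp(cohort, sl$nu))
    m_ante <- stats::runif(n) < stats::plogis(
      ic["tau0"] + .dep_lp(cohort, sl$tau) + ic["tau4"] * m_pet
    )
    conf_any <- m_pet | m_ante
    m_vdi <- stats::runif(n) < stats::plogis(
      ic["omega0"] + .dep_lp(cohort, sl$omega) + ic["omega4"] * conf_any
    )
  }

  mask <- cbind(VDI = m_vdi, PetOwn = m_pet, AnteVD = m_ante)
  attr(cohort, "mask_unintended") <- mask
  cohort$VDI[m_vdi] <- NA
  cohort$PetOwn[m_pet] <- NA
  cohort$AnteVD[m_ante] <- NA
  cohort
}

#' Case-cohort design configuration
#'
#' @param n_cohort full cohort size.
#' @param selection_probability probability that a record is selected into
#'   the subcohort (in (0, 1]).
#' @return a `cc_design_config` list.
#' @export
design_config <- function(n_cohort, selection_probability) {
  if (selection_probability <= 0 || selection_probability > 1) {
    stop("selection_probability must be in (0, 1]")
  }
  if (n_cohort < 1) stop("n_cohort must be >= 1")
  structure(
    list(
      n_cohort = as.integer(n_cohort),
      selection_probability = selection_probability
    ),
    class = "cc_design_config"
  )
}

#' Select the subcohort and impose intended exposure missingness
#'
#' Draws subcohort membership as independent Bernoulli with the design's
#' selection probability; the analysis subset is the union of the subcohort
#' and all cases. The exposure is masked (missing by design) for every
#' non-subset record, layered on top of any unintended mask, and the
#' complete-record indicator is computed as "all analysis variables
#' observed".
#'
#' @param cohort a `cc_cohort` (outcome fully observed; unintended
#'   missingness, if any, already induced).
#' @param design a [design_config()] (its `selection_probability` is used;
#'   the cohort's own size defines n).
#' @param seed optional integer seed.
#' @return the cohort with `in_subcohort`, `in_subset`, `is_complete`
#'   filled and intended exposure missingness applied.
#' @export
select_subset <- function(cohort, design, seed = NULL) {
  if (anyNA(cohort$FoodAllergy)) stop("outcome must be observed for all records")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cohort)
  cohort$in_subcohort <- stats::runif(n) < design$selection_probability
  cohort$in_subset <- cohort$is_case | cohort$in_subcohort
  intended <- !cohort$in_subset
  attr(cohort, "mask_intended") <- intended
  cohort$VDI[intended] <- NA
  vis <- as.data.frame(cohort)[, .cc_analysis_vars]
  cohort$is_complete <- stats::complete.cases(vis)
  attr(cohort, "design") <- design
  cohort
}

#' Serialize / read a calibrated missingness configuration
#'
#' Writes the mechanism, targets, slopes, calibrated intercepts or rates,
#' achieved proportions and calibration metadata as YAML.
#'
#' @param config a `cc_missingness_config`.
#' @param path file path.
#' @return `path` invisibly / the restored config.
#' @export
write_missingness_config <- function(config, path) {
  x <- unclass(config)
  x$intercepts <- as.list(x$intercepts)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_missingness_config
#' @export
read_missingness_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$intercepts)) x$intercepts <- unlist(x$intercepts)
  for (nm in names(x$slopes)) x$slopes[[nm]] <- as.numeric(x$slopes[[nm]])
  structure(x, class = "cc_missingness_config")
}
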