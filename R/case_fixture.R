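# Synthetic case-study fixture: a cohort whose marginal counts match the
# motivating birth-cohort food-allergy study's descriptive table, used to
# exercise all five analysis approaches on realistic margins. The joint
# distribution is synthetic (values are shuffled within the subset and
# non-subset strata); only the margins and missingness structure are
# reproduced.

#' Specification of the synthetic case-study fixture
#'
#' Frozen marginal counts: full cohort n = 786 with 61 cases, subset
#' n = 325 (all cases plus non-case subcohort members). The exposure is
#' observed for 246 subset records (79 unintended-missing) and for 47
#' non-subset records, so intended missingness is 414/786 and unintended
#' 79/786. Per-variable present/absent/missing counts for the full cohort
#' and subset are stored for each variable; maternal age is matched on
#' mean and SD.
#'
#' @param seed integer seed controlling the joint realization (margins are
#'   fixed regardless of seed).
#' @return a `cc_fixture_spec` list.
#' @export
fixture_spec <- function(seed = 2024L) {
  # counts: c(present, missing) for binary; 3-level variables give level
  # counts plus missing. Subset counts first, non-subset derived from the
  # full-cohort counts.
  spec <- list(
    n_full = 786L, n_subset = 325L, n_cases = 61L,
    n_vdi_unintended_subset = 79L, n_vdi_present_subset = 109L,
    n_vdi_observed_nonsubset = 47L, n_vdi_present_full = 132L,
    binary = list(
      # full = c(present, missing), subset = c(present, missing)
      Eth = list(full = c(573L, 3L), subset = c(240L, 2L)),
      PetOwn = list(full = c(602L, 8L), subset = c(239L, 3L)),
      AnteVD = list(full = c(460L, 206L), subset = c(193L, 71L)),
      FamHx = list(full = c(675L, 9L), subset = c(284L, 3L))
    ),
    threelevel = list(
      NSib = list(full = c(320L, 281L, 185L, 0L), subset = c(113L, 130L, 82L, 0L)),
      SEIFA = list(full = c(172L, 148L, 452L, 14L), subset = c(77L, 61L, 181L, 6L))
    ),
    mage = list(
      full = c(mean = 32.1, sd = 4.8, missing = 3L),
      subset = c(mean = 33.0, sd = 4.3, missing = 0L)
    ),
    seed = as.integer(seed)
  )
  # consistency checks
  if (spec$n_cases > spec$n_subset) stop("inconsistent fixture spec: cases exceed subset")
  for (v in names(spec$binary)) {
    b <- spec$binary[[v]]
    if (any(b$subset > b$full)) stop("inconsistent fixture spec for ", v)
    if (sum(b$full) > spec$n_full) stop("inconsistent fixture spec for ", v)
  }
  class(spec) <- "cc_fixture_spec"
  spec
}

# scatter counts of values into a vector of length n, in random order
.scatter <- function(n, values) {
  stopifnot(length(values) == n)
  sample(values, n)
}

#' Build the synthetic case-study cohort
#'
#' Constructs a `cc_cohort` of 786 records reproducing every count cell of
#' the motivating study's descriptive table exactly (case counts, subset
#' size, per-variable present and missing counts in both the full cohort
#' and the subset) and the maternal-age means/SDs to tabulation precision.
#' Values are assigned independently within the subset and non-subset
#' strata, so joint associations are synthetic.
#'
#' @param spec a [fixture_spec()].
#' @return a `cc_cohort` flagged as a case-study fixture (no underlying
#'   complete data: genuinely missing cells stay unknown).
#' @export
make_fixture <- function(spec = fixture_spec()) {
  set.seed(spec$seed)
  n <- spec$n_full
  ns <- spec$n_subset
  in_subset <- c(rep(TRUE, ns), rep(FALSE, n - ns))
  is_case <- c(rep(TRUE, spec$n_cases), rep(FALSE, n - spec$n_cases))
  # all cases are in the subset (rows 1..61)

  out <- data.frame(
    id = seq_len(n), FoodAllergy = as.numeric(is_case),
    VDI = NA_real_, Eth = NA_real_, PetOwn = NA_real_, AnteVD = NA_real_,
    FamHx = NA_real_, NSib = NA_real_, SEIFA = NA_real_, MAge = NA_real_,
    is_case = is_case, in_subcohort = in_subset & !is_case,
    in_subset = in_subset, is_complete = NA
  )

  sub_rows <- which(in_subset)
  non_rows <- which(!in_subset)

  fill_binary <- function(v) {
    b <- spec$binary[[v]]
    sub_miss <- b$subset[2]
    sub_pres <- b$subset[1]
    sub_abs <- ns - sub_pres - sub_miss
    non_miss <- b$full[2] - sub_miss
    non_pres <- b$full[1] - sub_pres
    non_abs <- (n - ns) - non_pres - non_miss
    if (min(sub_abs, non_abs, non_miss, non_pres) < 0) {
      stop("inconsistent fixture counts for ", v)
    }
    vals <- rep(NA_real_, n)
    vals[sub_rows] <- .scatter(ns, c(rep(1, sub_pres), rep(0, sub_abs), rep(NA, sub_miss)))
    vals[non_rows] <- .scatter(
      n - ns,
      c(rep(1, non_pres), rep(0, non_abs), rep(NA, non_miss))
    )
    vals
  }
  for (v in names(spec$binary)) out[[v]] <- fill_binary(v)

  fill_three <- function(v) {
    t3 <- spec$threelevel[[v]]
    subc <- t3$subset
    nonc <- t3$full - subc
    if (min(nonc) < 0 || sum(subc) != ns || sum(t3$full) != n) {
      stop("inconsistent fixture counts for ", v)
    }
    vals <- rep(NA_real_, n)
    vals[sub_rows] <- .scatter(ns, rep(c(0, 1, 2, NA), subc))
    vals[non_rows] <- .scatter(n - ns, rep(c(0, 1, 2, NA), nonc))
    vals
  }
  for (v in names(spec$threelevel)) out[[v]] <- fill_three(v)

  # VDI: subset has 79 unintended-missing, 246 observed (109 present);
  # 47 non-subset records are observed (reconciling the full-cohort
  # present count), the remaining 414 are missing by design.
  sub_pres <- spec$n_vdi_present_subset
  sub_miss <- spec$n_vdi_unintended_subset
  sub_abs <- ns - sub_pres - sub_miss
  non_obs <- spec$n_vdi_observed_nonsubset
  non_pres <- spec$n_vdi_present_full - sub_pres
  vdi <- rep(NA_real_, n)
  vdi[sub_rows] <- .scatter(ns, c(rep(1, sub_pres), rep(0, sub_abs), rep(NA, sub_miss)))
  non_vals <- c(
    rep(1, non_pres), rep(0, non_obs - non_pres),
    rep(NA, (n - ns) - non_obs)
  )
  vdi[non_rows] <- .scatter(n - ns, non_vals)
  out$VDI <- vdi

  # maternal age: subset complete, matched to mean/SD exactly; non-subset
  # observed records matched so the full-cohort mean/SD reproduce.
  ms <- spec$mage$subset
  mf <- spec$mage$full
  n_obs_full <- n - mf[["missing"]]
  n_obs_non <- n_obs_full - ns
  m_non <- (mf[["mean"]] * n_obs_full - ms[["mean"]] * ns) / n_obs_non
  # solve the non-subset SD from the pooled-variance identity
  ss_total <- (n_obs_full - 1) * mf[["sd"]]^2
  ss_sub <- (ns - 1) * ms[["sd"]]^2 + ns * (ms[["mean"]] - mf[["mean"]])^2
  ss_non_dev <- n_obs_non * (m_non - mf[["mean"]])^2
  s_non <- sqrt((ss_total - ss_sub - ss_non_dev) / (n_obs_non - 1))
  standardize <- function(x, m, s) m + s * (x - mean(x)) / stats::sd(x)
  mage <- rep(NA_real_, n)
  mage[sub_rows] <- standardize(stats::rnorm(ns), ms[["mean"]], ms[["sd"]])
  obs_non <- sample(non_rows, n_obs_non)
  mage[obs_non] <- standardize(stats::rnorm(n_obs_non), m_non, s_non)
  out$MAge <- mage

  out$is_complete <- stats::complete.cases(out[, .cc_analysis_vars])
  mask_un <- cbind(
    VDI = is.na(out$VDI) & in_subset, # unintended exposure missingness
    PetOwn = is.na(out$PetOwn), AnteVD = is.na(out$AnteVD)
  )
  # the 47 observed non-subset exposures are not design-missing
  vdi_intended <- is.na(out$VDI) & !in_subset
  attr(out, "complete") <- out[, .cc_all_vars] # no hidden truth: fixture only
  attr(out, "mask_unintended") <- mask_un
  attr(out, "mask_intended") <- vdi_intended
  attr(out, "design") <- design_config(n, 0.30)
  attr(out, "fixture") <- TRUE
  class(out) <- c("cc_cohort", "data.frame")
  out
}

#' Descriptive table of a cohort (summary and missingness)
#'
#' Tabulates, for the full cohort and the subset: for binary and
#' categorical variables the count and percentage present per level among
#' observed values, and the missing count and percentage of all records;
#' for maternal age the mean (SD). Percentages use half-up rounding to one
#' decimal, matching the tabulation convention of the motivating study.
#'
#' @param cohort a `cc_cohort` with the subset defined.
#' @return a data.frame with columns `variable`, `level`, `full_summary`,
#'   `full_missing`, `subset_summary`, `subset_missing`.
#' @export
summarize_table1 <- function(cohort) {
  dat <- as.data.frame(cohort)
  groups <- list(full = dat, subset = dat[dat$in_subset, , drop = FALSE])
  fmt_n <- function(k, pct) paste0(k, " (", sprintf("%.1f", .round_half_up(pct, 1)), ")")
  rows <- list()
  add <- function(variable, level, f_sum, f_mis, s_sum, s_mis) {
    rows[[length(rows) + 1]] <<- data.frame(
      variable = variable, level = level, full_summary = f_sum,
      full_missing = f_mis, subset_summary = s_sum, subset_missing = s_mis
    )
  }
  bin_cells <- function(g, v) {
    x <- g[[v]]
    n_mis <- sum(is.na(x))
    n_obs <- sum(!is.na(x))
    k <- sum(x == 1, na.rm = TRUE)
    list(
      s = fmt_n(k, 100 * k / n_obs),
      m = fmt_n(n_mis, 100 * n_mis / nrow(g))
    )
  }
  for (v in c("FoodAllergy", "VDI", "Eth", "PetOwn", "AnteVD", "FamHx")) {
    f <- bin_cells(groups$full, v)
    s <- bin_cells(groups$subset, v)
    add(v, "present", f$s, f$m, s$s, s$m)
  }
  for (v in c("NSib", "SEIFA")) {
    for (lev in 0:2) {
      cells <- lapply(groups, function(g) {
        x <- g[[v]]
        k <- sum(x == lev, na.rm = TRUE)
        fmt_n(k, 100 * k / sum(!is.na(x)))
      })
      mis <- lapply(groups, function(g) {
        nm <- sum(is.na(g[[v]]))
        fmt_n(nm, 100 * nm / nrow(g))
      })
      add(v, as.character(lev), cells$full, mis$full, cells$subset, mis$subset)
    }
  }
  mage <- lapply(groups, function(g) {
    x <- g$MAge
    list(
      s = paste0(
        sprintf("%.1f", .round_half_up(mean(x, na.rm = TRUE), 1)), " (",
        sprintf("%.1f", .round_half_up(stats::sd(x, na.rm = TRUE), 1)), ")"
      ),
      m = fmt_n(sum(is.na(x)), 100 * sum(is.na(x)) / nrow(g))
    )
  })
  add("MAge", "mean (SD)", mage$full$s, mage$full$m, mage$subset$s, mage$subset$m)
  do.call(rbind, rows)
}

#' Run the five analysis approaches on the case-study fixture
#'
#' Applies CCA, IPW-only, MI-IPW-Sub, MI-IPW-Int and MI-only with the
#' known design selection probability (non-case sampling weight
#' `1/0.30`). All incomplete variables — the exposure, both incomplete
#' confounders, family history, ethnicity, the socioeconomic tertile and
#' maternal age — are imputed with type-appropriate models (logistic,
#' ordinal logistic, linear). The IPW-only response model uses the outcome
#' and maternal age (the fully observed predictors in the subset).
#'
#' @param cohort a fixture-like `cc_cohort`.
#' @param m number of imputations (study default 50).
#' @param cycles FCS sweeps per imputation.
#' @param seed integer seed for the imputation draws.
#' @return data.frame with one row per approach: `approach`, `RR`,
#'   `ci_lower`, `ci_upper` (RR scale), `log_rr`, `se`.
#' @export
run_case_study <- function(cohort, m = 50, cycles = 10, seed = 1L) {
  approaches <- c("CCA", "IPW-only", "MI-IPW-Sub", "MI-IPW-Int", "MI-only")
  sel <- attr(cohort, "design")$selection_probability %||% 0.30
  out <- lapply(approaches, function(a) {
    spec <- imputation_spec(m = m, cycles = cycles, seed = derive_seed(seed, a, 1L))
    fit <- run_approach(cohort, a,
      spec = spec, selection_probability = sel,
      response_predictors = "MAge"
    )
    td <- tidy_estimate(fit)
    data.frame(
      approach = a, RR = exp(td$estimate),
      ci_lower = exp(td$ci_lower), ci_upper = exp(td$ci_upper),
      log_rr = td$estimate, se = td$se
    )
  })
  do.call(rbind, out)
}
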