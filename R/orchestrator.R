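# Scenario grid and replication engine: 24 factorial scenarios plus 2
# analysis-model-misspecification scenarios, with deterministic per-
# replication seed streams so results are identical regardless of
# execution order.

#' The 26-scenario study grid
#'
#' The factorial part crosses three designs — (n = 1,000, selection 0.3),
#' (n = 10,000, selection 0.1), (n = 10,000, selection 0.2) — with the
#' association setting (observed / enhanced), the unintended-missingness
#' level (low / high) and mechanism (independent / dependent): 24
#' scenarios. Two additional scenarios generate the outcome with an
#' exposure-by-ethnicity interaction (misspecifying the main-effects
#' analysis model) under the observed association, dependent mechanism and
#' low missingness, one per sample-size design.
#'
#' @return a data.frame with one row per scenario: `scenario` (stable id),
#'   `n_cohort`, `selection`, `setting`, `level`, `mechanism`,
#'   `interaction`.
#' @export
scenario_grid <- function() {
  designs <- data.frame(
    n_cohort = c(1000L, 10000L, 10000L),
    selection = c(0.3, 0.1, 0.2)
  )
  fact <- expand.grid(
    design = seq_len(nrow(designs)),
    setting = c("observed", "enhanced"),
    level = c("low", "high"),
    mechanism = c("independent", "dependent"),
    stringsAsFactors = FALSE
  )
  grid <- data.frame(
    n_cohort = designs$n_cohort[fact$design],
    selection = designs$selection[fact$design],
    setting = fact$setting, level = fact$level, mechanism = fact$mechanism,
    interaction = FALSE
  )
  extra <- data.frame(
    n_cohort = c(1000L, 10000L), selection = c(0.3, 0.1),
    setting = "observed", level = "low", mechanism = "dependent",
    interaction = TRUE
  )
  grid <- rbind(grid, extra)
  grid$scenario <- with(grid, paste0(
    "n", n_cohort, "_s", selection, "_", substr(setting, 1, 3), "_",
    level, "_", substr(mechanism, 1, 3), ifelse(interaction, "_int", "")
  ))
  grid[, c(
    "scenario", "n_cohort", "selection", "setting", "level",
    "mechanism", "interaction"
  )]
}

#' Run one simulation scenario
#'
#' For each replication: generate a complete cohort, induce unintended
#' missingness, select the subcohort/subset, and run each requested
#' analysis approach, collecting the exposure estimate, SE and 95% CI.
#' Per-replication seeds are derived deterministically from the master
#' seed, scenario id and replication index, so any subset of replications
#' can be re-run independently with identical results.
#'
#' @param scenario one row of [scenario_grid()] (or a list with the same
#'   fields).
#' @param n_reps number of replications (the study default is 2,000; use
#'   fewer for desk-scale runs).
#' @param approaches character vector of approaches (see [run_approach()]).
#' @param seed master seed.
#' @param m,cycles imputation settings for the MI approaches.
#' @param params optional pre-built generation parameters (otherwise built
#'   from the scenario's setting/interaction flags).
#' @param miss_config optional pre-calibrated missingness configuration
#'   (otherwise calibrated here once, against a 200,000-record reference
#'   cohort).
#' @param true_value optional true log risk ratio. Defaults to the
#'   generating exposure coefficient; for interaction scenarios, where the
#'   analysis model is misspecified, it is estimated via
#'   [true_value_misspecified()] at its desk-scale defaults unless
#'   supplied.
#' @param max_failure_rate abort if more than this fraction of
#'   replications fails for any approach (default 0.1).
#' @param keep_estimates if `TRUE`, attach the per-replication estimates
#'   as attribute `"estimates"`.
#' @return a data.frame of [summarize_performance()] rows, one per
#'   approach.
#' @export
run_scenario <- function(scenario, n_reps, approaches = c(
                           "complete-data", "CCA", "IPW-only",
                           "MI-IPW-Sub", "MI-IPW-Int", "MI-only"
                         ),
                         seed = 1L, m = 50, cycles = 10, params = NULL,
                         miss_config = NULL, true_value = NULL,
                         max_failure_rate = 0.1, keep_estimates = FALSE) {
  sc <- as.list(scenario)
  if (is.null(params)) {
    params <- default_generation_params(sc$setting, interaction = isTRUE(sc$interaction))
  }
  if (is.null(miss_config)) {
    miss_config <- calibrate_intercepts(
      params, missingness_config(sc$mechanism, sc$level, sc$setting),
      seed = derive_seed(seed, sc$scenario %||% "calib", 0L)
    )
  }
  if (is.null(true_value)) {
    true_value <- if (isTRUE(sc$interaction)) {
      true_value_misspecified(params, seed = derive_seed(seed, "misspec-truth", 1L))$value
    } else {
      params$theta[2]
    }
  }
  design <- design_config(sc$n_cohort, sc$selection)
  key <- sc$scenario %||% "scenario"

  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    rep_seed <- derive_seed(seed, key, r)
    set.seed(rep_seed)
    cohort <- generate_cohort(params, sc$n_cohort)
    cohort <- induce_unintended(cohort, miss_config)
    cohort <- select_subset(cohort, design)
    res <- lapply(approaches, function(a) {
      spec <- imputation_spec(m = m, cycles = cycles, seed = derive_seed(rep_seed, a, 1L))
      out <- tryCatch(
        tidy_estimate(run_approach(cohort, a, spec = spec)),
        error = function(e) {
          data.frame(
            estimate = NA_real_, se = NA_real_, ci_lower = NA_real_,
            ci_upper = NA_real_, converged = FALSE
          )
        }
      )
      cbind(rep = r, approach = a, out)
    })
    rows[[r]] <- do.call(rbind, res)
  }
  estimates <- do.call(rbind, rows)

  out <- do.call(rbind, lapply(approaches, function(a) {
    ea <- estimates[estimates$approach == a, , drop = FALSE]
    fail <- mean(!ea$converged)
    if (fail > max_failure_rate) {
      stop(
        "scenario ", key, ": approach ", a, " failed in ",
        round(100 * fail, 1), "% of replications"
      )
    }
    summarize_performance(ea, true_value, scenario = key, approach = a)
  }))
  attr(out, "true_value") <- true_value
  if (keep_estimates) attr(out, "estimates") <- estimates
  rownames(out) <- NULL
  out
}

#' Run the scenario grid
#'
#' Maps [run_scenario()] over a grid, optionally checkpointing each
#' scenario's summary as CSV so an interrupted run can resume (a scenario
#' whose checkpoint file exists is loaded instead of re-run). Replications
#' are independent given their derived seeds, so results do not depend on
#' execution order.
#'
#' @param grid a data.frame as from [scenario_grid()] (or a subset).
#' @param n_reps,approaches,seed,m,cycles passed to [run_scenario()].
#' @param checkpoint_dir optional directory for per-scenario CSVs.
#' @return combined performance data.frame, one row per scenario by
#'   approach.
#' @export
run_grid <- function(grid, n_reps, approaches = c("complete-data", "CCA", "IPW-only"),
                     seed = 1L, m = 50, cycles = 10, checkpoint_dir = NULL) {
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sc <- grid[i, , drop = FALSE]
    ck <- if (!is.null(checkpoint_dir)) {
      file.path(checkpoint_dir, paste0(sc$scenario, ".csv"))
    }
    if (!is.null(ck) && file.exists(ck)) {
      out[[i]] <- utils::read.csv(ck)
      next
    }
    res <- run_scenario(sc,
      n_reps = n_reps, approaches = approaches,
      seed = seed, m = m, cycles = cycles
    )
    if (!is.null(ck)) {
      dir.create(dirname(ck), recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(res, ck, row.names = FALSE)
    }
    out[[i]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
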