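# Multiple imputation by fully conditional specification (FCS) with proper
# (posterior-draw) univariate models: logistic for binary variables,
# ordinal logistic for ordered three-level variables, linear for
# continuous. This engine is the imputation stage shared by the
# MI-IPW-Sub, MI-IPW-Int and MI-only analysis approaches.

#' Imputation specification
#'
#' @param m number of imputations (>= 2; the study default is 50).
#' @param cycles FCS sweeps per imputation (default 10 burn-in sweeps).
#' @param scope `"subset"` (impute within the case-cohort subset only, so
#'   exposure values missing by design never enter the imputation problem)
#'   or `"full"` (impute the whole cohort, including the by-design missing
#'   exposure).
#' @param seed integer seed; imputation is deterministic given the seed.
#' @param predictors optional named list overriding the predictor set of a
#'   given incomplete variable (default: all other analysis and auxiliary
#'   variables, always including the outcome — the outcome's inclusion is
#'   what makes the unweighted imputation models compatible with the
#'   weighted analysis, because the sampling weights are constant within
#'   outcome strata). Overrides are an escape hatch for diagnostics;
#'   default sets always contain the outcome.
#' @param models optional named character vector overriding the model type
#'   (`"logistic"`, `"ordinal"`, `"linear"`) for a variable.
#' @return a `cc_imputation_spec` list.
#' @export
imputation_spec <- function(m = 50, cycles = 10, scope = c("subset", "full"),
                            seed = NULL, predictors = NULL, models = NULL) {
  scope <- match.arg(scope)
  if (m < 2) stop("m must be >= 2")
  if (cycles < 1) stop("cycles must be >= 1")
  structure(
    list(
      m = as.integer(m), cycles = as.integer(cycles), scope = scope,
      seed = seed, predictors = predictors, models = models
    ),
    class = "cc_imputation_spec"
  )
}

# default model type per study variable
.cc_default_models <- c(
  VDI = "logistic", PetOwn = "logistic", AnteVD = "logistic",
  FamHx = "logistic", Eth = "logistic", FoodAllergy = "logistic",
  NSib = "ordinal", SEIFA = "ordinal", MAge = "linear"
)

# Expand predictor names into a design matrix with intercept; three-level
# variables enter as two indicator columns.
.impute_design <- function(dat, preds) {
  cols <- list(rep(1, nrow(dat)))
  nms <- "(Intercept)"
  for (p in preds) {
    v <- dat[[p]]
    if (p %in% c("NSib", "SEIFA")) {
      cols <- c(cols, list(as.numeric(v == 1), as.numeric(v == 2)))
      nms <- c(nms, paste0(p, c("1", "2")))
    } else {
      cols <- c(cols, list(as.numeric(v)))
      nms <- c(nms, p)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- nms
  X
}

# Draw imputations for one variable given the currently completed data.
.impute_one <- function(dat, v, miss, preds, type) {
  X <- .impute_design(dat, preds)
  obs <- !miss
  yobs <- dat[[v]][obs]
  if (type == "logistic") {
    fit <- .fit_logistic_safe(X[obs, , drop = FALSE], yobs,
      context = paste("imputation model for", v)
    )
    # under the separation fallback the large-sample normal posterior is
    # invalid (information is near-singular in the separated direction);
    # use the penalized estimate directly
    b <- if (fit$penalized) fit$coef else .draw_coef(fit)
    p <- stats::plogis(drop(X[miss, , drop = FALSE] %*% b))
    stats::rbinom(sum(miss), 1, p)
  } else if (type == "linear") {
    Xo <- X[obs, , drop = FALSE]
    qr_x <- qr(Xo)
    if (qr_x$rank < ncol(Xo)) stop("rank-deficient linear imputation model for ", v)
    bhat <- qr.coef(qr_x, yobs)
    res <- yobs - drop(Xo %*% bhat)
    df <- length(yobs) - ncol(Xo)
    sigma2 <- sum(res^2) / stats::rchisq(1, df)
    XtXinv <- chol2inv(qr.R(qr_x))
    b <- bhat + drop(t(chol(XtXinv)) %*% stats::rnorm(ncol(Xo))) * sqrt(sigma2)
    drop(X[miss, , drop = FALSE] %*% b) +
      stats::rnorm(sum(miss), 0, sqrt(sigma2))
  } else { # ordinal
    .impute_ordinal(X, dat[[v]], miss)
  }
}

.impute_ordinal <- function(X, y, miss) {
  obs <- !miss
  yf <- factor(y[obs], levels = sort(unique(y[obs])), ordered = TRUE)
  Xo <- X[obs, -1, drop = FALSE] # polr supplies its own cutpoints
  fit <- tryCatch(
    MASS::polr(yf ~ Xo, Hess = TRUE, method = "logistic"),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(fit) || nlevels(yf) < 2) {
    # degenerate fit: fall back to marginal draws from the observed values
    return(sample(y[obs], sum(miss), replace = TRUE))
  }
  co <- c(fit$coefficients, fit$zeta)
  V <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  if (is.null(V) || any(!is.finite(V))) {
    return(sample(y[obs], sum(miss), replace = TRUE))
  }
  dr <- .draw_coef(list(coef = co, cov = V))
  k <- length(fit$coefficients)
  beta <- dr[seq_len(k)]
  zeta <- dr[k + seq_along(fit$zeta)]
  eta <- drop(X[miss, -1, drop = FALSE] %*% beta)
  lev <- as.numeric(levels(yf))
  cum <- vapply(zeta, function(z) stats::plogis(z - eta), numeric(sum(miss)))
  cum <- matrix(cum, nrow = sum(miss))
  u <- stats::runif(sum(miss))
  idx <- rowSums(u > cum) + 1
  lev[idx]
}

#' Multiply impute an incomplete dataset
#'
#' For each of `m` imputations: missing cells are initialized by random
#' draws from each variable's observed values; then `cycles` sweeps are
#' made over the incomplete variables in ascending order of missingness
#' count (ties by column order). Each sweep refits the variable's
#' univariate model to the currently completed data, draws model
#' parameters from their approximate large-sample posterior (normal around
#' the MLE; the linear model also draws its residual variance from a
#' scaled inverse-chi-square), and draws the missing values from the model
#' at the drawn parameters — "proper" imputation, so that between-imputation
#' variability reflects parameter uncertainty.
#'
#' @param data a data.frame view (e.g. from [scope_view()]) containing the
#'   study variables; the outcome must be fully observed and every
#'   incomplete variable must be observed on at least one record.
#' @param spec an [imputation_spec()].
#' @return a `cc_imputation_set`: list with `imputations` (list of `m`
#'   completed data.frames), `m`, `spec`, and per-variable missing counts
#'   `n_missing`. Observed cells are identical across copies.
#' @export
impute <- function(data, spec) {
  if (!inherits(spec, "cc_imputation_spec")) stop("spec must be an imputation_spec()")
  dat0 <- as.data.frame(data)
  vars <- intersect(.cc_all_vars, names(dat0))
  if (anyNA(dat0$FoodAllergy)) stop("outcome must be fully observed")
  nmiss <- vapply(dat0[vars], function(x) sum(is.na(x)), integer(1))
  incomplete <- names(nmiss)[nmiss > 0]
  for (v in incomplete) {
    if (nmiss[[v]] == nrow(dat0)) stop("variable ", v, " is 100% missing")
  }
  # visit order: ascending missingness, ties by column order
  incomplete <- incomplete[order(nmiss[incomplete])]
  models <- .cc_default_models
  if (!is.null(spec$models)) models[names(spec$models)] <- spec$models
  preds <- lapply(incomplete, function(v) {
    if (!is.null(spec$predictors) && v %in% names(spec$predictors)) {
      spec$predictors[[v]]
    } else {
      setdiff(vars, v)
    }
  })
  names(preds) <- incomplete
  missmat <- lapply(dat0[incomplete], is.na)

  if (!is.null(spec$seed)) set.seed(spec$seed)
  imputations <- vector("list", spec$m)
  for (k in seq_len(spec$m)) {
    dat <- dat0
    for (v in incomplete) {
      mi <- missmat[[v]]
      dat[[v]][mi] <- sample(dat0[[v]][!mi], sum(mi), replace = TRUE)
    }
    if (length(incomplete)) {
      for (cy in seq_len(spec$cycles)) {
        for (v in incomplete) {
          dat[[v]][missmat[[v]]] <- .impute_one(
            dat, v, missmat[[v]], preds[[v]], models[[v]]
          )
        }
      }
    }
    imputations[[k]] <- dat
  }
  structure(
    list(
      imputations = imputations, m = spec$m, spec = spec,
      n_missing = nmiss[nmiss > 0]
    ),
    class = "cc_imputation_set"
  )
}

#' @export
print.cc_imputation_set <- function(x, ...) {
  cat("<cc_imputation_set> m =", x$m, "imputations of", nrow(x$imputations[[1]]), "records\n")
  if (length(x$n_missing)) {
    cat(
      "  imputed cells:",
      paste0(names(x$n_missing), "=", x$n_missing, collapse = ", "), "\n"
    )
  }
  invisible(x)
}

#' Scope view of a cohort for imputation
#'
#' `"subset"` exposes only subset records, so exposure values that are
#' missing by design never enter the imputation problem and the exposure's
#' missing fraction equals the unintended-only rate; `"full"` exposes every
#' record, so the exposure carries both intended and unintended missingness
#' to be imputed.
#'
#' @param cohort a `cc_cohort` with the subset defined.
#' @param scope `"subset"` or `"full"`.
#' @return a data.frame view with the study variables plus `id`,
#'   `is_case`, `in_subset`.
#' @export
scope_view <- function(cohort, scope = c("subset", "full")) {
  scope <- match.arg(scope)
  if (anyNA(cohort$in_subset)) stop("subset must be defined before taking a scope view")
  dat <- as.data.frame(cohort)[, c("id", .cc_all_vars, "is_case", "in_subset")]
  if (scope == "subset") dat <- dat[dat$in_subset, , drop = FALSE]
  rownames(dat) <- NULL
  dat
}

#' Export an imputation set as stacked long-format CSV
#'
#' One block of rows per imputation, with an `.imp` index column (the
#' conventional stacked layout).
#'
#' @param imp a `cc_imputation_set`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_imputation_csv <- function(imp, path) {
  long <- do.call(rbind, lapply(seq_len(imp$m), function(k) {
    cbind(.imp = k, imp$imputations[[k]])
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
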