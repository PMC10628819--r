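# Model development: bootstrap replication, within-replicate random-forest
# imputation, fractional-polynomial transform choice, backwards selection,
# parameter-wise shrinkage, and aggregation by bootstrap inclusion fraction.

# Candidate predictor universe with fixed scale divisors. Cortisol
# baselines are scaled by 100 and the previous 30-minute cortisol by 1000
# (the scales of the published formulas); the remaining candidates use
# divisors that put them on order-1 scales.
candidate_scales <- c(new_baseline_cortisol = 100,
                      prev_baseline_cortisol = 100,
                      prev_cortisol_30 = 1000,
                      days_between = 100,
                      new_baseline_acth = 10,
                      prev_baseline_acth = 10,
                      new_ratio = 10,
                      prev_ratio = 10)

#' Candidate variable sets
#'
#' The full candidate set comprises the previous test's baseline cortisol,
#' baseline ACTH and 30-minute cortisol, the days between tests, the new
#' test's baseline cortisol and ACTH, and both cortisol/ACTH ratios. Since
#' baseline ACTH measurement is not universal practice, \code{acth =
#' FALSE} drops the ACTH values and ratios.
#'
#' @param acth Include ACTH-based candidates?
#' @return Character vector of candidate variable names.
#' @export
candidate_variables <- function(acth = TRUE) {
  all <- names(candidate_scales)
  if (acth) all else setdiff(all, c("new_baseline_acth",
                                    "prev_baseline_acth",
                                    "new_ratio", "prev_ratio"))
}

#' Model-development configuration
#'
#' @param n_bootstrap Number of bootstrap replicates of the development
#'   data (5000 for a full run; reduce for simulation studies).
#' @param alpha Significance level for backwards selection.
#' @param bif_threshold Bootstrap inclusion fraction at or above which a
#'   candidate enters the final model.
#' @param powers Admissible FP1 powers.
#' @param candidates Candidate variable names.
#' @param seed Master seed; replicate seeds are derived from it by a
#'   counter scheme, so results are independent of execution order.
#' @param impute_trees,impute_iterations Random-forest imputation settings.
#' @param shrinkage_folds Folds for cross-validation-calibration shrinkage.
#' @return A validated list of class \code{develop_config}.
#' @export
develop_config <- function(n_bootstrap = 5000, alpha = 0.05,
                           bif_threshold = 0.9, powers = fp_powers(),
                           candidates = candidate_variables(), seed = 1,
                           impute_trees = 100, impute_iterations = 2,
                           shrinkage_folds = 10) {
  if (!is_count(n_bootstrap) || n_bootstrap < 1)
    stop_config("n_bootstrap", "must be >= 1")
  if (alpha <= 0 || alpha > 1) stop_config("alpha", "must be in (0, 1]")
  if (bif_threshold <= 0 || bif_threshold > 1)
    stop_config("bif_threshold", "must be in (0, 1]")
  if (!all(powers %in% fp_powers()))
    stop_config("powers", "must be a subset of fp_powers()")
  unknown <- setdiff(candidates, names(candidate_scales))
  if (length(unknown))
    stop_config("candidates", paste("unknown variable(s):",
                                    paste(unknown, collapse = ", ")))
  if (!length(candidates)) stop_config("candidates", "must be non-empty")
  structure(list(n_bootstrap = n_bootstrap, alpha = alpha,
                 bif_threshold = bif_threshold, powers = powers,
                 candidates = candidates, seed = seed,
                 impute_trees = impute_trees,
                 impute_iterations = impute_iterations,
                 shrinkage_folds = shrinkage_folds),
            class = "develop_config")
}

#' Random-forest imputation of missing covariates
#'
#' Imputes missing ACTH values (the only covariates missing by design)
#' with random-forest regression on the complete covariates, iterating in
#' the usual chained fashion. Observed values are never altered; ratio
#' columns are recomputed from the imputed ACTH rather than imputed
#' directly. Deterministic given the seed.
#'
#' @param table Cohort data frame.
#' @param seed RNG seed.
#' @param trees Trees per forest.
#' @param iterations Imputation sweeps over the incomplete variables.
#' @param variables Imputable columns.
#' @return The table with no remaining missing values in
#'   \code{variables}.
#' @export
impute_random_forest <- function(table, seed = 1, trees = 100,
                                 iterations = 2,
                                 variables = c("prev_baseline_acth",
                                               "new_baseline_acth")) {
  variables <- intersect(variables, names(table))
  todo <- variables[vapply(variables, function(v) anyNA(table[[v]]),
                           logical(1))]
  if (!length(todo)) return(add_derived_columns(table))
  for (v in todo)
    if (all(is.na(table[[v]])))
      stop("cannot impute '", v, "': no observed values", call. = FALSE)
  predictors <- intersect(c("prev_baseline_cortisol", "prev_cortisol_30",
                            "new_baseline_cortisol", "new_cortisol_30",
                            "days_between"), names(table))
  work <- table
  # initialise with medians, then refine by chained forests
  for (v in todo) {
    na <- is.na(work[[v]])
    work[[v]][na] <- stats::median(work[[v]], na.rm = TRUE)
  }
  for (it in seq_len(iterations)) {
    for (k in seq_along(todo)) {
      v <- todo[k]
      na <- is.na(table[[v]])
      covars <- c(predictors, setdiff(todo, v))
      df <- work[, c(v, covars)]
      rf <- ranger::ranger(
        stats::as.formula(paste(v, "~ .")), data = df[!na, ],
        num.trees = trees, num.threads = 1,
        seed = derive_seed(seed, it * 131 + k))
      work[[v]][na] <- stats::predict(rf, df[na, ],
                                      num.threads = 1)$predictions
    }
  }
  add_derived_columns(work)
}

# Design matrix (with intercept) for a set of terms on a table.
fp_design <- function(table, variables, scale_divisors, powers) {
  m <- vapply(variables, function(v)
    fp_transform(table[[v]], scale_divisors[[v]], powers[[v]]),
    numeric(nrow(table)))
  if (is.null(dim(m))) m <- matrix(m, nrow = nrow(table))
  colnames(m) <- variables
  cbind(`(Intercept)` = 1, m)
}

# Coefficients and p-values of an OLS fit, robust to numerically perfect
# fits: when the residual sum of squares is negligible relative to the
# outcome's total sum of squares, t statistics are meaningless, so each
# variable's p-value is replaced by a drop-one RSS comparison (0 if its
# removal destroys the fit, 1 otherwise).
ols_pvalues <- function(X, y) {
  qr_ <- qr(X)
  if (qr_$rank < ncol(X)) {
    drop <- colnames(X)[qr_$pivot[(qr_$rank + 1):ncol(X)]]
    stop("singular fit; collinear term(s): ",
         paste(drop, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  coefs <- fit$coefficients
  df <- nrow(X) - ncol(X)
  if (rss > 1e-12 * tss && df > 0) {
    sigma2 <- rss / df
    XtXinv <- chol2inv(qr.R(qr_))
    se <- sqrt(diag(XtXinv) * sigma2)
    p <- 2 * stats::pt(abs(coefs / se), df, lower.tail = FALSE)
  } else {
    # degenerate (essentially perfect) fit
    p <- vapply(seq_len(ncol(X)), function(j) {
      if (ncol(X) == 1L) return(0)
      rss_j <- sum(stats::lm.fit(X[, -j, drop = FALSE], y)$residuals^2)
      if (rss_j - rss > 1e-10 * tss) 0 else 1
    }, numeric(1))
    se <- rep(NA_real_, ncol(X))
  }
  list(coefficients = coefs, p = stats::setNames(p, colnames(X)),
       se = stats::setNames(se, colnames(X)), rss = rss,
       fitted = fit$fitted.values)
}

#' Backwards selection of fractional-polynomial terms
#'
#' Starting from all candidate terms (with previously chosen powers),
#' repeatedly removes the term with the largest p-value while that
#' p-value exceeds \code{alpha}, refitting after each removal. May return
#' an intercept-only fit.
#'
#' @param table Complete-case data frame.
#' @param terms Data frame with columns \code{variable},
#'   \code{scale_divisor}, \code{power}.
#' @param alpha Exit significance level.
#' @param outcome Outcome column name.
#' @return List with the surviving \code{terms} (plus \code{coefficient},
#'   \code{p_value}, \code{standard_error}), \code{intercept},
#'   \code{sigma} and \code{fitted}.
#' @export
fit_backwards <- function(table, terms, alpha = 0.05,
                          outcome = "new_cortisol_30") {
  y <- table[[outcome]]
  keep <- terms
  repeat {
    X <- fp_design(table, keep$variable,
                   stats::setNames(keep$scale_divisor, keep$variable),
                   stats::setNames(keep$power, keep$variable))
    fit <- ols_pvalues(X, y)
    if (nrow(keep) == 0L) break
    pvar <- fit$p[keep$variable]
    worst <- which.max(pvar)
    if (pvar[worst] <= alpha) break
    keep <- keep[-worst, , drop = FALSE]
  }
  keep$coefficient <- if (nrow(keep)) unname(fit$coefficients[keep$variable])
                      else numeric(0)
  keep$p_value <- if (nrow(keep)) unname(fit$p[keep$variable])
                  else numeric(0)
  keep$standard_error <- if (nrow(keep)) unname(fit$se[keep$variable])
                         else numeric(0)
  n <- nrow(table); k <- nrow(keep) + 1L
  list(terms = keep,
       intercept = unname(fit$coefficients["(Intercept)"]),
       sigma = sqrt(fit$rss / max(n - k, 1L)),
       fitted = fit$fitted)
}

#' Parameter-wise shrinkage factors
#'
#' Estimates a multiplicative optimism correction per regression term by
#' K-fold cross-validation calibration: the model is refitted on each
#' training fold, per-term contributions (coefficient times transformed
#' covariate) are computed for the held-out fold, and the out-of-fold
#' outcomes are regressed jointly on those contributions. The calibration
#' slopes are the shrinkage factors; the intercept is re-estimated so
#' that shrunken predictions are mean-unbiased on the data.
#'
#' @param fit Result of \code{\link{fit_backwards}} with >= 1 term.
#' @param table The data the model was fitted on.
#' @param folds Number of folds (must not exceed the row count).
#' @param seed RNG seed for fold assignment.
#' @param outcome Outcome column name.
#' @return List with \code{factors} (named per variable) and the
#'   re-estimated \code{intercept}.
#' @export
parameterwise_shrinkage <- function(fit, table, folds = 10, seed = 1,
                                    outcome = "new_cortisol_30") {
  tm <- fit$terms
  if (nrow(tm) == 0L) stop("model has no terms to shrink", call. = FALSE)
  n <- nrow(table)
  if (folds > n) stop_config("folds", "must not exceed the row count")
  y <- table[[outcome]]
  sdv <- stats::setNames(tm$scale_divisor, tm$variable)
  pw <- stats::setNames(tm$power, tm$variable)
  X <- fp_design(table, tm$variable, sdv, pw)
  fold_id <- local_seed(seed, sample(rep_len(seq_len(folds), n)))
  contrib <- matrix(NA_real_, n, nrow(tm),
                    dimnames = list(NULL, tm$variable))
  for (f in seq_len(folds)) {
    test <- fold_id == f
    b <- stats::lm.fit(X[!test, , drop = FALSE], y[!test])$coefficients
    contrib[test, ] <- sweep(X[test, -1, drop = FALSE], 2,
                             b[tm$variable], `*`)
  }
  cal <- stats::lm.fit(cbind(1, contrib), y)$coefficients
  factors <- stats::setNames(cal[-1], tm$variable)
  shrunk <- tm$coefficient * factors
  intercept <- mean(y) - sum(shrunk * colMeans(X[, -1, drop = FALSE]))
  list(factors = factors, intercept = unname(intercept))
}

# One bootstrap replicate of the development procedure.
develop_replicate <- function(data, config, b, outcome) {
  rep_seed <- derive_seed(config$seed, b)
  idx <- local_seed(rep_seed, sample(nrow(data), replace = TRUE))
  rep_data <- data[idx, , drop = FALSE]
  if (anyNA(rep_data[, config$candidates, drop = FALSE]))
    rep_data <- impute_random_forest(rep_data,
                                     seed = derive_seed(rep_seed, 1L),
                                     trees = config$impute_trees,
                                     iterations = config$impute_iterations)
  y <- rep_data[[outcome]]
  sdv <- candidate_scales[config$candidates]
  powers <- select_fp_powers_adjusted(y, rep_data, config$candidates,
                                      sdv, config$powers)
  terms <- data.frame(variable = config$candidates,
                      scale_divisor = unname(sdv[config$candidates]),
                      power = unname(powers[config$candidates]),
                      stringsAsFactors = FALSE)
  fit <- fit_backwards(rep_data, terms, config$alpha, outcome)
  if (nrow(fit$terms)) {
    sh <- parameterwise_shrinkage(fit, rep_data,
                                  folds = config$shrinkage_folds,
                                  seed = derive_seed(rep_seed, 2L),
                                  outcome = outcome)
    shrunk_int <- sh$intercept
    factors <- sh$factors
  } else {
    shrunk_int <- fit$intercept
    factors <- numeric(0)
  }
  tm <- fit$terms
  if (nrow(tm)) {
    data.frame(replicate = b, variable = tm$variable, power = tm$power,
               raw_coefficient = tm$coefficient,
               shrinkage_factor = unname(factors[tm$variable]),
               shrunken_coefficient = tm$coefficient *
                 unname(factors[tm$variable]),
               p_value = tm$p_value,
               raw_intercept = fit$intercept,
               shrunken_intercept = shrunk_int,
               stringsAsFactors = FALSE)
  } else {
    data.frame(replicate = b, variable = NA_character_, power = NA_real_,
               raw_coefficient = NA_real_, shrinkage_factor = NA_real_,
               shrunken_coefficient = NA_real_, p_value = NA_real_,
               raw_intercept = fit$intercept,
               shrunken_intercept = shrunk_int, stringsAsFactors = FALSE)
  }
}

#' Develop a repeat-AST prediction model
#'
#' The full development procedure: for each bootstrap resample of the
#' data (with replacement, same size), missing ACTH values are imputed by
#' random forest, an FP1 power is chosen per candidate within the
#' multivariable model, backwards selection removes terms with p >
#' \code{alpha}, and the surviving coefficients are shrunken
#' parameter-wise by cross-validation calibration. A candidate enters the
#' final model if its bootstrap inclusion fraction (share of replicates
#' where it survived selection with p <= alpha) reaches
#' \code{bif_threshold}; its final power is the modal selected power, its
#' coefficient the mean shrunken coefficient over replicates selecting
#' that power, and the intercept the mean shrunken intercept over all
#' replicates. The residual SD is the RMSE of the final model on the
#' development data.
#'
#' @param data Cohort data frame (see \code{\link{generate_cohort}} /
#'   \code{\link{read_cohort}}).
#' @param config A \code{\link{develop_config}}.
#' @param outcome Outcome column name, nmol/L.
#' @return An object of class \code{sst_development}: the final
#'   \code{\link{sst_model}}, the per-variable inclusion fractions
#'   (\code{bif}), a shrinkage summary, and the replicate-level log.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_config(n_pairs = 120, seed = 7))
#' dev <- sst_develop(cohort, develop_config(
#'   n_bootstrap = 25, candidates = candidate_variables(acth = FALSE)))
#' print(dev)
#' }
#' @export
sst_develop <- function(data, config = develop_config(),
                        outcome = "new_cortisol_30") {
  stopifnot(inherits(config, "develop_config"))
  missing_cols <- setdiff(c(config$candidates, outcome), names(data))
  if (length(missing_cols))
    stop("data lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(data) < 10 * length(config$candidates))
    warning(sprintf(paste0("only %d rows for %d candidates; fewer than ",
                           "10 events per variable"),
                    nrow(data), length(config$candidates)), call. = FALSE)
  if (anyNA(data[[outcome]]))
    stop("outcome must be observed for every development pair",
         call. = FALSE)

  reps <- vector("list", config$n_bootstrap)
  failures <- 0L
  for (b in seq_len(config$n_bootstrap)) {
    reps[[b]] <- tryCatch(develop_replicate(data, config, b, outcome),
                          error = function(e) {
                            warning(sprintf("replicate %d failed: %s", b,
                                            conditionMessage(e)),
                                    call. = FALSE)
                            NULL
                          })
    if (is.null(reps[[b]])) failures <- failures + 1L
  }
  if (failures > 0.01 * config$n_bootstrap)
    stop(sprintf("%d of %d replicates failed; aborting", failures,
                 config$n_bootstrap), call. = FALSE)
  log <- do.call(rbind, reps)
  n_ok <- config$n_bootstrap - failures

  sel <- log[!is.na(log$variable) & log$p_value <= config$alpha, ]
  bif <- vapply(config$candidates, function(v)
    length(unique(sel$replicate[sel$variable == v])) / n_ok, numeric(1))

  final_vars <- config$candidates[bif >= config$bif_threshold]
  terms <- NULL
  modal_power <- numeric(0)
  for (v in final_vars) {
    rows <- sel[sel$variable == v, ]
    tab <- table(rows$power)
    modal <- as.numeric(names(tab)[which.max(tab)])
    modal_power[v] <- modal
    rows <- rows[rows$power == modal, ]
    terms <- rbind(terms, fp_term(
      v, scale_divisor = unname(candidate_scales[[v]]), power = modal,
      coefficient = mean(rows$shrunken_coefficient),
      shrinkage_factor = mean(rows$shrinkage_factor),
      standard_error = stats::sd(rows$shrunken_coefficient)))
  }
  # Intercepts are only commensurable between replicates that selected
  # every final variable at its final (modal) power; averaging across
  # different transforms of the same covariate would mix incompatible
  # parameterisations. When power choice is stable (the usual case) this
  # is simply the mean over all replicates.
  rep_ids <- unique(log$replicate)
  compatible <- vapply(rep_ids, function(r) {
    rows <- sel[sel$replicate == r, ]
    all(vapply(final_vars, function(v)
      any(rows$variable == v & rows$power == modal_power[v]),
      logical(1)))
  }, logical(1))
  intercept <- if (any(compatible))
    mean(log$shrunken_intercept[!duplicated(log$replicate)][compatible])
  else NA_real_

  if (is.null(terms))
    terms <- fp_term("new_baseline_cortisol", 100, 1,
                     coefficient = 0)[0, ]   # empty term frame

  # residual SD: RMSE of the final model on the development data
  complete <- stats::complete.cases(data[, c(final_vars, outcome),
                                         drop = FALSE])
  dev_data <- data[complete, , drop = FALSE]
  if (is.na(intercept)) {
    # no replicate selected the full final parameterisation: recalibrate
    # the intercept on the development data so predictions are
    # mean-unbiased
    prov0 <- sst_model("developed", 0, terms, residual_sd = NA_real_)
    intercept <- mean(dev_data[[outcome]]) -
      mean(sst_linear_predictor(prov0, dev_data, warn = FALSE))
  }
  prov <- sst_model("developed", intercept, terms, residual_sd = NA_real_)
  fitted <- sst_linear_predictor(prov, dev_data, warn = FALSE)
  resid <- dev_data[[outcome]] - fitted
  rmse <- sqrt(mean(resid^2))
  final <- sst_model("developed", intercept, terms, residual_sd = rmse)

  structure(list(final = final, bif = bif, log = log,
                 config = config, n = nrow(data), n_failures = failures,
                 fitted = fitted, residuals = resid,
                 observed = dev_data[[outcome]],
                 call = match.call()),
            class = "sst_development")
}

#' @export
print.sst_development <- function(x, ...) {
  cat(sprintf("Bootstrap model development (%d replicates, n = %d)\n\n",
              x$config$n_bootstrap, x$n))
  print(x$final)
  cat("\nBootstrap inclusion fractions (retention at >= ",
      x$config$bif_threshold, "):\n", sep = "")
  print(round(sort(x$bif, decreasing = TRUE), 3))
  invisible(x)
}

#' @export
summary.sst_development <- function(object, ...) {
  cs <- calibration_stats(object$observed, object$fitted)
  structure(list(model = summary(object$final), bif = object$bif,
                 development_fit = cs, n = object$n,
                 n_failures = object$n_failures),
            class = "summary.sst_development")
}

#' @export
print.summary.sst_development <- function(x, ...) {
  print(x$model)
  cat("\nBootstrap inclusion fractions:\n")
  print(round(sort(x$bif, decreasing = TRUE), 3))
  cat(sprintf(paste0("\nApparent fit on development data (n = %d): ",
                     "R^2 %.3f, RMSE %.1f nmol/L\n"),
              x$n, x$development_fit$r2, x$development_fit$rmse))
  if (x$n_failures > 0)
    cat(sprintf("%d replicate(s) failed\n", x$n_failures))
  invisible(x)
}

#' @export
coef.sst_development <- function(object, ...) coef(object$final)

#' @export
predict.sst_development <- function(object, newdata, ...)
  predict(object$final, newdata, ...)

#' @export
residuals.sst_development <- function(object, ...) object$residuals

#' @export
fitted.sst_development <- function(object, ...) object$fitted

#' @export
simulate.sst_development <- function(object, nsim = 1, seed = NULL,
                                     newdata, ...)
  simulate(object$final, nsim = nsim, seed = seed, newdata = newdata, ...)

#' Plot a developed model
#'
#' Two base-graphics panels: bootstrap inclusion fractions per candidate,
#' and observed versus fitted 30-minute cortisol on the development data
#' with the identity line and the pass threshold.
#'
#' @param x An \code{sst_development}.
#' @param which Panels to draw.
#' @param ... Passed to the underlying plot calls.
#' @export
plot.sst_development <- function(x, which = c("bif", "calibration"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  if ("bif" %in% which) {
    op <- graphics::par(mar = c(9, 4, 2, 1)); on.exit(graphics::par(op))
    graphics::barplot(sort(x$bif, decreasing = TRUE), las = 2,
                      ylab = "bootstrap inclusion fraction", ylim = c(0, 1),
                      ...)
    graphics::abline(h = x$config$bif_threshold, lty = 2)
  }
  if ("calibration" %in% which) {
    graphics::plot(x$fitted, x$observed,
                   xlab = "predicted 30-min cortisol (nmol/L)",
                   ylab = "observed 30-min cortisol (nmol/L)", ...)
    graphics::abline(0, 1, lty = 2)
    graphics::abline(h = x$final$pass_threshold,
                     v = x$final$pass_threshold, col = "grey")
  }
  invisible(x)
}
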