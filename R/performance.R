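# Calibration, discrimination and validation statistics.

#' Calibration statistics of continuous predictions
#'
#' @param observed Observed 30-minute cortisol, nmol/L.
#' @param predicted Model predictions, nmol/L (not constant).
#' @return List with \code{r2} (1 - SSE/SST; can be negative on external
#'   data), \code{rmse}, and the calibration \code{slope} and
#'   \code{intercept} from least-squares regression of observed on
#'   predicted (ideal 1 and 0; slope < 1 indicates overfitting).
#' @export
calibration_stats <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("'observed' and 'predicted' must have equal length", call. = FALSE)
  ok <- stats::complete.cases(observed, predicted)
  observed <- observed[ok]; predicted <- predicted[ok]
  if (length(observed) < 3L)
    stop("need at least 3 observation pairs", call. = FALSE)
  if (stats::sd(predicted) == 0)
    stop("calibration slope undefined: predictions are constant",
         call. = FALSE)
  res <- observed - predicted
  sse <- sum(res^2)
  sst <- sum((observed - mean(observed))^2)
  b <- stats::lm.fit(cbind(1, predicted), observed)$coefficients
  list(r2 = 1 - sse / sst, rmse = sqrt(mean(res^2)),
       slope = unname(b[2]), intercept = unname(b[1]),
       n = length(observed))
}

#' Discrimination (AUC) at the pass threshold
#'
#' Dichotomises the observed outcome at the pass threshold (observed >=
#' threshold is a pass) and computes the area under the ROC curve of the
#' continuous predictions as the Mann-Whitney concordance probability,
#' ties counting one half.
#'
#' @param observed Observed 30-minute cortisol, nmol/L.
#' @param predicted Continuous predictions, nmol/L.
#' @param threshold Pass threshold, nmol/L.
#' @return AUC in [0, 1].
#' @export
auc_at_threshold <- function(observed, predicted, threshold = 430) {
  ok <- stats::complete.cases(observed, predicted)
  observed <- observed[ok]; predicted <- predicted[ok]
  pass <- observed >= threshold
  n1 <- sum(pass); n0 <- sum(!pass)
  if (n1 == 0L || n0 == 0L)
    stop("discrimination undefined: only one outcome class at threshold ",
         threshold, call. = FALSE)
  r <- rank(predicted)          # midranks handle ties as 1/2
  (sum(r[pass]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Percentile bootstrap confidence interval
#'
#' @param statistic Function taking a resampled data frame (or vector)
#'   and returning a scalar.
#' @param data Data frame or vector resampled with replacement.
#' @param n_reps Bootstrap replicates.
#' @param seed RNG seed (interval is deterministic given the seed).
#' @param level Coverage.
#' @return Numeric \code{c(lower, upper)}.
#' @export
bootstrap_ci <- function(statistic, data, n_reps = 2000, seed = 1,
                         level = 0.95) {
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  take <- if (is.data.frame(data))
    function(i) data[i, , drop = FALSE] else function(i) data[i]
  stats_ <- local_seed(seed, vapply(seq_len(n_reps), function(r) {
    i <- sample(n, replace = TRUE)
    tryCatch(as.numeric(statistic(take(i))), error = function(e) NA_real_)
  }, numeric(1)))
  if (mean(is.na(stats_)) > 0.05)
    stop("statistic failed on more than 5% of bootstrap resamples",
         call. = FALSE)
  a <- (1 - level) / 2
  unname(stats::quantile(stats_, c(a, 1 - a), na.rm = TRUE))
}

#' Evaluate a model on a cohort
#'
#' Computes the full performance report -- R-squared, RMSE, calibration
#' slope and intercept, and AUC at the pass threshold -- each with a
#' percentile-bootstrap 95% CI over resampled (observed, predicted)
#' pairs.
#'
#' @param model An \code{sst_model} (or \code{sst_development}).
#' @param data Cohort data frame with the model covariates and observed
#'   outcome.
#' @param n_boot Bootstrap replicates for the CIs.
#' @param seed RNG seed.
#' @param outcome Outcome column name.
#' @return An object of class \code{sst_performance}.
#' @export
evaluate_model <- function(model, data, n_boot = 2000, seed = 1,
                           outcome = "new_cortisol_30") {
  if (inherits(model, "sst_development")) model <- model$final
  stopifnot(inherits(model, "sst_model"))
  pred <- sst_linear_predictor(model, data, warn = FALSE)
  obs <- data[[outcome]]
  ok <- stats::complete.cases(obs, pred)
  df <- data.frame(obs = obs[ok], pred = pred[ok])
  point <- calibration_stats(df$obs, df$pred)
  point$auc <- auc_at_threshold(df$obs, df$pred, model$pass_threshold)
  cis <- list(
    r2    = bootstrap_ci(function(d) calibration_stats(d$obs, d$pred)$r2,
                         df, n_boot, derive_seed(seed, 1L)),
    rmse  = bootstrap_ci(function(d) calibration_stats(d$obs, d$pred)$rmse,
                         df, n_boot, derive_seed(seed, 2L)),
    slope = bootstrap_ci(function(d) calibration_stats(d$obs, d$pred)$slope,
                         df, n_boot, derive_seed(seed, 3L)),
    intercept = bootstrap_ci(
      function(d) calibration_stats(d$obs, d$pred)$intercept,
      df, n_boot, derive_seed(seed, 4L)),
    auc = bootstrap_ci(
      function(d) auc_at_threshold(d$obs, d$pred, model$pass_threshold),
      df, n_boot, derive_seed(seed, 5L)))
  structure(list(model_name = model$name, point = point, ci = cis,
                 n = nrow(df), pass_threshold = model$pass_threshold),
            class = "sst_performance")
}

#' @export
print.sst_performance <- function(x, ...) {
  cat(sprintf("Performance of '%s' (n = %d, pass threshold %g nmol/L)\n",
              x$model_name, x$n, x$pass_threshold))
  row <- function(label, v, ci, digits = 3)
    cat(sprintf("  %-22s %8.*f  (95%% CI %.*f to %.*f)\n", label, digits,
                v, digits, ci[1], digits, ci[2]))
  row("R-squared", x$point$r2, x$ci$r2)
  row("RMSE (nmol/L)", x$point$rmse, x$ci$rmse, 1)
  row("Calibration slope", x$point$slope, x$ci$slope)
  row("Calibration intercept", x$point$intercept, x$ci$intercept, 1)
  row("AUC", x$point$auc, x$ci$auc)
  invisible(x)
}

#' Leave-one-group-out cross-validation
#'
#' For each level of a grouping variable (sex, AI type, steroid route or
#' formulation), develops a model on all other groups via
#' \code{\link{sst_develop}} and evaluates it on the held-out group.
#' Groups smaller than \code{min_group} rows are merged into
#' \code{"other"} with a warning.
#'
#' @param data Cohort data frame.
#' @param grouping Grouping column name.
#' @param config \code{\link{develop_config}} used for each development.
#' @param n_boot Bootstrap replicates for per-group CIs.
#' @param min_group Minimum rows per held-out group.
#' @param outcome Outcome column name.
#' @return An object of class \code{sst_grouped_cv}: per-group
#'   performance and the model developed on the remainder.
#' @export
cross_validate_groups <- function(data, grouping, config = develop_config(),
                                  n_boot = 200, min_group = 10,
                                  outcome = "new_cortisol_30") {
  if (!grouping %in% names(data))
    stop("grouping variable '", grouping, "' not present", call. = FALSE)
  g <- as.character(data[[grouping]])
  sizes <- table(g)
  small <- names(sizes)[sizes < min_group]
  if (length(small)) {
    warning("merging small group(s) into 'other': ",
            paste(small, collapse = ", "), call. = FALSE)
    g[g %in% small] <- "other"
  }
  groups <- sort(unique(g))
  if (length(groups) < 2L)
    stop("need at least 2 groups for cross-validation", call. = FALSE)
  res <- lapply(groups, function(grp) {
    held <- g == grp
    dev <- sst_develop(data[!held, , drop = FALSE], config, outcome)
    perf <- evaluate_model(dev$final, data[held, , drop = FALSE],
                           n_boot = n_boot,
                           seed = derive_seed(config$seed, match(grp, groups)),
                           outcome = outcome)
    list(group = grp, n_held_out = sum(held), model = dev$final,
         performance = perf)
  })
  names(res) <- groups
  structure(list(grouping = grouping, groups = res, n = nrow(data)),
            class = "sst_grouped_cv")
}

#' @export
print.sst_grouped_cv <- function(x, ...) {
  cat(sprintf("Leave-one-group-out cross-validation by '%s' (n = %d)\n\n",
              x$grouping, x$n))
  for (r in x$groups) {
    cat(sprintf("held out: %s (n = %d)  R^2 %.3f  RMSE %.1f  AUC %.3f\n",
                r$group, r$n_held_out, r$performance$point$r2,
                r$performance$point$rmse, r$performance$point$auc))
  }
  invisible(x)
}

#' Likelihood-ratio comparison of nested prediction models
#'
#' Compares two nested Gaussian prediction models on the same
#' observations by the likelihood ratio test,
#' \eqn{\chi^2 = n \log(SSE_a / SSE_b)} on
#' \code{params_b - params_a} degrees of freedom, together with the
#' incremental proportion of variance explained.
#'
#' @param observed Observed outcomes.
#' @param predicted_a,predicted_b Predictions of the smaller and the
#'   richer model.
#' @param params_a,params_b Parameter counts (richer model must have
#'   more).
#' @return List with \code{statistic}, \code{df}, \code{p_value} and
#'   \code{delta_r2}.
#' @export
compare_models <- function(observed, predicted_a, predicted_b,
                           params_a, params_b) {
  if (params_b <= params_a)
    stop("models are not nested: 'params_b' must exceed 'params_a'",
         call. = FALSE)
  n <- length(observed)
  sse_a <- sum((observed - predicted_a)^2)
  sse_b <- sum((observed - predicted_b)^2)
  stat <- n * log(sse_a / sse_b)
  df <- params_b - params_a
  sst <- sum((observed - mean(observed))^2)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       delta_r2 = (1 - sse_b / sst) - (1 - sse_a / sst))
}
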