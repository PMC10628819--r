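# Equivocal-range decision policy: predictions below a low threshold are
# acted on as adrenal insufficiency, predictions above a high threshold as
# adequate adrenal function, and only the equivocal range in between
# proceeds to an actual stimulation test. Ties sit in the equivocal range
# (conservative: borderline patients still get tested).

# Candidate thresholds: midpoints between consecutive sorted unique
# predictions, plus sentinels below and above everything. Using midpoints
# avoids the chosen threshold coinciding with an observed prediction.
candidate_thresholds <- function(predicted) {
  u <- sort(unique(predicted))
  c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
}

# Operating characteristics of the pass-detection rule "prediction > t":
# sensitivity(t) = fraction of observed passes predicted above t
# (non-increasing in t); specificity(t) = fraction of observed fails
# predicted at or below t (non-decreasing in t). These are the ROC axes
# at threshold t, with a pass as the positive class.

#' Prediction threshold attaining a target sensitivity
#'
#' Returns the largest prediction threshold \code{t} at which the
#' pass-detection rule \code{prediction > t} still captures at least
#' \code{target} of the observed passes (observed 30-minute cortisol at
#' or above the pass threshold). Predictions below this threshold are
#' safe to act on as adrenal insufficiency: at most \code{1 - target} of
#' true passes fall below it. Taking the largest such \code{t} also
#' maximises the rule's specificity, which is non-decreasing in \code{t}.
#'
#' @param observed Observed 30-minute cortisol, nmol/L.
#' @param predicted Model predictions, nmol/L.
#' @param target Target sensitivity in (0, 1].
#' @param pass_threshold Observed pass threshold, nmol/L.
#' @return The prediction threshold, nmol/L.
#' @export
threshold_for_sensitivity <- function(observed, predicted, target = 0.95,
                                      pass_threshold = 430) {
  stopifnot(target > 0, target <= 1)
  pass <- observed >= pass_threshold
  if (!any(pass) || all(pass))
    stop("both outcome classes are required to set a threshold",
         call. = FALSE)
  cand <- candidate_thresholds(predicted)
  sens <- vapply(cand, function(t) mean(predicted[pass] > t), numeric(1))
  feasible <- sens >= target
  if (!any(feasible))
    stop(sprintf("sensitivity %g not attainable", target), call. = FALSE)
  max(cand[feasible])
}

#' Prediction threshold attaining a target specificity
#'
#' Returns the smallest prediction threshold \code{t} at which the
#' pass-detection rule \code{prediction > t} keeps at least \code{target}
#' of the observed fails at or below it. Predictions above this threshold
#' are safe to act on as adequate adrenal function: at most
#' \code{1 - target} of true fails exceed it. Taking the smallest such
#' \code{t} also maximises the rule's sensitivity, which is
#' non-increasing in \code{t}.
#'
#' @inheritParams threshold_for_sensitivity
#' @param target Target specificity in (0, 1].
#' @return The prediction threshold, nmol/L.
#' @export
threshold_for_specificity <- function(observed, predicted, target = 0.95,
                                      pass_threshold = 430) {
  stopifnot(target > 0, target <= 1)
  pass <- observed >= pass_threshold
  if (!any(pass) || all(pass))
    stop("both outcome classes are required to set a threshold",
         call. = FALSE)
  cand <- candidate_thresholds(predicted)
  spec <- vapply(cand, function(t) mean(predicted[!pass] <= t), numeric(1))
  feasible <- spec >= target
  if (!any(feasible))
    stop(sprintf("specificity %g not attainable", target), call. = FALSE)
  min(cand[feasible])
}

#' Equivocal-range benefit policy
#'
#' Builds the two-threshold policy: the low threshold attains the target
#' sensitivity for diagnosing adrenal insufficiency, the high threshold
#' the target specificity for declaring adequate adrenal function, and
#' predictions in between remain equivocal and proceed to an actual
#' test. Should the two thresholds cross (a highly discriminating model),
#' both collapse to their midpoint and the equivocal range is empty.
#'
#' @inheritParams threshold_for_sensitivity
#' @param sensitivity,specificity Target fractions in (0, 1].
#' @return An object of class \code{benefit_policy}: thresholds, attained
#'   sensitivity/specificity recomputed from them, and the proportion of
#'   tests saved with its low- and high-side components.
#' @export
benefit_policy <- function(observed, predicted, sensitivity = 0.95,
                           specificity = 0.95, pass_threshold = 430) {
  low <- threshold_for_sensitivity(observed, predicted, sensitivity,
                                   pass_threshold)
  high <- threshold_for_specificity(observed, predicted, specificity,
                                    pass_threshold)
  crossed <- low > high
  if (crossed) low <- high <- (low + high) / 2
  pass <- observed >= pass_threshold
  policy <- structure(list(
    low_threshold = low, high_threshold = high,
    sensitivity = mean(predicted[pass] > low),
    specificity = mean(predicted[!pass] <= high),
    saved_low = mean(predicted < low),
    saved_high = mean(predicted > high),
    proportion_saved = mean(predicted < low | predicted > high),
    crossed = crossed,
    pass_threshold = pass_threshold, n = length(observed)),
    class = "benefit_policy")
  policy
}

#' Proportion of stimulation tests saved under a policy
#'
#' The fraction of predictions outside the equivocal range (strictly
#' below the low threshold or strictly above the high one); those
#' patients are acted on directly and never undergo the test. Equals
#' one minus the equivocal fraction exactly.
#'
#' @param predicted Model predictions, nmol/L.
#' @param policy A \code{\link{benefit_policy}} (or anything with
#'   \code{low_threshold} and \code{high_threshold}).
#' @return Fraction in [0, 1].
#' @export
proportion_saved <- function(predicted, policy) {
  if (policy$low_threshold > policy$high_threshold)
    stop("policy thresholds must be ordered", call. = FALSE)
  mean(predicted < policy$low_threshold |
         predicted > policy$high_threshold)
}

# classification used by predict(..., policy = )
classify_prediction <- function(predicted, policy) {
  ifelse(predicted < policy$low_threshold, "insufficient",
         ifelse(predicted > policy$high_threshold, "sufficient",
                "equivocal"))
}

#' Benefit curve over sensitivity/specificity targets
#'
#' Evaluates the equivocal-range policy on a grid of sensitivity and
#' specificity targets, decomposing the proportion of tests saved into
#' the low-side (declared insufficient) and high-side (declared
#' sufficient) contributions. Grid points whose targets are unattainable
#' are skipped with a warning.
#'
#' @inheritParams threshold_for_sensitivity
#' @param sensitivity_grid,specificity_grid Target grids in (0, 1].
#' @return Data frame with one row per (sensitivity, specificity) pair:
#'   targets, thresholds, attained values, and saved proportions.
#' @export
benefit_curve <- function(observed, predicted,
                          sensitivity_grid = seq(0.5, 1, by = 0.05),
                          specificity_grid = seq(0.5, 1, by = 0.05),
                          pass_threshold = 430) {
  stopifnot(all(sensitivity_grid > 0), all(sensitivity_grid <= 1),
            all(specificity_grid > 0), all(specificity_grid <= 1))
  grid <- expand.grid(sens_target = sensitivity_grid,
                      spec_target = specificity_grid)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- tryCatch(
      benefit_policy(observed, predicted, grid$sens_target[i],
                     grid$spec_target[i], pass_threshold),
      error = function(e) {
        warning(sprintf("grid point (%g, %g) skipped: %s",
                        grid$sens_target[i], grid$spec_target[i],
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
    if (is.null(p)) return(NULL)
    data.frame(sens_target = grid$sens_target[i],
               spec_target = grid$spec_target[i],
               low = p$low_threshold, high = p$high_threshold,
               sensitivity = p$sensitivity, specificity = p$specificity,
               saved_low = p$saved_low, saved_high = p$saved_high,
               saved_total = p$proportion_saved)
  })
  do.call(rbind, rows)
}

#' @export
print.benefit_policy <- function(x, ...) {
  cat("Equivocal-range policy (pass threshold",
      x$pass_threshold, "nmol/L)\n")
  cat(sprintf("  equivocal predictions: %.1f to %.1f nmol/L%s\n",
              x$low_threshold, x$high_threshold,
              if (x$crossed) " (targets crossed; range collapsed)" else ""))
  cat(sprintf("  attained sensitivity %.3f, specificity %.3f\n",
              x$sensitivity, x$specificity))
  cat(sprintf("  tests saved: %.1f%% (%.1f%% low side, %.1f%% high side)\n",
              100 * x$proportion_saved, 100 * x$saved_low,
              100 * x$saved_high))
  invisible(x)
}
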