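# fixtures are generated in code; nothing is stored on disk

quick_cohort <- function(n = 200, seed = 1, noise = 73.4, missing = 0) {
  generate_cohort(cohort_config(n_pairs = n, seed = seed,
                                outcome_noise_sd = noise,
                                acth_missing_rate = missing))
}

quick_dev_config <- function(n_bootstrap = 20, seed = 1, ...) {
  develop_config(n_bootstrap = n_bootstrap, seed = seed,
                 candidates = candidate_variables(acth = FALSE), ...)
}

# independent O(n^2) pairwise AUC oracle: mean over all (pass, fail)
# pairs of concordance, ties counting one half
auc_oracle <- function(observed, predicted, threshold = 430) {
  pass <- observed >= threshold
  pp <- predicted[pass]; pf <- predicted[!pass]
  total <- 0
  for (a in pp) total <- total + sum(a > pf) + 0.5 * sum(a == pf)
  total / (length(pp) * length(pf))
}

# closed-form least-squares oracle for the calibration line
ls_oracle <- function(y, x) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# enumeration oracles for the policy thresholds: scan every candidate
# (midpoints of sorted unique predictions plus sentinels), counting
# operating characteristics of the pass-call rule "prediction > t"
# explicitly, and apply the documented selection rule
threshold_oracle <- function(observed, predicted, target, side,
                             pass_threshold = 430) {
  u <- sort(unique(predicted))
  cand <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  pass <- observed >= pass_threshold
  best <- NULL
  for (t in cand) {
    sens <- sum(predicted[pass] > t) / sum(pass)
    spec <- sum(predicted[!pass] <= t) / sum(!pass)
    if (side == "sens" && sens >= target) {
      if (is.null(best) || t > best) best <- t
    }
    if (side == "spec" && spec >= target) {
      if (is.null(best) || t < best) best <- t
    }
  }
  best
}
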