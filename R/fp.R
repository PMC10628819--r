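#' Fractional polynomial (FP1) power set
#'
#' The conventional first-degree fractional-polynomial powers. Power 0
#' denotes the natural logarithm of the scaled variable.
#'
#' @return Numeric vector of the eight admissible powers.
#' @export
fp_powers <- function() c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

#' Fractional polynomial transform
#'
#' Computes \code{(value / scale_divisor) ^ power}, with power 0 meaning
#' \code{log(value / scale_divisor)}. Scaling keeps transformed covariates
#' on a numerically convenient scale (e.g. cortisol in nmol/L divided by
#' 100 before taking the square root).
#'
#' @param value Numeric vector, non-negative. Zero is only admissible for
#'   powers >= 0.5; negative or log powers require strictly positive values.
#' @param scale_divisor Positive scalar divisor applied before the power.
#' @param power One of \code{fp_powers()}.
#' @return Transformed numeric vector.
#' @examples
#' fp_transform(400, 100, 0.5)  # sqrt(4) = 2
#' fp_transform(100, 100, 0)    # ln(1) = 0
#' @export
fp_transform <- function(value, scale_divisor = 1, power = 1) {
  if (!is.numeric(scale_divisor) || length(scale_divisor) != 1L ||
      scale_divisor <= 0)
    stop("'scale_divisor' must be a positive scalar", call. = FALSE)
  if (!power %in% fp_powers())
    stop(sprintf("'power' must be one of {%s}",
                 paste(fp_powers(), collapse = ", ")), call. = FALSE)
  if (any(value < 0, na.rm = TRUE))
    stop("fractional polynomial transforms require non-negative values",
         call. = FALSE)
  if (power < 0.5 && any(value == 0, na.rm = TRUE))
    stop(sprintf("value 0 is not admissible for power %s", power),
         call. = FALSE)
  x <- value / scale_divisor
  if (power == 0) log(x) else x^power
}

# Human-readable label for a transformed term, e.g. "sqrt(x/100)".
fp_label <- function(variable, scale_divisor, power) {
  x <- if (scale_divisor == 1) variable
       else sprintf("%s/%g", variable, scale_divisor)
  if (power == 1) sprintf("(%s)", x)
  else if (power == 0.5) sprintf("sqrt(%s)", x)
  else if (power == 0) sprintf("ln(%s)", x)
  else sprintf("(%s)^%g", x, power)
}

#' Select an FP1 power for a single predictor
#'
#' Chooses the power minimising the residual sum of squares of a
#' univariable linear fit of \code{outcome} on the transformed predictor.
#' Ties (within relative tolerance 1e-8) are broken toward power 1,
#' i.e. toward linearity.
#'
#' @param outcome Numeric outcome vector.
#' @param predictor Numeric predictor vector (non-negative; if zeros are
#'   present the candidate powers are restricted to >= 0.5).
#' @param scale_divisor Divisor applied before transformation.
#' @param powers Candidate powers, a subset of \code{fp_powers()}.
#' @return The selected power (scalar).
#' @export
select_fp_power <- function(outcome, predictor, scale_divisor = 1,
                            powers = fp_powers()) {
  if (length(outcome) != length(predictor))
    stop("'outcome' and 'predictor' must have equal length", call. = FALSE)
  ok <- stats::complete.cases(outcome, predictor)
  outcome <- outcome[ok]; predictor <- predictor[ok]
  if (length(unique(predictor)) < 3L)
    stop("need at least 3 distinct predictor values to select a power",
         call. = FALSE)
  if (any(predictor == 0)) powers <- powers[powers >= 0.5]
  rss <- vapply(powers, function(p) {
    z <- fp_transform(predictor, scale_divisor, p)
    sum(stats::lm.fit(cbind(1, z), outcome)$residuals^2)
  }, numeric(1))
  tied <- powers[rss <= min(rss) * (1 + 1e-8)]
  if (1 %in% tied) 1 else powers[which.min(rss)]
}

# Adjusted (multivariable) FP1 power search: each variable's power is
# chosen to minimise the RSS of the full candidate model holding the other
# variables at their current powers, cycling until stable. Unlike the
# univariable search this recovers generating transforms when covariates
# are correlated.
select_fp_powers_adjusted <- function(y, data, variables, scale_divisors,
                                      powers = fp_powers(), max_cycles = 5L) {
  cur <- stats::setNames(rep(1, length(variables)), variables)
  cols <- lapply(variables, function(v) data[[v]])
  names(cols) <- variables
  admissible <- lapply(cols, function(x)
    if (any(x == 0, na.rm = TRUE)) powers[powers >= 0.5] else powers)
  design <- function(pw) {
    m <- vapply(variables, function(v)
      fp_transform(cols[[v]], scale_divisors[[v]], pw[[v]]),
      numeric(length(y)))
    cbind(1, m)
  }
  rss_of <- function(pw) sum(stats::lm.fit(design(pw), y)$residuals^2)
  for (cycle in seq_len(max_cycles)) {
    changed <- FALSE
    for (v in variables) {
      cand <- admissible[[v]]
      rss <- vapply(cand, function(p) {
        pw <- cur; pw[[v]] <- p; rss_of(pw)
      }, numeric(1))
      tied <- cand[rss <= min(rss) * (1 + 1e-8)]
      best <- if (1 %in% tied) 1 else cand[which.min(rss)]
      if (best != cur[[v]]) { cur[[v]] <- best; changed <- TRUE }
    }
    if (!changed) break
  }
  cur
}
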