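# Synthetic paired short-Synacthen-test cohorts.
#
# Marginals are truncated log-normals moment-matched (after truncation) to
# the configured mean/SD within the configured range; cross-dependence is
# induced through a Gaussian copula on the latent normal scale; the
# outcome (new 30-minute cortisol) is generated from the published
# previous-AST model's linear predictor plus Gaussian noise, clipped at 0.

cohort_columns <- c("patient_id", "prev_datetime", "prev_baseline_cortisol",
                    "prev_baseline_acth", "prev_cortisol_30", "new_datetime",
                    "new_baseline_cortisol", "new_baseline_acth",
                    "new_cortisol_30", "sex", "ai_type", "steroid_route",
                    "steroid_formulation")

#' Synthetic cohort configuration
#'
#' Builds a cohort configuration from the packaged default document
#' (development-cohort marginal statistics and subgroup mix), with any
#' field overridable. Defaults: 258 pairs, copula correlation 0.7 among
#' cortisol values, outcome noise SD 73.4 nmol/L (the development RMSE of
#' the generating model), ACTH missingness 8.1%.
#'
#' @param n_pairs Number of (previous test, new test) pairs to generate.
#' @param seed RNG seed; generation is bit-reproducible given the seed.
#' @param outcome_noise_sd Residual SD of the generated outcome, nmol/L.
#'   0 gives outcomes exactly equal to the generating linear predictor
#'   (clipped at zero).
#' @param acth_missing_rate Fraction of ACTH values set missing (MCAR).
#' @param correlation Latent log-scale correlation linking previous
#'   baseline cortisol with previous 30-minute and new baseline cortisol.
#' @param acth_correlation Latent correlation of each ACTH value with its
#'   same-test baseline cortisol.
#' @param file YAML document holding per-variable distribution parameters
#'   and group proportions; the packaged default encodes the development
#'   cohort's descriptive statistics.
#' @param ... Further overrides of top-level fields in the document.
#' @return A validated list of class \code{cohort_config}.
#' @export
cohort_config <- function(n_pairs = NULL, seed = NULL,
                          outcome_noise_sd = NULL, acth_missing_rate = NULL,
                          correlation = NULL, acth_correlation = NULL,
                          file = system.file("extdata",
                                             "cohort-default.yaml",
                                             package = "sstpredict"),
                          ...) {
  cfg <- yaml::read_yaml(file)
  override <- c(list(n_pairs = n_pairs, seed = seed,
                     outcome_noise_sd = outcome_noise_sd,
                     acth_missing_rate = acth_missing_rate,
                     correlation = correlation,
                     acth_correlation = acth_correlation),
                list(...))
  for (nm in names(override))
    if (!is.null(override[[nm]])) cfg[[nm]] <- override[[nm]]
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  if (!is_count(cfg$n_pairs) || cfg$n_pairs <= 0)
    stop_config("n_pairs", "must be a positive integer")
  if (!is_count(cfg$seed)) stop_config("seed", "must be an integer")
  if (cfg$outcome_noise_sd < 0)
    stop_config("outcome_noise_sd", "must be >= 0")
  if (cfg$acth_missing_rate < 0 || cfg$acth_missing_rate > 1)
    stop_config("acth_missing_rate", "must be in [0, 1]")
  for (r in c("correlation", "acth_correlation"))
    if (abs(cfg[[r]]) > 1) stop_config(r, "must be in [-1, 1]")
  for (v in names(cfg$variables)) {
    p <- cfg$variables[[v]]
    if (is.null(p$mean) || is.null(p$sd) || is.null(p$min) ||
        is.null(p$max))
      stop_config(v, "needs mean, sd, min, max")
    if (p$sd <= 0) stop_config(v, "sd must be > 0")
    if (p$min >= p$max) stop_config(v, "truncation bounds must be ordered")
    if (p$min < 0) stop_config(v, "values must be non-negative")
  }
  for (g in names(cfg$group_proportions)) {
    pr <- unlist(cfg$group_proportions[[g]])
    if (any(pr < 0) || abs(sum(pr) - 1) > 1e-6)
      stop_config(g, "proportions must be non-negative and sum to 1")
  }
  invisible(cfg)
}

# k-th moment of a log-normal truncated to [a, b]
trunc_lnorm_moment <- function(mu, sigma, a, b, k) {
  za <- (log(a) - mu) / sigma
  zb <- (log(b) - mu) / sigma
  p <- stats::pnorm(zb) - stats::pnorm(za)
  exp(k * mu + k^2 * sigma^2 / 2) *
    (stats::pnorm(zb - k * sigma) - stats::pnorm(za - k * sigma)) / p
}

# Solve (mu, sigma) so the TRUNCATED distribution has the target mean/sd.
trunc_lnorm_fit <- function(mean, sd, min, max) {
  obj <- function(par) {
    mu <- par[1]; sigma <- exp(par[2])
    m1 <- trunc_lnorm_moment(mu, sigma, min, max, 1)
    m2 <- trunc_lnorm_moment(mu, sigma, min, max, 2)
    s <- sqrt(pmax(m2 - m1^2, 1e-12))
    (m1 - mean)^2 / mean^2 + (s - sd)^2 / sd^2
  }
  s2 <- log(1 + sd^2 / mean^2)   # untruncated moment match as start
  fit <- stats::optim(c(log(mean) - s2 / 2, log(sqrt(s2))), obj,
                      control = list(maxit = 2000, reltol = 1e-13))
  list(mu = fit$par[1], sigma = exp(fit$par[2]), min = min, max = max)
}

# Truncated log-normal quantile applied to uniforms (copula margin).
trunc_lnorm_q <- function(u, fit) {
  pa <- stats::plnorm(fit$min, fit$mu, fit$sigma)
  pb <- stats::plnorm(fit$max, fit$mu, fit$sigma)
  q <- stats::qlnorm(pa + u * (pb - pa), fit$mu, fit$sigma)
  pmin(pmax(q, fit$min), fit$max)   # guard against quantile round-off
}

#' Generate a synthetic paired-AST cohort
#'
#' Draws \code{n_pairs} (previous test, new test) pairs. Hormone marginals
#' are truncated log-normals matched to the configured moments; a Gaussian
#' copula links previous baseline cortisol to previous 30-minute and new
#' baseline cortisol (correlation \code{correlation}) and each ACTH value
#' to its same-test baseline cortisol (\code{acth_correlation}). The new
#' 30-minute cortisol is the published previous-AST linear predictor plus
#' \code{N(0, outcome_noise_sd)} noise, clipped at zero. Test date-times
#' are spread over a year with morning draw times; the previous test date
#' is placed \code{days_between} days earlier.
#'
#' @param config A \code{\link{cohort_config}}.
#' @return A data frame of class \code{sst_cohort}: the fixed 13-column
#'   schema plus derived columns \code{days_between}, \code{prev_ratio},
#'   \code{new_ratio} (cortisol/ACTH, absent where ACTH is missing).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) validate_cohort_config(config)
  n <- config$n_pairs
  fits <- lapply(config$variables, function(p)
    trunc_lnorm_fit(p$mean, p$sd, p$min, p$max))
  r <- config$correlation
  a <- config$acth_correlation
  local_seed(config$seed, {
    e <- matrix(stats::rnorm(n * 6), n, 6)
    z_pb   <- e[, 1]
    z_p30  <- r * z_pb + sqrt(1 - r^2) * e[, 2]
    z_nb   <- r * z_pb + sqrt(1 - r^2) * e[, 3]
    z_pact <- a * z_pb + sqrt(1 - a^2) * e[, 4]
    z_nact <- a * z_nb + sqrt(1 - a^2) * e[, 5]
    z_day  <- e[, 6]
    pb   <- trunc_lnorm_q(stats::pnorm(z_pb),  fits$prev_baseline_cortisol)
    p30  <- trunc_lnorm_q(stats::pnorm(z_p30), fits$prev_cortisol_30)
    nb   <- trunc_lnorm_q(stats::pnorm(z_nb),  fits$new_baseline_cortisol)
    pact <- trunc_lnorm_q(stats::pnorm(z_pact), fits$prev_baseline_acth)
    nact <- trunc_lnorm_q(stats::pnorm(z_nact), fits$new_baseline_acth)
    days <- round(trunc_lnorm_q(stats::pnorm(z_day), fits$days_between))

    gen <- generating_model()
    lp <- gen$intercept +
      gen$terms$coefficient[1] * sqrt(nb / 100) +
      gen$terms$coefficient[2] * (pb / 100) +
      gen$terms$coefficient[3] * (p30 / 1000)
    y <- if (config$outcome_noise_sd > 0)
      lp + stats::rnorm(n, 0, config$outcome_noise_sd) else lp
    y <- pmax(0, y)

    groups <- lapply(config$group_proportions, function(pr)
      sample(names(pr), n, replace = TRUE, prob = unlist(pr)))

    new_dt <- as.POSIXct("2022-01-01 00:00:00", tz = "UTC") +
      sample(0:364, n, replace = TRUE) * 86400 +
      round(pmin(pmax(stats::rnorm(n, 9.95, 0.9), 8.25), 13.8) * 3600)
    prev_dt <- new_dt - days * 86400

    mis <- function(x) {
      if (config$acth_missing_rate > 0)
        x[stats::runif(n) < config$acth_missing_rate] <- NA_real_
      x
    }
    pact <- mis(pact); nact <- mis(nact)

    out <- data.frame(
      patient_id = sprintf("P%05d", seq_len(n)),
      prev_datetime = prev_dt,
      prev_baseline_cortisol = pb,
      prev_baseline_acth = pact,
      prev_cortisol_30 = p30,
      new_datetime = new_dt,
      new_baseline_cortisol = nb,
      new_baseline_acth = nact,
      new_cortisol_30 = y,
      sex = groups$sex,
      ai_type = groups$ai_type,
      steroid_route = groups$steroid_route,
      steroid_formulation = groups$steroid_formulation,
      stringsAsFactors = FALSE)
    out <- add_derived_columns(out)
    attr(out, "config") <- config
    class(out) <- c("sst_cohort", "data.frame")
    out
  })
}

# The outcome-generating model: the published previous-AST coefficients.
generating_model <- function() published_models()[["previous_ast"]]

# days_between and cortisol/ACTH ratios recomputed from the raw columns
add_derived_columns <- function(tab) {
  tab$days_between <- as.numeric(difftime(tab$new_datetime,
                                          tab$prev_datetime,
                                          units = "days"))
  tab$prev_ratio <- tab$prev_baseline_cortisol / tab$prev_baseline_acth
  tab$new_ratio <- tab$new_baseline_cortisol / tab$new_baseline_acth
  tab
}

#' Inject missing-completely-at-random values
#'
#' Sets each value of \code{variable} absent independently with
#' probability \code{rate}; cortisol/ACTH ratio columns are recomputed so
#' a ratio is absent exactly when its ACTH parent is.
#'
#' @param table Cohort data frame.
#' @param variable Column name.
#' @param rate Missingness probability in [0, 1].
#' @param seed RNG seed.
#' @return The table with values removed.
#' @export
inject_missingness <- function(table, variable, rate, seed = 1) {
  if (!variable %in% names(table))
    stop("unknown variable: ", variable, call. = FALSE)
  if (rate < 0 || rate > 1) stop_config("rate", "must be in [0, 1]")
  if (rate > 0) {
    local_seed(seed, {
      hit <- stats::runif(nrow(table)) < rate
      table[[variable]][hit] <- NA
    })
  }
  add_derived_columns(table)
}

#' Read / write a paired-AST cohort as CSV
#'
#' The on-disk format is the fixed 13-column schema: comma-separated,
#' header row, dot decimal, ISO-8601 date-times, empty field = missing.
#' Derived columns (days between tests, cortisol/ACTH ratios) are
#' recomputed on read.
#'
#' @param table Cohort data frame.
#' @param path File path.
#' @return \code{read_cohort}: the cohort data frame;
#'   \code{write_cohort}: \code{path}, invisibly.
#' @export
write_cohort <- function(table, path) {
  out <- table[, cohort_columns]
  for (col in c("prev_datetime", "new_datetime"))
    out[[col]] <- format(out[[col]], "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  missing_cols <- setdiff(cohort_columns, names(tab))
  if (length(missing_cols))
    stop("cohort file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in c("prev_datetime", "new_datetime"))
    tab[[col]] <- as.POSIXct(tab[[col]], format = "%Y-%m-%dT%H:%M:%S",
                             tz = "UTC")
  if (any(tab$prev_datetime >= tab$new_datetime))
    stop("previous test must predate the new test in every pair",
         call. = FALSE)
  tab <- add_derived_columns(tab)
  class(tab) <- c("sst_cohort", "data.frame")
  tab
}
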