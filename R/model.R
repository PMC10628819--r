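#' Construct a fractional-polynomial model term
#'
#' @param variable Covariate name.
#' @param scale_divisor Positive divisor applied before the power transform.
#' @param power FP1 power, one of \code{fp_powers()}.
#' @param coefficient Regression coefficient on the transformed scale
#'   (outcome units per transformed unit).
#' @param shrinkage_factor Multiplicative optimism correction already
#'   applied to \code{coefficient}; 1 means unshrunken.
#' @param standard_error Standard error of the (shrunken) coefficient.
#' @return A one-row data frame describing the term.
#' @export
fp_term <- function(variable, scale_divisor = 1, power = 1, coefficient,
                    shrinkage_factor = 1, standard_error = NA_real_) {
  stopifnot(is.character(variable), length(variable) == 1L)
  if (scale_divisor <= 0) stop_config("scale_divisor", "must be > 0")
  if (!power %in% fp_powers())
    stop_config("power", sprintf("must be one of {%s}",
                                 paste(fp_powers(), collapse = ", ")))
  data.frame(variable = variable, scale_divisor = scale_divisor,
             power = power, coefficient = coefficient,
             shrinkage_factor = shrinkage_factor,
             standard_error = standard_error,
             stringsAsFactors = FALSE)
}

#' Fractional-polynomial linear prediction model
#'
#' A prediction model for the 30-minute post-Synacthen cortisol of a new
#' ACTH stimulation test: an intercept plus a sum of FP1-transformed
#' covariate terms, with a residual standard deviation used for prediction
#' intervals and pass probabilities, and the cortisol threshold that
#' defines a passed test.
#'
#' @param name Model label.
#' @param intercept Intercept, nmol/L.
#' @param terms Data frame of terms, typically \code{rbind}-ed results of
#'   \code{\link{fp_term}}.
#' @param residual_sd Residual standard deviation (development RMSE),
#'   nmol/L; may be \code{NA} if intervals are never requested.
#' @param pass_threshold Observed 30-minute cortisol at or above which the
#'   test is passed (adrenal sufficiency), nmol/L.
#' @return An object of class \code{sst_model}.
#' @seealso \code{\link{published_models}}, \code{\link{predict.sst_model}}
#' @export
sst_model <- function(name, intercept, terms, residual_sd = NA_real_,
                      pass_threshold = 430) {
  stopifnot(is.data.frame(terms))
  need <- c("variable", "scale_divisor", "power", "coefficient")
  if (!all(need %in% names(terms)))
    stop("'terms' must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (anyDuplicated(terms$variable))
    stop("duplicate variable in model terms: ",
         terms$variable[duplicated(terms$variable)][1L], call. = FALSE)
  if (!is.na(residual_sd) && residual_sd <= 0)
    stop_config("residual_sd", "must be > 0")
  if (!"shrinkage_factor" %in% names(terms)) terms$shrinkage_factor <- 1
  if (!"standard_error" %in% names(terms)) terms$standard_error <- NA_real_
  structure(list(name = name, intercept = intercept,
                 terms = terms[, c("variable", "scale_divisor", "power",
                                   "coefficient", "shrinkage_factor",
                                   "standard_error")],
                 residual_sd = residual_sd,
                 pass_threshold = pass_threshold),
            class = "sst_model")
}

# Upper plausibility bounds for covariates (warnings, not errors): values
# above these are outside any realistic assay range.
plausibility_window <- function(variable) {
  if (grepl("acth", variable)) c(0, 500) else c(0, 2000)
}

# Linear predictor for a model on a data frame of covariates.
sst_linear_predictor <- function(object, newdata, warn = TRUE) {
  tm <- object$terms
  missing_vars <- setdiff(tm$variable, names(newdata))
  if (length(missing_vars))
    stop("missing covariate(s): ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  lp <- rep(object$intercept, nrow(newdata))
  for (i in seq_len(nrow(tm))) {
    v <- tm$variable[i]
    x <- newdata[[v]]
    w <- plausibility_window(v)
    if (warn && any(x < w[1] | x > w[2], na.rm = TRUE))
      warning(sprintf("'%s' outside plausibility window [%g, %g] nmol/L",
                      v, w[1], w[2]), call. = FALSE)
    lp <- lp + tm$coefficient[i] *
      fp_transform(x, tm$scale_divisor[i], tm$power[i])
  }
  lp
}

#' Predict from an \code{sst_model}
#'
#' Evaluates the model's linear predictor on new covariates. Point
#' predictions may be negative and are deliberately not clipped (clipping
#' would bias calibration statistics); user-facing calculator output
#' rounds and floors at zero instead (see \code{\link{sst_cli}}).
#'
#' @param object An \code{sst_model}.
#' @param newdata Data frame (or coercible list) with the model's
#'   covariates in their natural units (cortisol nmol/L, ACTH ng/L).
#' @param interval \code{"none"} for a vector of point predictions, or
#'   \code{"prediction"} for a data frame with normal-theory prediction
#'   bounds \code{point +/- z * residual_sd} and the probability of
#'   exceeding the pass threshold.
#' @param level Coverage of the prediction interval.
#' @param policy Optional \code{\link{benefit_policy}}; when supplied, a
#'   \code{classification} column (insufficient / equivocal / sufficient)
#'   is added.
#' @param ... Unused.
#' @return Numeric vector, or a data frame with columns \code{fit},
#'   \code{lwr}, \code{upr}, \code{pass_probability} (and optionally
#'   \code{classification}).
#' @examples
#' m <- published_models()[["previous_ast"]]
#' predict(m, data.frame(new_baseline_cortisol = 133,
#'                       prev_baseline_cortisol = 100,
#'                       prev_cortisol_30 = 200))
#' @export
predict.sst_model <- function(object, newdata,
                              interval = c("none", "prediction"),
                              level = 0.95, policy = NULL, ...) {
  interval <- match.arg(interval)
  if (!is.data.frame(newdata)) newdata <- as.data.frame(as.list(newdata))
  lp <- sst_linear_predictor(object, newdata)
  if (interval == "none" && is.null(policy)) return(lp)
  if (is.na(object$residual_sd))
    stop("model has no residual_sd; intervals and pass probabilities ",
         "are unavailable", call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- data.frame(fit = lp,
                    lwr = lp - z * object$residual_sd,
                    upr = lp + z * object$residual_sd,
                    pass_probability = pass_probability(
                      lp, object$residual_sd, object$pass_threshold))
  if (!is.null(policy))
    out$classification <- classify_prediction(lp, policy)
  out
}

#' Probability of passing the stimulation test
#'
#' Probability that a Gaussian outcome with mean \code{point} and standard
#' deviation \code{residual_sd} reaches the pass threshold. Equals 0.5
#' exactly when the point prediction sits on the threshold.
#'
#' @param point Point prediction(s), nmol/L.
#' @param residual_sd Residual standard deviation, nmol/L (> 0).
#' @param threshold Pass threshold, nmol/L.
#' @return Probability in [0, 1].
#' @export
pass_probability <- function(point, residual_sd, threshold = 430) {
  if (!is.numeric(residual_sd) || residual_sd <= 0)
    stop("'residual_sd' must be > 0", call. = FALSE)
  stats::pnorm((point - threshold) / residual_sd)
}

#' Solve for the covariate value attaining a target prediction
#'
#' Finds, by root bisection on a bounded window, the value of one
#' covariate for which the model prediction equals \code{target}, holding
#' any other covariates fixed. Requires the model to be monotone in the
#' free covariate over the window (guaranteed for a single FP1 term).
#'
#' @param model An \code{sst_model}.
#' @param target Target predicted 30-minute cortisol, nmol/L.
#' @param free_variable Name of the covariate solved for.
#' @param fixed Named list of the remaining covariate values.
#' @param window Search window for the free covariate, nmol/L.
#' @param tol Absolute tolerance on the prediction, nmol/L.
#' @return The solving covariate value.
#' @export
invert_covariate <- function(model, target, free_variable, fixed = list(),
                             window = c(0, 2000), tol = 1e-6) {
  tm <- model$terms
  if (!free_variable %in% tm$variable)
    stop("'", free_variable, "' is not a model covariate", call. = FALSE)
  pw <- tm$power[tm$variable == free_variable]
  lo <- window[1]; hi <- window[2]
  if (pw < 0.5 && lo <= 0) lo <- 1e-9   # log/negative powers need x > 0
  f <- function(x) {
    nd <- c(stats::setNames(list(x), free_variable), fixed)
    sst_linear_predictor(model, as.data.frame(nd), warn = FALSE) - target
  }
  flo <- f(lo); fhi <- f(hi)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0)
    stop(sprintf("target %g nmol/L not attainable for '%s' in [%g, %g]",
                 target, free_variable, window[1], window[2]),
         call. = FALSE)
  # plain bisection: prediction is monotone, so this converges linearly
  # and never leaves the bracket
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < tol || (hi - lo) / 2 < .Machine$double.eps * 1e3)
      return(mid)
    if (fm * flo < 0) hi <- mid else { lo <- mid; flo <- fm }
  }
  mid
}

#' The published calculator models
#'
#' Returns the two models with fixed, published shrunken coefficients:
#' \describe{
#'   \item{morning_only}{30-min cortisol = -54.476 +
#'     325.134 sqrt(new baseline cortisol / 100); residual SD 110.3.}
#'   \item{previous_ast}{30-min cortisol = -116.5 +
#'     251.5 sqrt(new baseline cortisol / 100)
#'     - 49.4 (previous baseline cortisol / 100)
#'     + 714.3 (previous 30-minute cortisol / 1000); residual SD 73.4.}
#' }
#' Both use pass threshold 430 nmol/L. The models are shipped as YAML
#' documents under \code{inst/extdata/models/} and parsed on demand.
#'
#' @return Named list of \code{\link{sst_model}} objects.
#' @export
published_models <- function() {
  dir <- system.file("extdata", "models", package = "sstpredict")
  files <- list.files(dir, pattern = "\\.yaml$", full.names = TRUE)
  models <- lapply(files, read_sst_model)
  stats::setNames(models, vapply(models, `[[`, "", "name"))
}

#' Read / write an \code{sst_model} as YAML
#'
#' Models serialise to a small key-value document (name, intercept,
#' residual_sd, pass_threshold and a term list); reading one back yields a
#' model making identical predictions.
#'
#' @param path File path.
#' @param model An \code{sst_model}.
#' @return \code{read_sst_model}: an \code{sst_model};
#'   \code{write_sst_model}: \code{path}, invisibly.
#' @export
read_sst_model <- function(path) {
  doc <- yaml::read_yaml(path)
  terms <- do.call(rbind, lapply(doc$terms, function(t)
    fp_term(t$variable, t$scale_divisor %||% 1, t$power %||% 1,
            t$coefficient, t$shrinkage_factor %||% 1,
            t$standard_error %||% NA_real_)))
  sst_model(doc$name, doc$intercept, terms,
            residual_sd = doc$residual_sd %||% NA_real_,
            pass_threshold = doc$pass_threshold %||% 430)
}

#' @rdname read_sst_model
#' @export
write_sst_model <- function(model, path) {
  stopifnot(inherits(model, "sst_model"))
  tm <- model$terms
  doc <- list(
    name = model$name, intercept = model$intercept,
    residual_sd = if (is.na(model$residual_sd)) NULL else model$residual_sd,
    pass_threshold = model$pass_threshold,
    terms = lapply(seq_len(nrow(tm)), function(i) {
      t <- as.list(tm[i, ])
      if (is.na(t$standard_error)) t$standard_error <- NULL
      t
    }))
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' @export
print.sst_model <- function(x, ...) {
  tm <- x$terms
  rhs <- sprintf("%.6g", x$intercept)
  for (i in seq_len(nrow(tm))) {
    b <- tm$coefficient[i]
    rhs <- paste0(rhs, if (b < 0) " - " else " + ",
                  sprintf("%.6g %s", abs(b),
                          fp_label(tm$variable[i], tm$scale_divisor[i],
                                   tm$power[i])))
  }
  cat("Short Synacthen test prediction model:", x$name, "\n")
  cat("  new 30-minute cortisol (nmol/L) =", rhs, "\n")
  if (!is.na(x$residual_sd))
    cat(sprintf("  residual SD %.4g nmol/L; pass threshold %g nmol/L\n",
                x$residual_sd, x$pass_threshold))
  invisible(x)
}

#' @export
coef.sst_model <- function(object, ...) {
  tm <- object$terms
  stats::setNames(c(object$intercept, tm$coefficient),
                  c("(Intercept)",
                    mapply(fp_label, tm$variable, tm$scale_divisor,
                           tm$power)))
}

#' @export
summary.sst_model <- function(object, ...) {
  tm <- object$terms
  tab <- data.frame(
    term = c("(Intercept)",
             mapply(fp_label, tm$variable, tm$scale_divisor, tm$power)),
    estimate = c(object$intercept, tm$coefficient),
    std_error = c(NA_real_, tm$standard_error),
    shrinkage_factor = c(NA_real_, tm$shrinkage_factor),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(name = object$name, coefficients = tab,
                 residual_sd = object$residual_sd,
                 pass_threshold = object$pass_threshold),
            class = "summary.sst_model")
}

#' @export
print.summary.sst_model <- function(x, ...) {
  cat("Model:", x$name, "\n\n")
  print(x$coefficients, digits = 6, row.names = FALSE)
  if (!is.na(x$residual_sd))
    cat(sprintf("\nResidual SD: %.4g nmol/L;  pass threshold: %g nmol/L\n",
                x$residual_sd, x$pass_threshold))
  invisible(x)
}

#' Simulate outcomes from a prediction model
#'
#' Draws 30-minute cortisol outcomes as the linear predictor plus Gaussian
#' residual noise with the model's residual SD, truncated at zero (cortisol
#' concentrations cannot be negative).
#'
#' @param object An \code{sst_model} with a finite \code{residual_sd}.
#' @param nsim Number of simulated outcome vectors.
#' @param seed Optional RNG seed.
#' @param newdata Covariate data frame.
#' @param ... Unused.
#' @return Data frame with \code{nsim} columns, one row per row of
#'   \code{newdata}.
#' @export
simulate.sst_model <- function(object, nsim = 1, seed = NULL,
                               newdata, ...) {
  if (is.na(object$residual_sd))
    stop("model has no residual_sd; cannot simulate", call. = FALSE)
  lp <- sst_linear_predictor(object, newdata, warn = FALSE)
  draw <- function() pmax(0, lp + stats::rnorm(length(lp), 0,
                                               object$residual_sd))
  sims <- if (is.null(seed)) replicate(nsim, draw())
          else local_seed(seed, replicate(nsim, draw()))
  out <- as.data.frame(matrix(sims, nrow = length(lp)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
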