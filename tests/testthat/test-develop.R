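test_that("random-forest imputation fills gaps without touching observed
           values", {
  co <- quick_cohort(n = 120, seed = 3, missing = 0)
  expect_identical(impute_random_forest(co),
                   sstpredict:::add_derived_columns(co))
  holey <- inject_missingness(co, "new_baseline_acth", 0.1, seed = 7)
  na_idx <- which(is.na(holey$new_baseline_acth))
  filled <- impute_random_forest(holey, seed = 1)
  expect_false(anyNA(filled$new_baseline_acth))
  expect_identical(filled$new_baseline_acth[-na_idx],
                   holey$new_baseline_acth[-na_idx])
  # forest predictions stay within the observed range by construction
  obs_range <- range(holey$new_baseline_acth, na.rm = TRUE)
  expect_true(all(filled$new_baseline_acth[na_idx] >= obs_range[1] &
                    filled$new_baseline_acth[na_idx] <= obs_range[2]))
  # ratios recomputed from imputed ACTH, never imputed directly
  expect_equal(filled$new_ratio,
               filled$new_baseline_cortisol / filled$new_baseline_acth)
  # deterministic given seed
  expect_identical(filled, impute_random_forest(holey, seed = 1))
  allgone <- holey; allgone$new_baseline_acth <- NA_real_
  expect_error(impute_random_forest(allgone), "no observed values")
})

test_that("backwards selection retains signal and drops noise", {
  set.seed(10)
  n <- 300
  tab <- data.frame(new_baseline_cortisol = runif(n, 20, 800),
                    junk = runif(n, 1, 100))
  tab$new_cortisol_30 <- 50 + 3 * tab$new_baseline_cortisol
  terms <- data.frame(variable = c("new_baseline_cortisol", "junk"),
                      scale_divisor = c(100, 10), power = c(1, 1))
  fit <- fit_backwards(tab, terms, alpha = 0.05)
  expect_equal(fit$terms$variable, "new_baseline_cortisol")
  expect_lt(fit$terms$p_value, 1e-10)
  # coefficient on the transformed (x/100) scale
  expect_equal(fit$terms$coefficient, 300, tolerance = 1e-6)
})

test_that("pure-noise candidates are retained at about the alpha rate", {
  kept <- 0L
  n <- 500
  for (s in 1:1000) {
    set.seed(s)
    tab <- data.frame(junk = runif(n, 1, 100),
                      new_cortisol_30 = rnorm(n, 400, 100))
    fit <- fit_backwards(tab,
                         data.frame(variable = "junk", scale_divisor = 10,
                                    power = 1), alpha = 0.05)
    kept <- kept + (nrow(fit$terms) == 1L)
  }
  # binomial(1000, 0.05): central 99.9% interval
  expect_gte(kept, qbinom(0.0005, 1000, 0.05))
  expect_lte(kept, qbinom(0.9995, 1000, 0.05))
})

test_that("collinear candidates raise a singular-fit error naming them", {
  set.seed(2)
  tab <- data.frame(new_baseline_cortisol = runif(50, 20, 800))
  tab$prev_baseline_cortisol <- 2 * tab$new_baseline_cortisol
  tab$new_cortisol_30 <- 10 + tab$new_baseline_cortisol
  terms <- data.frame(
    variable = c("new_baseline_cortisol", "prev_baseline_cortisol"),
    scale_divisor = c(100, 100), power = c(1, 1))
  expect_error(fit_backwards(tab, terms), "collinear")
})

test_that("shrinkage factors are near one without noise and below one
           when overfitting", {
  set.seed(5)
  n <- 2000
  tab <- data.frame(new_baseline_cortisol = runif(n, 20, 800),
                    prev_cortisol_30 = runif(n, 12, 826))
  tab$new_cortisol_30 <- -10 + 250 * sqrt(tab$new_baseline_cortisol / 100) +
    700 * tab$prev_cortisol_30 / 1000
  terms <- data.frame(
    variable = c("new_baseline_cortisol", "prev_cortisol_30"),
    scale_divisor = c(100, 1000), power = c(0.5, 1))
  fit <- fit_backwards(tab, terms)
  sh <- parameterwise_shrinkage(fit, tab, folds = 10, seed = 1)
  expect_equal(unname(sh$factors), c(1, 1), tolerance = 0.01)
  # shrunken = raw x factor bookkeeping identity
  expect_equal(fit$terms$coefficient * unname(sh$factors[fit$terms$variable]),
               fit$terms$coefficient * unname(sh$factors), tolerance = 0)

  mean_factors <- replicate(50, {
    nn <- 30
    noisy <- data.frame(matrix(runif(nn * 5, 1, 100), nn, 5))
    names(noisy) <- paste0("v", 1:5)
    noisy$y <- rnorm(nn, 400, 100)
    tm <- data.frame(variable = paste0("v", 1:5), scale_divisor = 10,
                     power = 1)
    f <- fit_backwards(noisy, tm, alpha = 1, outcome = "y")
    mean(parameterwise_shrinkage(f, noisy, folds = 5, seed = 3,
                                 outcome = "y")$factors)
  })
  expect_lt(mean(mean_factors), 1)
  expect_error(parameterwise_shrinkage(fit, tab, folds = 1e6), "folds")
})

test_that("a single-replicate development matches a hand-rolled fit", {
  co <- quick_cohort(n = 150, seed = 12, missing = 0)
  cfg <- quick_dev_config(n_bootstrap = 1, seed = 21)
  dev <- sst_develop(co, cfg)

  # hand-roll the same replicate with stats::lm and explicit steps
  rep_seed <- sstpredict:::derive_seed(21, 1)
  idx <- sstpredict:::local_seed(rep_seed, sample(nrow(co), replace = TRUE))
  rd <- as.data.frame(co)[idx, ]
  scales <- c(new_baseline_cortisol = 100, prev_baseline_cortisol = 100,
              prev_cortisol_30 = 1000, days_between = 100)
  pw <- sstpredict:::select_fp_powers_adjusted(
    rd$new_cortisol_30, rd, names(scales), scales)
  for (v in names(scales))
    rd[[paste0("t_", v)]] <- fp_transform(rd[[v]], scales[[v]], pw[[v]])
  vars <- names(scales)
  repeat {
    f <- lm(stats::reformulate(paste0("t_", vars), "new_cortisol_30"), rd)
    p <- summary(f)$coefficients[-1, 4]
    if (max(p) <= 0.05) break
    vars <- vars[-which.max(p)]
  }
  expect_setequal(dev$log$variable, vars)
  raw <- coef(f)[paste0("t_", dev$log$variable)]
  expect_equal(dev$log$raw_coefficient, unname(raw), tolerance = 1e-8)
})

test_that("development is deterministic and honours degenerate alpha", {
  co <- quick_cohort(n = 100, seed = 30)
  cfg <- quick_dev_config(n_bootstrap = 10, seed = 4)
  a <- sst_develop(co, cfg)
  b <- sst_develop(co, cfg)
  expect_identical(a$log, b$log)
  expect_identical(coef(a), coef(b))
  # alpha = 1 forces every candidate into every replicate
  cfg1 <- quick_dev_config(n_bootstrap = 10, seed = 4, alpha = 1)
  d <- sst_develop(co, cfg1)
  expect_true(all(d$bif == 1))
})

test_that("no variable reaches the retention fraction on a null cohort", {
  co <- quick_cohort(n = 258, seed = 77, missing = 0)
  co$new_cortisol_30 <- sstpredict:::local_seed(99, rnorm(258, 400, 100))
  dev <- suppressWarnings(
    sst_develop(co, quick_dev_config(n_bootstrap = 200, seed = 5)))
  expect_true(all(dev$bif < 0.9))
  expect_equal(nrow(dev$final$terms), 0)
})

test_that("development reports expose the fitted-model interface", {
  co <- quick_cohort(n = 150, seed = 2, missing = 0)
  dev <- sst_develop(co, quick_dev_config(n_bootstrap = 15, seed = 8))
  expect_s3_class(dev, "sst_development")
  expect_output(print(dev), "inclusion fractions")
  s <- summary(dev)
  expect_output(print(s), "R\\^2")
  expect_equal(length(residuals(dev)), length(fitted(dev)))
  expect_equal(unname(fitted(dev) + residuals(dev)),
               co$new_cortisol_30[complete.cases(
                 co[, c(dev$final$terms$variable, "new_cortisol_30")])],
               tolerance = 1e-9)
  pr <- predict(dev, co)
  expect_length(pr, nrow(co))
  expect_true(all(dev$bif >= 0 & dev$bif <= 1))
  expect_true(all(dev$final$terms$variable %in% dev$config$candidates))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(dev))
})

test_that("schema violations and all-missing outcomes are rejected", {
  co <- quick_cohort(n = 60, seed = 1)
  expect_error(sst_develop(co[, 1:3], quick_dev_config()), "lacks column")
  co2 <- co; co2$new_cortisol_30[5] <- NA
  expect_error(suppressWarnings(sst_develop(co2, quick_dev_config())),
               "outcome")
  expect_warning(sst_develop(quick_cohort(n = 30, seed = 2, missing = 0),
                             quick_dev_config(n_bootstrap = 2)),
                 "10")
  expect_error(develop_config(n_bootstrap = 0), "n_bootstrap")
  expect_error(develop_config(alpha = 0), "alpha")
  expect_error(develop_config(candidates = "bogus"), "unknown")
})
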