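pub <- published_models()

test_that("published models carry the fixed coefficient sets", {
  expect_named(pub, c("morning_only", "previous_ast"), ignore.order = TRUE)
  expect_equal(nrow(pub$previous_ast$terms), 3)
  expect_equal(pub$morning_only$intercept, -54.476)
  expect_equal(pub$morning_only$terms$coefficient, 325.134)
  expect_equal(pub$previous_ast$intercept, -116.5)
  expect_equal(pub$previous_ast$residual_sd, 73.4)
  expect_equal(pub$previous_ast$pass_threshold, 430)
})

test_that("worked examples evaluate to the published predictions", {
  p1 <- predict(pub$previous_ast,
                data.frame(new_baseline_cortisol = 133,
                           prev_baseline_cortisol = 100,
                           prev_cortisol_30 = 200))
  expect_equal(round(p1), 267)
  p2 <- predict(pub$previous_ast,
                data.frame(new_baseline_cortisol = 133,
                           prev_baseline_cortisol = 200,
                           prev_cortisol_30 = 400))
  expect_equal(p2, 360.46, tolerance = 1e-4)
  # morning model at baseline 100: unit transform, sum of coefficients
  p3 <- predict(pub$morning_only,
                data.frame(new_baseline_cortisol = 100))
  expect_equal(p3, -54.476 + 325.134)
})

test_that("prediction errors and warnings follow the contract", {
  expect_error(predict(pub$previous_ast,
                       data.frame(new_baseline_cortisol = 133)),
               "prev_baseline_cortisol")
  expect_warning(predict(pub$morning_only,
                         data.frame(new_baseline_cortisol = 2500)),
                 "plausibility")
  # negative point predictions are reported unclipped
  p <- predict(pub$previous_ast,
               data.frame(new_baseline_cortisol = 1,
                          prev_baseline_cortisol = 600,
                          prev_cortisol_30 = 12))
  expect_lt(p, 0)
})

test_that("prediction interval brackets the point and responds to level", {
  nd <- data.frame(new_baseline_cortisol = 133,
                   prev_baseline_cortisol = 100, prev_cortisol_30 = 200)
  out <- predict(pub$previous_ast, nd, interval = "prediction")
  expect_true(out$lwr <= out$fit && out$fit <= out$upr)
  expect_equal(out$upr - out$fit, qnorm(0.975) * 73.4)
})

test_that("pass probability is a calibrated normal exceedance", {
  expect_equal(pass_probability(430, 73.4), 0.5)
  expect_equal(pass_probability(430 + 1.96 * 73.4, 73.4), 0.975,
               tolerance = 1e-4)
  # frozen from an independent normal-CDF oracle: 1 - Phi(163/73.4)
  expect_equal(pass_probability(267, 73.4, 430), 0.0131853575,
               tolerance = 1e-7)
  expect_error(pass_probability(400, 0), "must be > 0")
  # monotone in the point prediction
  p <- pass_probability(seq(0, 900, by = 50), 73.4)
  expect_true(all(diff(p) > 0))
})

test_that("monotonicity of the previous-AST model matches coefficient signs", {
  base <- data.frame(new_baseline_cortisol = 150,
                     prev_baseline_cortisol = 150, prev_cortisol_30 = 300)
  for (v in c("new_baseline_cortisol", "prev_cortisol_30")) {
    hi <- base; hi[[v]] <- hi[[v]] + 50
    expect_gt(predict(pub$previous_ast, hi),
              predict(pub$previous_ast, base))
  }
  hi <- base; hi$prev_baseline_cortisol <- hi$prev_baseline_cortisol + 50
  expect_lt(predict(pub$previous_ast, hi), predict(pub$previous_ast, base))
})

test_that("covariate inversion solves the closed-form root", {
  # -54.476 + 325.134 sqrt(x/100) = 430  =>  x = 100 ((430+54.476)/325.134)^2
  x <- invert_covariate(pub$morning_only, 430, "new_baseline_cortisol")
  expect_equal(x, 100 * ((430 + 54.476) / 325.134)^2, tolerance = 1e-5)
  # inverse of the published worked example
  x2 <- invert_covariate(pub$previous_ast,
                         predict(pub$previous_ast,
                                 data.frame(new_baseline_cortisol = 133,
                                            prev_baseline_cortisol = 100,
                                            prev_cortisol_30 = 200)),
                         "new_baseline_cortisol",
                         fixed = list(prev_baseline_cortisol = 100,
                                      prev_cortisol_30 = 200))
  expect_equal(x2, 133, tolerance = 1e-4)
  expect_error(invert_covariate(pub$morning_only, -500,
                                "new_baseline_cortisol"),
               "not attainable")
})

test_that("inversion composed with prediction is the identity", {
  set.seed(4)
  for (target in runif(20, 50, 900)) {
    x <- invert_covariate(pub$morning_only, target,
                          "new_baseline_cortisol", window = c(0, 2000))
    p <- predict(pub$morning_only, data.frame(new_baseline_cortisol = x))
    expect_equal(p, target, tolerance = 1e-5)
  }
})

test_that("a serialised model round-trips to identical predictions", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sst_model(pub$previous_ast, path)
  back <- read_sst_model(path)
  set.seed(9)
  nd <- data.frame(new_baseline_cortisol = runif(100, 2, 836),
                   prev_baseline_cortisol = runif(100, 2, 664),
                   prev_cortisol_30 = runif(100, 12, 826))
  expect_identical(predict(back, nd), predict(pub$previous_ast, nd))
  expect_equal(back$residual_sd, pub$previous_ast$residual_sd)
})

test_that("model constructor enforces its invariants", {
  tm <- rbind(fp_term("a", 100, 0.5, 1), fp_term("a", 100, 1, 2))
  expect_error(sst_model("dup", 0, tm), "duplicate")
  expect_error(fp_term("a", -1, 1, 1), "scale_divisor")
  expect_error(fp_term("a", 1, 0.7, 1), "power")
  expect_error(sst_model("bad", 0, fp_term("a", 1, 1, 1),
                         residual_sd = -3), "residual_sd")
})

test_that("standard S3 methods work on a model", {
  m <- pub$previous_ast
  expect_output(print(m), "previous_ast")
  expect_named(coef(m)[1], "(Intercept)")
  expect_length(coef(m), 4)
  s <- summary(m)
  expect_s3_class(s, "summary.sst_model")
  expect_equal(nrow(s$coefficients), 4)
  sims <- simulate(m, nsim = 3, seed = 1,
                   newdata = data.frame(new_baseline_cortisol = 133,
                                        prev_baseline_cortisol = 100,
                                        prev_cortisol_30 = 200))
  expect_equal(dim(sims), c(1L, 3L))
  expect_true(all(sims >= 0))
})
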