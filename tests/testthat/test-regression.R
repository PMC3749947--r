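make_reg_data <- function(n = 40, seed = 2) {
  set.seed(seed)
  data.frame(pR1 = runif(n, 0, 10), pR2 = runif(n, 0, 5),
             pR3 = runif(n, 0, 2))
}

test_that("an exactly linear target is recovered exactly", {
  d <- make_reg_data()
  d$pErk <- 0.5 + 2 * d$pR1
  fit <- her_regression(d, "pErk", c("pR1", "pR2", "pR3"))
  b <- coef(fit, raw = TRUE)
  expect_equal(b[["(Intercept)"]], 0.5, tolerance = 1e-10)
  expect_equal(b[["pR1"]], 2, tolerance = 1e-10)
  expect_equal(b[["pR2"]], 0, tolerance = 1e-10)
  expect_equal(b[["pR3"]], 0, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(names(fit$importance)[1], "pR1")
})

test_that("a constant target yields zero slopes and the constant intercept", {
  d <- make_reg_data()
  d$pAkt <- 3.7
  fit <- her_regression(d, "pAkt", c("pR1", "pR2", "pR3"))
  b <- coef(fit, raw = TRUE)
  expect_equal(unname(b[-1]), rep(0, 3), tolerance = 1e-10)
  expect_equal(b[["(Intercept)"]], 3.7, tolerance = 1e-10)
})

test_that("coefficients are invariant to observation order", {
  d <- make_reg_data()
  d$pErk <- 1 + 0.8 * d$pR1 - 0.3 * d$pR2 + rnorm(nrow(d), 0, 0.1)
  f1 <- her_regression(d, "pErk", c("pR1", "pR2", "pR3"))
  set.seed(9)
  f2 <- her_regression(d[sample(nrow(d)), ], "pErk", c("pR1", "pR2", "pR3"))
  expect_equal(coef(f1), coef(f2), tolerance = 1e-10)
})

test_that("the dominant predictor is ranked first on synthetic targets", {
  # mimic dimer-mode predictors with one dominant driver
  set.seed(4)
  n <- 60
  d <- data.frame(pR1_11 = runif(n), pR1_12 = runif(n), pR3_13 = runif(n),
                  pR3_23 = runif(n))
  d$pAkt <- 0.2 + 5 * d$pR3_13 + 0.2 * d$pR1_11 + rnorm(n, 0, 0.05)
  fit <- her_regression(d, "pAkt", mode = "dimer")
  expect_equal(names(fit$importance)[1], "pR3_13")
  expect_gt(fit$r_squared, 0.9)
})

test_that("rank-deficient designs fall back to the minimum-norm fit", {
  d <- make_reg_data()
  d$dup <- d$pR1            # perfectly collinear
  d$pErk <- 1 + d$pR1
  expect_warning(
    fit <- her_regression(d, "pErk", c("pR1", "dup", "pR2"),
                          standardize = FALSE),
    "minimum-norm")
  expect_true(fit$rank_deficient)
  expect_equal(fit$fitted, d$pErk, tolerance = 1e-8)
})

test_that("predict reproduces the fitted values on the training data", {
  d <- make_reg_data()
  d$pErk <- 2 + 0.5 * d$pR1 + 0.1 * d$pR2
  fit <- her_regression(d, "pErk", c("pR1", "pR2", "pR3"))
  expect_equal(predict(fit, d), fit$fitted, tolerance = 1e-10)
})

test_that("undersized datasets are rejected", {
  d <- make_reg_data(n = 3)
  d$pErk <- d$pR1
  expect_error(her_regression(d, "pErk", c("pR1", "pR2", "pR3")),
               "observations")
})
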