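test_that("trafficking formulas reproduce the direct substitution case", {
  # kx = 0.09, f = 0.5, delta1 = 1: kr = 0.09*0.5*2, kl = same, kd = kl/1
  tr <- her_trafficking_rates(kx = 0.09, f = 0.5, delta1 = 1)
  expect_equal(tr$kr, 0.09)
  expect_equal(tr$kl, 0.09)
  expect_equal(tr$kd, 0.09)
  expect_equal(tr$delta, 1)
})

test_that("a species with the reference kx and f gets delta = delta1", {
  tr <- her_trafficking_rates(kx = c(0.15, 0.15), f = c(0.5, 0.5),
                              delta1 = 2.7)
  expect_equal(tr$delta, c(2.7, 2.7))
})

test_that("trafficking identities hold to machine precision", {
  set.seed(101)
  for (i in 1:50) {
    delta1 <- runif(1, 0.1, 10)
    kx1 <- runif(1, 0.05, 0.5)
    f1 <- runif(1, 0.1, 0.9)
    # sample other species keeping kx*(1-f) below the reference LE scale
    a <- kx1 * (1 - f1) * (1 + 1 / delta1)
    kx <- runif(4, 0.05, 0.5)
    f <- 1 - runif(4, 0.1, 0.95) * pmin(a / kx, 1)
    tr <- her_trafficking_rates(c(kx1, kx), c(f1, f), delta1)
    expect_equal(tr$kl / tr$kd, tr$delta, tolerance = 1e-12)
    expect_equal(tr$kr / (tr$kr + tr$kl), tr$f, tolerance = 1e-12)
    # definitional formulas
    expect_equal(tr$kr, tr$kx * tr$f * (1 + tr$delta), tolerance = 1e-12)
    expect_equal(tr$kl, tr$kx * (1 - tr$f) * (1 + tr$delta),
                 tolerance = 1e-12)
    expect_equal(tr$kd, tr$kx * (1 - tr$f) * (1 + tr$delta) / tr$delta,
                 tolerance = 1e-12)
    # sorting chain ties every delta to delta1
    expect_equal(1 + 1 / tr$delta,
                 (kx1 * (1 - f1) * (1 + 1 / delta1)) / (tr$kx * (1 - tr$f)),
                 tolerance = 1e-12)
    expect_equal(tr$delta[1], delta1, tolerance = 1e-12)
  }
})

test_that("degenerate trafficking inputs are rejected", {
  expect_error(her_trafficking_rates(kx = 0.1, f = 1, delta1 = 1), "\\[0, 1\\)")
  expect_error(her_trafficking_rates(kx = 0, f = 0.5, delta1 = 1), "positive")
  expect_error(her_trafficking_rates(kx = 0.1, f = 0.5, delta1 = 0), "delta1")
  # kx*(1-f) above the reference degradation scale has no positive delta
  expect_error(her_trafficking_rates(kx = c(0.1, 10), f = c(0.5, 0.1),
                                     delta1 = 1), "delta")
})
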