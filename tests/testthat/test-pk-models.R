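test_that("degenerate tissue parameters collapse the model as expected", {
  theta <- refAIF()
  tt <- c(-5, 0, 10, 60, 200)
  zero <- PKParameters(0, 0.3, 0)          # Ktrans = 0, vp = 0
  expect_equal(toftsConcentration(tt, zero, theta), rep(0, 5))
  plasma <- PKParameters(0.05, 0.3, 0)     # plasma-only term
  expect_equal(toftsConcentration(tt, plasma, theta),
               0.05 * aifConcentration(tt, theta))
  # ve = 0 forces Ktrans = 0 regardless of kep
  novE <- PKParameters(0, 0, 2)
  expect_equal(toftsConcentration(tt, novE, theta), rep(0, 5))
})

test_that("tissue concentration matches the quadrature oracle", {
  theta <- refAIF()
  u <- PKParameters(0.025, 0.2, 1.0)
  for (ts in c(10, 60, 120, 299)) {
    expect_equal(toftsConcentration(ts, u, theta), bruteTofts(ts, u, theta),
                 tolerance = 1e-5)
  }
  # boundary rates: kep at 0 and kep equal to the AIF washout rate
  u0 <- PKParameters(0.05, 0.3, 0)
  expect_equal(toftsConcentration(60, u0, theta), bruteTofts(60, u0, theta),
               tolerance = 1e-8)
  um <- PKParameters(0.05, 0.3, 0.171)
  expect_equal(toftsConcentration(60, um, theta), bruteTofts(60, um, theta),
               tolerance = 1e-6)
})

test_that("model is linear in vp and in the AIF amplitudes", {
  u <- PKParameters(0.05, 0.4, 1.2)
  u2 <- PKParameters(0.10, 0.4, 1.2)
  theta <- refAIF()
  theta2 <- AIFParameters(ab = 2 * 2.84, ae = 1.36)  # doubled amplitude
  tt <- c(15, 45, 150)
  base <- toftsConcentration(tt, u, theta)
  only_vp <- PKParameters(0.05, 0.4, 1.2)@vp * aifConcentration(tt, theta)
  expect_equal(toftsConcentration(tt, u2, theta) - base, only_vp)
  expect_equal(toftsConcentration(tt, u, theta2), 2 * base, tolerance = 1e-12)
})

test_that("directly averaged model and convolved-AIF model coincide", {
  theta <- refAIF()
  set.seed(11)
  for (i in 1:20) {
    u <- PKParameters(runif(1, 0, 0.37), runif(1), runif(1, 0, 3))
    dt <- sample(c(4, 8, 10, 15), 1)
    tc <- runif(1, 1, 290)
    quad <- averagedToftsConcentration(tc, u, theta, dt,
                                       method = "quadrature")
    expect_equal(averagedToftsViaConvolvedAif(tc, u, theta, dt), quad,
                 tolerance = 1e-6)
    expect_equal(averagedToftsConcentration(tc, u, theta, dt), quad,
                 tolerance = 1e-6)
  }
})

test_that("averaged model has the dt -> 0 limit and the smoothing bound", {
  theta <- refAIF()
  u <- PKParameters(0.05, 0.3, 2.0)
  expect_equal(averagedToftsConcentration(60, u, theta, dt = 0.01),
               toftsConcentration(60, u, theta), tolerance = 1e-4)
  grid <- seq(-10, 310, by = 0.5)
  for (uu in list(u, PKParameters(0.2, 0.8, 0.4))) {
    cmax <- max(toftsConcentration(pmax(grid, 0), uu, theta))
    cavg <- max(averagedToftsConcentration(grid, uu, theta, dt = 15))
    expect_lte(cavg, cmax)
  }
})

test_that("averaging error shrinks quadratically in dt", {
  theta <- refAIF()
  u <- PKParameters(0.05, 0.3, 1.5)
  tc <- 120  # smooth region, away from arrival and bolus end
  err <- function(dt) abs(averagedToftsConcentration(tc, u, theta, dt) -
                          toftsConcentration(tc, u, theta))
  ratio <- err(8) / err(4)
  expect_gt(ratio, 3.5)
  expect_lt(ratio, 4.5)
})

test_that("averaged-model oracle check at the spec's example point", {
  theta <- refAIF()
  u <- PKParameters(0.05, 0.3, 2.0)
  direct <- trapWindowMean(function(g)
    toftsConcentration(pmax(g, -1e-9), u, theta), 37.5, 15)
  expect_equal(averagedToftsConcentration(37.5, u, theta, 15), direct,
               tolerance = 1e-6)
})

test_that("invalid inputs are rejected", {
  u <- PKParameters(0.05, 0.3, 1)
  expect_error(averagedToftsConcentration(60, u, refAIF(), dt = 0), "dt")
  expect_error(toftsConcentration(NA_real_, u, refAIF()), "finite")
  expect_error(PKParameters(-0.1, 0.3, 1), "vp")
  expect_error(PKParameters(0.1, 1.3, 1), "ve")
  expect_error(PKParameters(0.1, 0.3, 3.5), "kep")
  many <- paramGrid()
  expect_error(toftsConcentration(60, many, refAIF()), "single")
})
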