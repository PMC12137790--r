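test_that("noiseless curves of the matching variant are recovered exactly", {
  theta <- refAIF()
  u <- PKParameters(0.025, 0.3, 1.5)
  tt <- seq(1, 300, by = 1)
  fit <- fitCurve(tt, toftsConcentration(tt, u, theta), "conventional",
                  theta)
  est <- as.data.frame(estimates(fit))
  expect_lt(max(abs(c(est$vp - 0.025, est$ve - 0.3, est$kep - 1.5))), 1e-4)
  expect_true(converged(fit))
  expect_lt(rss(fit), 1e-12)
})

test_that("ignoring time-averaging biases vp; the corrected fit does not", {
  theta <- refAIF()
  u <- PKParameters(0.025, 0.3, 1.5)
  dt <- 15
  tt <- seq(dt / 2, 300, by = dt)
  y <- averagedToftsConcentration(tt, u, theta, dt)   # noiseless averaged
  corrected <- fitCurve(tt, y, "time_averaged", theta, dt = dt)
  conventional <- fitCurve(tt, y, "conventional", theta)
  ec <- as.data.frame(estimates(corrected))
  eu <- as.data.frame(estimates(conventional))
  expect_lt(max(abs(c(ec$vp - 0.025, ec$ve - 0.3, ec$kep - 1.5))), 1e-3)
  expect_gt(abs(eu$vp - 0.025), abs(ec$vp - 0.025))
})

test_that("all-zero samples drive the plasma and leakage terms to zero", {
  fit <- fitCurve(seq(2, 298, 4), numeric(75), "conventional", refAIF())
  est <- as.data.frame(estimates(fit))
  expect_lt(est$vp, 1e-8)
  expect_lt(est$Ktrans, 1e-8)
  expect_lt(rss(fit), 1e-15)
})

test_that("estimates respect the constraint box and fits are deterministic", {
  theta <- refAIF()
  set.seed(21)
  u <- sampleParameters(8, seed = 21)
  ds <- generateDataset(u, AcquisitionScheme(dt = 10), theta,
                        NoiseModel(5), seed = 22)   # heavy noise
  for (i in seq_len(8)) {
    f1 <- fitCurve(ds$times[i, ], ds$averaged[i, ], "time_averaged", theta,
                   dt = 10)
    e <- as.data.frame(estimates(f1))
    expect_true(e$vp >= 0 && e$vp <= 1)
    expect_true(e$ve >= 0 && e$ve <= 1)
    expect_true(e$kep >= 0 && e$kep <= 3)
    f2 <- fitCurve(ds$times[i, ], ds$averaged[i, ], "time_averaged", theta,
                   dt = 10)
    expect_identical(as.data.frame(estimates(f1)),
                     as.data.frame(estimates(f2)))
  }
})

test_that("noiseless corrected estimates agree across frame durations", {
  theta <- refAIF()
  u <- PKParameters(0.08, 0.45, 2.1)
  ests <- lapply(c(4, 8, 10, 15), function(dt) {
    tt <- seq(dt / 2, 300, by = dt)
    y <- averagedToftsConcentration(tt, u, theta, dt)
    as.data.frame(estimates(fitCurve(tt, y, "time_averaged", theta,
                                     dt = dt)))
  })
  for (p in c("vp", "ve", "kep")) {
    vals <- vapply(ests, function(e) e[[p]], numeric(1))
    expect_lt(max(vals) - min(vals), 1e-2)
  }
})

test_that("fit input validation catches malformed curves", {
  expect_error(fitCurve(c(1, 2, 3), c(0, 0, 0), "conventional"), "4 samples")
  expect_error(fitCurve(c(1, 3, 2, 4), rep(0, 4), "conventional"),
               "increasing")
  expect_error(fitCurve(seq(2, 298, 4), numeric(75), "time_averaged"),
               "dt")
  expect_error(fitCurve(seq(2, 298, 4), numeric(74), "conventional"),
               "equal length")
})

test_that("signal-domain fitting recovers parameters from signal curves", {
  theta <- refAIF()
  p <- SPGRParameters()
  u <- PKParameters(0.05, 0.4, 1.2)
  dt <- 10
  tt <- seq(dt / 2, 300, by = dt)
  S <- averagedSignal(tt, u, theta, p, dt = dt, step = 0.02)
  fit <- fitCurve(tt, S, "signal_domain", theta, dt = dt, spgr = p)
  est <- as.data.frame(estimates(fit))
  expect_lt(max(abs(c(est$vp - 0.05, est$ve - 0.4, est$kep - 1.2))), 1e-3)
})

test_that("voxelwise map fitting recovers a two-region phantom", {
  theta <- refAIF()
  dt <- 10
  tt <- seq(dt / 2, 300, by = dt)
  uA <- PKParameters(0.02, 0.25, 0.8)
  uB <- PKParameters(0.10, 0.60, 2.0)
  m <- length(tt)
  vol <- array(0, c(4, 4, 1, m))
  for (x in 1:4) for (y in 1:4) {
    u <- if (x <= 2) uA else uB
    vol[x, y, 1, ] <- averagedToftsConcentration(tt, u, theta, dt)
  }
  maps <- fitImage(vol, tt, "time_averaged", theta, dt = dt,
                   input = "concentration")
  expect_equal(dim(maps$vp), c(4, 4, 1))
  expect_lt(max(abs(maps$vp[1:2, , 1] - 0.02)), 1e-3)
  expect_lt(max(abs(maps$vp[3:4, , 1] - 0.10)), 1e-3)
  expect_lt(max(abs(maps$ve[1:2, , 1] - 0.25)), 1e-3)
  expect_lt(max(abs(maps$kep[3:4, , 1] - 2.0)), 1e-2)
})

test_that("mask handling: empty mask fits nothing, one voxel matches fitCurve", {
  theta <- refAIF()
  dt <- 15
  tt <- seq(dt / 2, 300, by = dt)
  u <- PKParameters(0.05, 0.3, 1.5)
  vol <- array(rep(averagedToftsConcentration(tt, u, theta, dt),
                   each = 4), c(2, 2, 1, length(tt)))
  empty <- fitImage(vol, tt, "time_averaged", theta, dt = dt,
                    mask = array(FALSE, c(2, 2, 1)),
                    input = "concentration")
  expect_true(all(is.na(empty$vp)))
  one <- array(FALSE, c(2, 2, 1)); one[1, 1, 1] <- TRUE
  maps <- fitImage(vol, tt, "time_averaged", theta, dt = dt, mask = one,
                   input = "concentration")
  direct <- fitCurve(tt, vol[1, 1, 1, ], "time_averaged", theta, dt = dt)
  expect_equal(maps$vp[1, 1, 1], vp(estimates(direct)))
  expect_equal(maps$kep[1, 1, 1], kep(estimates(direct)))
  expect_true(is.na(maps$vp[2, 2, 1]))
  expect_error(fitImage(vol, NULL, "conventional"), "timing")
})

test_that("signal input volumes are converted before fitting", {
  theta <- refAIF()
  p <- SPGRParameters()
  dt <- 10
  tt <- seq(dt / 2, 300, by = dt)
  u <- PKParameters(0.04, 0.35, 1.0)
  conc <- averagedToftsConcentration(tt, u, theta, dt)
  vol <- array(rep(spgrSignal(conc, p), each = 1), c(1, 1, 1, length(tt)))
  maps <- fitImage(vol, tt, "time_averaged", theta, dt = dt, spgr = p,
                   input = "signal")
  expect_equal(maps$vp[1, 1, 1], 0.04, tolerance = 1e-4)
  expect_equal(maps$ve[1, 1, 1], 0.35, tolerance = 1e-4)
})
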