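test_that("prior draws respect their supports and are reproducible", {
  u <- sampleParameters(5000, seed = 7)
  expect_true(all(ve(u) >= 0 & ve(u) <= 1))
  expect_true(all(kep(u) >= 0 & kep(u) <= 3))
  expect_true(all(vp(u) >= 0 & vp(u) <= 0.37))
  again <- sampleParameters(5000, seed = 7)
  expect_identical(vp(u), vp(again))
  uni <- sampleParameters(2000, ParameterPrior(vpPrior = "uniform"),
                          seed = 8)
  expect_gt(max(vp(uni)), 0.5)   # uniform prior spans [0, 1]
  expect_error(sampleParameters(0), "n")
})

test_that("frame counts follow floor(duration / dt)", {
  expect_equal(vapply(c(4, 8, 10, 15), function(d)
    nFrames(AcquisitionScheme(dt = d, duration = 300)), integer(1)),
    c(75L, 37L, 30L, 20L))
  sch <- AcquisitionScheme(dt = 8, duration = 300, alignment = "centered")
  tt <- frameTimes(sch)
  expect_equal(length(tt), 37L)
  expect_equal(tt[1:3], c(4, 12, 20))
  expect_equal(frameTimes(AcquisitionScheme(dt = 10, alignment = "start"))[1:3],
               c(0, 10, 20))
})

test_that("noiseless averaged samples equal the quadrature oracle", {
  theta <- refAIF()
  u <- PKParameters(c(0.05, 0.2), c(0.3, 0.7), c(2, 0.4))
  ds <- generateDataset(u, AcquisitionScheme(dt = 15, alignment = "random"),
                        theta, NoiseModel(Inf), seed = 3)
  for (i in 1:2) {
    ui <- u[i]
    for (j in c(1, 2, 10, 20)) {
      expect_equal(ds$averaged[i, j],
                   averagedToftsConcentration(ds$times[i, j], ui, theta, 15,
                                              method = "quadrature"),
                   tolerance = 1e-6)
      expect_equal(ds$discrete[i, j],
                   toftsConcentration(ds$times[i, j], ui, theta))
    }
  }
  expect_equal(ds$sigma, c(0, 0))
})

test_that("zero-parameter curves are pure noise with the stated sigma", {
  u <- PKParameters(0, 0, 0)
  ds <- generateDataset(u, AcquisitionScheme(dt = 4), refAIF(),
                        NoiseModel(20), seed = 5)
  expect_equal(ds$sigma, 0)   # mean(C') = 0 -> sigma = 0
  expect_equal(as.vector(ds$averaged), numeric(75))
})

test_that("noise sigma equals mean of the noiseless averaged curve over SNR", {
  u <- sampleParameters(3, seed = 10)
  clean <- generateDataset(u, AcquisitionScheme(dt = 10), refAIF(),
                           NoiseModel(Inf), seed = 11)
  noisy <- generateDataset(u, AcquisitionScheme(dt = 10), refAIF(),
                           NoiseModel(20), seed = 11)
  # same seed -> same phases -> same grids
  expect_identical(clean$times, noisy$times)
  expect_equal(noisy$sigma, rowMeans(clean$averaged) / 20)
})

test_that("experiments are paired: same truths, grids and noisy samples", {
  a <- runExperiment("exp1", dt = 15, n = 25, seed = 9)
  b <- runExperiment("exp2", dt = 15, n = 25, seed = 9)
  r <- runExperiment("reference", dt = 15, n = 25, seed = 9)
  expect_identical(as.data.frame(truth(a)), as.data.frame(truth(b)))
  expect_identical(as.data.frame(truth(a)), as.data.frame(truth(r)))
  again <- runExperiment("exp1", dt = 15, n = 25, seed = 9)
  expect_identical(errors(a), errors(again))
  expect_error(runExperiment("nope", dt = 15), "experiment id")
})

test_that("corrected fits recover noiseless simulated curves at every dt", {
  u <- sampleParameters(6, seed = 13)
  for (dt in c(4, 15)) {
    ds <- generateDataset(u, AcquisitionScheme(dt = dt), refAIF(),
                          NoiseModel(Inf), seed = 14)
    f <- taetofts:::.fitBatch(ds$times, ds$averaged, "time_averaged",
                              refAIF(), dt)
    expect_lt(median(abs(f$vp - vp(u))), 1e-3)
    expect_lt(median(abs(f$ve - ve(u))), 1e-3)
    expect_lt(median(abs(f$kep - kep(u))), 1e-3)
  }
})

test_that("the time-averaged-AIF conventional fit is unbiased on averaged data", {
  # the equivalence identity in fitting form: conventional model with the
  # rect-averaged AIF reproduces time-averaged data exactly
  u <- sampleParameters(4, seed = 15)
  ds <- generateDataset(u, AcquisitionScheme(dt = 15), refAIF(),
                        NoiseModel(Inf), seed = 16)
  f <- taetofts:::.fitBatch(ds$times, ds$averaged, "conventional", refAIF(),
                            dt = 15, aifAveraged = TRUE)
  expect_lt(median(abs(f$vp - vp(u))), 1e-3)
  expect_lt(median(abs(f$ve - ve(u))), 1e-3)
})

test_that("double averaging (averaged model with averaged AIF) over-smooths", {
  u <- PKParameters(0.08, 0.4, 1.8)
  ds <- generateDataset(u, AcquisitionScheme(dt = 15, alignment = "centered"),
                        refAIF(), NoiseModel(Inf))
  f <- taetofts:::.fitBatch(ds$times, ds$averaged, "time_averaged", refAIF(),
                            dt = 15, aifAveraged = TRUE)
  # correcting twice mis-models the data, so recovery degrades
  expect_gt(abs(f$vp - 0.08) + abs(f$ve - 0.4), 1e-3)
  r <- runExperiment("s4_exp2", dt = 15, n = 3, seed = 17)
  expect_s4_class(r, "ExperimentResult")
})
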