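test_that("error summaries report mean and SD per parameter", {
  est <- PKParameters(c(0.03, 0.02), c(0.31, 0.29), c(1.1, 0.9))
  tru <- PKParameters(c(0.025, 0.025), c(0.3, 0.3), c(1, 1))
  s <- summarizeErrors(est, tru)
  expect_equal(s$parameter, c("Ktrans", "vp", "ve"))
  expect_equal(s$n, rep(2L, 3))
  # identical estimates give zero mean and SD
  s0 <- summarizeErrors(tru, tru)
  expect_equal(s0$mean_error, rep(0, 3))
  expect_equal(s0$sd_error, rep(0, 3))
  # arithmetic: errors +0.1 / -0.1 -> mean 0, sample SD sqrt(2)*0.1
  e <- data.frame(Ktrans = c(0.1, -0.1), vp = c(0.1, -0.1),
                  ve = c(0.1, -0.1))
  s1 <- summarizeErrors(e)
  expect_equal(s1$mean_error, rep(0, 3))
  expect_equal(s1$sd_error, rep(sqrt(2) * 0.1, 3), tolerance = 1e-12)
  expect_error(summarizeErrors(est, tru[1]), "equal length")
})

test_that("summaries agree with an independent two-pass computation", {
  set.seed(31)
  e <- data.frame(Ktrans = rnorm(1e4), vp = rnorm(1e4, sd = 0.01),
                  ve = rnorm(1e4, 0.3, 0.2))
  s <- summarizeErrors(e)
  for (i in 1:3) {
    x <- e[[s$parameter[i]]]
    mu <- sum(x) / length(x)
    sd2 <- sqrt(sum((x - mu)^2) / (length(x) - 1))
    expect_equal(s$mean_error[i], mu, tolerance = 1e-12)
    expect_equal(s$sd_error[i], sd2, tolerance = 1e-12)
  }
})

test_that("paired comparisons detect known shifts and variance ratios", {
  # identical errors: nonsignificant by convention
  x <- rnorm(100)
  same <- compareConditions(x, x)
  expect_equal(same$p_accuracy, 1)
  expect_false(same$sig_precision)
  set.seed(32)
  a <- rnorm(5000, sd = 1)
  tripled <- compareConditions(a, 3 * a)
  expect_true(tripled$sig_precision)
  expect_equal(tripled$better_precision, "A")
  shifted <- compareConditions(a, a + 0.05)
  expect_true(shifted$sig_accuracy)
  expect_error(compareConditions(a, a[-1]), "equal-length")
})

test_that("signed-error mode and centering options are available", {
  set.seed(33)
  a <- rnorm(2000, mean = 0, sd = 1)
  b <- a + 0.2
  signed <- compareConditions(a, b, accuracyOn = "signed")
  expect_true(signed$sig_accuracy)
  m <- compareConditions(a, 2 * a, leveneCenter = "mean")
  expect_true(m$sig_precision)
})

test_that("tests agree with permutation references on small samples", {
  set.seed(34)
  a <- rnorm(50, sd = 1)
  b <- rnorm(50, sd = 1.8) + 0.3
  out <- compareConditions(a, b)
  # permutation Wilcoxon: swap paired |errors| at random
  xa <- abs(a); xb <- abs(b)
  stat <- function(x, y) sum(rank(abs(x - y))[x - y > 0])
  obs <- stat(xa, xb)
  B <- 4000
  perm <- replicate(B, {
    swap <- runif(50) < 0.5
    stat(ifelse(swap, xb, xa), ifelse(swap, xa, xb))
  })
  p_perm <- mean(abs(perm - mean(perm)) >= abs(obs - mean(perm)))
  expect_equal(out$p_accuracy, p_perm, tolerance = 0.02)
  # permutation Brown-Forsythe: shuffle group labels
  z <- c(a, b)
  bf_stat <- function(g) {
    z1 <- abs(z[g == 1] - median(z[g == 1]))
    z2 <- abs(z[g == 2] - median(z[g == 2]))
    abs(mean(z1) - mean(z2))
  }
  g0 <- rep(1:2, each = 50)
  obs_bf <- bf_stat(g0)
  perm_bf <- replicate(B, bf_stat(sample(g0)))
  p_bf <- mean(perm_bf >= obs_bf)
  expect_equal(out$p_precision, p_bf, tolerance = 0.02)
})

test_that("comparison counting is exact bookkeeping on the full grid", {
  mk <- function(parameter, dt, sa, sp, ba, bp)
    data.frame(parameter = parameter, dt = dt, p_accuracy = 0.01,
               p_precision = 0.01, sig_accuracy = sa, sig_precision = sp,
               better_accuracy = ba, better_precision = bp,
               stringsAsFactors = FALSE)
  grid <- do.call(rbind, lapply(c(4, 8, 10, 15), function(d)
    rbind(mk("Ktrans", d, TRUE, TRUE, "A", "A"),
          mk("vp", d, TRUE, FALSE, "A", "B"),
          mk("ve", d, FALSE, TRUE, "B", "A"))))
  expect_equal(countSignificant(grid, "accuracy", "A")$count, 8)
  expect_equal(countSignificant(grid, "accuracy", "A")$total, 12)
  expect_equal(countSignificant(grid, "precision", "A")$count, 8)
  expect_equal(countSignificant(grid, "precision", "B")$count, 0)
  restricted <- grid[grid$dt %in% c(10, 15), ]
  expect_equal(countSignificant(restricted, "accuracy", "A",
                                dts = c(10, 15))$total, 6)
  # order independence
  shuffled <- grid[sample(nrow(grid)), ]
  expect_equal(countSignificant(shuffled, "accuracy", "A"),
               countSignificant(grid, "accuracy", "A"))
  expect_error(countSignificant(grid[-1, ], "accuracy", "A"), "grid")
})

test_that("mean absolute difference is the stated consistency metric", {
  expect_equal(meanAbsoluteDifference(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(meanAbsoluteDifference(c(1, 2), c(1.02, 2.02)), 0.02)
  m1 <- array(c(0.1, NA, 0.3, 0.4), c(2, 2))
  m2 <- array(c(0.2, NA, 0.3, 0.5), c(2, 2))
  expect_equal(meanAbsoluteDifference(m1, m2), mean(c(0.1, 0, 0.1)))
  expect_error(meanAbsoluteDifference(1:3, 1:4), "support")
  expect_error(meanAbsoluteDifference(c(1, NA), c(NA, 1)), "NA")
})
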