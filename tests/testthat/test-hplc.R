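test_that("simulator honors its generative area fraction exactly", {
  for (f in c(0.1, 0.363, 0.8)) {
    sim <- simulateChromatogram(SimSpec(f))
    t <- sim$chromatogram@time
    aA <- trapz(t, dgCurve(t, sim$antigenPeak))
    aW <- trapz(t, dgCurve(t, sim$wtPeak))
    expect_equal(aA / (aA + aW), f, tolerance = 1e-6)
    # closed-form areas agree with quadrature
    expect_equal(peakArea(sim$antigenPeak), aA, tolerance = 1e-6)
  }
})

test_that("simulator degenerate cases behave", {
  sim0 <- simulateChromatogram(SimSpec(0))
  expect_equal(sim0$truth, 0)
  expect_equal(sim0$chromatogram@signal,
               dgCurve(sim0$chromatogram@time, sim0$wtPeak),
               tolerance = 1e-12)

  # equal symmetric peaks: trace symmetric about the center midpoint
  simS <- simulateChromatogram(SimSpec(0.5, tailAreaFraction = 0,
                                       sigma2 = 0.18))
  t <- simS$chromatogram@time
  y <- simS$chromatogram@signal
  mid <- 51.3 + 0.3
  for (d in c(0.2, 0.5, 1.0)) {
    yl <- y[which.min(abs(t - (mid - d)))]
    yr <- y[which.min(abs(t - (mid + d)))]
    expect_equal(yl, yr, tolerance = 1e-6)
  }

  # noise is seeded and reproducible
  n1 <- simulateChromatogram(SimSpec(0.3, noiseSd = 0.5, seed = 9))
  n2 <- simulateChromatogram(SimSpec(0.3, noiseSd = 0.5, seed = 9))
  expect_identical(n1$chromatogram@signal, n2$chromatogram@signal)
})

test_that("initializer finds sensible starting centers", {
  sim <- simulateChromatogram(SimSpec(0.136))
  init <- pickInitialParams(sim$chromatogram)
  expect_lt(abs(init@wtPeak@mu1 - 51.3), 0.3)
  expect_lt(abs(init@antigenPeak@mu1 - 51.9), 0.3)

  sim0 <- simulateChromatogram(SimSpec(0))
  init0 <- pickInitialParams(sim0$chromatogram)
  expect_lt(init0@antigenPeak@a1 + init0@antigenPeak@a2,
            0.2 * (init0@wtPeak@a1 + init0@wtPeak@a2))

  flat <- Chromatogram(seq(48, 55, by = 0.01), rep(0, 701))
  expect_error(pickInitialParams(flat), class = "phageDesign_nopeak")
})

test_that("display ratio has its closed-form limits", {
  pk <- DoubleGaussianPeak(10, 3, 51.3, 51.5, 0.2, 0.4)
  same <- new("HplcFit", wtPeak = pk, antigenPeak = pk,
              baseline = c(0, 0), displayRatio = 0.5, rmse = 0,
              converged = TRUE)
  expect_equal(displayRatio(same), 0.5)

  none <- DoubleGaussianPeak(0, 0, 52, 52.2, 0.2, 0.4)
  nofit <- new("HplcFit", wtPeak = pk, antigenPeak = none,
               baseline = c(0, 0), displayRatio = 0, rmse = 0,
               converged = TRUE)
  expect_equal(displayRatio(nofit), 0)

  empty <- new("HplcFit", wtPeak = none, antigenPeak = none,
               baseline = c(0, 0), displayRatio = NA_real_, rmse = 0,
               converged = TRUE)
  expect_error(displayRatio(empty), class = "phageDesign_zeroArea")
})

test_that("noiseless deconvolution recovers generative ratios", {
  for (f in c(0, 0.136, 0.703)) {
    sim <- simulateChromatogram(SimSpec(f))
    fit <- fitDoubleGaussians(sim$chromatogram)
    expect_true(fit@converged)
    expect_lt(abs(fit@displayRatio - f), 0.005 + 0.01 * (f == 0))
    expect_gte(fit@displayRatio, 0)
    expect_lte(fit@displayRatio, 1)
  }
})

test_that("recovered ratio is monotone in the generative fraction", {
  truths <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  recs <- vapply(truths, function(f) {
    fitDoubleGaussians(simulateChromatogram(SimSpec(f))$chromatogram)@displayRatio
  }, numeric(1))
  expect_true(all(diff(recs) >= -1e-6))
})

test_that("the scaled-copy estimator matches the free fit on clean traces", {
  for (f in c(0.136, 0.574)) {
    sim <- simulateChromatogram(SimSpec(f))
    fit <- fitDoubleGaussians(sim$chromatogram, shape = "scaled")
    expect_true(fit@converged)
    expect_lt(abs(fit@displayRatio - f), 0.005)
  }
})
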