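.aziProfile <- function(f, nBins = 90L, label = "corrected") {
  e <- seq(0, 180, length.out = nBins + 1L)
  chi <- (e[-1] + e[-length(e)]) / 2
  new("AzimuthalProfile", chi = chi, intensity = f(chi),
      nPixels = rep(50L, length(chi)), ringLabel = label,
      qWindow = c(0.27, 0.30))
}

test_that("three-ring subtraction is the pointwise half-sum rule", {
  pk <- .aziProfile(function(x) rep(5, length(x)), label = "peak")
  inn <- .aziProfile(function(x) rep(5, length(x)), label = "inner")
  out <- .aziProfile(function(x) rep(5, length(x)), label = "outer")
  corr <- threeRingCorrect(pk, inn, out)
  expect_true(all(abs(corr@intensity) < 1e-12))
  g <- .aziProfile(function(x) exp(-(x - 90)^2 / 450), label = "peak")
  zero <- .aziProfile(function(x) rep(0, length(x)))
  expect_equal(threeRingCorrect(g, zero, zero)@intensity, g@intensity)
  bad <- .aziProfile(function(x) rep(0, length(x)), nBins = 45L)
  expect_error(threeRingCorrect(pk, bad, out), "chi grid")
})

test_that("zero-baseline Gaussian fit recovers exact inputs", {
  prof <- .aziProfile(function(x) 3 * exp(-(x - 90)^2 / (2 * 15^2)))
  fit <- fitAzimuthalGaussian(prof)
  expect_true(fit@fitOk)
  expect_equal(fit@chi0, 90, tolerance = 0.5 * 0.01 * 90)
  expect_equal(fit@angularWidth, 15, tolerance = 0.005 * 15)
  expect_equal(fit@amplitude, 3, tolerance = 0.005 * 3)
})

test_that("fitting handles wrap-around peaks at the 0/180 boundary", {
  prof <- .aziProfile(function(x) {
    d <- pmin(x %% 180, 180 - x %% 180)
    2 * exp(-d^2 / (2 * 12^2))
  })
  fit <- fitAzimuthalGaussian(prof)
  expect_true(fit@fitOk)
  expect_lt(min(fit@chi0, 180 - fit@chi0), 1)
  expect_equal(fit@angularWidth, 12, tolerance = 0.1)
})

test_that("flat profiles give amplitude 0 and rho exactly 0", {
  prof <- .aziProfile(function(x) rep(1.3, length(x)))
  fit <- fitAzimuthalGaussian(prof)
  expect_equal(fit@amplitude, 0)
  expect_identical(rhoParameter(fit), 0)
})

test_that("rho matches the closed form for a contained Gaussian", {
  # zero-baseline Gaussian, SD s fully inside [0, 180):
  # mean = A * s * sqrt(2*pi) / 180, min ~ 0 => rho = 180 / (s * sqrt(2*pi))
  prof <- .aziProfile(function(x) 2 * exp(-(x - 90)^2 / (2 * 20^2)), nBins = 360L)
  fit <- fitAzimuthalGaussian(prof)
  rho <- rhoParameter(fit)
  expect_equal(rho, 180 / (20 * sqrt(2 * pi)), tolerance = 0.01)
  expect_equal(rho, 3.59, tolerance = 0.01)
  # narrower peaks are more aligned: rho monotone decreasing in s
  rhos <- vapply(c(10, 15, 20, 30, 40), function(s) {
    p <- .aziProfile(function(x) exp(-(x - 90)^2 / (2 * s^2)), nBins = 360L)
    rhoParameter(fitAzimuthalGaussian(p))
  }, numeric(1))
  expect_true(all(diff(rhos) < 0))
  # and rho is invariant to intensity scaling
  p10 <- .aziProfile(function(x) 10 * exp(-(x - 90)^2 / (2 * 20^2)), nBins = 360L)
  expect_equal(rhoParameter(fitAzimuthalGaussian(p10)), rho, tolerance = 1e-6)
})

test_that("dead chi bins are excluded, not interpolated", {
  f <- function(x) 2 * exp(-(x - 90)^2 / (2 * 15^2))
  prof <- .aziProfile(f)
  prof@intensity[10:14] <- NA_real_
  fit <- fitAzimuthalGaussian(prof)
  expect_true(fit@fitOk)
  expect_equal(fit@chi0, 90, tolerance = 0.5)
})

test_that("vertical deep-zone fibrils are recovered at chi0 ~ 90", {
  pt <- truthPoint(kappa = 25, chi0_deg = 90)
  res <- analyzeAzimuthal(threeRingProfiles(nfFrame(pt)))
  expect_true(res$fit_ok)
  expect_lt(abs(res$chi0 - 90), 1)
  expect_gt(res$rho, 2.1)
})
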