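# helpers: analytic profiles on the standard grid
.gridProfile <- function(f, qMin = 0.1, qMax = 1.2, nBins = 600L) {
  e <- seq(qMin, qMax, length.out = nBins + 1L)
  qc <- (e[-1] + e[-length(e)]) / 2
  new("RadialProfile", q = qc, intensity = f(qc),
      nPixels = rep(100L, length(qc)))
}

test_that("total intensity is the trapezoidal area", {
  prof <- .gridProfile(function(q) rep(2.5, length(q)))
  expect_equal(totalSaxsIntensity(prof), 2.5 * diff(range(prof@q)))
  expect_error(totalSaxsIntensity(new("RadialProfile", q = c(0.1, 0.2),
                                      intensity = c(NA_real_, NA_real_),
                                      nPixels = c(0L, 0L))),
               "valid bins")
})

test_that("linear background subtraction is exact on a line and recovers a
           Gaussian riding a ramp", {
  lin <- .gridProfile(function(q) 4 - 2 * q)
  seg <- subtractLinearBackground(lin)
  expect_lt(max(abs(seg$intensity)), 1e-12)
  gauss <- function(q) 0.8 * exp(-(q - 0.285)^2 / (2 * 0.003^2))
  mix <- .gridProfile(function(q) gauss(q) + 4 - 2 * q)
  seg2 <- subtractLinearBackground(mix)
  trueArea <- 0.8 * 0.003 * sqrt(2 * pi)
  expect_equal(sum(seg2$intensity) * median(diff(seg2$q)), trueArea,
               tolerance = 0.01)
  expect_error(subtractLinearBackground(lin, qLeft = 0.05), "range")
})

test_that("moment statistics: symmetry, homogeneity, degenerate input", {
  gauss <- function(q) exp(-(q - 0.285)^2 / (2 * 0.003^2))
  seg <- local({
    q <- seq(0.27, 0.30, by = 5e-5)
    data.frame(q = q, intensity = gauss(q))
  })
  st <- momentPeakStats(seg)
  expect_equal(st$qFm, 0.285, tolerance = 1e-5)
  expect_equal(st$sigma, 0.003, tolerance = 1e-3)
  expect_lt(abs(st$skew), 1e-3)
  # scaling by k leaves the moments, scales the area
  sk <- momentPeakStats(transform(seg, intensity = intensity * 7))
  expect_equal(sk$qFm, st$qFm)
  expect_equal(sk$sigma, st$sigma)
  expect_equal(sk$skew, st$skew)
  expect_equal(sk$peakIntensity, 7 * st$peakIntensity)
  # all-zero segment is invalid with undefined stats
  z <- momentPeakStats(transform(seg, intensity = 0))
  expect_false(z$valid)
  expect_true(is.na(z$qFm))
})

test_that("moment estimator agrees with dense-quadrature oracle", {
  # same underlying (skewed) peak sampled on the analysis grid and on a
  # 40x finer grid; moments must agree to < 1e-4 relative
  f <- function(q) exp(-(q - 0.284)^2 / (2 * 0.0035^2)) *
    (1 + 30 * pmax(q - 0.284, 0))
  coarse <- local({
    q <- seq(0.2705, 0.2995, by = 5e-5 * 40)
    momentPeakStats(data.frame(q = q, intensity = f(q)))
  })
  fine <- local({
    q <- seq(0.2705, 0.2995, by = 5e-5)
    momentPeakStats(data.frame(q = q, intensity = f(q)))
  })
  expect_equal(coarse$qFm, fine$qFm, tolerance = 1e-4)
  expect_equal(coarse$sigma, fine$sigma, tolerance = 1e-3)
})

test_that("D-period inverts the peak position for any order", {
  expect_equal(dPeriod(6 * pi / 65.0), 65.0)
  expect_equal(dPeriod(10 * pi / 65.0, n = 5), 65.0)
  expect_equal(dPeriod(0.28647), 65.80, tolerance = 1e-4)
  expect_error(dPeriod(0), "positive")
  expect_error(dPeriod(-1), "positive")
})

test_that("calcified points dominate uncalcified in total intensity", {
  truth <- smallScanTruth(nX = 1)
  pts <- truthPoints(truth)
  cp <- pts[pts$zone == "CP", ][1, ]
  dz <- pts[pts$zone == "DZ", ][1, ]
  tcp <- totalSaxsIntensity(azimuthalIntegrate(nfFrame(cp)))
  tdz <- totalSaxsIntensity(azimuthalIntegrate(nfFrame(dz)))
  expect_gt(tcp, 2 * tdz)
  expect_gt(tcp, 2.0)   # calcified side of the classification threshold
  expect_lt(tdz, 2.0)
})
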