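test_that("intrinsic peak skewness is zero at ratio 1 and monotone in wp/wa", {
  sc <- simulateSkewCurve(65.8, 0.0035, seq(1, 10, by = 1), mode = "peak")
  tab <- skewTable(sc)
  expect_lt(abs(tab$skew[1]), 1e-3)
  expect_false(is.unsorted(tab$skew))
  expect_gt(tab$skew[nrow(tab)], tab$skew[1])
  # moment method underestimates D once the reflection is elongated
  expect_true(all(tab$d_apparent[tab$wp_over_wa > 1] <= 65.8))
  expect_equal(tab$d_apparent[1], 65.8, tolerance = 1e-4)
  # |bias| grows with the ratio
  expect_false(is.unsorted(65.8 - tab$d_apparent))
})

test_that("ring integration matches a brute-force 2D quadrature oracle", {
  wA <- 0.0035; r <- 5; qn <- 6 * pi / 65.8
  m <- fibreDiffractionModel(65.8, wA = wA, wP = r * wA, orders = 3L,
                             amplitudes = 1)
  qs <- seq(qn - 0.012, qn + 0.02, length.out = 2001L)
  # independent path: average layerLineIntensity over a dense azimuth grid
  # (the package integrates over the reflection-local azimuth offset)
  dl <- seq(-pi, pi, length.out = 4001L)[-1]
  brute <- vapply(qs, function(q)
    mean(layerLineIntensity(m, q * sin(dl), q * cos(dl))), numeric(1))
  bSt <- momentPeakStats(data.frame(q = qs, intensity = brute / max(brute)),
                         intensityThreshold = 0)
  curve <- simulateSkewCurve(65.8, wA, r, mode = "peak",
                             windowShift = c(qs[1] - qn, qs[length(qs)] - qn))
  tab <- skewTable(curve)
  expect_equal(tab$skew, bSt$skew, tolerance = 1e-3)
  expect_equal(tab$q0_apparent, bSt$qFm, tolerance = 1e-5)
})

test_that("skew-matched correction closes the loop to < 0.1%", {
  sc <- simulateSkewCurve(65.8, 0.0035, seq(1, 10, by = 0.5))
  tab <- skewTable(sc)
  err <- vapply(seq_len(nrow(tab)), function(i)
    suppressWarnings(correctDPeriod(tab$skew[i], sc, tab$d_apparent[i]))$dCorrected -
      65.8, numeric(1))
  expect_lt(max(abs(err)) / 65.8, 0.001)
  # negligible measured skew leaves the value essentially unchanged
  cr0 <- correctDPeriod(skewTable(sc)$skew[1], sc, 65.806)
  expect_equal(cr0$dCorrected, 65.806, tolerance = 5e-4 * 65.806)
  expect_gte(cr0$dCorrected, 65.806)   # correction never lowers D
})

test_that("correction preserves the ordering of injected D-periods", {
  scA <- simulateSkewCurve(66.0, 0.004, c(1, 4, 8))
  scB <- simulateSkewCurve(65.4, 0.004, c(1, 4, 8))
  ta <- skewTable(scA); tb <- skewTable(scB)
  for (i in 2:3) {
    ca <- correctDPeriod(ta$skew[i], scA, ta$d_apparent[i])$dCorrected
    cb <- correctDPeriod(tb$skew[i], scB, tb$d_apparent[i])$dCorrected
    expect_gt(ca, cb)
  }
})

test_that("out-of-range skews are refused with the uncorrected value", {
  sc <- simulateSkewCurve(65.8, 0.0035, c(1, 2, 3))
  expect_warning(cr <- correctDPeriod(5, sc, 65.5), "outside")
  expect_false(cr$corrected)
  expect_equal(cr$dCorrected, 65.5)
})

test_that("zone-level correction keeps the CP-TB contrast", {
  # apparent zonal values with bone more skewed than plate
  set.seed(4)
  res <- data.frame(zone = factor(rep(c("CP", "TB"), each = 30),
                                  levels = c("SZ", "TZ", "DZ", "CP", "TB", "INVALID")),
                    sigma = rep(c(0.0036, 0.0040), each = 30),
                    skew = rep(c(0.03, 0.06), each = 30) + rnorm(60, 0, 0.003),
                    d_period = rep(c(65.7, 65.0), each = 30) + rnorm(60, 0, 0.02),
                    valid = TRUE)
  tab <- zoneSkewCorrection(res)
  expect_true(all(tab$corrected))
  expect_true(all(tab$d_corrected >= tab$d_apparent))
  dc <- setNames(tab$d_corrected, tab$zone)
  expect_gt(dc[["CP"]], dc[["TB"]])   # contrast maintained after correction
})
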