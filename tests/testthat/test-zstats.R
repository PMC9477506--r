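.fakeResults <- function(zones, values, parameter = "d_period") {
  n <- length(values)
  df <- data.frame(row = seq_len(n), col = 1L, depth_um = seq_len(n) * 40,
                   zone = factor(zones, levels = c("SZ", "TZ", "DZ", "CP",
                                                   "TB", "INVALID")),
                   valid = TRUE)
  df[[parameter]] <- values
  df
}

test_that("zonal means: constants, circular chi0, missing zones", {
  res <- .fakeResults(rep("DZ", 5), rep(66.2, 5))
  sm <- zonalMeans(res, parameters = "d_period")
  expect_equal(sm$mean, 66.2)
  expect_equal(sm$sd, 0)
  expect_equal(sm$n, 5L)
  expect_false("SZ" %in% sm$zone)
  # chi0 straddling the 0/180 wrap averages to 0, not 90
  res2 <- .fakeResults(rep("SZ", 4), c(178, 179, 1, 2), parameter = "chi0")
  sm2 <- zonalMeans(res2, parameters = "chi0")
  expect_lt(min(sm2$mean, 180 - sm2$mean), 1)
})

test_that("paired adjacent-zone test equals one-sample t on differences", {
  set.seed(31)
  sams <- 1:6
  summaries <- do.call(rbind, lapply(sams, function(s) {
    data.frame(sample = s, zone = c("DZ", "CP"), parameter = "d_period",
               n = 50, mean = c(66 + rnorm(1, 0, 0.3), 65.8 + rnorm(1, 0, 0.3)),
               sd = 0.1)
  }))
  out <- pairedAdjacentZoneTests(summaries)
  dzcp <- out[out$pair == "DZ-CP", ]
  a <- summaries$mean[summaries$zone == "DZ"]
  b <- summaries$mean[summaries$zone == "CP"]
  oracle <- t.test(a - b)   # one-sample t on the differences
  expect_equal(dzcp$t_statistic, unname(oracle$statistic))
  expect_equal(dzcp$p_value, oracle$p.value)
  expect_equal(dzcp$n_samples, 6L)
  # pairs with missing zones are flagged underpowered, not fabricated
  expect_true(out$underpowered[out$pair == "SZ-TZ"])
})

test_that("identical zonal means give t = 0, p = 1", {
  summaries <- do.call(rbind, lapply(1:4, function(s)
    data.frame(sample = s, zone = c("CP", "TB"), parameter = "d_period",
               n = 10, mean = c(65.5, 65.5), sd = 0.1)))
  out <- pairedAdjacentZoneTests(summaries)
  cptb <- out[out$pair == "CP-TB", ]
  expect_equal(cptb$t_statistic, 0)
  expect_equal(cptb$p_value, 1)
})

test_that("two-group ANOVA F equals the squared t statistic", {
  set.seed(12)
  res <- .fakeResults(rep(c("CP", "TB"), each = 20),
                      c(rnorm(20, 65.8, 0.1), rnorm(20, 65.0, 0.1)))
  an <- intraSampleAnova(res)
  tt <- t.test(res$d_period[res$zone == "CP"], res$d_period[res$zone == "TB"],
               var.equal = TRUE)
  expect_equal(an$anova$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(an$tukey$stars, "***")
  # identical groups: F ~ 0, all pairs ns
  res0 <- .fakeResults(rep(c("CP", "TB"), each = 20), rep(65.5, 40))
  res0$d_period <- res0$d_period + rep(rnorm(20, 0, 1e-6), 2)
  an0 <- intraSampleAnova(res0)
  expect_lt(an0$anova$F, 1e-6)
  expect_equal(an0$tukey$stars, "ns")
})

test_that("ANOVA excludes degenerate groups with a trace", {
  set.seed(5)
  res <- .fakeResults(c(rep("CP", 10), rep("TB", 10), "DZ"),
                      c(rnorm(10, 65.8, 0.1), rnorm(10, 65, 0.1), 66))
  an <- intraSampleAnova(res)
  expect_equal(attr(an, "excluded_zones"), "DZ")
  expect_error(intraSampleAnova(.fakeResults(c("CP", "TB"), c(1, 2))),
               "at least two zones")
})

test_that("statistics are invariant to point ordering", {
  set.seed(8)
  res <- .fakeResults(sample(rep(c("DZ", "CP", "TB"), each = 15)),
                      rnorm(45, 65.5, 0.3))
  perm <- res[sample(nrow(res)), ]
  expect_equal(zonalMeans(res, parameters = "d_period")$mean,
               zonalMeans(perm, parameters = "d_period")$mean)
  expect_equal(intraSampleAnova(res)$anova$F, intraSampleAnova(perm)$anova$F)
})

test_that("significance stars follow the published coding", {
  expect_equal(significanceStars(c(0.0005, 0.004, 0.04, 0.4)),
               c("***", "**", "*", "ns"))
})

test_that("depth profiles average rows with SEM scaling ~ 1/sqrt(n)", {
  # constant parameter: flat profile, zero SEM
  res <- .fakeResults(rep("DZ", 12), rep(66, 12))
  res$depth_um <- rep(c(100, 140, 180), each = 4)
  prof <- lateralLineProfile(res)
  expect_equal(prof$mean, rep(66, 3))
  expect_equal(prof$sem, rep(0, 3))
  # quadrupling the lateral width halves the SEM (+/- 30%)
  set.seed(77)
  mk <- function(nLat) {
    r <- .fakeResults(rep("DZ", nLat * 40), rnorm(nLat * 40, 66, 0.1))
    r$depth_um <- rep(seq_len(40) * 5, each = nLat)
    mean(lateralLineProfile(r)$sem)
  }
  ratio <- mk(32) / mk(8)
  expect_gt(ratio, 0.5 * 0.7)
  expect_lt(ratio, 0.5 * 1.3)
})
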