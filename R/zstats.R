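# Zonal statistics: per-zone summaries, across-sample paired t-tests on
# adjacent zones, per-sample one-way ANOVA + Tukey HSD, and laterally
# averaged depth profiles. No multiple-testing correction is applied
# across zone pairs or parameters, matching the published protocol.

.adjacentPairs <- list(c("SZ", "TZ"), c("TZ", "DZ"), c("DZ", "CP"), c("CP", "TB"))

.saxsParameters <- c("d_period", "rho", "chi0", "total_intensity", "peak_intensity")

#' Per-zone summary of SAXS parameters
#'
#' Means, SDs and point counts per zone over valid points. Fibril
#' orientation chi0 is averaged with axial circular statistics (modulo
#' 180 degrees) so superficial-zone values straddling 0/180 do not corrupt
#' the mean. Zones absent from the sample are simply missing rows, never
#' zeros.
#'
#' @param results classified per-point results (with `zone` column).
#' @param parameters which parameter columns to summarise.
#' @param sample optional sample identifier stored alongside.
#' @return data.frame: `sample`, `zone`, `parameter`, `n`, `mean`, `sd`.
#' @export
zonalMeans <- function(results, parameters = .saxsParameters, sample = NA) {
  keep <- !is.na(results$zone) & results$zone != "INVALID"
  rows <- list()
  for (zn in intersect(levels(droplevels(results$zone[keep])), setdiff(.zoneLevels, "INVALID"))) {
    df <- results[keep & results$zone == zn, , drop = FALSE]
    for (p in parameters) {
      v <- df[[p]]
      v <- v[is.finite(v)]
      if (!length(v)) next
      if (p == "chi0") {
        mu <- .circularMean180(v)
        s <- sqrt(mean(.axialDiff(v, mu)^2))
      } else {
        mu <- mean(v); s <- sd(v)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sample, zone = zn, parameter = p, n = length(v),
        mean = mu, sd = ifelse(is.na(s), 0, s))
    }
  }
  out <- do.call(rbind, rows)
  out[order(match(out$zone, .zoneLevels)), , drop = FALSE]
}

#' Paired t-tests between adjacent zones across samples
#'
#' Two-tailed paired t-tests on per-sample zonal means for the four
#' adjacent zone pairs SZ-TZ, TZ-DZ, DZ-CP, CP-TB. Each pair uses only
#' samples in which both zones are present; pairs with fewer than
#' `minSamples` complete pairs are flagged underpowered (computed anyway
#' when at least 2 pairs exist).
#'
#' @param summaries row-bound [zonalMeans()] tables with a `sample` column.
#' @param parameter which parameter to test.
#' @param minSamples complete-pair count below which the result is flagged.
#' @return data.frame: `pair`, `parameter`, `n_samples`, `t_statistic`,
#'   `p_value`, `underpowered`, `stars`.
#' @export
pairedAdjacentZoneTests <- function(summaries, parameter = "d_period",
                                    minSamples = 3L) {
  df <- summaries[summaries$parameter == parameter, , drop = FALSE]
  rows <- lapply(.adjacentPairs, function(pr) {
    a <- df[df$zone == pr[1], c("sample", "mean")]
    b <- df[df$zone == pr[2], c("sample", "mean")]
    m <- merge(a, b, by = "sample", suffixes = c("_a", "_b"))
    m <- m[complete.cases(m), , drop = FALSE]
    n <- nrow(m)
    if (n < 2L)
      return(data.frame(pair = paste(pr, collapse = "-"), parameter = parameter,
                        n_samples = n, t_statistic = NA_real_, p_value = NA_real_,
                        underpowered = TRUE, stars = NA_character_))
    d <- m$mean_a - m$mean_b
    if (sd(d) == 0) {
      tt <- list(statistic = c(t = 0), p.value = 1)
    } else {
      tt <- t.test(m$mean_a, m$mean_b, paired = TRUE, alternative = "two.sided")
    }
    data.frame(pair = paste(pr, collapse = "-"), parameter = parameter,
               n_samples = n, t_statistic = unname(tt$statistic),
               p_value = tt$p.value, underpowered = n < minSamples,
               stars = significanceStars(tt$p.value))
  })
  do.call(rbind, rows)
}

#' Per-sample one-way ANOVA with Tukey HSD across zones
#'
#' Fits `parameter ~ zone` over the valid points of one sample, followed by
#' Tukey honestly-significant-difference pairwise comparisons with the
#' conventional star coding. Zones with fewer than 2 points are excluded
#' (recorded in the `excluded_zones` attribute).
#'
#' @param results classified per-point results of one sample.
#' @param parameter parameter column to test.
#' @return list with `anova` (data.frame: `F`, `p`, df) and `tukey`
#'   (data.frame of pairwise comparisons with `diff`, `p_adj`, `stars`).
#' @export
intraSampleAnova <- function(results, parameter = "d_period") {
  keep <- !is.na(results$zone) & results$zone != "INVALID" &
    is.finite(results[[parameter]])
  df <- data.frame(value = results[[parameter]][keep],
                   zone = droplevels(results$zone[keep]))
  cnt <- table(df$zone)
  small <- names(cnt)[cnt < 2L]
  df <- droplevels(df[!(df$zone %in% small), , drop = FALSE])
  if (nlevels(df$zone) < 2L)
    stop("need at least two zones with at least two points each")
  fit <- aov(value ~ zone, data = df)
  an <- summary(fit)[[1]]
  tk <- as.data.frame(TukeyHSD(fit)$zone)
  out <- list(
    anova = data.frame(F = an[["F value"]][1], p = an[["Pr(>F)"]][1],
                       df_between = an[["Df"]][1], df_within = an[["Df"]][2]),
    tukey = data.frame(pair = rownames(tk), diff = tk$diff,
                       p_adj = tk$`p adj`, stars = significanceStars(tk$`p adj`)))
  attr(out, "excluded_zones") <- small
  out
}

#' Laterally averaged depth profile of a parameter
#'
#' Row-wise (constant-depth) mean and standard error of the mean over the
#' valid points of the scan grid, the 1D line-profile representation of a
#' parameter map.
#'
#' @param results per-point results with `depth_um` and the parameter.
#' @param parameter parameter column.
#' @param requireValid use only points flagged valid.
#' @return data.frame: `depth_um`, `n`, `mean`, `sem`.
#' @export
lateralLineProfile <- function(results, parameter = "d_period",
                               requireValid = TRUE) {
  keep <- is.finite(results[[parameter]])
  if (requireValid && "valid" %in% names(results)) keep <- keep & results$valid
  df <- results[keep, , drop = FALSE]
  depths <- sort(unique(df$depth_um))
  rows <- lapply(depths, function(d) {
    v <- df[[parameter]][df$depth_um == d]
    data.frame(depth_um = d, n = length(v), mean = mean(v),
               sem = if (length(v) > 1L) sd(v) / sqrt(length(v)) else 0)
  })
  do.call(rbind, rows)
}
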