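# Five-zone tissue classification from scalar SAXS measures.

.zoneLevels <- c("SZ", "TZ", "DZ", "CP", "TB", "INVALID")

#' Default classification thresholds
#'
#' Total SAXS intensity >= 2.0 a.u. marks calcified tissue; uncalcified
#' points with degree of alignment rho < 2.1 are transitional zone; "around
#' horizontal" / "around vertical" fibril orientations are quantified as
#' +/- 30 degree windows (configurable; no published tolerance exists).
#'
#' @param totalIntensity calcified/uncalcified split (a.u.).
#' @param rhoTz alignment floor separating TZ from the aligned zones.
#' @param szAngleWindow half-window (deg) around 0/180 for SZ.
#' @param dzAngleWindow half-window (deg) around 90 for DZ.
#' @return named list of thresholds.
#' @export
zoneThresholds <- function(totalIntensity = 2.0, rhoTz = 2.1,
                           szAngleWindow = 30, dzAngleWindow = 30) {
  list(totalIntensity = totalIntensity, rhoTz = rhoTz,
       szAngleWindow = szAngleWindow, dzAngleWindow = dzAngleWindow)
}

#' Classify scan points into the five bone-cartilage zones
#'
#' Applies the scalar classification rules pointwise:
#' \enumerate{
#'   \item total SAXS intensity >= threshold: calcified; split into CP
#'     (above `cpTbBoundaryDepth`) and TB (below) by depth;
#'   \item invalid points (collagen peak below the intensity threshold,
#'     e.g. surrounding fluid): INVALID;
#'   \item uncalcified, rho < threshold: TZ (randomly aligned fibrils);
#'   \item uncalcified aligned points above the TZ band with chi0 within
#'     the horizontal window: SZ; below the TZ band within the vertical
#'     window: DZ;
#'   \item anything unresolved falls back to a depth rule (horizontal-ish
#'     orientation above the TZ band -> SZ, otherwise DZ), with the
#'     fallback recorded in the rule trace.
#' }
#' The TZ band reference is the per-column median depth of TZ points
#' (global median where a column has none). A sample genuinely lacking a
#' zone simply has no points with that label; no band is forced.
#'
#' @param results per-point data.frame: columns `row`, `col`, `depth_um`,
#'   `total_intensity`, `rho`, `chi0`, `valid` (output of the analysis
#'   pipeline).
#' @param thresholds list from [zoneThresholds()].
#' @param cpTbBoundaryDepth depth (um) of the calcified-plate /
#'   trabecular-bone demarcation. For synthetic scans the ground-truth
#'   boundary; `NULL` triggers the automatic rule (deepest row of the
#'   topmost contiguous high-intensity band).
#' @return `results` with added columns `zone` (factor) and `rule_trace`,
#'   plus attribute `cp_tb_boundary_depth`.
#' @export
classifyPoints <- function(results, thresholds = zoneThresholds(),
                           cpTbBoundaryDepth = NULL) {
  calc <- is.finite(results$total_intensity) &
    results$total_intensity >= thresholds$totalIntensity
  if (!any(calc)) {
    warning("no calcified points found; CP/TB boundary rules skipped")
    if (is.null(cpTbBoundaryDepth)) cpTbBoundaryDepth <- Inf
  } else if (is.null(cpTbBoundaryDepth)) {
    # automatic demarcation: deepest row of the topmost contiguous band of
    # rows whose majority of points is high-intensity
    byRow <- tapply(calc, results$depth_um, mean)
    depths <- as.numeric(names(byRow))
    hi <- which(byRow >= 0.5)
    if (length(hi)) {
      runEnd <- hi[c(diff(hi) != 1L, TRUE)][1]
      cpTbBoundaryDepth <- depths[runEnd] + 1e-9
    } else cpTbBoundaryDepth <- Inf
  }
  zone <- rep(NA_character_, nrow(results))
  trace <- rep(NA_character_, nrow(results))
  zone[calc] <- ifelse(results$depth_um[calc] <= cpTbBoundaryDepth, "CP", "TB")
  trace[calc] <- "total_intensity>=threshold"
  invalid <- !calc & !results$valid
  zone[invalid] <- "INVALID"
  trace[invalid] <- "below_peak_threshold"
  un <- which(is.na(zone))
  isTz <- un[!is.finite(results$rho[un]) | results$rho[un] < thresholds$rhoTz]
  zone[isTz] <- "TZ"
  trace[isTz] <- "rho<rho_tz"
  # TZ band reference depth per column
  isTzNow <- !is.na(zone) & zone == "TZ"
  tzGlobal <- suppressWarnings(median(results$depth_um[isTzNow], na.rm = TRUE))
  tzDepth <- vapply(results$col, function(cc) {
    d <- results$depth_um[isTzNow & results$col == cc]
    if (length(d)) median(d) else tzGlobal
  }, numeric(1))
  rest <- which(is.na(zone))
  for (i in rest) {
    above <- is.finite(tzDepth[i]) && results$depth_um[i] < tzDepth[i]
    horiz <- .axialDiff(results$chi0[i], 0) <= thresholds$szAngleWindow
    vert <- .axialDiff(results$chi0[i], 90) <= thresholds$dzAngleWindow
    if (isTRUE(above) && isTRUE(horiz)) {
      zone[i] <- "SZ"; trace[i] <- "above_tz_chi0_horizontal"
    } else if (!isTRUE(above) && isTRUE(vert)) {
      zone[i] <- "DZ"; trace[i] <- "below_tz_chi0_vertical"
    } else if (isTRUE(above)) {
      zone[i] <- "SZ"; trace[i] <- "fallback_depth"
    } else {
      zone[i] <- "DZ"; trace[i] <- "fallback_depth"
    }
  }
  results$zone <- factor(zone, levels = .zoneLevels)
  results$rule_trace <- trace
  attr(results, "cp_tb_boundary_depth") <- cpTbBoundaryDepth
  results
}

#' Render the 5-colour zone map
#'
#' @param zoneMap output of [classifyPoints()].
#' @return a ggplot object (tiles coloured by zone, legend embedded,
#'   depth increasing downwards).
#' @export
renderZoneMap <- function(zoneMap) {
  pal <- c(SZ = "#E41A1C", TZ = "#4DAF4A", DZ = "#377EB8",
           CP = "#00CED1", TB = "#FF00FF", INVALID = "grey85")
  df <- as.data.frame(zoneMap)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_um, y = .data$depth_um,
                                   fill = .data$zone)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = pal, drop = FALSE, name = "zone") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (\u00b5m)", y = "depth below surface (\u00b5m)") +
    ggplot2::theme_minimal()
}
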