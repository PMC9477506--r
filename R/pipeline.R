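# End-to-end orchestration: presets, per-frame analysis, streaming scan
# analysis, scan-dataset I/O (TIFF directory + JSON sidecar + ground-truth
# CSV) and parameter maps.
#
# Coordinate convention, fixed project-wide: y/depth is micrometres below
# the articular surface, increasing downward; chi0 is the fibril axis
# angle measured from the horizontal (joint-surface) axis, reported modulo
# 180; on the detector the meridional arcs of a fibril at chi0 appear at
# azimuth chi0 + 90.

#' Analysis parameters of the reduction/analysis pipeline
#'
#' All tunables of the per-frame analysis in one validated list, defaulting
#' to the published constants: I(q) over `[0.1, 1.2]` nm^-1, background
#' anchors at 0.27 / 0.30 nm^-1, collagen-peak validity threshold
#' 0.025 a.u., and the [zoneThresholds()] block.
#'
#' @param qRange radial integration range (nm^-1).
#' @param nBins radial bins.
#' @param qPeak,qInner,qOuter azimuthal ring windows (nm^-1).
#' @param nChiBins azimuthal bins over `[0, 180)`.
#' @param intensityThreshold collagen-peak validity threshold (a.u.).
#' @param order meridional order for the D-period.
#' @param thresholds classification thresholds ([zoneThresholds()]).
#' @return named list.
#' @export
analysisParams <- function(qRange = c(0.1, 1.2), nBins = 600L,
                           qPeak = c(0.27, 0.30), qInner = c(0.24, 0.27),
                           qOuter = c(0.30, 0.33), nChiBins = 90L,
                           intensityThreshold = 0.025, order = 3L,
                           thresholds = zoneThresholds()) {
  stopifnot(qRange[1] < qRange[2], intensityThreshold > 0)
  list(qRange = qRange, nBins = nBins, qPeak = qPeak, qInner = qInner,
       qOuter = qOuter, nChiBins = nChiBins,
       intensityThreshold = intensityThreshold, order = order,
       thresholds = thresholds)
}

#' Analyse a single SAXS frame
#'
#' Reduction plus radial and azimuthal analysis of one detector frame.
#'
#' @param frame a [SaxsFrame-class].
#' @param params [analysisParams()].
#' @param plan optional [reductionPlan()] (built from the frame geometry
#'   when missing).
#' @return one-row data.frame combining [analyzeRadial()] and
#'   [analyzeAzimuthal()].
#' @export
analyzeFrame <- function(frame, params = analysisParams(), plan = NULL) {
  if (is.null(plan))
    plan <- reductionPlan(frame@geometry, params$qRange[1], params$qRange[2],
                          params$nBins, params$qPeak, params$qInner,
                          params$qOuter, params$nChiBins)
  prof <- azimuthalIntegrate(frame, params$qRange[1], params$qRange[2],
                             params$nBins, plan)
  rad <- analyzeRadial(prof, params$qPeak[1], params$qPeak[2],
                       params$intensityThreshold, params$order,
                       qRange = params$qRange)
  rings <- threeRingProfiles(frame, params$qPeak, params$qInner,
                             params$qOuter, params$nChiBins, plan)
  cbind(rad, analyzeAzimuthal(rings))
}

#' Scan presets emulating the beamline protocols
#'
#' Three scan configurations on the desk-scale detector
#' ([reducedGeometry()]):
#' \describe{
#'   \item{regular}{0.8 mm x 2.6 mm at 40 um steps (21 x 66 points), the
#'     full bone-cartilage unit; the n = 6 protocol.}
#'   \item{detailed}{a 45 um x 600 um strip at 5 um steps (9 x 121 points)
#'     across the deep-zone/calcified-plate interface (depths
#'     900-1500 um), resolving the interface D-period dip and plateau.}
#'   \item{full-length}{0.38 mm x 5 mm at 20 um steps (19 x 250 points),
#'     the whole core.}
#' }
#'
#' @param name preset name.
#' @param config zonal configuration (defaults to [bcuZonalConfig()]).
#' @return list with `grid`, `geometry`, `config`, `name`.
#' @export
scanPreset <- function(name = c("regular", "detailed", "full-length"),
                       config = bcuZonalConfig()) {
  name <- match.arg(name)
  grid <- switch(name,
    "regular" = gridSpec(21, 66, 40, 40, originDepth = 20),
    "detailed" = gridSpec(9, 121, 5, 5, originDepth = 900),
    "full-length" = gridSpec(19, 250, 20, 20, originDepth = 20))
  list(grid = grid, geometry = reducedGeometry(), config = config, name = name)
}

#' Analyse a scan point-by-point (streaming closed loop)
#'
#' Renders (or reads) one frame at a time, analyses it, and discards it, so
#' full scans run in constant memory. Per-point failures are isolated: the
#' point is flagged invalid and the scan continues.
#'
#' @param source a [GroundTruthMap-class] (frames rendered on the fly), a
#'   scan-dataset directory (see [writeScanDataset()]), or a list of
#'   [SaxsFrame-class] objects.
#' @param geometry required when `source` is a truth map.
#' @param params [analysisParams()].
#' @param countsScale,seed,model rendering controls (truth-map source).
#' @param grid required when `source` is a frame list.
#' @return per-point results data.frame (`row`, `col`, `x_um`, `depth_um`
#'   plus the [analyzeFrame()] columns).
#' @export
analyzeScan <- function(source, geometry = NULL, params = analysisParams(),
                        countsScale = 100, seed = 1L,
                        model = fibreModelParams(), grid = NULL) {
  if (is.character(source)) {
    ds <- readScanDataset(source)
    return(analyzeScan(ds$frames, params = params, grid = ds$grid))
  }
  if (is(source, "GroundTruthMap")) {
    stopifnot(!is.null(geometry))
    pts <- source@points
    seeds <- .childSeeds(seed, nrow(pts))
    plan <- reductionPlan(geometry, params$qRange[1], params$qRange[2],
                          params$nBins, params$qPeak, params$qInner,
                          params$qOuter, params$nChiBins)
    plan$qSub <- .subPixelQ(geometry)
    getFrame <- function(k) renderFrame(pts[k, ], geometry, countsScale,
                                        seeds[k], model, plan)
    n <- nrow(pts)
    meta <- pts[, c("row", "col", "x_um", "depth_um")]
  } else {
    stopifnot(is.list(source), !is.null(grid))
    n <- length(source)
    stopifnot(n == grid@nX * grid@nY)
    rows <- rep(seq_len(grid@nY), each = grid@nX)
    cols <- rep(seq_len(grid@nX), times = grid@nY)
    meta <- data.frame(row = rows, col = cols,
                       x_um = (cols - 1L) * grid@stepX,
                       depth_um = grid@originDepth + (rows - 1L) * grid@stepY)
    plan <- NULL
    getFrame <- function(k) source[[k]]
  }
  empty <- data.frame(total_intensity = NA_real_, peak_intensity = NA_real_,
                      q0 = NA_real_, sigma = NA_real_, skew = NA_real_,
                      d_period = NA_real_, valid = FALSE, chi0 = NA_real_,
                      angular_width = NA_real_, amplitude = NA_real_,
                      rho = NA_real_, fit_ok = FALSE)
  res <- vector("list", n)
  for (k in seq_len(n)) {
    frame <- getFrame(k)
    if (is.null(plan))
      plan <- reductionPlan(frame@geometry, params$qRange[1], params$qRange[2],
                            params$nBins, params$qPeak, params$qInner,
                            params$qOuter, params$nChiBins)
    res[[k]] <- tryCatch(analyzeFrame(frame, params, plan),
                         error = function(e) empty)
  }
  cbind(meta, do.call(rbind, res))
}

#' Run the full pipeline on a synthetic preset
#'
#' Generation -> reduction -> radial + azimuthal analysis -> zone
#' classification -> zonal summary -> (optional) zone-level skew
#' correction, returned as one result bundle. Deterministic given the
#' seed.
#'
#' @param preset from [scanPreset()], or a list with `grid`, `geometry`,
#'   `config`.
#' @param seed master seed (generation noise and per-sample effects).
#' @param countsScale photons per a.u.; `Inf` for noise-free.
#' @param params [analysisParams()].
#' @param skewCorrection add a zone-level [zoneSkewCorrection()] table.
#' @param sample sample label carried into the summary.
#' @return list: `truth`, `results` (classified), `summary`, `skew`
#'   (or `NULL`), `manifest`.
#' @export
runPipeline <- function(preset = scanPreset("regular"), seed = 1L,
                        countsScale = 100, params = analysisParams(),
                        skewCorrection = FALSE, sample = 1L) {
  truth <- buildGroundTruth(preset$config, preset$grid, seed)
  results <- analyzeScan(truth, preset$geometry, params, countsScale, seed)
  results <- classifyPoints(results, params$thresholds,
                            cpTbBoundaryDepth = if (length(truth@boundaries) >= 4L)
                              truth@boundaries[[4]] else NULL)
  summary <- zonalMeans(results, sample = sample)
  skew <- if (skewCorrection) zoneSkewCorrection(results) else NULL
  manifest <- list(preset = preset$name, seed = seed,
                   countsScale = countsScale,
                   grid = c(nX = preset$grid@nX, nY = preset$grid@nY),
                   nInvalid = sum(results$zone == "INVALID", na.rm = TRUE),
                   nFallback = sum(results$rule_trace == "fallback_depth",
                                   na.rm = TRUE),
                   packageVersion = as.character(utils::packageVersion("bcuSAXS")))
  list(truth = truth, results = results, summary = summary, skew = skew,
       manifest = manifest)
}

#' Write / read a scan dataset as a TIFF directory
#'
#' The on-disk scan format: one 32-bit float TIFF per frame
#' (`frame_000001.tif`, scan order), `metadata.json` (geometry, grid,
#' per-frame intensity scale factors, rendering provenance), `mask.tif`,
#' and `ground_truth.csv` when the scan is synthetic. TIFF float storage
#' is clamped to `[0, 1]`, so each frame is stored divided by its scale
#' factor from the sidecar.
#'
#' @param path dataset directory (created if needed).
#' @param truth a [GroundTruthMap-class].
#' @param geometry a [ScanGeometry-class].
#' @param countsScale,seed,model rendering controls.
#' @return `path`, invisibly.
#' @export
writeScanDataset <- function(path, truth, geometry, countsScale = 100,
                             seed = 1L, model = fibreModelParams()) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  pts <- truth@points
  seeds <- .childSeeds(seed, nrow(pts))
  plan <- list(polar = .detectorPolar(geometry), qSub = .subPixelQ(geometry))
  scales <- numeric(nrow(pts))
  for (k in seq_len(nrow(pts))) {
    fr <- renderFrame(pts[k, ], geometry, countsScale, seeds[k], model, plan)
    d <- fr@data
    d[is.na(d)] <- 0
    scales[k] <- max(d, 1e-12)
    tiff::writeTIFF(d / scales[k], file.path(path, sprintf("frame_%06d.tif", k)),
                    bits.per.sample = 32L, compression = "none", reduce = FALSE)
  }
  tiff::writeTIFF(matrix(as.numeric(geometry@mask), nrow(geometry@mask)),
                  file.path(path, "mask.tif"), bits.per.sample = 8L)
  meta <- list(
    format = "bcuSAXS-scan-1",
    geometry = list(distance_mm = geometry@distance, energy_keV = geometry@energy,
                    pixel_size_um = geometry@pixelSize,
                    detector_shape = geometry@detectorShape,
                    beam_center = geometry@beamCenter),
    grid = list(nX = truth@grid@nX, nY = truth@grid@nY,
                stepX_um = truth@grid@stepX, stepY_um = truth@grid@stepY,
                originDepth_um = truth@grid@originDepth),
    boundaries_um = as.list(truth@boundaries),
    counts_scale = countsScale, seed = seed, nFrames = nrow(pts),
    frame_scales = scales)
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(pts, file.path(path, "ground_truth.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname writeScanDataset
#' @return for `readScanDataset`: list with `frames` (list of
#'   [SaxsFrame-class]), `geometry`, `grid`, `truth` (or `NULL`),
#'   `meta`.
#' @export
readScanDataset <- function(path) {
  metaFile <- file.path(path, "metadata.json")
  if (!file.exists(metaFile)) stop("missing geometry metadata: ", metaFile)
  meta <- jsonlite::read_json(metaFile, simplifyVector = TRUE)
  g <- meta$geometry
  for (f in c("distance_mm", "energy_keV", "pixel_size_um", "detector_shape",
              "beam_center"))
    if (is.null(g[[f]])) stop("scan metadata is missing field '", f, "'")
  maskFile <- file.path(path, "mask.tif")
  mask <- if (file.exists(maskFile)) {
    tiff::readTIFF(maskFile) > 0.5
  } else {
    warning("mask.tif absent; assuming all pixels live")
    NULL
  }
  geometry <- scanGeometry(g$distance_mm, g$energy_keV, g$pixel_size_um,
                           g$detector_shape, g$beam_center, mask)
  grid <- gridSpec(meta$grid$nX, meta$grid$nY, meta$grid$stepX_um,
                   meta$grid$stepY_um, meta$grid$originDepth_um)
  files <- file.path(path, sprintf("frame_%06d.tif", seq_len(meta$nFrames)))
  missing <- which(!file.exists(files))
  if (length(missing))
    stop("scan dataset is missing frame(s): ", paste(missing, collapse = ", "))
  frames <- lapply(seq_along(files), function(k)
    saxsFrame(tiff::readTIFF(files[k]) * meta$frame_scales[k], geometry))
  truthFile <- file.path(path, "ground_truth.csv")
  truth <- if (file.exists(truthFile)) {
    pts <- utils::read.csv(truthFile, stringsAsFactors = FALSE)
    groundTruthMap(grid, pts, unlist(meta$boundaries_um))
  } else NULL
  list(frames = frames, geometry = geometry, grid = grid, truth = truth,
       meta = meta)
}

#' Colour-scale map of a per-point parameter
#'
#' The bitmap representation of a scan parameter, optionally overlaid with
#' orientation glyphs: line segments at angle chi0 with length
#' proportional to rho.
#'
#' @param results per-point results.
#' @param parameter column to map.
#' @param orientationGlyphs overlay chi0/rho glyphs.
#' @param glyphScale glyph half-length (um) at rho = 1.
#' @return a ggplot object.
#' @export
renderParameterMap <- function(results, parameter = "d_period",
                               orientationGlyphs = FALSE, glyphScale = 6) {
  df <- as.data.frame(results)
  df$value <- df[[parameter]]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x_um, y = .data$depth_um,
                                        fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = parameter, na.value = "grey85") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (\u00b5m)", y = "depth below surface (\u00b5m)") +
    ggplot2::theme_minimal()
  if (orientationGlyphs) {
    g <- df[is.finite(df$chi0) & is.finite(df$rho), , drop = FALSE]
    half <- glyphScale * pmin(g$rho, 8) / 2
    p <- p + ggplot2::annotate("segment",
      x = g$x_um - half * cos(g$chi0 * pi / 180),
      xend = g$x_um + half * cos(g$chi0 * pi / 180),
      y = g$depth_um + half * sin(g$chi0 * pi / 180),
      yend = g$depth_um - half * sin(g$chi0 * pi / 180),
      colour = "white", linewidth = 0.3)
  }
  p
}
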