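#' @import methods
NULL

#' Scan geometry of a SAXS detector setup
#'
#' Holds everything needed to map a detector pixel to reciprocal space:
#' sample-detector distance, beam energy, pixel size, detector shape, beam
#' centre and the dead-pixel/beamstop mask.
#'
#' @slot distance sample-detector distance in mm.
#' @slot energy beam energy in keV.
#' @slot pixelSize pixel edge length in micrometres.
#' @slot detectorShape integer vector `(rows, cols)`.
#' @slot beamCenter numeric vector `(row, col)` in (real-valued) pixels.
#' @slot mask logical matrix, `TRUE` = dead pixel / beamstop (excluded).
#' @exportClass ScanGeometry
setClass("ScanGeometry",
  representation(distance = "numeric", energy = "numeric",
                 pixelSize = "numeric", detectorShape = "integer",
                 beamCenter = "numeric", mask = "matrix"),
  validity = function(object) {
    msg <- NULL
    if (length(object@distance) != 1L || object@distance <= 0)
      msg <- c(msg, "distance must be a single positive number (mm)")
    if (length(object@energy) != 1L || object@energy <= 0)
      msg <- c(msg, "energy must be a single positive number (keV)")
    if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
      msg <- c(msg, "pixelSize must be a single positive number (um)")
    if (length(object@detectorShape) != 2L || any(object@detectorShape < 1L))
      msg <- c(msg, "detectorShape must be two positive integers")
    if (length(object@beamCenter) != 2L ||
        any(object@beamCenter < 1) ||
        any(object@beamCenter > object@detectorShape))
      msg <- c(msg, "beamCenter must lie inside the detector bounds")
    if (!is.logical(object@mask) ||
        !identical(dim(object@mask), as.integer(object@detectorShape)))
      msg <- c(msg, "mask must be a logical matrix of shape detectorShape")
    if (is.null(msg)) TRUE else msg
  })

#' Raster grid of a scanning-SAXS measurement
#'
#' @slot nX,nY number of scan columns / rows.
#' @slot stepX,stepY step sizes in micrometres.
#' @slot originDepth depth (um below the articular surface) of the first row.
#' @exportClass GridSpec
setClass("GridSpec",
  representation(nX = "integer", nY = "integer",
                 stepX = "numeric", stepY = "numeric",
                 originDepth = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@nX < 1L || object@nY < 1L) msg <- c(msg, "nX, nY must be >= 1")
    if (object@stepX <= 0 || object@stepY <= 0) msg <- c(msg, "steps must be > 0")
    if (is.null(msg)) TRUE else msg
  })

#' A single 2D SAXS detector frame
#'
#' Pixel intensities are in the pipeline's arbitrary units; masked pixels are
#' stored as `NA` and never contribute to any reduction bin.
#'
#' @slot data numeric matrix of pixel intensities (a.u.).
#' @slot geometry the [ScanGeometry-class] the frame was recorded with.
#' @exportClass SaxsFrame
setClass("SaxsFrame",
  representation(data = "matrix", geometry = "ScanGeometry"),
  validity = function(object) {
    if (!identical(dim(object@data), as.integer(object@geometry@detectorShape)))
      "frame data shape must equal the detector shape" else TRUE
  })

#' Radially integrated 1D profile I(q)
#'
#' @slot q scattering-vector magnitudes (nm^-1, strictly ascending bin centres).
#' @slot intensity mean pixel intensity per bin (a.u.); `NA` where no pixel
#'   contributed.
#' @slot nPixels contributing-pixel count per bin.
#' @exportClass RadialProfile
setClass("RadialProfile",
  representation(q = "numeric", intensity = "numeric", nPixels = "integer"),
  validity = function(object) {
    msg <- NULL
    if (is.unsorted(object@q, strictly = TRUE)) msg <- c(msg, "q must be strictly increasing")
    if (length(object@q) != length(object@intensity) ||
        length(object@q) != length(object@nPixels))
      msg <- c(msg, "q, intensity, nPixels must have equal length")
    if (any(is.finite(object@intensity) & object@nPixels == 0L))
      msg <- c(msg, "intensity must be NA where nPixels == 0")
    if (is.null(msg)) TRUE else msg
  })

#' Azimuthal 1D profile I(chi) restricted to a q ring
#'
#' @slot chi azimuth bin centres in degrees, within `[0, 180)`.
#' @slot intensity mean pixel intensity per bin (a.u.).
#' @slot nPixels contributing-pixel count per bin.
#' @slot ringLabel one of `"peak"`, `"inner"`, `"outer"`, `"corrected"`.
#' @slot qWindow the `(q_lo, q_hi)` window (nm^-1) the ring was averaged over.
#' @exportClass AzimuthalProfile
setClass("AzimuthalProfile",
  representation(chi = "numeric", intensity = "numeric", nPixels = "integer",
                 ringLabel = "character", qWindow = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (is.unsorted(object@chi, strictly = TRUE)) msg <- c(msg, "chi must be strictly increasing")
    if (any(object@chi < 0 | object@chi >= 180)) msg <- c(msg, "chi must lie in [0, 180)")
    if (length(object@chi) != length(object@intensity))
      msg <- c(msg, "chi and intensity must have equal length")
    if (is.null(msg)) TRUE else msg
  })

#' Fibre-diffraction layer-line model of a collagen fibril
#'
#' Each meridional order n contributes a separable bivariate Gaussian
#' ("ellipsoidal") reflection centred at axial wavevector `n * 2*pi / D` with
#' axial SD `wA` and equatorial SD `wP`. `wP` scales inversely with fibril
#' radius, so thin fibrils have elongated reflections and an azimuthally
#' integrated peak with positive (rightward) skew.
#'
#' @slot dPeriod axial D-period in nm.
#' @slot orders integer vector of meridional orders (default 3 and 5).
#' @slot wA axial peak SD (nm^-1).
#' @slot wP equatorial peak SD (nm^-1).
#' @slot amplitudes per-order relative weights.
#' @exportClass FibreDiffractionModel
setClass("FibreDiffractionModel",
  representation(dPeriod = "numeric", orders = "integer",
                 wA = "numeric", wP = "numeric", amplitudes = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@dPeriod <= 0) msg <- c(msg, "dPeriod must be > 0")
    if (object@wA <= 0 || object@wP <= 0) msg <- c(msg, "wA and wP must be > 0")
    if (length(object@amplitudes) != length(object@orders))
      msg <- c(msg, "amplitudes must match orders in length")
    if (is.null(msg)) TRUE else msg
  })

#' Ground-truth parameter map of a synthetic bone-cartilage scan
#'
#' The oracle for closed-loop recovery tests: every scan point's injected
#' D-period, fibril orientation, alignment concentration, mineral fraction,
#' collagen density, layer-line width ratio and tissue zone.
#'
#' @slot grid the [GridSpec-class] of the scan.
#' @slot points data.frame with one row per scan point (columns `row`, `col`,
#'   `x_um`, `depth_um`, `d_period_nm`, `chi0_deg`, `kappa`,
#'   `mineral_fraction`, `collagen_density`, `wp_over_wa`, `zone`).
#' @slot boundaries named numeric depths (um) of the SZ/TZ, TZ/DZ, DZ/CP and
#'   CP/TB transitions, strictly increasing.
#' @exportClass GroundTruthMap
setClass("GroundTruthMap",
  representation(grid = "GridSpec", points = "data.frame", boundaries = "numeric"),
  validity = function(object) {
    msg <- NULL
    need <- c("row", "col", "x_um", "depth_um", "d_period_nm", "chi0_deg",
              "kappa", "mineral_fraction", "collagen_density", "wp_over_wa", "zone")
    if (!all(need %in% names(object@points)))
      msg <- c(msg, paste("points must have columns:", paste(need, collapse = ", ")))
    if (length(object@boundaries) > 1L && is.unsorted(object@boundaries, strictly = TRUE))
      msg <- c(msg, "boundary depths must be strictly increasing")
    if (nrow(object@points) != object@grid@nX * object@grid@nY)
      msg <- c(msg, "points must cover the full grid")
    pts <- object@points
    tissue <- pts$zone != "FLUID"
    if (any(tissue & (pts$d_period_nm < 60 | pts$d_period_nm > 70)))
      msg <- c(msg, "tissue D-periods must lie in [60, 70] nm")
    if (any(pts$chi0_deg < 0 | pts$chi0_deg >= 180)) msg <- c(msg, "chi0 must be in [0, 180)")
    if (any(pts$kappa < 0)) msg <- c(msg, "kappa must be >= 0")
    if (any(pts$wp_over_wa < 1)) msg <- c(msg, "wp_over_wa must be >= 1")
    if (is.null(msg)) TRUE else msg
  })

#' Orientation fit of a background-corrected azimuthal profile
#'
#' @slot chi0 mean fibril orientation (deg in `[0, 180)`, 0 = parallel to the
#'   joint surface).
#' @slot angularWidth Gaussian SD of the azimuthal peak (deg).
#' @slot amplitude fitted peak amplitude (a.u.).
#' @slot rho degree of fibrillar alignment, `(max - min) / mean` of the fitted
#'   curve (NA until computed).
#' @slot fitOk whether the zero-baseline Gaussian fit converged acceptably.
#' @slot relResidual relative fit residual norm.
#' @slot chiGrid the azimuth grid (deg) the profile was fitted on.
#' @exportClass OrientationResult
setClass("OrientationResult",
  representation(chi0 = "numeric", angularWidth = "numeric",
                 amplitude = "numeric", rho = "numeric", fitOk = "logical",
                 relResidual = "numeric", chiGrid = "numeric"))

#' Simulated skew-vs-width-ratio curve for moment-method bias correction
#'
#' @slot wA axial layer-line SD used in the simulation (nm^-1).
#' @slot dPeriodTrue injected true D-period (nm).
#' @slot order meridional order simulated.
#' @slot table data.frame with columns `wp_over_wa`, `skew`, `q0_apparent`,
#'   `q0_shift`, `d_apparent`.
#' @exportClass SkewCurve
setClass("SkewCurve",
  representation(wA = "numeric", dPeriodTrue = "numeric", order = "integer",
                 table = "data.frame"),
  validity = function(object) {
    need <- c("wp_over_wa", "skew", "q0_apparent", "q0_shift", "d_apparent")
    if (!all(need %in% names(object@table)))
      paste("table must have columns:", paste(need, collapse = ", ")) else TRUE
  })

setMethod("show", "ScanGeometry", function(object) {
  cat("ScanGeometry:", paste(object@detectorShape, collapse = " x "),
      sprintf("pixels (%g um), L = %g mm, E = %g keV\n",
              object@pixelSize, object@distance, object@energy))
  cat(sprintf("  beam centre (row, col) = (%.2f, %.2f); %d masked pixels\n",
              object@beamCenter[1], object@beamCenter[2], sum(object@mask)))
})

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d points, steps %g x %g um, first row at %g um depth\n",
              object@nX, object@nY, object@stepX, object@stepY, object@originDepth))
})

setMethod("show", "SaxsFrame", function(object) {
  v <- object@data[is.finite(object@data)]
  cat(sprintf("SaxsFrame: %d x %d pixels, intensity range [%.3g, %.3g] a.u.\n",
              nrow(object@data), ncol(object@data),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
})

setMethod("show", "RadialProfile", function(object) {
  cat(sprintf("RadialProfile: %d bins, q in [%.3g, %.3g] nm^-1 (%d empty)\n",
              length(object@q), min(object@q), max(object@q),
              sum(object@nPixels == 0L)))
})

setMethod("show", "AzimuthalProfile", function(object) {
  cat(sprintf("AzimuthalProfile (%s ring, q in [%.3g, %.3g]): %d chi bins over [0, 180)\n",
              object@ringLabel, object@qWindow[1], object@qWindow[2], length(object@chi)))
})

setMethod("show", "GroundTruthMap", function(object) {
  cat("GroundTruthMap:\n  ")
  show(object@grid)
  cat(sprintf("  zone boundaries (um): %s\n",
              paste(sprintf("%s=%g", names(object@boundaries), object@boundaries),
                    collapse = ", ")))
  print(table(object@points$zone))
})

setMethod("show", "OrientationResult", function(object) {
  cat(sprintf("OrientationResult: chi0 = %.2f deg, width = %.2f deg, rho = %.3g, fitOk = %s\n",
              object@chi0, object@angularWidth, object@rho, object@fitOk))
})

setMethod("show", "SkewCurve", function(object) {
  cat(sprintf("SkewCurve: D_true = %g nm, wA = %g nm^-1, order %d, %d width ratios in [%g, %g]\n",
              object@dPeriodTrue, object@wA, object@order, nrow(object@table),
              min(object@table$wp_over_wa), max(object@table$wp_over_wa)))
})
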