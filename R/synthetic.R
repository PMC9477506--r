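# Synthetic bone-cartilage-unit scan generator.
#
# The forward model for one scan point factorises in detector polar
# coordinates (q, chi):
#
#   I(q, chi) = R(q) * W(chi) + B(q)
#
# R(q) is the azimuthal (constant-|q|) average of the fibril layer-line
# reflections: for each meridional order n an "ellipsoidal" separable
# bivariate Gaussian centred at q_axial = n*2*pi/D with axial SD w_a and
# equatorial SD w_p. Because azimuthal integration commutes with any
# rotation of the pattern, R(q) is exact for every orientation
# distribution; the skew of R(q) for w_p > w_a is the fibre-diffraction
# effect the skew-correction module quantifies. W(chi) is the fibril
# orientation distribution on the detector: a wrapped Gaussian with 180-deg
# periodicity centred at chi0 + 90 whose variance adds the intrinsic
# angular footprint (w_p/q_n) of the reflection; W is normalised to unit
# circular mean so it never changes R(q). B(q) is isotropic diffuse
# scattering: exponential terms scaled by mineral fraction (strong) and
# collagen density (weak) plus a flat instrument floor.

#' Zonal parameter profile for the synthetic bone-cartilage unit
#'
#' Defines the depth profile a virtual bovine bone-cartilage core is built
#' from: per-zone D-period, fibril orientation, alignment concentration,
#' mineral fraction, collagen density and layer-line width ratio, plus the
#' depths of the four zone transitions. Defaults encode the canonical
#' depth-graded structure: zonal D-periods SZ 65.2 / TZ 65.5 / DZ 66.0 /
#' CP 65.8 / TB 65.0 nm, a local D minimum of 65.4 nm right at the DZ/CP
#' interface rising to the 65.8 nm plateau over 70 um, the Benninghof
#' orientation arcade (horizontal fibrils in SZ, unaligned TZ, vertical DZ
#' and CP, unaligned TB), and mineral-driven diffuse intensity in the
#' calcified tissue.
#'
#' @param zones data.frame with one row per zone in depth order; columns
#'   `zone`, `d_period` (nm), `chi0` (deg), `kappa` (alignment
#'   concentration, 0 = isotropic), `mineral` (fraction in `[0,1]`),
#'   `collagen` (relative density), `wp_over_wa` (>= 1).
#' @param boundaries strictly increasing transition depths (um), one fewer
#'   than the number of zones.
#' @param smoothingWidth half-width (um) of the linear blend applied to all
#'   parameters at zone boundaries (and to the D-period at the simple
#'   boundaries).
#' @param interfaceDip list describing the D-period feature at the DZ/CP
#'   interface: `dMin` (nm, the local minimum at the boundary), `dropWidth`
#'   (um, approach on the DZ side), `riseWidth` (um, recovery to the CP
#'   plateau).
#' @param tbDeclineWidth width (um) of the D-period decline from the CP
#'   plateau to the TB value, below the CP/TB boundary.
#' @param betweenSampleSd between-sample SD (nm) of per-zone D-period
#'   offsets, used only when `sampleEffects = TRUE`; a scalar or one value
#'   per zone. The default makes the cartilaginous zones (hydration- and
#'   pre-strain-driven D) more variable across animals than trabecular
#'   bone, whose mineralised-collagen D-period is tightly conserved.
#' @param sampleEffects draw per-zone random D offsets per sample (for
#'   multi-sample statistical simulations). The default `FALSE` injects the
#'   canonical values exactly.
#' @return an object of class `ZonalConfig` (a validated list).
#' @export
#' @examples
#' cfg <- bcuZonalConfig()
#' cfg$zones
bcuZonalConfig <- function(zones = data.frame(
                             zone = c("SZ", "TZ", "DZ", "CP", "TB"),
                             d_period = c(65.2, 65.5, 66.0, 65.8, 65.0),
                             chi0 = c(0, 45, 90, 90, 90),
                             kappa = c(30, 0.2, 25, 20, 0.5),
                             mineral = c(0, 0, 0, 1, 0.7),
                             collagen = c(0.7, 0.85, 1.0, 0.9, 0.6),
                             wp_over_wa = 1),
                           boundaries = c(szTz = 120, tzDz = 400,
                                          dzCp = 1040, cpTb = 1240),
                           smoothingWidth = 20,
                           interfaceDip = list(dMin = 65.4, dropWidth = 40,
                                               riseWidth = 70),
                           tbDeclineWidth = 170,
                           betweenSampleSd = c(0.3, 0.3, 0.35, 0.35, 0.15),
                           sampleEffects = FALSE) {
  nz <- nrow(zones)
  if (nz > 1) {
    if (length(boundaries) != nz - 1L)
      stop("configuration error: need one boundary per zone transition")
    if (is.unsorted(boundaries, strictly = TRUE))
      stop("configuration error: boundary depths must be strictly increasing")
  }
  need <- c("zone", "d_period", "chi0", "kappa", "mineral", "collagen", "wp_over_wa")
  if (!all(need %in% names(zones)))
    stop("zones must have columns: ", paste(need, collapse = ", "))
  structure(list(zones = zones, boundaries = boundaries,
                 smoothingWidth = smoothingWidth, interfaceDip = interfaceDip,
                 tbDeclineWidth = tbDeclineWidth,
                 betweenSampleSd = betweenSampleSd,
                 sampleEffects = sampleEffects),
            class = "ZonalConfig")
}

# piecewise-linear depth profile through ramped per-zone constants
.rampProfile <- function(depth, values, boundaries, h) {
  if (length(values) == 1L) return(rep(values, length(depth)))
  h <- max(h, 1e-9)
  kx <- c(min(depth, 0) - 1, as.vector(rbind(boundaries - h, boundaries + h)),
          max(depth) + 1)
  # knot values: v1 at b1-h, v2 at b1+h, v2 at b2-h, ...
  ky <- c(values[1], as.vector(rbind(values[-length(values)], values[-1])),
          values[length(values)])
  approx(kx, ky, xout = depth, rule = 2)$y
}

# D-period depth profile: ramped zonal constants plus, when a DZ->CP
# transition exists, the interface dip/rise feature, and a finite decline
# into TB below the CP/TB boundary.
.dPeriodProfile <- function(depth, cfg, dZone) {
  z <- cfg$zones
  if (nrow(z) == 1L) return(rep(dZone[1], length(depth)))
  b <- cfg$boundaries
  h <- max(cfg$smoothingWidth, 1e-9)
  iCP <- which(z$zone[-1] == "CP" & z$zone[-nrow(z)] == "DZ")
  iTB <- which(z$zone[-1] == "TB" & z$zone[-nrow(z)] == "CP")
  kx <- min(depth, 0) - 1; ky <- dZone[1]
  for (i in seq_len(nrow(z) - 1L)) {
    if (length(iCP) && i == iCP) {
      dip <- cfg$interfaceDip
      kx <- c(kx, b[i] - dip$dropWidth, b[i], b[i] + dip$riseWidth)
      ky <- c(ky, dZone[i], dip$dMin + (dZone[i + 1] - z$d_period[i + 1]), dZone[i + 1])
    } else if (length(iTB) && i == iTB) {
      kx <- c(kx, b[i], b[i] + cfg$tbDeclineWidth)
      ky <- c(ky, dZone[i], dZone[i + 1])
    } else {
      kx <- c(kx, b[i] - h, b[i] + h)
      ky <- c(ky, dZone[i], dZone[i + 1])
    }
  }
  kx <- c(kx, max(depth) + 1); ky <- c(ky, dZone[nrow(z)])
  o <- order(kx)
  approx(kx[o], ky[o], xout = depth, rule = 2)$y
}

#' Build the ground-truth parameter map for a synthetic scan
#'
#' Evaluates the zonal depth profiles of [bcuZonalConfig()] on a scan grid.
#' All parameters vary with depth only (the cylindrical core geometry makes
#' the tissue structure effectively one-dimensional); zone labels are
#' assigned by depth against the configured boundaries. Deterministic given
#' `seed`; `seed` only matters when `sampleEffects` is enabled.
#'
#' @param config a `ZonalConfig` from [bcuZonalConfig()].
#' @param grid a [GridSpec-class].
#' @param seed integer seed for the per-sample zonal offsets.
#' @return a [GroundTruthMap-class].
#' @export
#' @examples
#' truth <- buildGroundTruth(bcuZonalConfig(), gridSpec(5, 20, 40, 40, 20))
#' truth
buildGroundTruth <- function(config, grid, seed = 1L) {
  z <- config$zones
  nz <- nrow(z)
  dZone <- z$d_period
  if (isTRUE(config$sampleEffects) && any(config$betweenSampleSd > 0)) {
    tau <- rep_len(config$betweenSampleSd, nz)
    dZone <- dZone + .withSeed(seed, rnorm(nz, 0, tau))
  }
  rows <- rep(seq_len(grid@nY), each = grid@nX)
  cols <- rep(seq_len(grid@nX), times = grid@nY)
  depth <- grid@originDepth + (rows - 1L) * grid@stepY
  xum <- (cols - 1L) * grid@stepX
  b <- if (nz > 1) config$boundaries else numeric()
  h <- config$smoothingWidth
  zoneIdx <- if (nz > 1) findInterval(depth, b, left.open = TRUE) + 1L else rep(1L, length(depth))
  pts <- data.frame(
    row = rows, col = cols, x_um = xum, depth_um = depth,
    d_period_nm = .dPeriodProfile(depth, config, dZone),
    chi0_deg = .fold180(.rampProfile(depth, z$chi0, b, h)),
    kappa = .rampProfile(depth, z$kappa, b, h),
    mineral_fraction = .rampProfile(depth, z$mineral, b, h),
    collagen_density = .rampProfile(depth, z$collagen, b, h),
    wp_over_wa = .rampProfile(depth, z$wp_over_wa, b, h),
    zone = z$zone[zoneIdx],
    stringsAsFactors = FALSE)
  bounds <- if (nz > 1) config$boundaries else numeric()
  new("GroundTruthMap", grid = grid, points = pts, boundaries = bounds)
}

#' Construct a ground-truth map directly
#'
#' Low-level constructor for tests and custom scans (e.g. inserting a FLUID
#' margin by zeroing `collagen_density` and `mineral_fraction`).
#'
#' @param grid a [GridSpec-class].
#' @param points per-point parameter data.frame (see [GroundTruthMap-class]).
#' @param boundaries transition depths (um).
#' @return a [GroundTruthMap-class].
#' @export
groundTruthMap <- function(grid, points, boundaries) {
  new("GroundTruthMap", grid = grid, points = points, boundaries = boundaries)
}

#' @rdname groundTruthMap
#' @param truth a [GroundTruthMap-class].
#' @export
truthPoints <- function(truth) truth@points

#' @rdname groundTruthMap
#' @export
truthGrid <- function(truth) truth@grid

#' @rdname groundTruthMap
#' @export
zoneBoundaries <- function(truth) truth@boundaries

#' Construct a fibre-diffraction layer-line model
#'
#' @param dPeriod axial D-period (nm).
#' @param wA axial peak SD (nm^-1).
#' @param wP equatorial peak SD (nm^-1); `wP/wA` encodes the inverse fibril
#'   radius.
#' @param orders meridional orders to include.
#' @param amplitudes per-order relative weights.
#' @return a [FibreDiffractionModel-class].
#' @export
fibreDiffractionModel <- function(dPeriod, wA, wP = wA, orders = c(3L, 5L),
                                  amplitudes = c(1, 0.4)[seq_along(orders)]) {
  new("FibreDiffractionModel", dPeriod = dPeriod, orders = as.integer(orders),
      wA = wA, wP = wP, amplitudes = amplitudes)
}

#' Layer-line intensity of the fibre-diffraction model
#'
#' Evaluates the sum over meridional orders of separable bivariate Gaussian
#' reflections: order n peaks at `q_axial = n * 2 * pi / D`, with axial SD
#' `wA` and equatorial SD `wP`.
#'
#' @param model a [FibreDiffractionModel-class].
#' @param qParallel,qAxial equatorial and axial wavevector components
#'   (nm^-1), vectors of equal length (or one scalar).
#' @return intensity (a.u.), same length as the inputs.
#' @export
#' @examples
#' m <- fibreDiffractionModel(65.8, wA = 0.0035)
#' layerLineIntensity(m, 0, 3 * 2 * pi / 65.8)  # 3rd-order peak centre
layerLineIntensity <- function(model, qParallel, qAxial) {
  out <- 0
  for (i in seq_along(model@orders)) {
    qn <- model@orders[i] * 2 * pi / model@dPeriod
    out <- out + model@amplitudes[i] *
      exp(-(qAxial - qn)^2 / (2 * model@wA^2) -
            qParallel^2 / (2 * model@wP^2))
  }
  out
}

# exponentially scaled modified Bessel I0(z)*exp(-z); R's besselI uses a
# backward recurrence whose cost grows linearly in z, so the (here typical)
# z ~ 1e4 regime switches to the asymptotic expansion (rel. error < 1e-8
# at the z = 50 crossover)
.besselI0Scaled <- function(z) {
  out <- numeric(length(z))
  small <- z < 50
  if (any(small)) out[small] <- besselI(z[small], 0, expon.scaled = TRUE)
  if (any(!small)) {
    zb <- z[!small]
    out[!small] <- (1 + 1 / (8 * zb) + 9 / (128 * zb^2) + 225 / (3072 * zb^3)) /
      sqrt(2 * pi * zb)
  }
  out
}

# Azimuthal (constant-|q|) average of one layer-line order.
# Circular reflections (wP == wA) have the closed form
#   K(q) = I0(q*qn / w^2) * exp(-(q - qn)^2 / (2 w^2))
# (exponentially scaled Bessel keeps this stable); elongated reflections
# are integrated numerically over the azimuth offset.
.ringKernel <- function(q, qn, wA, wP) {
  if (abs(wP - wA) < 1e-12 * wA) {
    out <- numeric(length(q))
    sel <- abs(q - qn) <= 15 * wA   # beyond 15 sigma the kernel is ~0
    if (any(sel)) {
      z <- q[sel] * qn / wA^2
      out[sel] <- .besselI0Scaled(z) * exp(-(q[sel] - qn)^2 / (2 * wA^2))
    }
    out
  } else {
    dmax <- min(pi / 2, 8 * wP / qn + 0.2)
    dl <- seq(-dmax, dmax, length.out = 1501L)
    wts <- rep(1, length(dl)); wts[c(1L, length(dl))] <- 0.5
    ax <- outer(q, cos(dl)); eq <- outer(q, sin(dl))
    v <- exp(-(ax - qn)^2 / (2 * wA^2) - eq^2 / (2 * wP^2))
    as.vector(v %*% wts) * (dl[2] - dl[1]) / (2 * pi)
  }
}

# q-area of a ring kernel (for unit-area normalisation)
.ringKernelArea <- function(qn, wA, wP) {
  qq <- seq(max(qn - 10 * wA, 1e-4), qn + 10 * wA + 30 * wP^2 / qn,
            length.out = 801L)
  .trapz(qq, .ringKernel(qq, qn, wA, wP))
}

# collagen radial profile R(q) of a ground-truth point, normalised so the
# order-3 ring has q-area peakScale * collagen_density (a.u.)
.collagenRadial <- function(q, point, model) {
  if (point$collagen_density <= 0) return(numeric(length(q)) + 0)
  wA <- model$wA
  wP <- wA * point$wp_over_wa
  out <- 0
  for (i in seq_along(model$orders)) {
    qn <- model$orders[i] * 2 * pi / point$d_period_nm
    out <- out + model$orderWeights[i] *
      .ringKernel(q, qn, wA, wP) / .ringKernelArea(qn, wA, wP)
  }
  model$peakScale * point$collagen_density * out
}

# wrapped-Gaussian azimuthal weight, unit circular mean; lobes at chi0 + 90
.angularWeight <- function(chiDeg, chi0, kappa, wP, q3) {
  if (kappa < 1e-6) return(rep(1, length(chiDeg)))
  sigma <- sqrt(1 / kappa + (wP / q3)^2) * 180 / pi
  if (sigma > 250) return(rep(1, length(chiDeg)))
  m0 <- .fold180(chi0 + 90)
  d <- (chiDeg - m0) %% 180
  w <- 0
  for (k in -3:3) w <- w + exp(-(d + 180 * k)^2 / (2 * sigma^2))
  w * 180 / (sqrt(2 * pi) * sigma)
}

# isotropic diffuse background B(q)
.diffuseRadial <- function(q, point, model) {
  model$floor +
    point$mineral_fraction * model$aMineral * exp(-q / model$bMineral) +
    point$collagen_density * model$aCollagen * exp(-q / model$bCollagen)
}

#' Forward-model parameters and arbitrary-unit calibration
#'
#' Collects the rendering constants of the synthetic generator. The
#' amplitudes of the two diffuse terms are calibrated once, analytically,
#' so that a default articular-cartilage point (full collagen density, no
#' mineral) has total SAXS intensity ~1 a.u. and a calcified-plate point
#' ~5 a.u. over the standard `[0.1, 1.2]` nm^-1 window. This pins the
#' pipeline's arbitrary-unit scale so the published thresholds (2.0 a.u.
#' total intensity, 0.025 a.u. collagen peak intensity) are meaningful on
#' synthetic data.
#'
#' @param wA axial layer-line SD (nm^-1); the default 0.0035 puts the
#'   3rd-order peak comfortably inside the `[0.27, 0.30]` background
#'   bracket for all zonal D-periods.
#' @param orders,orderWeights meridional orders rendered and their weights.
#' @param peakScale q-area (a.u.) of the order-3 ring at unit collagen
#'   density.
#' @param floor flat instrument/solvent background (a.u.).
#' @param bMineral,bCollagen decay constants (nm^-1) of the diffuse terms.
#' @param acTotal,cpTotal calibration targets (a.u.) for the uncalcified /
#'   calcified total intensity.
#' @param qWindow q-range (nm^-1) the totals are calibrated over.
#' @return list of model constants with calibrated `aMineral`, `aCollagen`.
#' @export
fibreModelParams <- function(wA = 0.0035, orders = c(3L, 5L),
                             orderWeights = c(1, 0.4), peakScale = 0.25,
                             floor = 0.05, bMineral = 0.25, bCollagen = 0.3,
                             acTotal = 1, cpTotal = 5, qWindow = c(0.1, 1.2)) {
  intExp <- function(b) b * (exp(-qWindow[1] / b) - exp(-qWindow[2] / b))
  span <- diff(qWindow)
  peakArea <- peakScale * sum(orderWeights)
  aCollagen <- max(0, (acTotal - floor * span - peakArea)) / intExp(bCollagen)
  # CP reference point: mineral 1, collagen 0.9
  cpColl <- 0.9
  aMineral <- max(0, (cpTotal - floor * span - cpColl * peakArea -
                        cpColl * aCollagen * intExp(bCollagen))) / intExp(bMineral)
  list(wA = wA, orders = as.integer(orders), orderWeights = orderWeights,
       peakScale = peakScale, floor = floor, bMineral = bMineral,
       bCollagen = bCollagen, aMineral = aMineral, aCollagen = aCollagen,
       qWindow = qWindow)
}

# analytic forward model I(q, chi) for a point (no noise, no mask)
.modelIntensity <- function(q, chi, point, model) {
  q3 <- 3 * 2 * pi / point$d_period_nm
  .collagenRadial(q, point, model) *
    .angularWeight(chi, point$chi0_deg, point$kappa,
                   model$wA * point$wp_over_wa, q3) +
    .diffuseRadial(q, point, model)
}

#' Render one synthetic SAXS detector frame
#'
#' Evaluates the forward model at every unmasked pixel and, unless
#' `countsScale` is infinite, applies Poisson counting noise: expected
#' photon counts are `intensity * countsScale` and the stored frame is
#' counts / countsScale, so pixel values stay on the calibrated
#' arbitrary-unit scale with shot noise shrinking as `countsScale` grows.
#'
#' @param point one scan point: a single-row data.frame (or list) with the
#'   [GroundTruthMap-class] point columns.
#' @param geometry a [ScanGeometry-class].
#' @param countsScale photons per arbitrary unit; `Inf` renders the
#'   noise-free expectation.
#' @param seed integer seed for the counting noise.
#' @param model constants from [fibreModelParams()].
#' @param plan optional precomputed [reductionPlan()] (reused for speed; any
#'   object carrying `$polar` for this geometry works).
#' @return a [SaxsFrame-class].
#' @export
#' @examples
#' pt <- truthPoints(buildGroundTruth(bcuZonalConfig(), gridSpec(1, 1, 40, 40, 500)))
#' frame <- renderFrame(pt, reducedGeometry(), countsScale = 100, seed = 7)
#' frame
renderFrame <- function(point, geometry, countsScale = 100, seed = 1L,
                        model = fibreModelParams(), plan = NULL) {
  stopifnot(countsScale > 0)
  point <- as.list(point)
  polar <- if (!is.null(plan)) plan$polar else .detectorPolar(geometry)
  qSub <- if (!is.null(plan) && !is.null(plan$qSub)) plan$qSub
          else .subPixelQ(geometry)
  # collagen rings are narrow on the pixel scale: integrate them over the
  # pixel area (2x2 Gauss-Legendre); the smooth terms use pixel centres
  coll <- 0
  for (qs in qSub) coll <- coll + .collagenRadial(qs, point, model)
  q3 <- 3 * 2 * pi / point$d_period_nm
  lam <- (coll / length(qSub)) *
    .angularWeight(polar$chi, point$chi0_deg, point$kappa,
                   model$wA * point$wp_over_wa, q3) +
    .diffuseRadial(polar$q, point, model)
  lam[polar$mask] <- 0
  if (is.finite(countsScale)) {
    vals <- .withSeed(seed, rpois(length(lam), lam * countsScale)) / countsScale
  } else {
    vals <- lam
  }
  saxsFrame(matrix(vals, geometry@detectorShape[1], geometry@detectorShape[2]),
            geometry)
}

#' Render a full synthetic scan
#'
#' One frame per grid point, with per-point noise seeds derived
#' deterministically from the master seed. Frames are either returned
#' in-memory (small scans) or written to a TIFF-directory scan dataset with
#' the ground truth alongside (see [writeScanDataset()]).
#'
#' @param truth a [GroundTruthMap-class].
#' @param geometry a [ScanGeometry-class].
#' @param countsScale photons per arbitrary unit (`Inf` = noise-free).
#' @param seed master seed.
#' @param outDir if non-`NULL`, write the dataset there and return the path
#'   invisibly; otherwise return a list of [SaxsFrame-class] objects in scan
#'   order.
#' @param model constants from [fibreModelParams()].
#' @return list of frames, or (invisibly) `outDir`.
#' @export
renderScan <- function(truth, geometry, countsScale = 100, seed = 1L,
                       outDir = NULL, model = fibreModelParams()) {
  pts <- truth@points
  seeds <- .childSeeds(seed, nrow(pts))
  plan <- list(polar = .detectorPolar(geometry), qSub = .subPixelQ(geometry))
  if (is.null(outDir)) {
    return(lapply(seq_len(nrow(pts)), function(k)
      renderFrame(pts[k, ], geometry, countsScale, seeds[k], model, plan)))
  }
  writeScanDataset(outDir, truth, geometry, countsScale, seed, model)
}
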