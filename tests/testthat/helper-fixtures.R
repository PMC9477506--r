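# Shared fixtures. Everything is generated in code; geometries are chosen
# by what the test needs: `tinyGeometry()` for binning/IO mechanics (fast,
# does not resolve the collagen peak), `reducedGeometry()` wherever the
# physics (peak recovery) matters.

tinyGeometry <- function(withMask = FALSE) {
  mask <- if (withMask) detectorMask(c(64L, 64L), c(33.2, 31.7),
                                     beamstopRadius = 2, deadRows = 25L)
  else NULL
  scanGeometry(5800, 14, 2400, c(64L, 64L), c(33.2, 31.7), mask)
}

# a single mid-deep-zone ground-truth point with overridable fields
truthPoint <- function(...) {
  pt <- truthPoints(buildGroundTruth(bcuZonalConfig(),
                                     gridSpec(1, 1, 5, 5, 700)))
  over <- list(...)
  for (nm in names(over)) pt[[nm]] <- over[[nm]]
  pt
}

# noise-free frame for a point on the desk-scale detector
nfFrame <- function(pt, geometry = reducedGeometry(), ...) {
  renderFrame(pt, geometry, countsScale = Inf, seed = 1, ...)
}

# small scan: 2 columns x 5 rows spanning all five zones
smallScanTruth <- function(nX = 2, nY = 5, stepY = 520) {
  buildGroundTruth(bcuZonalConfig(), gridSpec(nX, nY, 40, stepY, 20))
}
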