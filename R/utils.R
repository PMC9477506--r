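# Small numeric helpers shared across modules.

#' @importFrom stats approx rnorm rpois sd median setNames t.test aov TukeyHSD
#'   complete.cases coef resid
#' @importFrom rlang .data
NULL

# X-ray wavelength (nm) from photon energy (keV)
.wavelengthNm <- function(energyKeV) 1.239841984 / energyKeV

# trapezoidal area; x ascending, NA pairs dropped
.trapz <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) stop("need at least two finite points for trapezoidal area")
  sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)
}

# fold an azimuth (deg) into [0, 180)
.fold180 <- function(chi) chi %% 180

# axial (180-degree periodic) circular mean of angles in degrees
.circularMean180 <- function(theta, na.rm = TRUE) {
  if (na.rm) theta <- theta[is.finite(theta)]
  if (!length(theta)) return(NA_real_)
  a <- 2 * theta * pi / 180
  .fold180(atan2(mean(sin(a)), mean(cos(a))) * 180 / pi / 2)
}

# smallest angular distance (deg) between two axial orientations
.axialDiff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# deterministic per-point seed streams derived from a master seed
.childSeeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# evaluate an expression with a temporary RNG state
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# significance stars as used in the supplementary tables
#' Star-code a p-value
#'
#' Encodes p-values with the conventional significance stars:
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, `ns` otherwise.
#'
#' @param p numeric vector of p-values.
#' @return character vector of the same length.
#' @export
#' @examples
#' significanceStars(c(0.0005, 0.004, 0.04, 0.4))
significanceStars <- function(p) {
  out <- rep(NA_character_, length(p))
  ok <- is.finite(p)
  out[ok] <- as.character(cut(p[ok], breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
                              labels = c("***", "**", "*", "ns")))
  out
}

# head/tail without dispatch surprises
head <- utils::head
tail <- utils::tail
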