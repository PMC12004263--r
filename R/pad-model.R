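#' Photoelectron angular distribution (PAD) coefficients
#'
#' Container for the pair (b1, b2) describing a one-photon photoelectron
#' angular distribution, `I^p(theta) = 1 + b1^p P1(cos theta) + b2^p P2(cos theta)`.
#' `b1` is the dichroic (chiral) parameter for circular polarization p = +1;
#' it flips sign on exchange of enantiomer or light handedness and is zero for
#' achiral targets. `b2` is the second-order parameter for p = +/-1, related
#' to the familiar linear-polarization anisotropy parameter by
#' `b2 = -beta/2` (and `b2^0 = beta` for p = 0).
#'
#' @param b1 dichroic parameter for p = +1 (dimensionless).
#' @param b2 second-order parameter for circular polarization. Give either
#'   `b2` or `beta`, not both.
#' @param beta linear-polarization anisotropy parameter, in `[-1, 2]`.
#' @return An object of class `pad_coefficients` with fields `b1`, `b2`,
#'   `beta`.
#' @examples
#' pad_coefficients(b1 = 0.02, beta = 0.5)
#' @export
pad_coefficients <- function(b1 = 0, b2 = NULL, beta = NULL) {
  stopifnot(is.numeric(b1), length(b1) == 1L, is.finite(b1))
  if (!is.null(b2) && !is.null(beta)) {
    if (abs(beta + 2 * b2) > 1e-12)
      stop("inconsistent b2 and beta: b2 must equal -beta/2")
  }
  if (is.null(beta)) beta <- if (is.null(b2)) 0 else -2 * b2
  if (beta < -1 - 1e-9 || beta > 2 + 1e-9)
    stop("non-physical anisotropy: beta must lie in [-1, 2], got ", beta)
  structure(list(b1 = b1, b2 = -beta / 2, beta = beta),
            class = "pad_coefficients")
}

#' @export
print.pad_coefficients <- function(x, ...) {
  cat(sprintf("PAD coefficients: b1 = %g, b2 = %g (beta = %g)\n",
              x$b1, x$b2, x$beta))
  invisible(x)
}

#' Detection geometry
#'
#' Detection angle relative to the photon-propagation axis, plus the analyzer
#' half-acceptance angle. The angle convention is absolute: backward-hemisphere
#' detection at 50 degrees from the axis is represented as `theta_deg = 130`,
#' so that all signs in the PAD algebra follow from `cos(theta)` with no
#' ad-hoc hemisphere flags.
#'
#' @param theta_deg detection angle in degrees, in `[0, 180]`.
#' @param half_acceptance_deg analyzer half-acceptance angle in degrees (>= 0).
#' @return An object of class `pecd_geometry` with fields `theta_deg`,
#'   `half_acceptance_deg`, and a derived `hemisphere` flag
#'   (`"backward"` iff `theta_deg > 90`).
#' @examples
#' geometry(130, 15)   # 50 degrees backward, +/-15 degree acceptance
#' @export
geometry <- function(theta_deg, half_acceptance_deg = 0) {
  stopifnot(is.numeric(theta_deg), length(theta_deg) == 1L,
            is.numeric(half_acceptance_deg), length(half_acceptance_deg) == 1L)
  if (theta_deg < 0 || theta_deg > 180)
    stop("theta_deg must lie in [0, 180]")
  if (half_acceptance_deg < 0) stop("half_acceptance_deg must be >= 0")
  structure(list(theta_deg = theta_deg,
                 half_acceptance_deg = half_acceptance_deg,
                 hemisphere = if (theta_deg > 90) "backward" else "forward"),
            class = "pecd_geometry")
}

#' @export
print.pecd_geometry <- function(x, ...) {
  cat(sprintf("Detection geometry: theta = %g deg (%s hemisphere), half-acceptance = %g deg\n",
              x$theta_deg, x$hemisphere, x$half_acceptance_deg))
  invisible(x)
}

#' Legendre polynomials of order 1 and 2
#'
#' @param n polynomial order, 1 or 2.
#' @param x cosine values in `[-1, 1]` (vectorized).
#' @return `x` for `n = 1`; `(3 x^2 - 1)/2` for `n = 2`.
#' @examples
#' legendre_p(2, cos(54.7356 * pi / 180))  # ~0 at the magic angle
#' @export
legendre_p <- function(n, x) {
  if (!(length(n) == 1L && n %in% c(1, 2)))
    stop("only Legendre orders 1 and 2 are supported")
  if (any(abs(x) > 1 + 1e-9)) stop("cosine values must lie in [-1, 1]")
  if (n == 1) x else (3 * x^2 - 1) / 2
}

#' Normalized PAD intensity
#'
#' Evaluates `I^p(theta) = 1 + b1^p P1(cos theta) + b2^p P2(cos theta)`, with
#' `b1^p = p * b1` (so the b1 term vanishes for linear polarization and flips
#' sign between the two circular polarizations) and `b2^p` equal to `b2` for
#' p = +/-1 and to `beta` for p = 0.
#'
#' @param coef a [pad_coefficients()] object.
#' @param p polarization: +1, -1 (circular) or 0 (linear).
#' @param theta_deg emission angle(s) in degrees from the photon-propagation
#'   axis.
#' @return Normalized intensity (vectorized over `theta_deg`).
#' @examples
#' pad_intensity(pad_coefficients(0.1, beta = 0.5), p = +1, theta_deg = 130)
#' @export
pad_intensity <- function(coef, p, theta_deg) {
  stopifnot(inherits(coef, "pad_coefficients"))
  if (!(length(p) == 1L && p %in% c(-1, 0, 1)))
    stop("polarization p must be one of -1, 0, +1")
  ct <- cos(theta_deg * pi / 180)
  b1p <- p * coef$b1
  b2p <- if (p == 0) coef$beta else coef$b2
  1 + b1p * legendre_p(1, ct) + b2p * legendre_p(2, ct)
}

#' Circular-dichroism asymmetry factor G
#'
#' The difference between the intensities measured with left- and right-handed
#' circularly polarized light divided by their average:
#' `G = 2 b1 P1(cos theta) / (1 + b2 P2(cos theta))`. At the magic angle
#' (`P2 = 0`) this reduces to `G = 2 b1 cos(theta)`, which is negative for
#' positive b1 when the measurement is made in the backward hemisphere.
#'
#' @inheritParams pad_intensity
#' @return The dimensionless asymmetry factor (vectorized over `theta_deg`).
#' @examples
#' asymmetry_G(pad_coefficients(0.05), theta_deg = 125.264)
#' @export
asymmetry_G <- function(coef, theta_deg) {
  stopifnot(inherits(coef, "pad_coefficients"))
  ct <- cos(theta_deg * pi / 180)
  den <- 1 + coef$b2 * legendre_p(2, ct)
  if (any(den <= 0))
    stop("non-physical coefficients: average PAD intensity <= 0 at this angle")
  2 * coef$b1 * legendre_p(1, ct) / den
}

#' Magic angle in degrees
#'
#' The root of the second Legendre polynomial, `arccos(1/sqrt(3))`, at which
#' the PAD is insensitive to b2 and the measured asymmetry isolates b1. The
#' supplementary angle (its backward-hemisphere image, 125.264 degrees) is a
#' root as well since P2 is even in `cos(theta)`.
#'
#' @return The magic angle, 54.7356 degrees.
#' @export
magic_angle_deg <- function() acos(1 / sqrt(3)) * 180 / pi

#' Acceptance-averaged b2 correction factor
#'
#' A near-magic-angle measurement retains a residual b2 contribution in the
#' denominator of the asymmetry factor. Assuming an anisotropy `beta`
#' (so `b2 = -beta/2`), the multiplicative correction on the naive magic-angle
#' b1 estimate is `1 + b2 * <P2(cos theta)>`, with the average taken over the
#' analyzer acceptance window `theta +/- half_acceptance`. The default average
#' is uniform in theta; a solid-angle (sin-theta) weighting is available
#' behind the `weighting` flag.
#'
#' For the conservative upper-limit assumption beta = 0.5 at the 50-degree
#' backward geometry (theta = 130) with +/-15 degrees acceptance, the factor
#' evaluates to 0.97.
#'
#' @param beta_assumed assumed anisotropy parameter, in `[-1, 2]`.
#' @param geom a [geometry()] object.
#' @param weighting `"uniform"` (average uniform in theta) or
#'   `"solid_angle"` (weighted by sin theta).
#' @return Multiplicative factor to apply to a naive magic-angle b1 estimate.
#' @examples
#' b2_correction_factor(0.5, geometry(130, 15))  # ~0.97
#' @export
b2_correction_factor <- function(beta_assumed, geom,
                                 weighting = c("uniform", "solid_angle")) {
  stopifnot(inherits(geom, "pecd_geometry"))
  weighting <- match.arg(weighting)
  if (beta_assumed < -1 - 1e-9 || beta_assumed > 2 + 1e-9)
    stop("beta_assumed must lie in [-1, 2]")
  b2 <- -beta_assumed / 2
  th <- geom$theta_deg
  d <- geom$half_acceptance_deg
  if (th - d < 0 || th + d > 180)
    stop("acceptance window crosses 0 or 180 degrees; not supported")
  if (d == 0) return(1 + b2 * legendre_p(2, cos(th * pi / 180)))
  p2 <- function(t) legendre_p(2, cos(t * pi / 180))
  if (weighting == "uniform") {
    avg <- integrate(p2, th - d, th + d, rel.tol = 1e-10)$value / (2 * d)
  } else {
    w <- function(t) sin(t * pi / 180)
    num <- integrate(function(t) p2(t) * w(t), th - d, th + d, rel.tol = 1e-10)$value
    den <- integrate(w, th - d, th + d, rel.tol = 1e-10)$value
    avg <- num / den
  }
  1 + b2 * avg
}

#' Invert the asymmetry factor to a b1 estimate
#'
#' Inverts the magic-angle relation `G = 2 b1 P1(cos theta)` at the nominal
#' detection angle and then applies the acceptance-averaged b2 correction of
#' [b2_correction_factor()]. With zero half-acceptance this is the exact
#' inverse of [asymmetry_G()].
#'
#' @param G asymmetry factor(s), `|G| < 2`.
#' @param geom a [geometry()] object.
#' @param beta_assumed assumed anisotropy for the residual-b2 correction
#'   (0 disables it).
#' @param weighting passed to [b2_correction_factor()].
#' @return b1 estimate(s), vectorized over `G`.
#' @examples
#' g <- geometry(125.264)
#' b1_from_G(-0.057735, g)  # 0.05
#' @export
b1_from_G <- function(G, geom, beta_assumed = 0,
                      weighting = c("uniform", "solid_angle")) {
  stopifnot(inherits(geom, "pecd_geometry"), is.numeric(G))
  if (any(abs(G) >= 2)) stop("asymmetry factor must satisfy |G| < 2")
  p1 <- cos(geom$theta_deg * pi / 180)
  if (abs(p1) < 1e-12) stop("detection at 90 degrees carries no b1 information")
  G / (2 * p1) * b2_correction_factor(beta_assumed, geom, weighting)
}
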