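# Circular angle arithmetic and von Mises helpers.
#
# All public angles are in degrees; trigonometry is done in radians
# internally. Signed errors follow the convention (-180, 180], positive =
# counter-clockwise.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Canonicalize angles to [0, 360)
#'
#' @param x Numeric vector of angles in degrees.
#' @return Angles wrapped into `[0, 360)`. Wrapping is idempotent.
#' @examples
#' wrap_angle(c(-20, 360, 540))
#' @export
wrap_angle <- function(x) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop("angles must be finite numeric values", call. = FALSE)
  }
  x %% 360
}

#' Signed circular error between a response and a target angle
#'
#' Computes `response - target` on the circle, mapped into the signed range
#' `(-180, 180]`. The boundary case of exact opposition maps to +180 by
#' convention. Positive errors are counter-clockwise of the target.
#'
#' @param response,target Numeric vectors of angles in degrees (recycled).
#' @return Signed errors in degrees, in `(-180, 180]`.
#' @examples
#' wrap_error(10, 10)   # 0
#' wrap_error(350, 10)  # -20
#' wrap_error(190, 10)  # 180
#' @export
wrap_error <- function(response, target) {
  if (!is.numeric(response) || !is.numeric(target) ||
      anyNA(response) || anyNA(target) ||
      any(!is.finite(response)) || any(!is.finite(target))) {
    stop("angles must be finite numeric values", call. = FALSE)
  }
  d <- (response - target) %% 360
  ifelse(d > 180, d - 360, d)
}

#' von Mises density on the 360-degree circle
#'
#' Density per degree of a von Mises distribution with mean direction `mu`
#' and concentration `kappa`, normalised so that it integrates to 1 over a
#' full turn. `kappa = 0` gives the circular uniform density `1/360`.
#'
#' Uses exponentially scaled Bessel functions so large concentrations do not
#' overflow.
#'
#' @param theta Angles at which to evaluate, degrees.
#' @param mu Mean direction, degrees.
#' @param kappa Concentration parameter, dimensionless, `>= 0`.
#' @return Density per degree at `theta`.
#' @examples
#' dvonmises_deg(0, 0, 0)  # 1/360
#' dvonmises_deg(c(-10, 10), 0, 5)  # symmetric about mu
#' @export
dvonmises_deg <- function(theta, mu, kappa) {
  if (length(kappa) != 1L || !is.finite(kappa) || kappa < 0) {
    stop("`kappa` must be a single finite value >= 0", call. = FALSE)
  }
  delta <- deg2rad(theta - mu)
  # exp(k cos d) / (2 pi I0(k)) per radian == exp(k (cos d - 1)) / (2 pi I0(k) e^-k)
  dens_rad <- exp(kappa * (cos(delta) - 1)) /
    (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
  dens_rad * pi / 180
}

# Mean resultant length A(kappa) = I1(kappa) / I0(kappa), scaled Bessels for
# numerical stability at large kappa.
bessel_ratio <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

#' Convert a von Mises concentration to a circular standard deviation
#'
#' Uses the standard mapping `SD = sqrt(-2 * ln(I1(k) / I0(k)))` (radians),
#' reported in degrees. The map is strictly decreasing in `k`: higher
#' concentration means a narrower error distribution.
#'
#' @param kappa Concentration(s), `> 0`.
#' @return Circular standard deviation(s) in degrees.
#' @examples
#' k_to_sd(11.78)  # ~17.07 degrees
#' k_to_sd(10.22)  # ~18.40 degrees
#' @seealso [sd_to_k()] for the inverse.
#' @export
k_to_sd <- function(kappa) {
  if (!is.numeric(kappa) || anyNA(kappa) || any(!is.finite(kappa)) ||
      any(kappa <= 0)) {
    stop("`kappa` must be finite and > 0 (SD is undefined at kappa = 0)",
         call. = FALSE)
  }
  rad2deg(sqrt(-2 * log(bessel_ratio(kappa))))
}

# Invertible range of k_to_sd on the root-finding bracket kappa in
# [1e-6, 1e4]: roughly 0.58 to 308.6 degrees.
.sd_k_bracket <- c(1e-6, 1e4)

#' Convert a circular standard deviation to a von Mises concentration
#'
#' Inverts [k_to_sd()] by bracketed root-finding (bisection via
#' [stats::uniroot()] on `kappa` in `[1e-6, 1e4]`, tolerance 1e-9).
#'
#' @param sd_deg Circular standard deviation(s) in degrees. Must lie inside
#'   the range spanned by the bracket (about 0.58 to 308 degrees).
#' @return Concentration(s) such that `k_to_sd(sd_to_k(x)) == x` to within
#'   1e-6 relative tolerance.
#' @examples
#' sd_to_k(17.07)  # ~11.78
#' sd_to_k(18.4)   # ~10.22
#' @export
sd_to_k <- function(sd_deg) {
  lo <- k_to_sd(.sd_k_bracket[2])
  hi <- k_to_sd(.sd_k_bracket[1])
  if (!is.numeric(sd_deg) || anyNA(sd_deg) || any(!is.finite(sd_deg)) ||
      any(sd_deg <= lo) || any(sd_deg >= hi)) {
    stop(sprintf("`sd_deg` must lie in the invertible range (%.3f, %.3f) degrees",
                 lo, hi), call. = FALSE)
  }
  vapply(sd_deg, function(s) {
    stats::uniroot(function(k) k_to_sd(k) - s,
                   interval = .sd_k_bracket, tol = 1e-9)$root
  }, numeric(1))
}

# von Mises random deviates centred at 0 (radians input-free; returns
# degrees). Best & Fisher (1979) wrapped-Cauchy envelope rejection sampler.
rvonmises_deg <- function(n, kappa) {
  if (kappa < 0) stop("`kappa` must be >= 0", call. = FALSE)
  if (n == 0L) return(numeric(0))
  if (kappa == 0) return(stats::runif(n, -180, 180))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    u2 <- stats::runif(m)
    keep <- (c_ * (2 - c_) - u2 > 0) | (log(c_ / u2) + 1 - c_ >= 0)
    th <- sign(stats::runif(m) - 0.5)[keep] * acos(f[keep])
    take <- min(length(th), n - got)
    if (take > 0L) out[(got + 1L):(got + take)] <- th[seq_len(take)]
    got <- got + take
  }
  rad2deg(out)
}

# Wrapped-normal deviates centred at 0, SD in degrees; returned signed.
rwrappednormal_deg <- function(n, sd_deg) {
  wrap_error(stats::rnorm(n, 0, sd_deg), 0)
}
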