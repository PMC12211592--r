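# Circular-statistics primitives used throughout the package. Phases and
# phase differences are expressed in cycles (range [0, 1)) unless a function
# explicitly works in radians.

#' Wrap values to the interval [0, 1)
#'
#' @param x Numeric vector of phases or phase differences in cycles.
#' @return `x` reduced modulo 1 into `[0, 1)`.
#' @keywords internal
wrap_cycle <- function(x) x %% 1

#' Minimal circular distance between two phases
#'
#' Distance between two points on a circle of unit circumference, i.e. the
#' shorter of the two arcs joining them.
#'
#' @param a,b Numeric vectors of phases in cycles (recycled).
#' @return Non-negative distances in `[0, 0.5]` cycles.
#' @examples
#' circular_delta(0.9, 0.1)  # 0.2, across the wrap
#' circular_delta(0.25, 0.75)  # 0.5, antipodal maximum
#' @export
circular_delta <- function(a, b) {
  d <- abs(a - b) %% 1
  pmin(d, 1 - d)
}

#' Signed minimal circular difference, in (-0.5, 0.5]
#'
#' Wraps `a - b` to its minimal signed representative. The magnitude equals
#' [circular_delta()]; the sign records lead versus lag. Exact antipodes map
#' to +0.5 so that the representative is unique.
#'
#' @param a,b Numeric vectors of phases in cycles (recycled).
#' @return Signed differences in `(-0.5, 0.5]` cycles.
#' @keywords internal
circular_diff_signed <- function(a, b) {
  d <- (a - b) %% 1
  ifelse(d > 0.5, d - 1, d)
}

#' Circular mean and resultant length of phases in cycles
#'
#' @param x Numeric vector of phases in cycles; `NA`s are dropped.
#' @return For `circular_mean`, the mean direction in `[0, 1)` cycles.
#'   For `resultant_length`, the mean resultant length `R` in `[0, 1]`.
#' @examples
#' circular_mean(c(0.9, 0.1))  # 0, not 0.5
#' @export
circular_mean <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  th <- 2 * pi * x
  out <- wrap_cycle(atan2(mean(sin(th)), mean(cos(th))) / (2 * pi))
  # floating-point wrap: values within rounding of a full turn are 0
  if (out >= 1 - 1e-12) out <- 0
  out
}

#' @rdname circular_mean
#' @export
resultant_length <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  th <- 2 * pi * x
  sqrt(mean(sin(th))^2 + mean(cos(th))^2)
}

#' von Mises random deviates
#'
#' Best & Fisher (1979) rejection sampler. Used for simulating phase noise
#' around model-gait phase differences; `kappa = 0` reduces to the uniform
#' distribution on the circle.
#'
#' @param n Number of deviates.
#' @param mu Mean direction, radians.
#' @param kappa Concentration parameter, `>= 0`.
#' @return `n` angles in `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(n >= 0, is.finite(mu))
  if (kappa < 0) stop("`kappa` must be non-negative", call. = FALSE)
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-9) return((stats::runif(n, 0, 2 * pi) + mu) %% (2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- n - length(out)
    u1 <- stats::runif(m)
    u2 <- stats::runif(m)
    u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    out <- c(out, sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1)))
  }
  (out + mu) %% (2 * pi)
}

# Ratio of modified Bessel functions A(kappa) = I1(kappa)/I0(kappa),
# the expected resultant length of a von Mises sample. Exponential scaling
# keeps the ratio finite for large kappa.
bessel_ratio <- function(kappa) {
  ifelse(kappa == 0, 0,
         besselI(kappa, 1, expon.scaled = TRUE) /
           besselI(kappa, 0, expon.scaled = TRUE))
}
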