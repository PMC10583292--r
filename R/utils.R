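# Shared numerical helpers: rotations, quadrature, finite differences,
# deterministic sphere coverings, error functions.

#: gyromagnetic ratio of 1H, rad s^-1 T^-1
GAMMA_1H <- 2.6752218744e8

#' The magic angle, in degrees
#'
#' `acos(1/sqrt(3))`, approximately 54.7356 degrees: the zero of the second
#' Legendre polynomial.  Rotation of the q vector on a cone at this
#' inclination averages the second-rank anisotropy to zero, so it is the
#' default rotation-axis inclination for isotropic encoding.  (The commonly
#' printed value 54.7 is a rounding; using it leaves a residual anisotropy
#' of about 4e-4.)
#'
#' @return The magic angle in degrees.
#' @export
magic_angle <- function() 180 / pi * acos(1 / sqrt(3))

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Elementary rotation matrices (active, right-handed)
#'
#' `rot_z()` and `rot_y()` return the 3x3 active rotation matrices about the
#' laboratory z and y axes. Compositions are applied right to left.
#'
#' @param a rotation angle in radians.
#' @return A 3x3 numeric matrix.
#' @export
rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}

#' @rdname rot_z
#' @export
rot_y <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3)
}

# trapezoidal integral of sampled y on a uniform grid with spacing dx
trapz <- function(y, dx) {
  n <- length(y)
  dx * (sum(y) - 0.5 * (y[1L] + y[n]))
}

# cumulative trapezoidal integral, same length as y, starts at 0
cumtrapz <- function(y, dx) {
  n <- length(y)
  c(0, cumsum((y[-1L] + y[-n]) / 2)) * dx
}

# fourth-order finite-difference derivative on a uniform grid;
# one-sided fourth-order stencils at the four edge points
fd_derivative <- function(y, dx) {
  n <- length(y)
  if (n < 6L) stop("need at least 6 samples for the derivative stencil")
  d <- numeric(n)
  i <- 3:(n - 2L)
  d[i] <- (8 * (y[i + 1L] - y[i - 1L]) - (y[i + 2L] - y[i - 2L])) / (12 * dx)
  d[1L] <- (-25 * y[1L] + 48 * y[2L] - 36 * y[3L] + 16 * y[4L] - 3 * y[5L]) / (12 * dx)
  d[2L] <- (-3 * y[1L] - 10 * y[2L] + 18 * y[3L] - 6 * y[4L] + y[5L]) / (12 * dx)
  d[n - 1L] <- -(-3 * y[n] - 10 * y[n - 1L] + 18 * y[n - 2L] - 6 * y[n - 3L] + y[n - 4L]) / (12 * dx)
  d[n] <- -(-25 * y[n] + 48 * y[n - 1L] - 36 * y[n - 2L] + 16 * y[n - 3L] - 3 * y[n - 4L]) / (12 * dx)
  d
}

#' Deterministic quasi-uniform directions on the unit sphere
#'
#' Fibonacci-lattice point set; used for protocol orientations and as the
#' numerical powder-average orientation ensemble.
#'
#' @param n number of directions.
#' @return An `n` x 3 matrix of unit vectors.
#' @export
sphere_directions <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z)
}

# error function and imaginary error function
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

erfi <- function(x) {
  # Maclaurin series (all terms positive, no cancellation); asymptotic
  # expansion for large argument
  vapply(x, function(xx) {
    if (xx < 0) return(-erfi(-xx))
    if (xx == 0) return(0)
    if (xx <= 6) {
      term <- xx
      s <- xx
      k <- 0
      while (TRUE) {
        k <- k + 1
        term <- term * xx^2 / k
        inc <- term / (2 * k + 1)
        s <- s + inc
        if (inc < 1e-17 * s) break
      }
      2 / sqrt(pi) * s
    } else {
      # e^{x^2}/(x sqrt(pi)) (1 + 1/(2x^2) + 3/(4x^4) + 15/(8x^6))
      ix2 <- 1 / (2 * xx^2)
      exp(xx^2) / (xx * sqrt(pi)) * (1 + ix2 + 3 * ix2^2 + 15 * ix2^3)
    }
  }, numeric(1))
}

# sqrt(pi)/2 * exp(A/3) * erf(sqrt(A))/sqrt(A), continued to A <= 0;
# the powder-average attenuation factor multiplying exp(-b*Diso)
powder_factor <- function(A) {
  vapply(A, function(a) {
    if (abs(a) < 1e-4) {
      # series of sqrt(pi)/2 erf(sqrt A)/sqrt A = 1 - A/3 + A^2/10 - ...
      (1 - a / 3 + a^2 / 10) * exp(a / 3)
    } else if (a > 0) {
      sqrt(pi) / 2 * exp(a / 3) * erf(sqrt(a)) / sqrt(a)
    } else {
      sqrt(pi) / 2 * exp(a / 3) * erfi(sqrt(-a)) / sqrt(-a)
    }
  }, numeric(1))
}

# Haeberlen ordering |lZZ - iso| >= |lXX - iso| >= |lYY - iso|
# returns c(bXX, bYY, bZZ)
haeberlen_order <- function(ev) {
  iso <- mean(ev)
  dev <- abs(ev - iso)
  # largest deviation -> ZZ, smallest -> YY; degenerate deviations broken by
  # descending eigenvalue for continuity at the isotropic point
  ord <- order(-dev, -ev)
  c(XX = ev[ord[2L]], YY = ev[ord[3L]], ZZ = ev[ord[1L]])
}
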