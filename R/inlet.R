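#' Womersley number
#'
#' \eqn{\alpha = R\sqrt{\omega\rho/\mu}}: the ratio of pulsatile inertia
#' to viscous forces in oscillatory pipe flow. Defaults use the
#' Newtonian reference viscosity (0.00345 Pa s) and a blood density of
#' 1050 kg/m3, the values under which the packaged per-case table (T1)
#' is reproduced.
#'
#' @param R Inlet radius, m.
#' @param omega Fundamental angular frequency, rad/s (2*pi for a 1 s
#'   cycle).
#' @param rho Fluid density, kg/m3.
#' @param mu Dynamic viscosity, Pa s.
#' @return Dimensionless Womersley number, linear in `R`.
#' @examples
#' womersley_alpha(0.01157)  # ~16.00
#' @export
womersley_alpha <- function(R, omega = 2 * pi, rho = 1050, mu = 0.00345) {
  if (any(c(R, omega, rho, mu) <= 0))
    stop("all inputs must be positive", call. = FALSE)
  R * sqrt(omega * rho / mu)
}

#' Diameter-based Reynolds number
#'
#' \eqn{Re = 2\rho U R/\mu} for a circular inlet of radius `R`.
#'
#' @param rho Density, kg/m3.
#' @param U Characteristic (mean or peak) velocity, m/s; `U = 0` gives 0.
#' @param R Inlet radius, m.
#' @param mu Dynamic viscosity, Pa s.
#' @return Dimensionless Reynolds number.
#' @export
reynolds <- function(rho = 1050, U, R, mu = 0.00345) {
  if (any(c(rho, R, mu) <= 0) || any(U < 0))
    stop("inputs must be positive (U may be zero)", call. = FALSE)
  2 * rho * U * R / mu
}

# Bessel function J_nu (nu = 0 or 1) of a complex argument, by power
# series. Arguments met in Womersley profiles (|z| up to ~60 at alpha 16,
# 14 modes) keep the alternating series within double range; the largest
# term then exceeds the result by ~1e6, which still leaves ~10 accurate
# digits -- ample for the 0.5% profile tolerances.
besselJ_complex <- function(z, nu = 0) {
  stopifnot(nu %in% c(0, 1))
  term <- (z / 2)^nu / gamma(nu + 1)
  total <- term
  for (k in 1:400) {
    term <- -term * (z / 2)^2 / (k * (k + nu))
    total <- total + term
    if (abs(term) < 1e-18 * abs(total)) break
  }
  total
}

new_inlet_profile <- function(kind, radii, times, u, R, period) {
  structure(list(kind = kind, radii = radii, times = times, u = u,
                 R = R, period = period),
            class = "inlet_profile")
}

#' @export
print.inlet_profile <- function(x, ...) {
  cat(sprintf("<inlet_profile> %s: %d radii x %d times, R = %g m\n",
              x$kind, length(x$radii), length(x$times), x$R))
  invisible(x)
}

check_radii <- function(radii, R) {
  if (any(radii < 0 | radii > R))
    stop("radii must lie in [0, R]", call. = FALSE)
}

#' Parabolic (Poiseuille-shaped) inlet profile
#'
#' \eqn{u(r,t) = 2\,U_{mean}(t)\,[1-(r/R)^2]}: centerline speed twice
#' the instantaneous mean, exact no-slip at the wall, and disc average
#' equal to the waveform at every instant.
#'
#' @param w A [waveform()] of mean velocity.
#' @param R Inlet radius, m.
#' @param radii Radial evaluation points in `[0, R]`; default a uniform
#'   grid of 51 points.
#' @return An `inlet_profile` with speed matrix `u` (radii x times).
#' @export
parabolic_profile <- function(w, R, radii = seq(0, R, length.out = 51)) {
  stopifnot(inherits(w, "waveform"))
  check_radii(radii, R)
  u <- outer(2 * (1 - (radii / R)^2), w$values)
  new_inlet_profile("Parabolic", radii, w$times, u, R, w$period)
}

#' Plug (flat) inlet profile
#'
#' \eqn{u(r,t) = U_{mean}(t)} at every radius: zero spatial variance and
#' disc average equal to the waveform.
#'
#' @inheritParams parabolic_profile
#' @return An `inlet_profile`.
#' @export
plug_profile <- function(w, R, radii = seq(0, R, length.out = 51)) {
  stopifnot(inherits(w, "waveform"))
  check_radii(radii, R)
  u <- matrix(rep(w$values, each = length(radii)), length(radii))
  new_inlet_profile("Plug", radii, w$times, u, R, w$period)
}

#' Womersley pulsatile inlet profile
#'
#' Constructs the analytic oscillatory pipe-flow solution whose disc
#' average reproduces the waveform mode by mode. The waveform is Fourier
#' decomposed into `n_modes` harmonics; mode 0 is carried by a steady
#' Poiseuille profile and each oscillatory mode `n` by the Womersley
#' shape
#' \deqn{F_n(\xi) = \frac{1 - J_0(\Lambda_n \xi)/J_0(\Lambda_n)}
#'                      {1 - 2 J_1(\Lambda_n)/(\Lambda_n J_0(\Lambda_n))},
#'       \qquad \Lambda_n = \alpha\sqrt{n}\, i^{3/2},}
#' with \eqn{\xi = r/R} and \eqn{\alpha = R\sqrt{\omega\rho/\mu}}. The
#' denominator is the disc average of the numerator, so each modal
#' amplitude is calibrated to return exactly the corresponding waveform
#' Fourier coefficient; this is the closed constraint that makes all
#' three inlet profiles share the same instantaneous mean. The axial
#' pressure-gradient amplitude per mode is implied rather than supplied.
#' No-slip is exact at `r = R` (the numerator bracket vanishes).
#'
#' @inheritParams parabolic_profile
#' @param n_modes Number of Fourier modes (default 14, which keeps the
#'   reconstruction of a band-limited waveform within 0.5% of its peak).
#' @param rho Density, kg/m3.
#' @param mu Dynamic viscosity, Pa s (Newtonian reference, regardless of
#'   the bulk rheology model).
#' @return An `inlet_profile`; attribute `alpha` carries the Womersley
#'   number and `reconstruction_dev_rel_peak` the waveform truncation
#'   deviation.
#' @export
womersley_profile <- function(w, R, radii = seq(0, R, length.out = 51),
                              n_modes = 14, rho = 1050, mu = 0.00345) {
  stopifnot(inherits(w, "waveform"))
  check_radii(radii, R)
  alpha <- womersley_alpha(R, 2 * pi / w$period, rho, mu)
  modes <- fourier_decompose(w, n_modes)
  omega <- modes$omega
  xi <- radii / R
  u <- outer(2 * (1 - xi^2), rep(Re(modes$coefficients[1]),
                                 length(w$times)))
  if (n_modes >= 1) {
    i32 <- exp(1i * 3 * pi / 4)
    for (n in seq_len(n_modes)) {
      cn <- modes$coefficients[n + 1]
      if (abs(cn) == 0) next
      Lam <- alpha * sqrt(n) * i32
      J0L <- besselJ_complex(Lam, 0)
      if (!is.finite(abs(J0L)))
        stop("Bessel evaluation overflowed; reduce alpha or n_modes",
             call. = FALSE)
      shape <- (1 - vapply(Lam * xi, function(z)
        besselJ_complex(z, 0), complex(1)) / J0L) /
        (1 - 2 * besselJ_complex(Lam, 1) / (Lam * J0L))
      u <- u + Re(outer(cn * shape, exp(1i * n * omega * w$times)))
    }
  }
  out <- new_inlet_profile("Womersley", radii, w$times, u, R, w$period)
  attr(out, "alpha") <- alpha
  attr(out, "reconstruction_dev_rel_peak") <- modes$max_deviation_rel_peak
  out
}

#' Disc-averaged velocity of an inlet profile
#'
#' Cross-sectional mean \eqn{(2/R^2)\int_0^R u\, r\, dr} per time step.
#' The integral is evaluated as \eqn{\int_0^1 u\, dv} in the area
#' variable \eqn{v = (r/R)^2} by trapezoidal quadrature, which is exact
#' for profiles linear in \eqn{v} (plug and parabolic) and
#' second-order-accurate otherwise; use a radial grid of a few hundred
#' points when sub-0.1% accuracy is needed for high-Womersley-number
#' profiles.
#'
#' @param profile An `inlet_profile`.
#' @return Numeric vector of means, one per time sample.
#' @export
profile_mean <- function(profile) {
  v <- (profile$radii / profile$R)^2
  w <- v * 0
  dv <- diff(v)
  w[-length(v)] <- w[-length(v)] + dv / 2
  w[-1] <- w[-1] + dv / 2
  as.numeric(colSums(profile$u * w))
}
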