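#' Construct a periodic mean-velocity waveform
#'
#' A waveform is one period of the cross-sectionally averaged inlet
#' velocity of a cardiac cycle, sampled on a uniform time grid. By the
#' periodic convention the grid covers `[0, T)`: the sample at `t = T`
#' would duplicate the one at `t = 0` and is not stored.
#'
#' @param times Sample times in seconds, strictly increasing, uniformly
#'   spaced, starting at 0 and ending strictly before `period`.
#' @param values Mean axial velocity at each sample, m/s.
#' @param period Cycle period T in seconds.
#' @return An object of class `waveform` with fields `times`, `values`
#'   and `period`.
#' @seealso [make_waveform()] for a deterministic synthetic pulse.
#' @export
waveform <- function(times, values, period = 1) {
  if (length(times) != length(values))
    stop("`times` and `values` must have equal length", call. = FALSE)
  if (length(times) < 8L)
    stop("a waveform needs at least 8 samples per period", call. = FALSE)
  dt <- diff(times)
  if (any(dt <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  if (max(abs(dt - dt[1])) > 1e-9 * dt[1])
    stop("`times` must be uniformly spaced", call. = FALSE)
  if (times[1] != 0 || times[length(times)] >= period)
    stop("`times` must start at 0 and end strictly before `period`",
         call. = FALSE)
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 period = as.numeric(period)),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples over T = %g s, mean %.4g m/s, peak %.4g m/s\n",
              length(x$times), x$period, mean(x$values), max(x$values)))
  invisible(x)
}

#' Deterministic synthetic cardiac waveform
#'
#' Builds a band-limited pulse with prescribed time-averaged velocity and
#' peak-to-mean ratio, standing in for a measured cardiac flow waveform.
#' The shape is the raised trigonometric pulse
#' \deqn{u(t) = \bar{U}\,[1 + A\, g(t)], \quad
#'       g(t) = \frac{\cos^{2m}(\pi (t - t_0)/T) - \bar{c}}{1 - \bar{c}},}
#' where \eqn{m} is `n_harmonics`, \eqn{\bar c = \binom{2m}{m}/4^m} is the
#' exact time average of \eqn{\cos^{2m}}, and \eqn{A =} `peak_ratio` − 1.
#' `g` is a zero-mean trigonometric polynomial with `n_harmonics`
#' harmonics and unit maximum, so the returned waveform has time average
#' exactly `mean` (the discrete average over the uniform grid is exact
#' because every harmonic below the sample count averages to zero) and
#' max/mean exactly `peak_ratio` (the peak time is snapped to the grid).
#'
#' The defaults emulate the study conditions of an abdominal aortic
#' aneurysm inlet: period 1 s, 200 samples (time step 0.005 s), mean
#' speed 0.0647 m/s and peak/mean ratio 4.483 (peak Reynolds over mean
#' Reynolds of the reference case).
#'
#' @param mean Time-averaged velocity, m/s; must be > 0.
#' @param peak_ratio Ratio max/mean, >= 1.
#' @param period Cycle period T, s.
#' @param n_samples Number of uniform samples over one period (>= 8).
#' @param n_harmonics Number of harmonics in the pulse (band limit);
#'   0 yields a constant waveform (only attainable for `peak_ratio = 1`).
#' @param peak_time Nominal time of the systolic peak, s; snapped to the
#'   nearest grid point.
#' @return A [waveform()].
#' @examples
#' w <- make_waveform()
#' c(mean(w$values), max(w$values) / mean(w$values))
#' @export
make_waveform <- function(mean = 0.0647, peak_ratio = 4.483, period = 1,
                          n_samples = 200, n_harmonics = 10,
                          peak_time = 0.2 * period) {
  if (mean <= 0) stop("`mean` must be positive", call. = FALSE)
  if (peak_ratio < 1) stop("`peak_ratio` must be >= 1", call. = FALSE)
  if (n_samples < 8) stop("need at least 8 samples", call. = FALSE)
  if (n_harmonics < 0) stop("`n_harmonics` must be >= 0", call. = FALSE)
  if (n_harmonics == 0 && peak_ratio > 1)
    stop("peak_ratio > 1 is unattainable with 0 harmonics", call. = FALSE)
  if (2 * n_harmonics >= n_samples)
    stop("`n_samples` must exceed twice the harmonic count", call. = FALSE)
  times <- period * (seq_len(n_samples) - 1) / n_samples
  if (n_harmonics == 0) return(waveform(times, rep(mean, n_samples), period))
  t0 <- times[which.min(abs(times - peak_time))]
  m <- n_harmonics
  cbar <- choose(2 * m, m) / 4^m
  g <- (cos(pi * (times - t0) / period)^(2 * m) - cbar) / (1 - cbar)
  waveform(times, mean * (1 + (peak_ratio - 1) * g), period)
}

#' Fourier decomposition of a waveform
#'
#' Computes complex modal coefficients `c_n`, `n = 0..n_modes`, such that
#' \eqn{u(t) \approx \mathrm{Re}\sum_n c_n e^{i n \omega t}} with
#' \eqn{\omega = 2\pi/T}. `c_0` is real and equals the discrete time
#' average. The maximum pointwise reconstruction deviation (absolute,
#' and relative to the waveform peak) is reported so the caller can
#' verify the truncation: the default 14-mode pipeline requires the
#' relative deviation to stay below 0.5 % of the peak.
#'
#' @param w A [waveform()].
#' @param n_modes Number of oscillatory modes retained (`<= n_samples/2`).
#' @return A list of class `waveform_modes`: `coefficients` (complex,
#'   length `n_modes + 1`, mode 0 first), `omega`, `period`,
#'   `max_deviation` (m/s) and `max_deviation_rel_peak`.
#' @export
fourier_decompose <- function(w, n_modes = 14) {
  stopifnot(inherits(w, "waveform"))
  n <- length(w$values)
  if (n_modes < 0 || n_modes > floor(n / 2))
    stop("`n_modes` must lie in [0, n_samples/2]", call. = FALSE)
  X <- fft(w$values) / n
  coef <- complex(real = numeric(n_modes + 1))
  coef[1] <- Re(X[1])
  if (n_modes >= 1) coef[2:(n_modes + 1)] <- 2 * X[2:(n_modes + 1)]
  recon <- reconstruct_modes(coef, w$times, w$period)
  dev <- max(abs(recon - w$values))
  structure(list(coefficients = coef, omega = 2 * pi / w$period,
                 period = w$period, max_deviation = dev,
                 max_deviation_rel_peak = dev / max(abs(w$values))),
            class = "waveform_modes")
}

#' Evaluate a truncated Fourier series
#'
#' @param coefficients Complex coefficients `c_0..c_N` as produced by
#'   [fourier_decompose()].
#' @param times Evaluation times, s.
#' @param period Period T, s.
#' @return Real velocity values at `times`.
#' @export
reconstruct_modes <- function(coefficients, times, period) {
  omega <- 2 * pi / period
  n <- seq_along(coefficients) - 1
  vapply(times, function(t)
    sum(Re(coefficients * exp(1i * n * omega * t))), numeric(1))
}
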