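#' Synthetic surface WSS field with analytic index targets
#'
#' Generates a per-element WSS vector time series
#' \deqn{\mathbf{WSS}_i(t) = m_i\,\hat d_i +
#'       a_i \sin(2\pi t/T + \phi_i)\,\hat e_i,}
#' where \eqn{\hat e_i = \hat d_i} in `"aligned"` mode and
#' \eqn{\hat e_i \perp \hat d_i} in `"orthogonal"` mode. Aligned
#' elements admit closed-form index values, attached as the
#' `ground_truth` attribute: for \eqn{m \ge a} the magnitude never
#' changes sign so \eqn{TAWSS = m} and \eqn{OSI = 0} (for
#' \eqn{\phi}-independent); for \eqn{m < a},
#' \deqn{TAWSS = \frac{2}{\pi}\left[\sqrt{a^2-m^2} +
#'       m\,\arcsin(m/a)\right], \qquad
#'       OSI = \frac{1}{2}\left(1 - \frac{m}{TAWSS}\right).}
#' In particular \eqn{m = 0} gives \eqn{TAWSS = 2a/\pi}, \eqn{OSI = 0.5}.
#'
#' Directions are fixed unit vectors along the coordinate axes unless
#' `random_directions = TRUE`, in which case each element receives a
#' uniformly random unit direction (ground truth is unaffected: the
#' indices are rotation invariant per element).
#'
#' @param n_elements Number of surface elements (>= 1).
#' @param steady Steady magnitude `m` per element, Pa (recycled).
#' @param amplitude Oscillation amplitude `a` per element, Pa (recycled).
#' @param phase Phase offset per element, rad (recycled).
#' @param direction_mode `"aligned"` or `"orthogonal"`.
#' @param n_times Time samples over one period.
#' @param period Cycle period T, s.
#' @param areas Element areas, m2; default all 1.
#' @param random_directions Draw a random base direction per element.
#' @param seed Integer seed used when `random_directions = TRUE`;
#'   identical seed gives identical output.
#' @return A [surface_wss_field()] with attribute `ground_truth`
#'   (a `data.frame` of analytic `tawss`/`osi` for aligned mode, `NULL`
#'   otherwise).
#' @export
make_wss_field <- function(n_elements, steady = 1, amplitude = 0,
                           phase = 0,
                           direction_mode = c("aligned", "orthogonal"),
                           n_times = 200, period = 1, areas = NULL,
                           random_directions = FALSE, seed = NULL) {
  direction_mode <- match.arg(direction_mode)
  if (n_elements < 1) stop("need at least one element", call. = FALSE)
  m <- rep_len(steady, n_elements)
  a <- rep_len(amplitude, n_elements)
  ph <- rep_len(phase, n_elements)
  if (any(m < 0) || any(a < 0))
    stop("magnitudes must be non-negative", call. = FALSE)
  if (is.null(areas)) areas <- rep(1, n_elements)
  times <- period * (seq_len(n_times) - 1) / n_times

  if (random_directions) {
    if (!is.null(seed)) set.seed(seed)
    v <- matrix(rnorm(3 * n_elements), ncol = 3)
    d <- v / sqrt(rowSums(v^2))
    # any unit vector orthogonal to d
    helper <- cbind(-d[, 2], d[, 1], 0)
    deg <- abs(helper[, 1]) + abs(helper[, 2]) < 1e-12
    helper[deg, ] <- matrix(rep(c(1, 0, 0), sum(deg)), ncol = 3,
                            byrow = TRUE)
    e_orth <- helper / sqrt(rowSums(helper^2))
  } else {
    d <- matrix(rep(c(1, 0, 0), n_elements), ncol = 3, byrow = TRUE)
    e_orth <- matrix(rep(c(0, 1, 0), n_elements), ncol = 3, byrow = TRUE)
  }
  e <- if (direction_mode == "aligned") d else e_orth

  osc <- sin(outer(ph, 2 * pi * times / period, `+`))  # n_elem x n_times
  wss <- array(0, dim = c(n_elements, n_times, 3))
  for (k in 1:3)
    wss[, , k] <- m * d[, k] + a * e[, k] * osc

  gt <- NULL
  if (direction_mode == "aligned") {
    tw <- m
    sgn <- a > m  # magnitude changes sign over the cycle
    tw[sgn] <- (2 / pi) * (sqrt(a[sgn]^2 - m[sgn]^2) +
                             m[sgn] * asin(m[sgn] / a[sgn]))
    os <- rep(NA_real_, n_elements)
    pos <- tw > 0
    os[pos] <- pmin(pmax(0.5 * (1 - m[pos] / tw[pos]), 0), 0.5)
    gt <- data.frame(tawss = tw, osi = os)
  }
  out <- surface_wss_field(wss, areas, times, period)
  attr(out, "ground_truth") <- gt
  out
}

#' Synthetic cross-sectional plane with known flow-metric ground truth
#'
#' Builds a tessellated circular plane of radius `R` (Cartesian cells of
#' side `2R/n_cells` clipped to the disc) carrying one of three speed
#' patterns:
#' \describe{
#'   \item{`centered_parabolic`}{\eqn{u = v_{max}(1 - (r/R)^2)}: by
#'     symmetry the high-velocity band is centred, so asymmetry is 0;
#'     the band `u >= 0.85 vmax` is the disc `r <= R sqrt(0.15)`, so
#'     dispersion is 15% (for the default band fraction).}
#'   \item{`offset_jet`}{Gaussian jet of width `sigma` centred at
#'     `offset` from the plane centre. For a jet fully inside the plane
#'     the band is a disc of radius \eqn{r_b = \sigma\sqrt{2\ln(1/0.85)}}
#'     around the jet centre, so asymmetry is
#'     \eqn{100\,\|offset\|/R_{eq}} and dispersion
#'     \eqn{100\,\pi r_b^2/A}.}
#'   \item{`uniform`}{Constant speed: asymmetry 0, dispersion 100.}
#' }
#' The analytic values (continuum limit) are attached as the
#' `ground_truth` attribute; tessellated estimates converge to them as
#' `n_cells` grows.
#'
#' @param kind Pattern name.
#' @param R Plane radius, m.
#' @param n_cells Cells per diameter of the tessellation.
#' @param vmax Peak speed, m/s.
#' @param offset Length-2 in-plane offset of the jet centre, m.
#' @param sigma Gaussian jet width, m.
#' @param fraction Band fraction the ground truth refers to.
#' @return A [plane_velocity_field()] with attribute `ground_truth`
#'   (list `fA`, `fD` in percent).
#' @export
make_plane_field <- function(kind = c("centered_parabolic", "offset_jet",
                                      "uniform"),
                             R = 0.01, n_cells = 101, vmax = 1,
                             offset = c(0.5 * R, 0), sigma = 0.1 * R,
                             fraction = 0.15) {
  kind <- match.arg(kind)
  if (R <= 0 || n_cells < 3) stop("degenerate plane geometry", call. = FALSE)
  h <- 2 * R / n_cells
  ctr <- h * (seq_len(n_cells) - (n_cells + 1) / 2)
  g <- expand.grid(x = ctr, y = ctr)
  keep <- g$x^2 + g$y^2 <= R^2
  g <- g[keep, ]
  if (nrow(g) == 0) stop("degenerate plane geometry", call. = FALSE)
  r2 <- g$x^2 + g$y^2
  speed <- switch(kind,
    centered_parabolic = vmax * (1 - r2 / R^2),
    uniform = rep(vmax, nrow(g)),
    offset_jet = vmax * exp(-((g$x - offset[1])^2 +
                                (g$y - offset[2])^2) / (2 * sigma^2)))
  field <- plane_velocity_field(
    data.frame(x = g$x, y = g$y, z = 0, area = h^2, speed = speed))
  A <- sum(field$cells$area)
  gt <- switch(kind,
    centered_parabolic = list(fA = 0, fD = 100 * fraction * pi * R^2 / A),
    uniform = list(fA = 0, fD = 100),
    offset_jet = {
      rb <- sigma * sqrt(2 * log(1 / (1 - fraction)))
      list(fA = 100 * sqrt(sum(offset^2)) / field$Req,
           fD = 100 * pi * rb^2 / A)
    })
  attr(field, "ground_truth") <- gt
  field
}

#' Synthetic balanced factorial response table
#'
#' Draws responses from the cell-means model
#' \deqn{y_{ijk} = \mu + a_i + b_j + (ab)_{ij} + \epsilon_{ijk},}
#' with per-cell Gaussian noise scales (heteroscedasticity) and optional
#' outlier contamination: each observation is, with probability
#' `outlier_rate`, multiplied-noise inflated by `outlier_scale`. The
#' design mirrors the simulation campaign analysed by the robust
#' factorial procedure: factor A with five levels (rheology), factor B
#' with three (inlet profile), `n_per_cell` replicates (default 7,
#' one per geometry).
#'
#' @param grand_mean Overall mean.
#' @param factorA_effects Length-5 numeric, must sum to zero (1e-8
#'   tolerance); names default to `Cs, CY, HB, N, P`.
#' @param factorB_effects Length-3 numeric, sum zero; names default to
#'   `Parabolic, Plug, Womersley`.
#' @param interaction_effects 5 x 3 matrix, default zero.
#' @param noise_scales Positive scalar or 5 x 3 matrix of per-cell
#'   standard deviations.
#' @param outlier_rate Contamination probability in `[0, 1)`.
#' @param outlier_scale Noise inflation factor for contaminated draws.
#' @param n_per_cell Replicates per cell.
#' @param seed Integer seed; identical seed gives identical tables.
#' @return A `factorial_table` (`data.frame` with columns `case`,
#'   `rheology`, `inlet`, `variable`, `value`).
#' @export
make_factorial_table <- function(grand_mean = 0,
                                 factorA_effects = numeric(5),
                                 factorB_effects = numeric(3),
                                 interaction_effects = matrix(0, 5, 3),
                                 noise_scales = 1,
                                 outlier_rate = 0, outlier_scale = 10,
                                 n_per_cell = 7, seed = 1) {
  levA <- names(factorA_effects) %||% c("Cs", "CY", "HB", "N", "P")
  levB <- names(factorB_effects) %||% c("Parabolic", "Plug", "Womersley")
  if (length(factorA_effects) != 5 || length(factorB_effects) != 3)
    stop("expected 5 factor A and 3 factor B effects", call. = FALSE)
  if (abs(sum(factorA_effects)) > 1e-8 || abs(sum(factorB_effects)) > 1e-8)
    stop("effects must sum to zero within each factor", call. = FALSE)
  if (outlier_rate < 0 || outlier_rate >= 1)
    stop("`outlier_rate` must lie in [0, 1)", call. = FALSE)
  sc <- if (length(noise_scales) == 1) matrix(noise_scales, 5, 3)
        else noise_scales
  if (any(sc <= 0)) stop("noise scales must be positive", call. = FALSE)
  set.seed(seed)
  recs <- expand.grid(case = paste0("g", seq_len(n_per_cell)),
                      rheology = levA, inlet = levB,
                      stringsAsFactors = FALSE)
  i <- match(recs$rheology, levA)
  j <- match(recs$inlet, levB)
  mu <- grand_mean + factorA_effects[i] + factorB_effects[j] +
    interaction_effects[cbind(i, j)]
  eps <- rnorm(nrow(recs), sd = sc[cbind(i, j)])
  contaminated <- runif(nrow(recs)) < outlier_rate
  eps[contaminated] <- eps[contaminated] * outlier_scale
  out <- data.frame(case = recs$case, rheology = recs$rheology,
                    inlet = recs$inlet, variable = "synthetic",
                    value = mu + eps, stringsAsFactors = FALSE)
  class(out) <- c("factorial_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
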