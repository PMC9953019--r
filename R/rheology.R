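#' Blood rheology specifications
#'
#' Constructs a named generalized-Newtonian constitutive law with the
#' parameter set used throughout the package. Five models are available,
#' selected to span the main families of shear-thinning blood rheology:
#'
#' \describe{
#'   \item{CY (Carreau-Yasuda)}{\eqn{\mu(\dot\gamma) = \mu_\infty +
#'     (\mu_0-\mu_\infty)[1+(\lambda\dot\gamma)^a]^{(n-1)/a}} with
#'     \eqn{\mu_\infty = 0.00345}, \eqn{\mu_0 = 0.056} Pa s,
#'     \eqn{\lambda = 1.902} s, \eqn{n = 0.22}, \eqn{a = 1.25}.}
#'   \item{Cs (Casson)}{\eqn{\mu(\dot\gamma) = (\sqrt{k} +
#'     \sqrt{\tau_0/\dot\gamma})^2} with \eqn{k = 0.00345} Pa s,
#'     \eqn{\tau_0 = 0.005} Pa.}
#'   \item{HB (Herschel-Bulkley)}{\eqn{\mu(\dot\gamma) =
#'     k\dot\gamma^{n-1} + \tau_0/\dot\gamma} with \eqn{k = 0.008},
#'     \eqn{n = 0.8375}, \eqn{\tau_0 = 0.00345} Pa.}
#'   \item{N (Newtonian)}{\eqn{\mu = \mu_\infty = 0.00345} Pa s.}
#'   \item{P (power law)}{\eqn{\mu(\dot\gamma) = k\dot\gamma^{n-1}} with
#'     \eqn{k = 0.01467}, \eqn{n = 0.7755}.}
#' }
#'
#' The exponent of the Carreau-Yasuda bracket is taken as \eqn{(n-1)/a},
#' the standard shear-thinning form under which the viscosity decreases
#' monotonically from \eqn{\mu_0} to \eqn{\mu_\infty}.
#'
#' @param name Model abbreviation: `"CY"`, `"Cs"`, `"HB"`, `"N"` or `"P"`.
#' @param ... Named parameter overrides (e.g. `mu_0 = 0.05`). Only
#'   parameters belonging to the chosen model may be overridden.
#' @return An object of class `rheology_spec`.
#' @examples
#' apparent_viscosity(rheology_spec("P"), 1)  # equals k
#' @export
rheology_spec <- function(name = c("CY", "Cs", "HB", "N", "P"), ...) {
  name <- match.arg(name)
  defaults <- switch(name,
    CY = list(mu_inf = 0.00345, mu_0 = 0.056, lambda = 1.902,
              n_index = 0.22, a_index = 1.25),
    Cs = list(k_consistency = 0.00345, tau_0 = 0.005),
    HB = list(k_consistency = 0.008, n_index = 0.8375, tau_0 = 0.00345),
    N  = list(mu_inf = 0.00345),
    P  = list(k_consistency = 0.01467, n_index = 0.7755))
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad))
    stop("parameter(s) not used by model ", name, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  pars <- utils::modifyList(defaults, over)
  if (any(unlist(pars) <= 0))
    stop("all rheology parameters must be positive", call. = FALSE)
  structure(c(list(name = name), pars), class = "rheology_spec")
}

#' @export
print.rheology_spec <- function(x, ...) {
  pars <- x[setdiff(names(x), "name")]
  cat(sprintf("<rheology_spec> %s: %s\n", x$name,
              paste(names(pars), unlist(pars), sep = " = ",
                    collapse = ", ")))
  invisible(x)
}

#' Apparent viscosity of a rheology model
#'
#' Evaluates the constitutive law of a [rheology_spec()] at the given
#' scalar shear rates. The yield-stress models (Cs, HB) and the power
#' law diverge as \eqn{\dot\gamma \to 0}; their apparent viscosity is
#' capped at `mu_max` (solver-style regularization) so downstream index
#' computations stay finite.
#'
#' @param spec A [rheology_spec()].
#' @param gamma_dot Shear rate(s), 1/s, non-negative; vectorized.
#' @param mu_max Regularization cap, Pa s.
#' @return Apparent viscosity in Pa s, same length as `gamma_dot`.
#' @export
apparent_viscosity <- function(spec, gamma_dot, mu_max = 10) {
  stopifnot(inherits(spec, "rheology_spec"))
  if (any(gamma_dot < 0))
    stop("shear rate must be non-negative", call. = FALSE)
  g <- as.numeric(gamma_dot)
  mu <- switch(spec$name,
    N = rep(spec$mu_inf, length(g)),
    CY = spec$mu_inf + (spec$mu_0 - spec$mu_inf) *
      (1 + (spec$lambda * g)^spec$a_index)^((spec$n_index - 1) / spec$a_index),
    Cs = (sqrt(spec$k_consistency) + sqrt(spec$tau_0 / g))^2,
    HB = spec$k_consistency * g^(spec$n_index - 1) + spec$tau_0 / g,
    P = spec$k_consistency * g^(spec$n_index - 1))
  pmin(mu, mu_max)
}

#' Scalar shear rate from the rate-of-deformation tensor
#'
#' Uses the generalized-Newtonian convention
#' \eqn{\dot\gamma = \sqrt{2\, \mathbf{D}:\mathbf{D}}}, which recovers
#' \eqn{\dot\gamma_0} for simple shear with off-diagonal entries
#' \eqn{\dot\gamma_0/2}.
#'
#' @param D Symmetric 3x3 rate-of-deformation tensor, 1/s.
#' @return Non-negative scalar shear rate, 1/s; zero iff `D` is zero.
#' @export
shear_rate_from_D <- function(D) {
  if (!is.matrix(D) || !all(dim(D) == c(3, 3)))
    stop("`D` must be a 3x3 matrix", call. = FALSE)
  if (max(abs(D - t(D))) > 1e-10 * max(1, max(abs(D))))
    stop("`D` must be symmetric", call. = FALSE)
  sqrt(2 * sum(D * D))
}

#' Viscous stress tensor
#'
#' \eqn{\tau = 2\,\mu(\dot\gamma)\,\mathbf{D}} with the scalar shear
#' rate derived from `D`. The result is symmetric and traceless whenever
#' `D` is.
#'
#' @inheritParams apparent_viscosity
#' @param D Symmetric 3x3 rate-of-deformation tensor, 1/s.
#' @return 3x3 stress tensor, Pa.
#' @export
stress_tensor <- function(spec, D, mu_max = 10) {
  gd <- shear_rate_from_D(D)
  if (gd == 0) return(matrix(0, 3, 3))
  2 * apparent_viscosity(spec, gd, mu_max = mu_max) * D
}
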