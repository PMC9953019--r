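#' Grid triplet for a convergence study
#'
#' Bundles solution values of one scalar quantity on three
#' systematically refined meshes (constant refinement ratio `r`).
#'
#' @param f1,f2,f3 Solution on the fine, medium and coarse mesh.
#' @param r Refinement ratio between successive meshes (> 1).
#' @param fs Safety factor (>= 1), conventionally 1.25.
#' @return An object of class `grid_triplet`.
#' @export
grid_triplet <- function(f1, f2, f3, r = 2, fs = 1.25) {
  if (r <= 1) stop("refinement ratio must exceed 1", call. = FALSE)
  if (fs < 1) stop("safety factor must be >= 1", call. = FALSE)
  structure(list(f1 = f1, f2 = f2, f3 = f3, r = r, fs = fs),
            class = "grid_triplet")
}

#' Observed order of convergence
#'
#' \eqn{p = \ln\left(\frac{f_3 - f_2}{f_2 - f_1}\right)/\ln r}. Requires
#' monotone convergence: `(f3 - f2)` and `(f2 - f1)` must be nonzero and
#' share a sign, otherwise the triplet is oscillatory and no order can
#' be estimated.
#'
#' @param t A [grid_triplet()].
#' @return The order `p`.
#' @export
order_of_convergence <- function(t) {
  stopifnot(inherits(t, "grid_triplet"))
  d32 <- t$f3 - t$f2
  d21 <- t$f2 - t$f1
  if (d32 == 0 || d21 == 0 || sign(d32) != sign(d21))
    stop("non-monotone (oscillatory) triplet: cannot estimate order",
         call. = FALSE)
  log(d32 / d21) / log(t$r)
}

#' Grid Convergence Index for both refinement pairs
#'
#' Relative errors are fine-grid referenced,
#' \eqn{e_{ij} = 100\,|f_i - f_j|/f_i} (percent), and
#' \eqn{GCI_{ij} = F_s\, e_{ij} / (r^p - 1)}.
#'
#' @param t A [grid_triplet()].
#' @param p Order of convergence; computed from `t` when omitted.
#' @return Named vector `c(gci12, gci23)` in percent.
#' @export
gci_pair <- function(t, p = order_of_convergence(t)) {
  stopifnot(inherits(t, "grid_triplet"))
  if (t$f1 == 0 || t$f2 == 0)
    stop("relative error undefined for zero reference value", call. = FALSE)
  e12 <- 100 * abs(t$f1 - t$f2) / abs(t$f1)
  e23 <- 100 * abs(t$f2 - t$f3) / abs(t$f2)
  denom <- t$r^p - 1
  c(gci12 = t$fs * e12 / denom, gci23 = t$fs * e23 / denom)
}

#' Asymptotic-range diagnostic
#'
#' \eqn{GCI_{23}/(r^p\, GCI_{12})}; values near 1 indicate the solutions
#' lie in the asymptotic convergence range.
#'
#' @param gci12,gci23 GCI values from [gci_pair()].
#' @param r Refinement ratio.
#' @param p Order of convergence.
#' @return The ratio (dimensionless).
#' @export
asymptotic_ratio <- function(gci12, gci23, r, p) {
  if (gci12 <= 0 || gci23 <= 0)
    stop("GCI values must be positive", call. = FALSE)
  gci23 / (r^p * gci12)
}

#' Full grid-convergence study of one quantity
#'
#' @param f1,f2,f3 Fine, medium and coarse solutions.
#' @inheritParams grid_triplet
#' @return A list of class `gci_result`: `p_order`, `e12`, `e23` (%),
#'   `gci12`, `gci23` (%), `asymptotic_ratio`.
#' @examples
#' gci_study(5.1875, 5.1355, 5.0077)  # order ~1.297, ratio ~1
#' @export
gci_study <- function(f1, f2, f3, r = 2, fs = 1.25) {
  t <- grid_triplet(f1, f2, f3, r, fs)
  p <- order_of_convergence(t)
  g <- gci_pair(t, p)
  structure(list(p_order = p,
                 e12 = 100 * abs(f1 - f2) / abs(f1),
                 e23 = 100 * abs(f2 - f3) / abs(f2),
                 gci12 = g[["gci12"]], gci23 = g[["gci23"]],
                 asymptotic_ratio = asymptotic_ratio(g[["gci12"]],
                                                     g[["gci23"]], r, p)),
            class = "gci_result")
}

#' @export
print.gci_result <- function(x, ...) {
  cat(sprintf(
    "<gci_result> p = %.5f | GCI12 = %.4f%% GCI23 = %.4f%% | ratio = %.4f\n",
    x$p_order, x$gci12, x$gci23, x$asymptotic_ratio))
  invisible(x)
}
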