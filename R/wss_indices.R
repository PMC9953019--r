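#' Surface WSS field container
#'
#' Holds a wall-shear-stress vector time series over one cardiac cycle
#' for each surface element, plus element areas. Time samples must lie
#' on a uniform grid covering `[0, T)` (periodic convention).
#'
#' @param wss Numeric array of dimension (elements, times, 3), Pa.
#' @param areas Element areas, m2, positive.
#' @param times Sample times, s.
#' @param period Cycle period T, s.
#' @return An object of class `surface_wss_field`.
#' @export
surface_wss_field <- function(wss, areas, times, period = 1) {
  if (length(dim(wss)) != 3 || dim(wss)[3] != 3)
    stop("`wss` must be an (elements x times x 3) array", call. = FALSE)
  if (dim(wss)[1] != length(areas))
    stop("`areas` length must match element count", call. = FALSE)
  if (dim(wss)[2] != length(times))
    stop("`times` length must match time dimension", call. = FALSE)
  if (length(times) < 8)
    stop("at least 8 time samples are required", call. = FALSE)
  if (any(areas <= 0)) stop("areas must be positive", call. = FALSE)
  dt <- diff(times)
  if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-9 * dt[1])
    stop("`times` must be uniform and increasing", call. = FALSE)
  structure(list(wss = wss, areas = as.numeric(areas),
                 times = as.numeric(times), period = period),
            class = "surface_wss_field")
}

#' @export
print.surface_wss_field <- function(x, ...) {
  cat(sprintf("<surface_wss_field> %d elements x %d time samples, T = %g s\n",
              dim(x$wss)[1], dim(x$wss)[2], x$period))
  invisible(x)
}

# periodic rectangle rule: mean over samples x T; on a uniform periodic
# grid this coincides with the periodically wrapped trapezoid rule
cycle_mean <- function(m) rowMeans(m)

# (elements x times) slice of component k, dimension-stable for 1 element
wss_comp <- function(field, k) {
  matrix(field$wss[, , k], nrow = dim(field$wss)[1])
}

#' Time-averaged wall shear stress
#'
#' \eqn{TAWSS = \frac{1}{T}\int_0^T |\mathbf{WSS}|\,dt} per element,
#' via the periodic rectangle rule on the uniform time grid.
#'
#' @param field A [surface_wss_field()].
#' @return Non-negative TAWSS per element, Pa.
#' @export
tawss <- function(field) {
  stopifnot(inherits(field, "surface_wss_field"))
  mag <- sqrt(wss_comp(field, 1)^2 + wss_comp(field, 2)^2 +
                wss_comp(field, 3)^2)
  cycle_mean(mag)
}

#' Oscillatory shear index
#'
#' \eqn{OSI = \frac{1}{2}\left(1 -
#'   \frac{|\int_0^T \mathbf{WSS}\,dt|}{\int_0^T |\mathbf{WSS}|\,dt}
#' \right)} per element. Uniaxial (fixed-direction) loading yields 0;
#' loading with no net direction yields 0.5. Elements whose magnitude
#' integral vanishes have no defined oscillation and are returned as
#' `NA` rather than 0.5.
#'
#' @param field A [surface_wss_field()].
#' @return OSI per element in `[0, 0.5]`, `NA` where undefined.
#' @export
osi <- function(field) {
  stopifnot(inherits(field, "surface_wss_field"))
  mean_vec <- vapply(1:3, function(k) cycle_mean(wss_comp(field, k)),
                     numeric(dim(field$wss)[1]))
  num <- sqrt(rowSums(matrix(mean_vec, ncol = 3)^2))
  den <- tawss(field)
  out <- 0.5 * (1 - num / den)
  out[den == 0] <- NA_real_
  pmin(pmax(out, 0), 0.5)
}

#' Relative residence time
#'
#' \eqn{RRT = 1/[(1 - 2\,OSI)\cdot TAWSS]} (proportionality constant
#' fixed to 1), a proxy for how long blood resides near the wall.
#' `OSI = 0.5` gives `Inf`; `TAWSS = 0` is undefined and returns `NA`.
#'
#' @param tawss TAWSS per element, Pa.
#' @param osi OSI per element.
#' @return RRT per element, 1/Pa.
#' @export
rrt <- function(tawss, osi) {
  if (length(tawss) != length(osi))
    stop("`tawss` and `osi` must have equal length", call. = FALSE)
  out <- 1 / ((1 - 2 * osi) * tawss)
  out[tawss == 0] <- NA_real_
  out
}

#' Per-element hemodynamic index maps
#'
#' Convenience wrapper computing [tawss()], [osi()] and [rrt()] for a
#' field in one pass.
#'
#' @param field A [surface_wss_field()].
#' @return A `data.frame` with columns `element`, `area`, `tawss`,
#'   `osi`, `rrt`.
#' @export
wss_indices <- function(field) {
  tw <- tawss(field)
  os <- osi(field)
  data.frame(element = seq_along(tw), area = field$areas,
             tawss = tw, osi = os, rrt = rrt(tw, os))
}

#' Thrombus-prone area percentages
#'
#' Area-weighted percentage of the surface inside thrombogenic
#' stimulating environments: `TAWSS < 0.4 Pa`, `OSI > 0.3` and
#' `RRT > 10 1/Pa` (strict inequalities; infinite RRT counts as above
#' threshold).
#'
#' @param maps Index maps from [wss_indices()] (columns `area`, `tawss`,
#'   `osi`, `rrt`).
#' @param tawss_low,osi_high,rrt_high Thresholds.
#' @return Named vector `c(pct_tawss_low, pct_osi_high, pct_rrt_high)`
#'   in percent of total area.
#' @export
threshold_percentages <- function(maps, tawss_low = 0.4, osi_high = 0.3,
                                  rrt_high = 10) {
  req <- c("area", "tawss", "osi", "rrt")
  if (!all(req %in% names(maps)))
    stop("`maps` must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  total <- sum(maps$area)
  pct <- function(flag) 100 * sum(maps$area[which(flag)]) / total
  c(pct_tawss_low = pct(maps$tawss < tawss_low),
    pct_osi_high = pct(maps$osi > osi_high),
    pct_rrt_high = pct(maps$rrt > rrt_high | is.infinite(maps$rrt)))
}

#' Summary statistics of index maps
#'
#' Average (area-weighted by default), minimum and maximum of each index
#' over the surface, plus the thrombus-prone area percentages. Elements
#' with infinite or undefined RRT are excluded from the RRT average;
#' their presence is reported via `rrt_has_inf`.
#'
#' @param maps Index maps from [wss_indices()].
#' @param weighted Use area weighting for averages (default); `FALSE`
#'   gives unweighted element-wise means for sensitivity checks.
#' @return A list of class `index_summary` with components `tawss`,
#'   `osi`, `rrt` (each `c(ave, min, max)`), `percentages` and
#'   `rrt_has_inf`.
#' @export
summarize_indices <- function(maps, weighted = TRUE) {
  wmean <- function(x, a) {
    keep <- is.finite(x)
    if (!any(keep)) return(NA_real_)
    if (weighted) sum(x[keep] * a[keep]) / sum(a[keep])
    else mean(x[keep])
  }
  rng <- function(x) range(x[is.finite(x)])
  summ <- function(x) {
    r <- rng(x)
    c(ave = wmean(x, maps$area), min = r[1], max = r[2])
  }
  structure(list(tawss = summ(maps$tawss), osi = summ(maps$osi),
                 rrt = summ(maps$rrt),
                 percentages = threshold_percentages(maps),
                 rrt_has_inf = any(is.infinite(maps$rrt))),
            class = "index_summary")
}

#' @export
print.index_summary <- function(x, ...) {
  for (v in c("tawss", "osi", "rrt"))
    cat(sprintf("%-6s ave %.4g  min %.4g  max %.4g\n", toupper(v),
                x[[v]]["ave"], x[[v]]["min"], x[[v]]["max"]))
  cat(sprintf("area%%: TAWSS<0.4 %.2f | OSI>0.3 %.2f | RRT>10 %.2f\n",
              x$percentages[1], x$percentages[2], x$percentages[3]))
  invisible(x)
}
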