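#' Trimmed mean
#'
#' Sorts the sample, drops `g = floor(trim * n)` observations from each
#' end and averages the remainder. With the default 20% trim this is the
#' location estimator underlying the robust factorial analysis; it is
#' insensitive to up to `g` arbitrary outliers per tail.
#'
#' @param x Numeric vector, non-empty.
#' @param trim Trim proportion per tail in `[0, 0.5)`; 0 recovers the
#'   arithmetic mean.
#' @return The trimmed mean.
#' @export
trimmed_mean <- function(x, trim = 0.2) {
  if (length(x) == 0) stop("empty input", call. = FALSE)
  if (trim < 0 || trim >= 0.5) stop("`trim` must lie in [0, 0.5)",
                                    call. = FALSE)
  n <- length(x)
  g <- floor(trim * n)
  y <- sort(x)
  mean(y[(g + 1):(n - g)])
}

#' Winsorized variance
#'
#' Replaces the `g = floor(trim * n)` smallest observations by the
#' `(g+1)`-th order statistic and the `g` largest by the `(n-g)`-th,
#' then takes the ordinary sample variance (denominator `n - 1`). Pairs
#' with the trimmed mean in robust standard errors: the squared standard
#' error of an n-sample trimmed mean is
#' `(n - 1) * winsorized_variance / (h * (h - 1))` with
#' `h = n - 2g` retained observations.
#'
#' @inheritParams trimmed_mean
#' @return The winsorized sample variance.
#' @export
winsorized_variance <- function(x, trim = 0.2) {
  n <- length(x)
  if (n < 2) stop("need at least two observations", call. = FALSE)
  if (trim < 0 || trim >= 0.5) stop("`trim` must lie in [0, 0.5)",
                                    call. = FALSE)
  g <- floor(trim * n)
  y <- sort(x)
  if (g > 0) {
    y[seq_len(g)] <- y[g + 1]
    y[(n - g + 1):n] <- y[n - g]
  }
  sum((y - mean(y))^2) / (n - 1)
}

# squared standard error of the trimmed mean, and retained count
tm_se2 <- function(x, trim) {
  n <- length(x)
  h <- n - 2 * floor(trim * n)
  list(d = (n - 1) * winsorized_variance(x, trim) / (h * (h - 1)), h = h)
}

# Johansen-type statistic for H0: cmat %*% mu_t = 0 on cell trimmed
# means with heteroscedastic squared SEs v (diagonal) and effective
# per-cell degrees of freedom h - 1.
johansen_stat <- function(cmat, tmeans, v, h) {
  yv <- matrix(tmeans)
  W <- cmat %*% v %*% t(cmat)
  # degenerate (e.g. constant) cells: zero contrast carries no evidence
  if (rcond(W) < .Machine$double.eps) {
    if (max(abs(cmat %*% yv)) == 0)
      return(list(Q = 0, A = 0, df = nrow(cmat)))
    stop("singular covariance of cell trimmed means", call. = FALSE)
  }
  Winv <- solve(W)
  Q <- drop(t(yv) %*% t(cmat) %*% Winv %*% cmat %*% yv)
  R <- v %*% t(cmat) %*% Winv %*% cmat
  A <- sum(diag(R)^2 / (h - 1))
  list(Q = Q, A = A, df = nrow(cmat))
}

# adjusted chi-square critical value at level alpha (vectorized in alpha)
johansen_crit <- function(stat, alpha) {
  crit <- qchisq(1 - alpha, stat$df)
  crit + (crit / (2 * stat$df)) * A_times(stat$A, crit, stat$df)
}
A_times <- function(A, crit, df) A * (1 + 3 * crit / (df + 2))

# p-value on the alpha grid 0.001..0.999: smallest level at which the
# statistic exceeds its adjusted critical value. Granularity 0.001; a
# statistic that never rejects reports 0.999.
johansen_p <- function(stat, grid = (1:999) / 1000) {
  crit <- johansen_crit(stat, grid)
  i <- which(stat$Q > crit)[1]
  if (is.na(i)) grid[length(grid)] else grid[i]
}

check_factorial <- function(data, value, factorA, factorB) {
  for (col in c(value, factorA, factorB))
    if (!col %in% names(data))
      stop("column `", col, "` not found", call. = FALSE)
  fa <- factor(data[[factorA]])
  fb <- factor(data[[factorB]])
  if (nlevels(fa) < 2 || nlevels(fb) < 2)
    stop("each factor needs at least 2 levels", call. = FALSE)
  counts <- table(fa, fb)
  if (length(unique(as.vector(counts))) != 1)
    stop("design must be balanced (equal n per cell)", call. = FALSE)
  if (counts[1] < 4)
    stop("need at least 4 observations per cell", call. = FALSE)
  list(y = data[[value]], fa = fa, fb = fb, n = counts[1])
}

#' Heteroscedasticity-robust two-way ANOVA on trimmed means
#'
#' Tests both main effects and the interaction of a balanced two-factor
#' design using 20% trimmed cell means with winsorized-variance-based
#' standard errors (Johansen-type Wald statistics with
#' adjusted chi-square critical values). The procedure tolerates unequal
#' cell variances and up to `floor(trim * n)` outliers per cell tail.
#'
#' p-values are obtained by locating the smallest significance level on
#' the grid `0.001, 0.002, ..., 0.999` at which the statistic exceeds
#' its level-dependent critical value, so they carry a granularity of
#' 0.001 and are reported in `[0.001, 0.999]`.
#'
#' @param data A `data.frame` (e.g. a `factorial_table`).
#' @param value,factorA,factorB Column names of the response and the two
#'   factors.
#' @param trim Trim proportion per tail (default 0.2); `trim = 0`
#'   reduces the procedure to a heteroscedastic (Welch/Johansen-type)
#'   ANOVA on ordinary means.
#' @return A list of class `robust_anova`: per effect (`factorA`,
#'   `factorB`, `interaction`) the statistic `Q` and `p.value`, plus
#'   `trim`, `cell_means` and the factor level sets.
#' @examples
#' t5 <- load_reference_table("T5")
#' robust_two_way_anova(subset(t5, variable == "FD_pct"))
#' @export
robust_two_way_anova <- function(data, value = "value",
                                 factorA = "rheology", factorB = "inlet",
                                 trim = 0.2) {
  d <- check_factorial(data, value, factorA, factorB)
  J <- nlevels(d$fa); K <- nlevels(d$fb)
  cells <- split(d$y, list(d$fa, d$fb))  # factor A varies fastest
  tmeans <- vapply(cells, trimmed_mean, numeric(1), trim = trim)
  se2 <- lapply(cells, tm_se2, trim = trim)
  v <- diag(vapply(se2, `[[`, numeric(1), "d"))
  h <- vapply(se2, `[[`, numeric(1), "h")
  cj <- diag(1, J - 1, J); for (i in seq_len(J - 1)) cj[i, i + 1] <- -1
  ck <- diag(1, K - 1, K); for (i in seq_len(K - 1)) ck[i, i + 1] <- -1
  ij <- matrix(1, 1, J); ik <- matrix(1, 1, K)
  eff <- list(factorA = kronecker(ik, cj),
              factorB = kronecker(ck, ij),
              interaction = kronecker(ck, cj))
  res <- lapply(eff, function(cmat) {
    s <- johansen_stat(cmat, tmeans, v, h)
    list(Q = s$Q, df = s$df, p.value = johansen_p(s))
  })
  structure(list(factorA = res$factorA, factorB = res$factorB,
                 interaction = res$interaction, trim = trim,
                 cell_means = matrix(tmeans, J, K,
                                     dimnames = list(levels(d$fa),
                                                     levels(d$fb))),
                 levelsA = levels(d$fa), levelsB = levels(d$fb),
                 n_per_cell = d$n),
            class = "robust_anova")
}

#' @export
print.robust_anova <- function(x, ...) {
  cat(sprintf("Robust two-way ANOVA on %.0f%% trimmed means (n = %d/cell)\n",
              100 * x$trim, x$n_per_cell))
  for (e in c("factorA", "factorB", "interaction"))
    cat(sprintf("  %-12s Q = %8.3f  df = %d  p = %.3f\n", e,
                x[[e]]$Q, x[[e]]$df, x[[e]]$p.value))
  invisible(x)
}

#' Yuen-type comparison of two trimmed means
#'
#' Two-sample heteroscedastic test on trimmed means with
#' winsorized-variance standard errors and Welch-Satterthwaite degrees
#' of freedom.
#'
#' @param x1,x2 Numeric samples.
#' @param trim Trim proportion per tail.
#' @return List with `estimate` (trimmed-mean difference `x1 - x2`),
#'   `se`, `df`, `statistic` and two-sided `p.value`.
#' @export
yuen_test <- function(x1, x2, trim = 0.2) {
  a <- tm_se2(x1, trim); b <- tm_se2(x2, trim)
  est <- trimmed_mean(x1, trim) - trimmed_mean(x2, trim)
  se <- sqrt(a$d + b$d)
  df <- (a$d + b$d)^2 / (a$d^2 / (a$h - 1) + b$d^2 / (b$h - 1))
  stat <- est / se
  list(estimate = est, se = se, df = df, statistic = stat,
       p.value = 2 * pt(-abs(stat), df))
}

#' Hochberg step-up p-value adjustment
#'
#' Controls the family-wise error rate across `m` comparisons: with
#' p-values sorted increasingly, the adjusted value of the k-th is
#' \eqn{\min_{j \ge k} \{(m - j + 1)\, p_{(j)}\}} capped at 1, which is
#' monotone non-decreasing and never below the raw value.
#'
#' @param p Raw p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
hochberg_adjust <- function(p) {
  if (any(p < 0 | p > 1 | is.na(p)))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  if (m == 1) return(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(seq_len(m) * p[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Evidence label for a p-value
#'
#' Classifies the strength of evidence against a null hypothesis:
#' p below 0.005 is `"strong"`, p in `[0.005, 0.05]` is `"weak"`
#' (suggestive), and larger values are `"none"`.
#'
#' @param p p-value(s) in `[0, 1]`; vectorized.
#' @return Character vector of labels.
#' @export
evidence_label <- function(p) {
  if (any(p < 0 | p > 1 | is.na(p)))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  ifelse(p < 0.005, "strong", ifelse(p <= 0.05, "weak", "none"))
}

#' Post hoc pairwise contrasts for one factor
#'
#' For every pair of levels of `factor_col` (alphabetical order, first
#' minus second), compares the 20% trimmed means of all observations at
#' each level pooled across the other factor (e.g. n = 35 per inlet
#' level, n = 21 per rheology level in the packaged campaign), using the
#' Yuen-type heteroscedastic test. p-values are Hochberg-adjusted across
#' the family of pairs, and confidence intervals are widened using the
#' per-comparison significance level implied by the Hochberg step-up
#' sequence (`alpha / k` for the comparison with the k-th largest raw
#' p-value).
#'
#' `pooling = "cellwise"` instead averages per-cell trimmed means within
#' each level, retained for sensitivity analysis.
#'
#' @param data A `data.frame` with the response and factor columns.
#' @param factor_col Name of the factor whose levels are compared.
#' @param value Response column name.
#' @param trim Trim proportion per tail.
#' @param conf.level Family-wise confidence level for the intervals.
#' @param pooling `"pooled"` (default) or `"cellwise"`.
#' @param other_factor Required for `pooling = "cellwise"`: the other
#'   factor's column name.
#' @return A `data.frame` of class `contrast_result` with one row per
#'   pair: `level1`, `level2`, `estimate`, `se`, `df`, `ci_lower`,
#'   `ci_upper`, `p.value`, `p.adjusted`, `evidence`.
#' @examples
#' t6 <- load_reference_table("T6")
#' posthoc_contrasts(subset(t6, variable == "OSI_pct"), "inlet")
#' @export
posthoc_contrasts <- function(data, factor_col, value = "value",
                              trim = 0.2, conf.level = 0.95,
                              pooling = c("pooled", "cellwise"),
                              other_factor = NULL) {
  pooling <- match.arg(pooling)
  if (!factor_col %in% names(data) || !value %in% names(data))
    stop("missing column(s)", call. = FALSE)
  lev <- unique(as.character(data[[factor_col]]))
  # locale-independent case-insensitive alphabetical order, fixing the
  # first-minus-second sign convention (Cs - CY, ..., N - P)
  lev <- lev[order(tolower(lev), lev, method = "radix")]
  if (length(lev) < 2) stop("need at least 2 levels", call. = FALSE)
  pairs <- utils::combn(lev, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    l1 <- pairs[1, k]; l2 <- pairs[2, k]
    x1 <- data[[value]][data[[factor_col]] == l1]
    x2 <- data[[value]][data[[factor_col]] == l2]
    if (pooling == "cellwise") {
      if (is.null(other_factor))
        stop("`other_factor` required for cellwise pooling", call. = FALSE)
      g1 <- data[[other_factor]][data[[factor_col]] == l1]
      g2 <- data[[other_factor]][data[[factor_col]] == l2]
      est <- mean(vapply(split(x1, g1), trimmed_mean, numeric(1),
                         trim = trim)) -
        mean(vapply(split(x2, g2), trimmed_mean, numeric(1), trim = trim))
      yt <- yuen_test(x1, x2, trim)  # SE/df still from pooled samples
      yt$estimate <- est
      yt$statistic <- est / yt$se
      yt$p.value <- 2 * pt(-abs(yt$statistic), yt$df)
      yt
    } else {
      yuen_test(x1, x2, trim)
    }
  })
  est <- vapply(rows, `[[`, numeric(1), "estimate")
  se <- vapply(rows, `[[`, numeric(1), "se")
  df <- vapply(rows, `[[`, numeric(1), "df")
  p <- vapply(rows, `[[`, numeric(1), "p.value")
  padj <- hochberg_adjust(p)
  # Hochberg-implied per-comparison level: alpha/k for the k-th largest p
  k <- rank(-p, ties.method = "first")
  alpha_k <- (1 - conf.level) / k
  crit <- qt(1 - alpha_k / 2, df)
  out <- data.frame(level1 = pairs[1, ], level2 = pairs[2, ],
                    estimate = est, se = se, df = df,
                    ci_lower = est - crit * se,
                    ci_upper = est + crit * se,
                    p.value = p, p.adjusted = padj,
                    evidence = evidence_label(padj),
                    stringsAsFactors = FALSE)
  class(out) <- c("contrast_result", "data.frame")
  out
}
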