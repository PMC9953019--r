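# Brute-force / independent-route helpers shared across test files.

# direct loop implementation of an area-weighted mean
brute_weighted_mean <- function(x, a) {
  s <- 0; w <- 0
  for (i in seq_along(x)) {
    if (is.finite(x[i])) { s <- s + x[i] * a[i]; w <- w + a[i] }
  }
  s / w
}

# winsorize-then-var oracle
brute_winvar <- function(x, trim) {
  n <- length(x); g <- floor(trim * n)
  y <- sort(x)
  low <- y[g + 1]; high <- y[n - g]
  y[y < low] <- low; y[y > high] <- high
  stats::var(y)
}

# independent Johansen-type statistic on ORDINARY means/variances
# (Welch-style), written as explicit loops for the trim = 0 cross-check
brute_johansen_means <- function(cells, cmat) {
  m <- vapply(cells, mean, numeric(1))
  d <- vapply(cells, function(x) stats::var(x) / length(x), numeric(1))
  h <- vapply(cells, length, numeric(1))
  W <- cmat %*% diag(d) %*% t(cmat)
  Q <- drop(t(cmat %*% m) %*% solve(W) %*% (cmat %*% m))
  R <- diag(d) %*% t(cmat) %*% solve(W) %*% cmat
  A <- sum(diag(R)^2 / (h - 1))
  list(Q = Q, A = A)
}

# contrast matrices for a 5 x 3 design, cell order: factor A fastest
con_5x3 <- function() {
  cj <- diag(1, 4, 5); for (i in 1:4) cj[i, i + 1] <- -1
  ck <- diag(1, 2, 3); for (i in 1:2) ck[i, i + 1] <- -1
  list(A = kronecker(matrix(1, 1, 3), cj),
       B = kronecker(ck, matrix(1, 1, 5)),
       AB = kronecker(ck, cj))
}

# random surface WSS field with arbitrary per-element vector series
random_wss_field <- function(n_elements, n_times = 32, seed = 1) {
  set.seed(seed)
  wss <- array(rnorm(n_elements * n_times * 3), c(n_elements, n_times, 3))
  surface_wss_field(wss, areas = runif(n_elements, 0.5, 2),
                    times = (seq_len(n_times) - 1) / n_times, period = 1)
}
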