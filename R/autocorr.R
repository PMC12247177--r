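## Global spatial autocorrelation: Moran's I and Geary's C with analytic
## (normality / randomization) and permutation inference.

.autocorr_setup <- function(y, W) {
  if (inherits(W, "weight_matrix")) W <- W$w
  W <- as.matrix(W)
  n <- length(y)
  if (n < 3L) stop("need at least 3 areal units")
  if (nrow(W) != n || ncol(W) != n) stop("weight matrix does not match y")
  if (any(diag(W) != 0)) stop("weight matrix must have a zero diagonal")
  if (any(W < 0)) stop("weights must be non-negative")
  S0 <- sum(W)
  if (S0 <= 0) stop("weight matrix has no positive entries")
  d <- y - mean(y)
  m2 <- sum(d^2)
  if (m2 == 0) stop("y is constant; autocorrelation undefined")
  Wt <- W + t(W)
  list(W = W, n = n, d = d, m2 = m2, S0 = S0,
       S1 = sum(Wt^2) / 2,
       S2 = sum((rowSums(W) + colSums(W))^2),
       b2 = n * sum(d^4) / m2^2)
}

.moran_stat <- function(d, W, n, S0, m2) {
  as.numeric(n / S0 * crossprod(d, W %*% d) / m2)
}

## sum_ij w_ij (y_i - y_j)^2 = sum_i y_i^2 (rs_i + cs_i) - 2 y' W y
.geary_num <- function(y, W, rs_cs) {
  sum(y^2 * rs_cs) - 2 * as.numeric(crossprod(y, W %*% y))
}

.moran_var <- function(s, assumption) {
  n <- s$n; S0 <- s$S0; S1 <- s$S1; S2 <- s$S2
  E <- -1 / (n - 1)
  if (assumption == "normality") {
    (n^2 * S1 - n * S2 + 3 * S0^2) / (S0^2 * (n^2 - 1)) - E^2
  } else {
    b2 <- s$b2
    (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
       b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
      ((n - 1) * (n - 2) * (n - 3) * S0^2) - E^2
  }
}

.geary_var <- function(s, assumption) {
  n <- s$n; S0 <- s$S0; S1 <- s$S1; S2 <- s$S2
  if (assumption == "normality") {
    ((2 * S1 + S2) * (n - 1) - 4 * S0^2) / (2 * (n + 1) * S0^2)
  } else {
    b2 <- s$b2
    v <- (n - 1) * S1 * (n^2 - 3 * n + 3 - (n - 1) * b2)
    v <- v - (n - 1) * S2 * (n^2 + 3 * n - 6 - (n^2 - n + 2) * b2) / 4
    v <- v + S0^2 * (n^2 - 3 - (n - 1)^2 * b2)
    v / (n * (n - 2) * (n - 3) * S0^2)
  }
}

.autocorr_result <- function(statistic, estimate, expectation, variance, z,
                             p_analytic, p_permutation, n_perm, assumption,
                             alternative) {
  structure(list(statistic = statistic, estimate = estimate,
                 expectation = expectation, variance = variance, z = z,
                 p_analytic = p_analytic, p_permutation = p_permutation,
                 n_perm = n_perm, assumption = assumption,
                 alternative = alternative),
            class = "autocorr_result")
}

#' @export
print.autocorr_result <- function(x, ...) {
  cat(switch(x$statistic, morans_i = "Moran's I", gearys_c = "Geary's C"),
      "(", x$assumption, ")\n")
  cat(sprintf("  estimate %.4f  expectation %.4f  variance %.3g  z %.3f\n",
              x$estimate, x$expectation, x$variance, x$z))
  cat(sprintf("  analytic p (%s): %.4g\n", x$alternative, x$p_analytic))
  if (!is.null(x$p_permutation))
    cat(sprintf("  permutation p (%d perms): %.4g\n", x$n_perm,
                x$p_permutation))
  invisible(x)
}

.analytic_p <- function(z, alternative) {
  switch(alternative,
         two.sided = 2 * stats::pnorm(-abs(z)),
         greater = stats::pnorm(z, lower.tail = FALSE),
         less = stats::pnorm(z))
}

#' Global Moran's I test of spatial autocorrelation
#'
#' Computes I = (N / S0) * sum_ij w_ij (y_i - ybar)(y_j - ybar) /
#' sum_i (y_i - ybar)^2 where S0 = sum_ij w_ij. Values near +1 indicate
#' clustering of similar values, values near -1 dispersion, and the null
#' expectation is -1/(N-1). The null variance is available in closed form
#' under the normality or the randomization (permutation-consistent)
#' assumption; a Monte-Carlo permutation p-value can be requested as well.
#'
#' @param y numeric outcome vector over the areal units.
#' @param W a [weight_matrix] or a plain non-negative matrix with zero
#'   diagonal.
#' @param assumption `"randomization"` (default) or `"normality"` for the
#'   analytic null variance.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param n_perm number of random permutations for the Monte-Carlo null
#'   (0 to skip).
#' @param seed RNG seed for the permutation null (required if n_perm > 0).
#' @return an `autocorr_result` with the estimate, null expectation and
#'   variance, z-score, analytic p-value and (optionally) the add-one
#'   permutation p-value (1 + #{|I*-E| >= |I-E|}) / (n_perm + 1) for the
#'   two-sided case.
#' @export
morans_i <- function(y, W, assumption = c("randomization", "normality"),
                     alternative = c("two.sided", "greater", "less"),
                     n_perm = 0L, seed = NULL) {
  assumption <- match.arg(assumption)
  alternative <- match.arg(alternative)
  s <- .autocorr_setup(y, W)
  est <- .moran_stat(s$d, s$W, s$n, s$S0, s$m2)
  E <- -1 / (s$n - 1)
  V <- .moran_var(s, assumption)
  z <- (est - E) / sqrt(V)
  p_perm <- NULL
  if (n_perm > 0L) {
    null <- permutation_null(morans_i_stat, y, s$W, n_perm = n_perm,
                             seed = seed)
    p_perm <- .perm_p(est, null, E, alternative)
  }
  .autocorr_result("morans_i", est, E, V, z, .analytic_p(z, alternative),
                   p_perm, n_perm, assumption, alternative)
}

#' Global Geary's C test of spatial autocorrelation
#'
#' Computes C = (N - 1) * sum_ij w_ij (y_i - y_j)^2 /
#' (2 S0 sum_i (y_i - ybar)^2), with null expectation E(C) = 1. C below 1
#' indicates positive spatial autocorrelation (similar neighbouring
#' values), C above 1 negative autocorrelation; the statistic is driven by
#' squared differences between neighbours and so is more sensitive to
#' local contrasts than Moran's I.
#'
#' @inheritParams morans_i
#' @return an `autocorr_result`; see [morans_i].
#' @export
gearys_c <- function(y, W, assumption = c("randomization", "normality"),
                     alternative = c("two.sided", "greater", "less"),
                     n_perm = 0L, seed = NULL) {
  assumption <- match.arg(assumption)
  alternative <- match.arg(alternative)
  s <- .autocorr_setup(y, W)
  est <- gearys_c_stat(y, s$W)
  E <- 1
  V <- .geary_var(s, assumption)
  ## low C = positive autocorrelation: "greater" means greater
  ## autocorrelation, i.e. C below its expectation
  zdir <- switch(alternative, two.sided = , less = 1, greater = -1)
  z <- (est - E) / sqrt(V)
  p <- .analytic_p(zdir * z, alternative)
  p_perm <- NULL
  if (n_perm > 0L) {
    null <- permutation_null(gearys_c_stat, y, s$W, n_perm = n_perm,
                             seed = seed)
    p_perm <- .perm_p(est, null, E, alternative, flip = TRUE)
  }
  .autocorr_result("gearys_c", est, E, V, z, p, p_perm, n_perm, assumption,
                   alternative)
}

.perm_p <- function(obs, null, E, alternative, flip = FALSE) {
  n_perm <- length(null)
  dir <- if (flip) -1 else 1
  extreme <- switch(alternative,
    two.sided = sum(abs(null - E) >= abs(obs - E)),
    greater = sum(dir * null >= dir * obs),
    less = sum(dir * null <= dir * obs))
  (1 + extreme) / (n_perm + 1)
}

#' Moran's I point estimate
#' @param y numeric vector.
#' @param W numeric weight matrix (zero diagonal).
#' @return scalar estimate.
#' @export
morans_i_stat <- function(y, W) {
  if (inherits(W, "weight_matrix")) W <- W$w
  d <- y - mean(y)
  .moran_stat(d, W, length(y), sum(W), sum(d^2))
}

#' Geary's C point estimate
#' @inheritParams morans_i_stat
#' @return scalar estimate.
#' @export
gearys_c_stat <- function(y, W) {
  if (inherits(W, "weight_matrix")) W <- W$w
  n <- length(y)
  d <- y - mean(y)
  rs_cs <- rowSums(W) + colSums(W)
  (n - 1) * .geary_num(y, W, rs_cs) / (2 * sum(W) * sum(d^2))
}

#' Permutation null distribution of a spatial statistic
#'
#' Recomputes `statistic_fn(y[perm], W)` over `n_perm` uniform random
#' relabelings of the observations across the areal units.
#'
#' @param statistic_fn function of `(y, W)` returning a scalar, e.g.
#'   [morans_i_stat] or [gearys_c_stat].
#' @param y numeric vector.
#' @param W weight matrix.
#' @param n_perm number of permutations (>= 99).
#' @param seed RNG seed (required, for reproducibility).
#' @return numeric vector of `n_perm` permuted statistic values.
#' @export
permutation_null <- function(statistic_fn, y, W, n_perm = 999L, seed) {
  if (missing(seed) || is.null(seed))
    stop("a seed is required for the permutation null")
  if (n_perm < 99L) stop("n_perm must be at least 99")
  if (inherits(W, "weight_matrix")) W <- W$w
  n <- length(y)
  set.seed(seed)
  vapply(seq_len(n_perm),
         function(b) statistic_fn(y[sample.int(n)], W),
         numeric(1L))
}
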