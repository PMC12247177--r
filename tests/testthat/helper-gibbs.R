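## Independent dense-matrix Gibbs sampler for the model
##   y = X beta + u + v + eps,  u ~ iCAR(tau_u), v ~ N(0, 1/tau_v)
## used as a brute-force oracle: the whole coefficient vector
## theta = (beta, u, v) is drawn in ONE joint Gaussian block from its full
## conditional, with the sum-to-zero constraint on u imposed by
## conditioning-by-kriging, followed by the same Gamma precision updates.
## Everything is dense and literal; no code shared with the package
## sampler beyond the structure matrix constructor.
brute_force_bym_sampler <- function(y, X, Qu, n_iter, n_burn, seed,
                                    prior = c(1, 5e-5), beta_prec = 1e-6) {
  set.seed(seed)
  n <- length(y); p <- ncol(X)
  M <- cbind(X, diag(n), diag(n))
  d <- ncol(M)
  A <- matrix(0, 1, d); A[1, p + seq_len(n)] <- 1   # sum(u) = 0
  tau_eps <- 1 / var(y); tau_u <- 1; tau_v <- 1
  keep <- matrix(NA_real_, n_iter - n_burn, d + 3L)
  for (it in seq_len(n_iter)) {
    P <- matrix(0, d, d)
    diag(P)[seq_len(p)] <- beta_prec
    P[p + seq_len(n), p + seq_len(n)] <- tau_u * Qu
    diag(P)[p + n + seq_len(n)] <- tau_v
    Q <- tau_eps * crossprod(M) + P
    R <- chol(Q)
    mu <- backsolve(R, backsolve(R, tau_eps * crossprod(M, y),
                                 transpose = TRUE))
    th <- mu + backsolve(R, rnorm(d))
    ## condition on A theta = 0
    QiA <- backsolve(R, backsolve(R, t(A), transpose = TRUE))
    th <- th - QiA %*% solve(A %*% QiA, A %*% th)
    th <- as.numeric(th)
    beta <- th[seq_len(p)]
    u <- th[p + seq_len(n)]
    v <- th[p + n + seq_len(n)]
    resid <- y - as.numeric(M %*% th)
    tau_eps <- rgamma(1, prior[1] + n / 2, prior[2] + sum(resid^2) / 2)
    tau_u <- rgamma(1, prior[1] + (n - 1) / 2,
                    prior[2] + as.numeric(t(u) %*% Qu %*% u) / 2)
    tau_v <- rgamma(1, prior[1] + n / 2, prior[2] + sum(v^2) / 2)
    if (it > n_burn)
      keep[it - n_burn, ] <- c(th, tau_eps, tau_u, tau_v)
  }
  list(beta = keep[, seq_len(p), drop = FALSE],
       u = keep[, p + seq_len(n), drop = FALSE],
       v = keep[, p + n + seq_len(n), drop = FALSE],
       tau = keep[, d + 1:3, drop = FALSE])
}

## standardize a covariate exactly as build_designs does
std_cov <- function(x) (x - mean(x)) / sd(x)

## a small Gaussian region table with one covariate, no spatial structure
toy_linear_table <- function(n, beta0, beta1, sigma, seed) {
  set.seed(seed)
  x <- runif(n)
  y <- beta0 + beta1 * std_cov(x) + rnorm(n, 0, sigma)
  region_table(data.frame(unit_id = sprintf("u%03d", seq_len(n)),
                          sample = 1L, events = 0L, x1 = x, y = y))
}
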