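## Conjugate Gibbs sampler for the Gaussian geo-additive model
##   y = X beta + sum_j A_j f_j + u + v + eps
## All full conditionals are Gaussian (effect blocks) or Gamma
## (precisions); blocks are updated sequentially with the i.i.d. field v
## marginalized out of the other effect updates (partially collapsed
## Gibbs), and u and each f_j are recentred to mean zero after every
## sweep with the subtracted mean absorbed into the intercept.

## draw from N(Q^{-1} b, Q^{-1}) for small dense Q
.draw_gaussian <- function(Q, b) {
  R <- chol(Q)
  m <- backsolve(R, backsolve(R, b, transpose = TRUE))
  as.numeric(m + backsolve(R, stats::rnorm(length(b))))
}

#' Fit a geo-additive model by Gibbs sampling
#'
#' Runs a blocked Gibbs sampler for the Gaussian identity-link
#' geo-additive model defined by a [model_spec] over a [region_table].
#' Every full conditional is conjugate: the fixed effects, each RW2
#' smooth, the iCAR field u and the i.i.d. field v are Gaussian blocks,
#' and each precision is Gamma with shape increased by half the rank of
#' its structure matrix and rate increased by half the corresponding
#' quadratic form. Because v and the observation error are only jointly
#' identified with one observation per unit, v is integrated out of the
#' beta/smooth/u updates (their effective noise is v + eps) and redrawn
#' from its own conditional each sweep, which keeps the sampler mixing
#' well along the weakly identified tau_v/tau_eps ridge. After each sweep u and each smooth are recentred to
#' mean zero (per graph component for u) and the removed mean is absorbed
#' into the intercept, which enforces the usual iCAR/RW2 sum-to-zero
#' identifiability constraints.
#'
#' The response must already be on a Gaussian scale: either transform it
#' first (see [fit_rank_normal]) or pass data that is Gaussian as is.
#'
#' @param table a [region_table] with the covariate columns of `spec` and
#'   the response column `response`.
#' @param spec a [model_spec].
#' @param response name of the response column (default `"y"`).
#' @param n_iter total MCMC iterations (default 10000).
#' @param n_burn burn-in iterations discarded (default 2000).
#' @param thin thinning interval (default 2).
#' @param seed RNG seed (mandatory).
#' @return object of class `anc_gibbs_fit`: retained draws of `beta`
#'   (standardized-covariate scale), `f` (per smooth), `u`, `v`,
#'   precisions, per-draw fitted values, plus the designs and bookkeeping
#'   needed by [summarize_fit], [model_criteria] and [predict.anc_gibbs_fit].
#' @export
gibbs_fit <- function(table, spec, response = "y",
                      n_iter = 10000L, n_burn = 2000L, thin = 2L, seed) {
  stopifnot(inherits(table, "region_table"), inherits(spec, "model_spec"))
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  if (n_iter <= n_burn) stop("n_iter must exceed n_burn")
  if (!response %in% names(table))
    stop("response column '", response, "' not found; transform the ",
         "outcome first (fit_rank_normal) or supply a Gaussian column")
  y <- table[[response]]
  if (any(is.na(y))) stop("response has missing values")
  des <- build_designs(table, spec)
  n <- length(y)
  X <- des$X; p <- ncol(X)
  J <- length(des$A)
  has_v <- spec$variant %in% c("additive_iid", "bym")
  has_u <- spec$variant == "bym"
  pr <- spec$priors

  set.seed(seed)
  XtX <- crossprod(X)
  if (has_u) {
    eig <- eigen(des$Q_u, symmetric = TRUE)
    E <- eig$vectors
    lam <- pmax(eig$values, 0)
    ncomp <- max(des$components)
    rank_u <- n - ncomp
  }
  rank_f <- vapply(des$K, function(K) ncol(K) - 2L, integer(1L))

  ## state
  beta <- c(mean(y), rep(0, p - 1L))
  f <- lapply(des$A, function(Aj) rep(0, ncol(Aj)))
  u <- rep(0, n); v <- rep(0, n)
  tau_eps <- 1 / max(stats::var(y), 1e-12)
  tau_u <- 1; tau_v <- 1
  tau_f <- rep(1, J)
  Xb <- as.numeric(X %*% beta)
  Af <- rep(0, n)

  n_keep <- length(seq(n_burn + 1L, n_iter, by = thin))
  keep_beta <- matrix(NA_real_, n_keep, p,
                      dimnames = list(NULL, colnames(X)))
  keep_f <- lapply(des$A, function(Aj) matrix(NA_real_, n_keep, ncol(Aj)))
  keep_u <- if (has_u) matrix(NA_real_, n_keep, n) else NULL
  keep_v <- if (has_v) matrix(NA_real_, n_keep, n) else NULL
  keep_fitted <- matrix(NA_real_, n_keep, n)
  keep_prec <- matrix(NA_real_, n_keep, 3L + J)
  colnames(keep_prec) <- c("tau_eps", "tau_u", "tau_v",
                           if (J > 0L) paste0("tau_f_", names(des$A)))
  s <- 0L
  for (it in seq_len(n_iter)) {
    ## v_i + eps_i is only jointly identified under a Gaussian
    ## likelihood, so v is marginalized out of the effect-block updates
    ## (partially collapsed Gibbs) and redrawn afterwards: the combined
    ## noise w = v + eps has precision tau_w. This avoids the slow ridge
    ## walk between tau_v and tau_eps freezing the effect blocks.
    tau_w <- if (has_v) 1 / (1 / tau_eps + 1 / tau_v) else tau_eps

    ## fixed effects
    r <- y - Af - u
    beta <- .draw_gaussian(tau_w * XtX + diag(spec$beta_prec, p),
                           tau_w * crossprod(X, r))
    Xb <- as.numeric(X %*% beta)

    ## smooths
    for (j in seq_len(J)) {
      Aj <- des$A[[j]]
      Af <- Af - as.numeric(Aj %*% f[[j]])
      rj <- y - Xb - Af - u
      Qj <- tau_w * crossprod(Aj) + tau_f[j] * des$K[[j]]
      fj <- .draw_gaussian(Qj, tau_w * crossprod(Aj, rj))
      m <- mean(fj)
      fj <- fj - m
      beta[1L] <- beta[1L] + m
      Xb <- Xb + m
      f[[j]] <- fj
      Af <- Af + as.numeric(Aj %*% fj)
    }

    ## structured spatial field (iCAR)
    if (has_u) {
      ru <- y - Xb - Af
      denom <- tau_u * lam + tau_w
      mean_u <- E %*% (crossprod(E, tau_w * ru) / denom)
      u <- as.numeric(mean_u + E %*% (stats::rnorm(n) / sqrt(denom)))
      m <- mean(u)
      u <- u - stats::ave(u, des$components)
      beta[1L] <- beta[1L] + m
      Xb <- Xb + m
    }

    ## unstructured field
    if (has_v) {
      rv <- y - Xb - Af - u
      prec <- tau_eps + tau_v
      v <- stats::rnorm(n, tau_eps * rv / prec, sqrt(1 / prec))
    }

    ## precisions
    resid <- y - Xb - Af - u - v
    tau_eps <- stats::rgamma(1L, pr$tau_eps[1L] + n / 2,
                             pr$tau_eps[2L] + sum(resid^2) / 2)
    if (has_u)
      tau_u <- stats::rgamma(1L, pr$tau_u[1L] + rank_u / 2,
                             pr$tau_u[2L] +
                               as.numeric(crossprod(u, des$Q_u %*% u)) / 2)
    if (has_v)
      tau_v <- stats::rgamma(1L, pr$tau_v[1L] + n / 2,
                             pr$tau_v[2L] + sum(v^2) / 2)
    for (j in seq_len(J))
      tau_f[j] <- stats::rgamma(1L, pr$tau_smooth[1L] + rank_f[j] / 2,
                                pr$tau_smooth[2L] +
                                  as.numeric(crossprod(f[[j]],
                                    des$K[[j]] %*% f[[j]])) / 2)
    taus <- c(tau_eps, tau_u, tau_v, tau_f)
    if (!all(is.finite(taus)) || any(taus > 1e15))
      stop("precision diverged at iteration ", it,
           " (tau = ", paste(format(taus), collapse = ", "), ")")

    if (it > n_burn && (it - n_burn - 1L) %% thin == 0L) {
      s <- s + 1L
      keep_beta[s, ] <- beta
      for (j in seq_len(J)) keep_f[[j]][s, ] <- f[[j]]
      if (has_u) keep_u[s, ] <- u
      if (has_v) keep_v[s, ] <- v
      keep_fitted[s, ] <- Xb + Af + u + v
      keep_prec[s, ] <- c(tau_eps, tau_u, tau_v, tau_f)
    }
  }
  structure(list(beta = keep_beta[seq_len(s), , drop = FALSE],
                 f = lapply(keep_f, function(m) m[seq_len(s), , drop = FALSE]),
                 u = if (has_u) keep_u[seq_len(s), , drop = FALSE],
                 v = if (has_v) keep_v[seq_len(s), , drop = FALSE],
                 fitted = keep_fitted[seq_len(s), , drop = FALSE],
                 precisions = keep_prec[seq_len(s), , drop = FALSE],
                 y = y, designs = des, spec = spec,
                 control = list(n_iter = n_iter, n_burn = n_burn,
                                thin = thin, seed = seed),
                 unit_id = table$unit_id),
            class = "anc_gibbs_fit")
}

#' @export
print.anc_gibbs_fit <- function(x, ...) {
  cat("anc_gibbs_fit:", x$spec$variant, "|", nrow(x$beta),
      "retained draws |", length(x$y), "units\n")
  invisible(x)
}

.quantile_row <- function(x) {
  q <- stats::quantile(x, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
  c(mean = mean(x), sd = stats::sd(x), q2.5 = q[1L], q50 = q[2L],
    q97.5 = q[3L])
}

## fixed-effect draws back-transformed to the original covariate scale
.beta_original_scale <- function(fit) {
  des <- fit$designs
  b <- fit$beta
  out <- b
  for (nm in colnames(b)) {
    if (nm == "(Intercept)") next
    sc <- des$scaling[[nm]]
    out[, nm] <- b[, nm] / sc["sd"]
    out[, "(Intercept)"] <- out[, "(Intercept)"] -
      b[, nm] * sc["mean"] / sc["sd"]
  }
  out
}

#' Posterior summary of a geo-additive fit
#'
#' Summarizes the retained draws into the conventional five-column table
#' (mean, sd, 2.5%, 50%, 97.5%) for the fixed effects (reported on the
#' original covariate scale) and the precisions, pointwise posterior mean
#' and 95% credible band per smooth over the bin midpoints, and per-unit
#' posterior-mean fitted values with residuals. A fixed effect is flagged
#' significant when its 95% credible interval excludes zero.
#'
#' @param fit an [gibbs_fit] result.
#' @param transform optional [fit_rank_normal] model; if supplied, fitted
#'   values and residuals are also reported back on the original response
#'   scale.
#' @return object of class `anc_fit_summary`: list with data frames
#'   `fixed`, `precisions`, `fitted`, and list `smooths` (per-smooth data
#'   frame with `x`, `mean`, `sd`, `q2.5`, `q50`, `q97.5`).
#' @export
summarize_fit <- function(fit, transform = NULL) {
  stopifnot(inherits(fit, "anc_gibbs_fit"))
  if (nrow(fit$beta) < 100L)
    stop("need at least 100 retained draws to summarize")
  b <- .beta_original_scale(fit)
  fx <- t(apply(b, 2L, .quantile_row))
  fixed <- data.frame(term = rownames(fx), fx, row.names = NULL,
                      check.names = FALSE)
  fixed$significant <- fixed$q2.5 > 0 | fixed$q97.5 < 0
  prec <- t(apply(fit$precisions, 2L, .quantile_row))
  ## drop precision rows for effects absent from the variant
  active <- c(TRUE, !is.null(fit$u), !is.null(fit$v),
              rep(TRUE, length(fit$f)))
  precisions <- data.frame(term = rownames(prec), prec,
                           row.names = NULL, check.names = FALSE)[active, ]
  smooths <- list()
  for (nm in names(fit$f)) {
    sm <- t(apply(fit$f[[nm]], 2L, .quantile_row))
    smooths[[nm]] <- data.frame(x = as.numeric(fit$designs$bin_mid[[nm]]),
                                sm, row.names = NULL, check.names = FALSE)
  }
  fitted_mean <- colMeans(fit$fitted)
  fitted <- data.frame(unit_id = fit$unit_id, observed = fit$y,
                       fitted = fitted_mean,
                       residual = fit$y - fitted_mean,
                       stringsAsFactors = FALSE)
  if (!is.null(transform)) {
    fitted$observed_original <- rank_normal_inverse(transform, fit$y)
    fitted$fitted_original <- rank_normal_inverse(transform, fitted_mean)
    fitted$residual_original <- fitted$observed_original -
      fitted$fitted_original
  }
  structure(list(fixed = fixed, precisions = precisions, smooths = smooths,
                 fitted = fitted, variant = fit$spec$variant),
            class = "anc_fit_summary")
}

#' @export
print.anc_fit_summary <- function(x, ...) {
  cat("Posterior summary (", x$variant, ")\n\nFixed effects:\n", sep = "")
  print(x$fixed, digits = 4)
  cat("\nPrecisions:\n")
  print(x$precisions, digits = 4)
  if (length(x$smooths) > 0L)
    cat("\nSmooths:", paste(names(x$smooths), collapse = ", "), "\n")
  invisible(x)
}

#' Fitted values and residuals from a geo-additive fit
#'
#' @param object an [gibbs_fit] result.
#' @param transform optional [fit_rank_normal] model for reporting on the
#'   original response scale.
#' @param ... unused.
#' @return data frame keyed by `unit_id` with observed, posterior-mean
#'   fitted and residual columns (plus `_original` versions when a
#'   transform is given), suitable for joining to polygon geometries for
#'   choropleth rendering.
#' @export
predict.anc_gibbs_fit <- function(object, transform = NULL, ...) {
  summarize_fit(object, transform = transform)$fitted
}

#' Empirical check of the iCAR conditional-mean property
#'
#' For a correctly implemented iCAR update, each structured effect u_i is
#' conditionally centred on the mean of its neighbours with precision
#' proportional to the neighbour count. Pooling retained draws, the
#' regression of u_i on its neighbour mean should have a slope near 1
#' when the structured field dominates.
#'
#' @param fit a [gibbs_fit] result for a `"bym"` model.
#' @param graph the [spatial_graph] used in the fit (defaults to the
#'   spec's graph).
#' @return list with `slope`, `n_pooled`, and `skipped` (TRUE with a
#'   notice when the graph has no edges).
#' @export
icar_full_conditional_check <- function(fit, graph = fit$spec$graph) {
  stopifnot(inherits(fit, "anc_gibbs_fit"))
  if (is.null(fit$u)) stop("fit has no structured spatial field")
  if (nrow(graph$edges) == 0L) {
    message("graph has no edges; iCAR conditional check skipped")
    return(list(slope = NA_real_, n_pooled = 0L, skipped = TRUE))
  }
  W <- weight_matrix(graph, "binary")$w
  perm <- match(fit$unit_id, graph$node_ids)
  W <- W[perm, perm, drop = FALSE]
  deg <- rowSums(W)
  keep <- deg > 0
  ubar <- t(W[keep, , drop = FALSE] %*% t(fit$u)) / rep(deg[keep],
                                                        each = nrow(fit$u))
  ui <- fit$u[, keep, drop = FALSE]
  slope <- stats::cov(as.numeric(ubar), as.numeric(ui)) /
    stats::var(as.numeric(ubar))
  list(slope = slope, n_pooled = length(ui), skipped = FALSE)
}
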