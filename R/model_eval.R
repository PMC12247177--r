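## Model comparison criteria (DIC, WAIC, sum-log-CPO) and the
## probability-integral-transform calibration diagnostic, all computed
## from the per-draw pointwise Gaussian log-likelihood matrix.

#' Pointwise predictive log-likelihood matrix of a fit
#'
#' Entry (s, i) is the log predictive density of y_i under draw s. The
#' criteria take a predictive focus: a unit's own unstructured effect
#' v_i is idiosyncratic and unobservable for a new or held-out
#' observation, so for variants that carry v the density is
#' log N(y_i | X_i beta + sum_j f_j + u_i, 1/tau_eps + 1/tau_v), i.e. v
#' is folded into the noise. For variants without v this reduces to
#' log N(y_i | fitted_i^(s), 1/tau_eps^(s)). Without this focus the
#' unstructured field can interpolate the data and every
#' conditional-likelihood criterion degenerates.
#'
#' @param fit a [gibbs_fit] result.
#' @return S x N numeric matrix.
#' @export
pointwise_loglik <- function(fit) {
  stopifnot(inherits(fit, "anc_gibbs_fit"))
  pm <- .predictive_moments(fit)
  S <- nrow(pm$mean)
  ll <- matrix(NA_real_, S, length(fit$y))
  for (s in seq_len(S))
    ll[s, ] <- stats::dnorm(fit$y, pm$mean[s, ], pm$sd[s], log = TRUE)
  ll
}

## per-draw predictive mean (structured part) and sd (v folded into the
## noise when present)
.predictive_moments <- function(fit) {
  mean_s <- fit$fitted
  var_s <- 1 / fit$precisions[, "tau_eps"]
  if (!is.null(fit$v)) {
    mean_s <- mean_s - fit$v
    var_s <- var_s + 1 / fit$precisions[, "tau_v"]
  }
  list(mean = mean_s, sd = sqrt(unname(var_s)))
}

## column-wise log(mean(exp(x))) without overflow
.log_col_mean_exp <- function(m) {
  mx <- apply(m, 2L, max)
  mx + log(colMeans(exp(sweep(m, 2L, mx))))
}

#' Deviance information criterion
#'
#' DIC = Dbar + pD with Dbar the posterior mean deviance
#' (mean over draws of -2 * sum_i loglik) and pD = Dbar - D(thetabar),
#' the deviance at the plug-in posterior mean.
#'
#' @param loglik S x N pointwise log-likelihood matrix (see
#'   [pointwise_loglik]).
#' @param deviance_at_posterior_mean deviance evaluated at the plug-in
#'   posterior-mean parameters (posterior-mean fitted values and
#'   posterior-mean error precision; see [model_criteria]).
#' @return list with `DIC`, `pD`, `Dbar`. Negative pD is reported as is
#'   (a warning is raised), never clipped.
#' @export
dic <- function(loglik, deviance_at_posterior_mean) {
  if (nrow(loglik) < 100L) stop("need at least 100 draws")
  Dbar <- mean(-2 * rowSums(loglik))
  pD <- Dbar - deviance_at_posterior_mean
  if (pD < 0) warning("negative pD (", format(pD), "); poorly behaved fit")
  list(DIC = Dbar + pD, pD = pD, Dbar = Dbar)
}

#' Widely applicable information criterion
#'
#' lppd = sum_i log(mean_s exp loglik(s, i)) via log-sum-exp;
#' pWAIC = sum_i var_s(loglik(s, i)); WAIC = -2 (lppd - pWAIC).
#'
#' @inheritParams dic
#' @return list with `WAIC`, `pWAIC`, `lppd`, and `unreliable` (indices of
#'   observations whose loglik variance exceeds 0.4, for which the pWAIC
#'   contribution is a poor variance estimate).
#' @export
waic <- function(loglik) {
  if (nrow(loglik) < 100L) stop("need at least 100 draws")
  lppd_i <- .log_col_mean_exp(loglik)
  var_i <- apply(loglik, 2L, stats::var)
  unreliable <- which(var_i > 0.4)
  if (length(unreliable) > 0L)
    warning(length(unreliable),
            " observation(s) with loglik variance > 0.4; ",
            "their WAIC contribution is unreliable")
  list(WAIC = -2 * (sum(lppd_i) - sum(var_i)), pWAIC = sum(var_i),
       lppd = sum(lppd_i), unreliable = unreliable)
}

#' Conditional predictive ordinate
#'
#' CPO_i is the harmonic-mean estimator of the leave-one-out predictive
#' density: CPO_i = 1 / mean_s exp(-loglik(s, i)), evaluated via
#' log-sum-exp. Larger sum of log CPO indicates better out-of-sample fit.
#'
#' @inheritParams dic
#' @return list with `cpo` (per-observation vector), `sum_log_cpo`, and
#'   `flagged` (indices with numerically zero CPO).
#' @export
cpo <- function(loglik) {
  if (nrow(loglik) < 100L) stop("need at least 100 draws")
  log_cpo <- -.log_col_mean_exp(-loglik)
  flagged <- which(!is.finite(log_cpo))
  if (length(flagged) > 0L)
    warning(length(flagged), " observation(s) with numerically zero CPO")
  list(cpo = exp(log_cpo), sum_log_cpo = sum(log_cpo), flagged = flagged)
}

#' Probability integral transform calibration check
#'
#' PIT_i = mean_s Phi((y_i - mu_i^(s)) / sd^(s)) is the
#' posterior-predictive probability of a new observation falling below the
#' observed one, with the predictive mean and sd of [pointwise_loglik]
#' (a unit's own unstructured effect counts as noise). Under a well-calibrated model the PIT values are
#' approximately uniform on (0, 1); uniformity is scored with a
#' Kolmogorov-Smirnov test.
#'
#' @param fit a [gibbs_fit] result.
#' @return list with `pit` (per-observation vector in [0, 1]),
#'   `ks_statistic`, `ks_p`.
#' @export
pit <- function(fit) {
  stopifnot(inherits(fit, "anc_gibbs_fit"))
  pm <- .predictive_moments(fit)
  S <- nrow(pm$mean)
  p <- rep(0, length(fit$y))
  for (s in seq_len(S))
    p <- p + stats::pnorm(fit$y, pm$mean[s, ], pm$sd[s])
  p <- p / S
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  list(pit = p, ks_statistic = unname(ks$statistic), ks_p = ks$p.value)
}

#' All comparison criteria for one fit
#'
#' Convenience wrapper computing sum-log-CPO, DIC (with plug-in deviance
#' at the posterior-mean fitted values and posterior-mean error
#' precision), WAIC and the PIT vector for a single fitted model.
#'
#' @param fit a [gibbs_fit] result.
#' @param label model label used in comparison tables.
#' @return object of class `criteria_report`.
#' @export
model_criteria <- function(fit, label = fit$spec$variant) {
  stopifnot(inherits(fit, "anc_gibbs_fit"))
  ll <- pointwise_loglik(fit)
  pm <- .predictive_moments(fit)
  dev_plugin <- -2 * sum(stats::dnorm(fit$y, colMeans(pm$mean),
                                      sqrt(mean(pm$sd^2)), log = TRUE))
  d <- dic(ll, dev_plugin)
  w <- waic(ll)
  cp <- cpo(ll)
  pt <- pit(fit)
  structure(list(label = label, sum_log_cpo = cp$sum_log_cpo,
                 DIC = d$DIC, pD = d$pD, WAIC = w$WAIC, pWAIC = w$pWAIC,
                 lppd = w$lppd, pit = pt$pit,
                 ks_statistic = pt$ks_statistic, ks_p = pt$ks_p,
                 n_obs = length(fit$y),
                 y_digest = sum(fit$y) + sum(fit$y^2) * pi),
            class = "criteria_report")
}

#' @export
print.criteria_report <- function(x, ...) {
  cat(sprintf("%s: sum log CPO %.2f | DIC %.2f (pD %.1f) | WAIC %.2f\n",
              x$label, x$sum_log_cpo, x$DIC, x$pD, x$WAIC))
  invisible(x)
}

#' Rank competing models by information criteria
#'
#' Orders models by DIC ascending, breaking ties by WAIC ascending and
#' then by sum-log-CPO descending; the first row is the selected model.
#' All reports must have been computed on identical data.
#'
#' @param reports list of `criteria_report` objects (>= 1) from
#'   [model_criteria].
#' @return data frame with columns `model`, `sum_log_cpo`, `DIC`, `WAIC`,
#'   `rank`, `best`, and `tied_best` (TRUE when several models share the
#'   top criteria exactly).
#' @export
compare_models <- function(reports) {
  if (inherits(reports, "criteria_report")) reports <- list(reports)
  stopifnot(length(reports) >= 1L,
            all(vapply(reports, inherits, logical(1L), "criteria_report")))
  n_obs <- vapply(reports, `[[`, numeric(1L), "n_obs")
  dig <- vapply(reports, `[[`, numeric(1L), "y_digest")
  if (length(unique(n_obs)) > 1L || length(unique(dig)) > 1L)
    stop("criteria were computed on differing data; refusing to compare")
  tab <- data.frame(
    model = vapply(reports, `[[`, character(1L), "label"),
    sum_log_cpo = vapply(reports, `[[`, numeric(1L), "sum_log_cpo"),
    DIC = vapply(reports, `[[`, numeric(1L), "DIC"),
    WAIC = vapply(reports, `[[`, numeric(1L), "WAIC"),
    stringsAsFactors = FALSE)
  ord <- order(tab$DIC, tab$WAIC, -tab$sum_log_cpo)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  tab$best <- tab$rank == 1L
  tab$tied_best <- nrow(tab) > 1L &&
    all(abs(tab$DIC[1:2] - tab$DIC[1L]) < 1e-12) &&
    all(abs(tab$WAIC[1:2] - tab$WAIC[1L]) < 1e-12) &&
    all(abs(tab$sum_log_cpo[1:2] - tab$sum_log_cpo[1L]) < 1e-12)
  rownames(tab) <- NULL
  tab
}
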