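## minimal fit-shaped object: criteria only need fitted draws, tau_eps
## draws and the observations
fake_fit <- function(fitted, tau_eps, y) {
  structure(list(fitted = fitted,
                 precisions = cbind(tau_eps = tau_eps),
                 y = y),
            class = "anc_gibbs_fit")
}

test_that("pointwise log-likelihoods match a literal scalar loop", {
  set.seed(1)
  S <- 120; N <- 3
  fit <- fake_fit(matrix(rnorm(S * N), S, N), rgamma(S, 5, 1), rnorm(N))
  ll <- pointwise_loglik(fit)
  expect_equal(dim(ll), c(S, N))
  for (s in c(1, 57, S)) for (i in 1:N) {
    sd_s <- 1 / sqrt(unname(fit$precisions[s, 1]))
    expect_equal(ll[s, i],
                 log(1 / (sd_s * sqrt(2 * pi))) -
                   (fit$y[i] - fit$fitted[s, i])^2 / (2 * sd_s^2))
  }
  ## at the mode with unit precision the density is 1/sqrt(2*pi)
  fit0 <- fake_fit(matrix(2, 100, 4), rep(1, 100), rep(2, 4))
  expect_equal(unique(as.numeric(pointwise_loglik(fit0))),
               log(1 / sqrt(2 * pi)))
})

test_that("a degenerate chain collapses every criterion correctly", {
  y <- c(0.2, -1, 0.7, 2)
  fit <- fake_fit(matrix(rep(c(0, -1, 1, 1.5), each = 150), 150, 4),
                  rep(2, 150), y)
  ll <- pointwise_loglik(fit)
  D_point <- -2 * sum(ll[1, ])
  d <- dic(ll, D_point)
  expect_equal(d$pD, 0)
  expect_equal(d$DIC, D_point)
  w <- waic(ll)
  expect_equal(w$pWAIC, 0)
  expect_equal(w$WAIC, D_point)
  cp <- cpo(ll)
  expect_equal(cp$cpo, exp(ll[1, ]))
  expect_equal(cp$sum_log_cpo, sum(ll[1, ]))
})

test_that("pD approximates the effective parameter count on a conjugate toy", {
  ## y_i ~ N(mu, 1), flat-ish prior: posterior mu ~ N(ybar, 1/n); a
  ## single free parameter, so pD should be close to 1
  set.seed(8)
  n <- 50; y <- rnorm(n, 3, 1)
  mu_draws <- rnorm(5000, mean(y), 1 / sqrt(n))
  fit <- fake_fit(matrix(mu_draws, 5000, n), rep(1, 5000), y)
  ll <- pointwise_loglik(fit)
  D_plug <- -2 * sum(dnorm(y, mean(mu_draws), 1, log = TRUE))
  d <- dic(ll, D_plug)
  expect_equal(d$pD, 1, tolerance = 0.1)
  w <- waic(ll)
  expect_equal(w$pWAIC, 1, tolerance = 0.15)
  ## on this large-n Gaussian toy DIC and WAIC agree to first order
  expect_lt(abs(w$WAIC - d$DIC), 0.05 * abs(d$DIC))
})

test_that("WAIC matches the arviz reference implementation", {
  set.seed(3)
  S <- 400; N <- 10
  fit <- fake_fit(matrix(rnorm(S * N, 0, 0.7), S, N),
                  rgamma(S, 20, 10), rnorm(N))
  ll <- pointwise_loglik(fit)
  tmp <- withr::local_tempfile(fileext = ".csv")
  out <- withr::local_tempfile(fileext = ".txt")
  utils::write.table(ll, tmp, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  script <- withr::local_tempfile(fileext = ".py")
  writeLines(c(
    "import sys, numpy as np, arviz as az",
    "ll = np.loadtxt(sys.argv[1], delimiter=',')",
    "idata = az.from_dict(log_likelihood={'y': ll[None, :, :]})",
    "w = az.waic(idata, scale='deviance')",
    "open(sys.argv[2], 'w').write('%.12f %.12f' % (w.elpd_waic, w.p_waic))"),
    script)
  status <- system2("python", c(script, tmp, out),
                    stdout = FALSE, stderr = FALSE)
  expect_equal(status, 0L)
  ref <- scan(out, quiet = TRUE)
  mine <- suppressWarnings(waic(ll))
  ## arviz computes the draw variance with denominator S (population
  ## form); this package uses the textbook sample variance (S - 1), so
  ## rescale before comparing
  adj <- (S - 1) / S
  expect_equal(mine$pWAIC * adj, ref[2], tolerance = 1e-8)
  expect_equal(-2 * (mine$lppd - mine$pWAIC * adj), ref[1],
               tolerance = 1e-8)
})

test_that("CPO matches a brute-force loop and obeys Jensen's bound", {
  set.seed(9)
  S <- 150; N <- 2
  fit <- fake_fit(matrix(rnorm(S * N), S, N), rgamma(S, 4, 2), rnorm(N))
  ll <- pointwise_loglik(fit)
  cp <- cpo(ll)
  for (i in 1:N) {
    acc <- 0
    for (s in 1:S) acc <- acc + exp(-ll[s, i])
    expect_equal(cp$cpo[i], 1 / (acc / S), tolerance = 1e-12)
  }
  ## harmonic mean <= arithmetic mean, pointwise and in sum
  expect_lte(cp$sum_log_cpo, suppressWarnings(waic(ll))$lppd)
})

test_that("criteria are invariant to draw order and robust to huge logliks", {
  set.seed(2)
  S <- 200; N <- 6
  ll <- matrix(rnorm(S * N, -2, 1), S, N)
  perm <- sample(S)
  expect_equal(suppressWarnings(waic(ll)),
               suppressWarnings(waic(ll[perm, ])))
  expect_equal(cpo(ll), cpo(ll[perm, ]))
  expect_equal(dic(ll, 10)$DIC, dic(ll[perm, ], 10)$DIC)
  ## log-sum-exp must not overflow at |loglik| ~ 1e4
  big <- matrix(-1e4 + rnorm(200 * 4), 200, 4)
  expect_true(is.finite(suppressWarnings(waic(big))$WAIC))
  expect_true(is.finite(suppressWarnings(cpo(big))$sum_log_cpo))
  small <- matrix(1e4 + rnorm(200 * 4), 200, 4)
  expect_true(is.finite(suppressWarnings(waic(small))$WAIC))
  expect_true(is.finite(suppressWarnings(cpo(small))$sum_log_cpo))
})

test_that("PIT hits its extremes and stays in the unit interval", {
  S <- 150
  fit_hi <- fake_fit(matrix(rnorm(S * 3), S, 3), rep(4, S),
                     c(50, 60, 70))    # y far above every fitted value
  expect_equal(pit(fit_hi)$pit, c(1, 1, 1), tolerance = 1e-10)
  fit_lo <- fake_fit(matrix(rnorm(S * 3), S, 3), rep(4, S),
                     c(-50, -60, -70))
  expect_equal(pit(fit_lo)$pit, c(0, 0, 0), tolerance = 1e-10)
  set.seed(4)
  fit <- fake_fit(matrix(rnorm(S * 20), S, 20), rgamma(S, 5, 2),
                  rnorm(20))
  p <- pit(fit)
  expect_true(all(p$pit >= 0 & p$pit <= 1))
  expect_true(p$ks_p >= 0 && p$ks_p <= 1)
})

test_that("model comparison ranks by DIC, then WAIC, then sum-log-CPO", {
  mk <- function(label, cpo_v, dic_v, waic_v)
    structure(list(label = label, sum_log_cpo = cpo_v, DIC = dic_v,
                   pD = 1, WAIC = waic_v, pWAIC = 1, lppd = 0,
                   pit = numeric(0), ks_statistic = 0, ks_p = 1,
                   n_obs = 10L, y_digest = 42),
              class = "criteria_report")
  tab <- compare_models(list(mk("a", -5, 100, 110), mk("b", -4, 90, 120),
                             mk("c", -3, 90, 100)))
  expect_equal(tab$model, c("c", "b", "a"))
  expect_true(tab$best[1] && !any(tab$best[-1]))
  ## exact tie is reported
  tie <- compare_models(list(mk("m1", -5, 100, 110), mk("m2", -5, 100, 110)))
  expect_true(all(tie$tied_best))
  ## single model is trivially ranked first
  one <- compare_models(list(mk("only", -5, 100, 110)))
  expect_equal(one$rank, 1L)
  ## differing data refused
  other <- mk("d", -5, 100, 110); other$y_digest <- 43
  expect_error(compare_models(list(mk("a", -5, 100, 110), other)),
               "differing data")
})
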