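test_that("posterior for the linear sub-model matches the conjugate closed form", {
  ## single linear term, no random effects, error precision pinned by a
  ## very concentrated prior -> beta | y is Gaussian in closed form
  sigma <- 0.7
  tau_true <- 1 / sigma^2
  tab <- toy_linear_table(n = 80, beta0 = 2, beta1 = 1.5, sigma = sigma,
                          seed = 5)
  spec <- model_spec("linear_fixed", linear_terms = "x1",
                     priors = list(tau_eps = c(1e8, 1e8 / tau_true)))
  fit <- gibbs_fit(tab, spec, n_iter = 6000, n_burn = 1000, thin = 1,
                   seed = 9)
  X <- cbind(1, std_cov(tab$x1))
  Q <- tau_true * crossprod(X) + diag(1e-6, 2)
  Sigma <- solve(Q)
  m <- as.numeric(Sigma %*% (tau_true * crossprod(X, tab$y)))
  S <- nrow(fit$beta)
  for (k in 1:2) {
    mc_se <- sd(fit$beta[, k]) / sqrt(S / 5)   # conservative ESS
    expect_lt(abs(mean(fit$beta[, k]) - m[k]), 3 * mc_se)
    expect_lt(abs(sd(fit$beta[, k]) - sqrt(Sigma[k, k])),
              3 * sqrt(Sigma[k, k]) / sqrt(S / 5))
  }
})

test_that("the noiseless limit reproduces least squares", {
  tab <- toy_linear_table(n = 50, beta0 = -1, beta1 = 2, sigma = 1e-6,
                          seed = 7)
  spec <- model_spec("linear_fixed", linear_terms = "x1")
  fit <- gibbs_fit(tab, spec, n_iter = 2000, n_burn = 500, thin = 1,
                   seed = 3)
  ls <- unname(coef(lm(tab$y ~ std_cov(tab$x1))))
  expect_equal(unname(colMeans(fit$beta)), ls, tolerance = 1e-4)
})

test_that("sequential-sweep sampler matches a brute-force joint-block sampler", {
  ## BYM model on a 4x4 lattice; the oracle draws (beta, u, v) in one
  ## dense constrained Gaussian block
  sc <- make_scenario(rows = 4, cols = 4, beta = c(x1 = 1),
                      smooth_menu = character(0), tau_u = 1, tau_v = 4,
                      sigma_eps = 0.5, seed = 21)
  spec <- model_spec("bym", linear_terms = "x1", graph = sc$graph)
  fit <- gibbs_fit(sc$table, spec, n_iter = 11000, n_burn = 1000,
                   thin = 1, seed = 13)
  X <- cbind(1, std_cov(sc$table$x1))
  Qu <- build_designs(sc$table, spec)$Q_u
  oracle <- brute_force_bym_sampler(sc$table$y, X, Qu,
                                    n_iter = 11000, n_burn = 1000,
                                    seed = 29)
  S <- nrow(fit$beta)
  ess <- S / 20                      # conservative for correlated chains
  for (k in 1:2) {
    se <- sqrt(sd(fit$beta[, k])^2 + sd(oracle$beta[, k])^2) / sqrt(ess)
    expect_lt(abs(mean(fit$beta[, k]) - mean(oracle$beta[, k])), 4 * se)
    expect_lt(abs(sd(fit$beta[, k]) - sd(oracle$beta[, k])),
              0.3 * sd(oracle$beta[, k]))
  }
  ## structured-field posterior means agree unit by unit
  se_u <- sqrt(apply(fit$u, 2, sd)^2 + apply(oracle$u, 2, sd)^2) /
    sqrt(ess)
  expect_true(all(abs(colMeans(fit$u) - colMeans(oracle$u)) < 4 * se_u))
  ## error-precision posterior agrees
  te_fit <- fit$precisions[, "tau_eps"]
  te_or <- oracle$tau[, 1]
  se_t <- sqrt(sd(te_fit)^2 + sd(te_or)^2) / sqrt(ess)
  expect_lt(abs(mean(te_fit) - mean(te_or)), 4 * se_t)
})

test_that("retained draws satisfy the identifiability constraints", {
  sc <- make_scenario(rows = 5, cols = 5, beta = c(x1 = 1),
                      smooth_menu = "sinusoid", seed = 2)
  spec <- model_spec("bym", linear_terms = "x1", smooth_terms = "s1",
                     n_bins = 10, graph = sc$graph)
  fit <- gibbs_fit(sc$table, spec, n_iter = 600, n_burn = 200, thin = 2,
                   seed = 11)
  expect_true(all(abs(rowMeans(fit$u)) < 1e-10))
  expect_true(all(abs(rowMeans(fit$f[["s1"]])) < 1e-10))
  expect_true(all(fit$precisions > 0))
})

test_that("fits are reproducible from their seed", {
  tab <- toy_linear_table(n = 30, beta0 = 0, beta1 = 1, sigma = 1,
                          seed = 1)
  spec <- model_spec("linear_fixed", linear_terms = "x1")
  f1 <- gibbs_fit(tab, spec, n_iter = 400, n_burn = 100, thin = 2,
                  seed = 77)
  f2 <- gibbs_fit(tab, spec, n_iter = 400, n_burn = 100, thin = 2,
                  seed = 77)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$precisions, f2$precisions)
  expect_error(gibbs_fit(tab, spec, seed = NULL), "seed")
  expect_error(gibbs_fit(tab, spec, n_iter = 100, n_burn = 200, seed = 1),
               "exceed")
  expect_error(gibbs_fit(tab, model_spec("linear_fixed"),
                         response = "missing", seed = 1), "transform")
})

test_that("a BYM fit over an edgeless graph collapses to the i.i.d. model", {
  set.seed(40)
  tab <- toy_linear_table(n = 36, beta0 = 1, beta1 = -1, sigma = 0.6,
                          seed = 40)
  g0 <- spatial_graph(tab$unit_id, NULL)
  bym <- gibbs_fit(tab, model_spec("bym", linear_terms = "x1", graph = g0),
                   n_iter = 3000, n_burn = 1000, thin = 1, seed = 15)
  ## every node is its own component, so u is constrained to exactly 0
  expect_true(all(bym$u == 0))
  iid <- gibbs_fit(tab, model_spec("additive_iid", linear_terms = "x1"),
                   n_iter = 3000, n_burn = 1000, thin = 1, seed = 15)
  for (k in 1:2) {
    se <- sqrt(sd(bym$beta[, k])^2 + sd(iid$beta[, k])^2) /
      sqrt(nrow(bym$beta) / 10)
    expect_lt(abs(mean(bym$beta[, k]) - mean(iid$beta[, k])), 4 * se)
  }
})

test_that("iCAR full conditionals centre on neighbour means", {
  sc <- make_scenario(rows = 10, cols = 10, beta = numeric(0),
                      smooth_menu = character(0), tau_u = 2,
                      tau_v = 1e6, sigma_eps = 1, seed = 101)
  spec <- model_spec("bym", graph = sc$graph)
  fit <- gibbs_fit(sc$table, spec, n_iter = 2500, n_burn = 500, thin = 2,
                   seed = 19)
  chk <- icar_full_conditional_check(fit)
  expect_false(chk$skipped)
  expect_gt(chk$slope, 0.9)
  expect_lt(chk$slope, 1.1)
  ## negative control: score the same draws against a shuffled graph
  set.seed(55)
  shuffled <- spatial_graph(sample(sc$graph$node_ids), sc$graph$edges)
  chk0 <- icar_full_conditional_check(fit, graph = shuffled)
  expect_lt(abs(chk0$slope), 0.5)
  ## edgeless graph: check is skipped with a notice
  g0 <- spatial_graph(sc$graph$node_ids, NULL)
  fit$spec$graph <- g0
  expect_message(chk_skip <- icar_full_conditional_check(fit, graph = g0),
                 "skipped")
  expect_true(chk_skip$skipped)
})

test_that("posterior summaries have the five-column schema and sane quantiles", {
  tab <- toy_linear_table(n = 40, beta0 = 0.5, beta1 = 1, sigma = 0.5,
                          seed = 3)
  spec <- model_spec("linear_fixed", linear_terms = "x1")
  fit <- gibbs_fit(tab, spec, n_iter = 1500, n_burn = 500, thin = 2,
                   seed = 23)
  s <- summarize_fit(fit)
  expect_named(s$fixed, c("term", "mean", "sd", "q2.5", "q50", "q97.5",
                          "significant"))
  expect_true(all(s$fixed$q2.5 <= s$fixed$q50 & s$fixed$q50 <= s$fixed$q97.5))
  expect_true(all(s$precisions$q2.5 <= s$precisions$q50))
  ## standard-normal pseudo-draws recover the known quantiles
  set.seed(6)
  fake <- fit
  fake$beta[, 1] <- rnorm(nrow(fake$beta))
  fake$beta[, 2] <- 0        # so the original-scale intercept is beta[, 1]
  sf <- summarize_fit(fake)
  expect_equal(sf$fixed$q2.5[1], -1.96, tolerance = 0.15)
  expect_equal(sf$fixed$q50[1], 0, tolerance = 0.15)
  expect_equal(sf$fixed$q97.5[1], 1.96, tolerance = 0.15)
  ## a constant chain is summarized with zero spread
  fake$beta[, 2] <- 4.2
  sf2 <- summarize_fit(fake)
  ## (x1 is reported on the original covariate scale: 4.2 / sd(x1))
  k <- 4.2 / sd(tab$x1)
  expect_equal(sf2$fixed$mean[2], k)
  expect_equal(sf2$fixed$sd[2], 0)
  expect_equal(sf2$fixed$q2.5[2], k)
  expect_equal(sf2$fixed$q97.5[2], k)
})

test_that("fitted values behave under intercept-only and rich models", {
  tab <- toy_linear_table(n = 30, beta0 = 3, beta1 = 0, sigma = 0.4,
                          seed = 8)
  fit0 <- gibbs_fit(tab, model_spec("linear_fixed"), n_iter = 1200,
                    n_burn = 200, thin = 2, seed = 31)
  pr <- predict(fit0)
  expect_equal(diff(range(pr$fitted)), 0, tolerance = 1e-12)
  expect_named(pr, c("unit_id", "observed", "fitted", "residual"))
  ## residual variance never exceeds observed variance
  for (seed in 1:3) {
    sc <- make_scenario(rows = 5, cols = 5, seed = seed)
    spec <- model_spec("bym", linear_terms = c("x1", "x2"),
                       smooth_terms = "s1", n_bins = 8, graph = sc$graph)
    fit <- gibbs_fit(sc$table, spec, n_iter = 800, n_burn = 300, thin = 2,
                     seed = seed)
    pr <- predict(fit)
    expect_lte(var(pr$residual), var(pr$observed))
  }
  ## near-saturated model on noiseless data leaves ~zero residuals
  scn <- make_scenario(rows = 4, cols = 4, beta = c(x1 = 1),
                       smooth_menu = character(0), tau_u = Inf,
                       tau_v = Inf, sigma_eps = 1e-8, seed = 77)
  fitn <- gibbs_fit(scn$table, model_spec("linear_fixed",
                                          linear_terms = "x1"),
                    n_iter = 1200, n_burn = 200, thin = 2, seed = 5)
  ## the weak Gamma prior rate floors tau_eps, so "zero" is order 1e-3
  expect_lt(max(abs(predict(fitn)$residual)), 1e-3)
})
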