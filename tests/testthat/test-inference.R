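test_that("a data-free run recovers the prior of the correlation factor", {
  sd_b <- 0.7
  mod <- mcmc_model(
    par_init = function() c(beta = rnorm(1, 0, sd_b)),
    log_prior = function(th) dnorm(th[["beta"]], 0, sd_b, log = TRUE),
    log_lik = function(th) 0,
    blocks = list(list(name = "beta", pars = "beta", type = "rw", scale = 0.5))
  )
  fit <- run_mcmc(mod, iterations = 20000, burnin = 2000, seed = 3)
  q <- quantile(fit$draws$beta, c(0.025, 0.5, 0.975))
  expect_equal(unname(q), qnorm(c(0.025, 0.5, 0.975), 0, sd_b), tolerance = 0.08)
  # posterior mass on beta < 0 is one half, and the Bayes factor ~ 1
  bf <- bayes_factor_beta(fit$draws$beta)
  expect_equal(bf$posterior_prob, 0.5, tolerance = 0.03)
  expect_equal(bf$bayes_factor, 1, tolerance = 0.15)
})

test_that("the engine reproduces the conjugate normal posterior", {
  set.seed(1)
  y <- rnorm(10, 1.5, 1)
  mod <- conjugate_model(y, s = 1, mu0 = 0, tau0 = 2)
  fit <- run_mcmc(mod, iterations = 20000, burnin = 2000, seed = 11)
  post_prec <- 1 / 4 + length(y)
  post_mean <- sum(y) / post_prec
  post_sd <- sqrt(1 / post_prec)
  mc_se <- post_sd / sqrt(ess_autocorr(fit$draws$theta))
  expect_lt(abs(mean(fit$draws$theta) - post_mean), 3 * mc_se)
  expect_equal(sd(fit$draws$theta), post_sd, tolerance = 0.05)
})

test_that("initialization retries from the prior and errors afterwards", {
  mod <- mcmc_model(
    par_init = function() c(x = rnorm(1)),
    log_prior = function(th) -Inf,
    log_lik = function(th) 0,
    blocks = list(list(name = "x", pars = "x", type = "rw", scale = 0.5))
  )
  expect_error(run_mcmc(mod, iterations = 10, seed = 1), "100 prior draws")
})

test_that("stepping stone is exact for a flat likelihood and recovers the conjugate evidence", {
  # likelihood identically c: log evidence = log c regardless of the prior
  modc <- mcmc_model(
    par_init = function() c(x = rnorm(1)),
    log_prior = function(th) dnorm(th[["x"]], log = TRUE),
    log_lik = function(th) log(0.123),
    blocks = list(list(name = "x", pars = "x", type = "rw", scale = 0.5))
  )
  ev <- stepping_stone(modc, stones = 8, iters = 200, seed = 2)
  expect_equal(ev$log_marginal, log(0.123), tolerance = 1e-10)
  expect_true(all(diff(ev$stone_table$power) > 0))
  expect_true(all(ev$stone_table$power >= 0 & ev$stone_table$power <= 1))

  set.seed(4)
  y <- rnorm(10, 0.8, 1)
  mod <- conjugate_model(y, s = 1, mu0 = 0, tau0 = 2)
  ev2 <- stepping_stone(mod, stones = 32, iters = 500, seed = 5)
  truth <- conjugate_log_evidence(y, 1, 0, 2)
  # three estimates with different seeds bound the MC error
  reps <- c(ev2$log_marginal,
            stepping_stone(mod, stones = 32, iters = 500, seed = 6)$log_marginal,
            stepping_stone(mod, stones = 32, iters = 500, seed = 7)$log_marginal)
  mc_se <- sd(reps) / sqrt(3)
  expect_lt(abs(mean(reps) - truth), 3 * mc_se + 0.05)
  # deterministic given the seed
  expect_identical(ev2$log_marginal,
                   stepping_stone(mod, stones = 32, iters = 500, seed = 5)$log_marginal)
})

test_that("the posterior-odds Bayes factor uses add-one smoothing", {
  expect_equal(bayes_factor_beta(c(rep(-1, 4899), rep(1, 99)))$bayes_factor, 49)
  expect_equal(bayes_factor_beta(rep(-0.5, 37500))$bayes_factor, 37501)
  # symmetric counts: about 1
  expect_equal(bayes_factor_beta(c(rep(-1, 500), rep(1, 500)))$bayes_factor, 1,
               tolerance = 0.01)
  # raw odds available by flag
  expect_equal(bayes_factor_beta(c(rep(-1, 400), rep(1, 100)),
                                 smoothing = "raw")$bayes_factor, 4)
  expect_equal(bayes_factor_beta(c(-1, -1, 1), direction = "positive",
                                 smoothing = "raw")$bayes_factor, 0.5)
  expect_error(bayes_factor_beta(numeric(0)), "Empty trace")
  expect_equal(bf_label(c(0.5, 5, 50, 5e4)),
               c("against", "substantial", "strong", "decisive"))
})

test_that("rate summaries have the documented schema and quantile behavior", {
  env <- synthetic_cenozoic_co2()
  tr <- simulate_env_tree(env, root_age = 40, epochs = 10, lambda0 = 0.17,
                          mu0 = 0.05, beta = -0.005, sigma = 0.02,
                          model = "gmrf", seed = 101)
  mod <- div_model(tr, epochs = 10, prior = "gmrf", env = env)
  fit <- run_mcmc(mod, iterations = 60, burnin = 20, seed = 2)
  s <- summarize_rates(fit)
  expect_equal(nrow(s), 10L)
  expect_true(all(c("age_mid", "lambda_med", "lambda_lo", "lambda_hi",
                    "mu_med", "mu_lo", "mu_hi", "netdiv_med") %in% names(s)))
  expect_true(all(s$lambda_lo <= s$lambda_med & s$lambda_med <= s$lambda_hi))
  expect_equal(s$netdiv_med, apply(
    as.matrix(fit$draws[paste0("lambda_", 1:10)]) -
      as.matrix(fit$draws[paste0("mu_", 1:10)]), 2, median),
    ignore_attr = TRUE)

  # a one-sample trace yields that sample as every summary point
  fit1 <- fit
  fit1$draws <- fit$draws[1, ]
  s1 <- summarize_rates(fit1)
  expect_equal(s1$lambda_med, unlist(fit$draws[1, paste0("lambda_", 1:10)]),
               ignore_attr = TRUE)
  expect_equal(s1$lambda_lo, s1$lambda_hi)

  # quantiles of a known normal within Monte Carlo error
  set.seed(8)
  fitn <- fit
  fitn$draws <- fit$draws[rep(1, 4000), ]
  for (j in 1:10) {
    fitn$draws[[paste0("lambda_", j)]] <- exp(rnorm(4000, log(0.2), 0.1))
    fitn$draws[[paste0("mu_", j)]] <- exp(rnorm(4000, log(0.05), 0.1))
  }
  sn <- summarize_rates(fitn)
  expect_equal(sn$lambda_med, rep(0.2, 10), tolerance = 0.02)
  expect_equal(sn$lambda_lo, rep(exp(log(0.2) + qnorm(0.025) * 0.1), 10),
               tolerance = 0.03)

  # broom-style accessors
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "conf.low", "conf.high", "ess") %in% names(td)))
  expect_true("beta_lambda" %in% td$term)
  g <- glance(fit)
  expect_equal(g$retained, nrow(fit$draws))
})

test_that("plot builders return ggplot objects", {
  env <- synthetic_cenozoic_co2()
  b <- bin_environment(env, seq(0, 40, 4))
  expect_s3_class(plot_env_series(env, b), "ggplot")
  tr <- simulate_tree(20, 0.25, 0.05, seed = 31)
  mod <- div_model(tr, epochs = 10, prior = "gmrf", env = env)
  fit <- run_mcmc(mod, iterations = 60, burnin = 20, seed = 2)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
  expect_s3_class(plot_beta_posterior(fit), "ggplot")
  expect_s3_class(plot_rates_through_time(summarize_rates(fit)), "ggplot")
})

test_that("simulation-based calibration: prior draws yield uniform beta ranks", {
  # fixed-link model on small trees: draw beta from its prior, simulate,
  # fit, and rank the true beta within the posterior sample
  env <- synthetic_cenozoic_co2()
  n_sbc <- 12L
  ranks <- numeric(n_sbc)
  set.seed(123)
  for (i in seq_len(n_sbc)) {
    repeat {
      beta_true <- rnorm(1, 0, 0.002)
      lam0 <- runif(1, 0.1, 0.3)
      tr <- try(simulate_env_tree(env, root_age = 25, epochs = 10,
                                  lambda0 = lam0, mu0 = lam0 / 4,
                                  beta = beta_true, sigma = 0, model = "fixed",
                                  seed = 5000 + i, max_attempts = 200),
                silent = TRUE)
      if (!inherits(tr, "try-error") && tr$n_tips >= 8 && tr$n_tips <= 2000) break
    }
    mod <- div_model(tr, epochs = 10, prior = "constant", env = env,
                     beta_prior_sd = 0.002)
    fit <- run_mcmc(mod, iterations = 1200, burnin = 400, seed = 6000 + i)
    ranks[i] <- mean(fit$draws$beta_lambda < beta_true)
  }
  # ranks should be uniform on (0, 1): chi-square on 3 bins
  counts <- table(cut(ranks, breaks = c(0, 1/3, 2/3, 1), include.lowest = TRUE))
  p <- suppressWarnings(chisq.test(as.vector(counts), p = rep(1/3, 3))$p.value)
  expect_gt(p, 0.01)
  # and centered: no systematic over- or under-coverage
  expect_gt(mean(ranks), 0.15)
  expect_lt(mean(ranks), 0.85)
})
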