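empty_data <- function() patient_data(integer(), integer(), integer())

# MC standard error of an empirical quantile from correlated draws:
# batch-means variance of the indicator I(x <= q_true), converted through
# the density at the true quantile.
quantile_mc_se <- function(x, q_true, dens, n_batch = 40) {
  z <- as.numeric(x <= q_true)
  bm <- colMeans(matrix(z[seq_len(n_batch * (length(z) %/% n_batch))],
                        ncol = n_batch))
  se_p <- sd(bm) / sqrt(n_batch)
  se_p / dens
}

test_that("with empty data the sampler recovers the prior", {
  fit <- sample_posterior(empty_data(), grid44, prior_spec(), model = "sa",
                          mcmc = mcmc_control(), seed = 101)
  checks <- list(
    list(par = "alpha", q = function(l) 2 * l, d = function(x) 0.5),
    list(par = "gamma", q = function(l) qnorm(l, 0, sqrt(10)),
         d = function(x) dnorm(x, 0, sqrt(10))),
    list(par = "lambda", q = function(l) qbeta(l, 4 / 3, 1),
         d = function(x) dbeta(x, 4 / 3, 1))
  )
  for (ck in checks) {
    x <- fit$draws[[ck$par]]
    for (lev in c(0.05, 0.5, 0.95)) {
      q_true <- ck$q(lev)
      se <- quantile_mc_se(x, q_true, ck$d(q_true))
      expect_lt(abs(quantile(x, lev, names = FALSE) - q_true), 3 * se)
    }
  }
})

test_that("sampling is reproducible given a seed and draws stay in support", {
  d <- patient_data(c(1, 1, 2, 2), c(1, 1, 1, 2), c(0, 2, 0, 1))
  f1 <- sample_posterior(d, grid44, prior_spec(), "sa", mcmc_quick(), seed = 5)
  f2 <- sample_posterior(d, grid44, prior_spec(), "sa", mcmc_quick(), seed = 5)
  expect_identical(f1$draws, f2$draws)
  expect_true(all(f1$draws$alpha >= 0 & f1$draws$alpha <= 2))
  expect_true(all(f1$draws$beta >= 0 & f1$draws$beta <= 2))
  expect_true(all(f1$draws$lambda >= 0 & f1$draws$lambda < 1))
  expect_true(all(is.finite(f1$rhat)))
})

test_that("posterior medians agree with the quadrature oracle", {
  set.seed(21)
  for (i in 1:6) {
    pr <- random_params()
    d <- random_dataset(sample(4:10, 1), params = pr)
    model <- if (i %% 2 == 0) "sa" else "na"
    fit <- sample_posterior(d, grid44, prior_spec(), model,
                            mcmc_control(chains = 2, burn_in = 500,
                                         keep = 2000, thin = 2))
    s_mcmc <- posterior_summary(fit)
    s_quad <- quadrature_posterior(d, grid44, prior_spec(), model,
                                   n_points = 60)
    expect_lt(max(abs(s_mcmc$median_surface - s_quad$median_surface)), 0.02)
    expect_lt(abs(s_mcmc$exceedance_lowest - s_quad$exceedance_lowest), 0.03)
  }
})

test_that("estimation sharpens with sample size for the marginal powers", {
  truth <- model_params(1.8, 0.4, 0.5)
  sizes <- c(20, 60, 200)
  set.seed(31)
  rmse <- sapply(sizes, function(n) {
    err <- replicate(50, {
      a <- rep_len(rep(1:4, each = 4), n)
      b <- rep_len(rep(1:4, times = 4), n)
      pi_t <- prob_dlt_cycle(grid44, truth, a, b)
      d <- patient_data(a, b, ifelse(runif(n) < pi_t, 2L, 0L))
      fit <- suppressWarnings(
        sample_posterior(d, grid44, prior_spec(), "na", mcmc_quick())
      )
      c(median(fit$draws$alpha) - truth$alpha,
        median(fit$draws$beta) - truth$beta)
    })
    sqrt(rowMeans(err^2))
  })
  expect_true(all(diff(rmse[1, ]) < 0))  # alpha RMSE decreasing in n
  expect_true(all(diff(rmse[2, ]) < 0))  # beta RMSE decreasing in n
})

test_that("tidiers and draw export expose the fit", {
  d <- patient_data(c(1, 1), c(1, 1), c(0, 0))
  fit <- sample_posterior(d, grid44, prior_spec(), "na", mcmc_quick(), seed = 3)
  td <- tidy(fit)
  expect_equal(td$term, c("alpha", "beta", "gamma"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$n_patients, 2L)
  expect_equal(gl$n_draws, 1000L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_draws(fit, path)
  out <- read.csv(path)
  expect_equal(nrow(out), 1000L)
  expect_true(all(c("chain", "iter", "alpha", "pi_T_11") %in% names(out)))
  expect_equal(out$pi_T_11[1],
               oracle_pi(0.10, 0.06, out$alpha[1], out$beta[1], out$gamma[1]))
})
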