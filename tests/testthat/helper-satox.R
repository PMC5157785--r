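# Shared fixtures, built in code at test time.

grid44 <- default_grid()

# Draw model parameters from the default priors.
random_params <- function(lambda = TRUE) {
  model_params(
    alpha = runif(1, 0, 2), beta = runif(1, 0, 2),
    gamma = rnorm(1, 0, sqrt(10)),
    lambda = if (lambda) rbeta(1, 4 / 3, 1) * 0.999 else 0
  )
}

# A random dataset of n patients at random combinations, outcomes drawn
# from the model's own trinary probabilities.
random_dataset <- function(n, grid = grid44, params = random_params()) {
  J <- length(grid$skeleton_p); K <- length(grid$skeleton_q)
  a <- sample.int(J, n, replace = TRUE)
  b <- sample.int(K, n, replace = TRUE)
  probs <- outcome_probs(grid, params, a, b)
  y <- vapply(seq_len(n), function(i) {
    sample(0:2, 1, prob = c(probs$p0[i], probs$p1[i], probs$p2[i]))
  }, integer(1))
  patient_data(a, b, y)
}

# Small sampler settings for tests that only need a rough posterior.
mcmc_quick <- function() mcmc_control(chains = 1, burn_in = 250, keep = 1000, thin = 2)

# Term-by-term transcription of the copula surface, kept deliberately
# independent of the package implementation (different algebraic form).
oracle_pi <- function(p, q, alpha, beta, gamma) {
  pa <- p^alpha
  qb <- q^beta
  interaction <- (exp(gamma) - 1) / (exp(gamma) + 1)
  pa + qb - pa * qb + pa * (1 - pa) * qb * (1 - qb) * interaction
}
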