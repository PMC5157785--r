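#' MCMC settings
#'
#' Defaults: two chains, each with a burn-in of 500 iterations and 4000
#' retained draws thinned every two iterations (so 8500 iterations per
#' chain in total). Step sizes of the component-wise random-walk proposals
#' adapt during burn-in only.
#'
#' @param chains Number of chains.
#' @param burn_in Burn-in iterations per chain (discarded, used for
#'   adaptation).
#' @param keep Retained draws per chain (after thinning).
#' @param thin Thinning interval.
#' @param init_jitter SD of the seed-controlled jitter applied to the
#'   prior-median starting point of each chain, on the unconstrained scale.
#' @return An object of class `mcmc_control`.
#' @export
mcmc_control <- function(chains = 2, burn_in = 500, keep = 4000, thin = 2,
                         init_jitter = 0.1) {
  stopifnot(chains >= 1, burn_in >= 0, keep >= 1, thin >= 1, init_jitter > 0)
  structure(
    list(chains = as.integer(chains), burn_in = as.integer(burn_in),
         keep = as.integer(keep), thin = as.integer(thin),
         init_jitter = init_jitter),
    class = "mcmc_control"
  )
}

#' Reduced MCMC settings for large simulation batches
#'
#' One chain, 250 burn-in, 1000 retained draws: the settings used for
#' batch operating-characteristic simulations, where thousands of posterior
#' fits are required.
#'
#' @inheritParams mcmc_control
#' @return An `mcmc_control`.
#' @export
mcmc_control_reduced <- function(chains = 1, burn_in = 250, keep = 1000,
                                 thin = 2) {
  mcmc_control(chains = chains, burn_in = burn_in, keep = keep, thin = thin)
}

#' Sample the posterior of the dose-toxicity model
#'
#' Draws from the posterior of (`alpha`, `beta`, `gamma`[, `lambda`]) given
#' accrued trial data, under either the trinary semi-attributable (`"sa"`)
#' or binary non-attributable (`"na"`) likelihood, by adaptive
#' component-wise random-walk Metropolis. `alpha` and `beta` are sampled on
#' a logit-of-range scale and `lambda` on the logit scale, with Jacobians,
#' so every draw respects the bounded prior support; `gamma` is
#' unconstrained. With empty data the draws target the prior.
#'
#' A split-chain potential-scale-reduction statistic is computed per
#' parameter; values above 1.1 raise a warning (not an error, so batch
#' simulations are never aborted).
#'
#' @param data A data frame from [patient_data()] (may have zero rows).
#' @param grid A [dose_grid()].
#' @param prior A [prior_spec()].
#' @param model `"sa"` or `"na"`.
#' @param mcmc An [mcmc_control()].
#' @param seed Optional integer seed (sets R's RNG before sampling).
#'
#' @return An object of class `tox_fit` with elements `draws` (tibble:
#'   `chain`, `iter`, `alpha`, `beta`, `gamma`, `lambda`), `acceptance`,
#'   `rhat`, and the inputs.
#' @examples
#' d <- patient_data(c(1, 1), c(1, 1), c(0, 0))
#' fit <- sample_posterior(d, default_grid(), prior_spec(), model = "na",
#'                         mcmc = mcmc_control(chains = 1, keep = 500), seed = 1)
#' tidy(fit)
#' @export
sample_posterior <- function(data, grid, prior = prior_spec(),
                             model = c("sa", "na"), mcmc = mcmc_control(),
                             seed = NULL) {
  model <- match.arg(model)
  if (!inherits(grid, "dose_grid")) stop("`grid` must be a dose_grid.", call. = FALSE)
  data <- patient_data(data$a_idx, data$b_idx, data$outcome,
                       data$b_administered %||% (data$outcome != 1L),
                       grid = grid)
  if (!is.null(seed)) set.seed(seed)
  sa <- model == "sa"
  lam_est <- sa && prior$lambda_mode == "estimated"
  res <- rwm_sample(
    a_idx = data$a_idx - 1L, b_idx = data$b_idx - 1L, y = data$outcome,
    skel_p = grid$skeleton_p, skel_q = grid$skeleton_q,
    sa = sa, lam_est = lam_est, lam_fixed = prior$lambda_fixed,
    alpha_range = prior$alpha_range, beta_range = prior$beta_range,
    gamma_mean = prior$gamma_mean, gamma_var = prior$gamma_var,
    lam_shape1 = prior$lambda_shapes[1], lam_shape2 = prior$lambda_shapes[2],
    n_chains = mcmc$chains, burn_in = mcmc$burn_in, keep = mcmc$keep,
    thin = mcmc$thin, init_jitter = mcmc$init_jitter
  )
  draws <- tibble::tibble(
    chain = res$chain, iter = res$iter,
    alpha = res$draws[, 1], beta = res$draws[, 2], gamma = res$draws[, 3],
    lambda = res$draws[, 4]
  )
  par_names <- c("alpha", "beta", "gamma", if (lam_est) "lambda")
  rhat <- vapply(par_names, function(p) {
    split_rhat(draws[[p]], draws$chain)
  }, numeric(1))
  if (any(rhat > 1.1, na.rm = TRUE)) {
    warning("split-chain scale-reduction statistic above 1.1 for: ",
            paste(par_names[which(rhat > 1.1)], collapse = ", "), call. = FALSE)
  }
  structure(
    list(draws = draws, acceptance = res$acceptance, rhat = rhat,
         data = data, grid = grid, prior = prior, model = model, mcmc = mcmc,
         parameters = par_names),
    class = "tox_fit"
  )
}

# Split-chain potential scale reduction (each chain halved; rank-free form).
split_rhat <- function(x, chain) {
  pieces <- unlist(lapply(split(x, chain), function(v) {
    h <- floor(length(v) / 2)
    if (h < 2) return(list(v))
    list(v[seq_len(h)], v[(h + 1):(2 * h)])
  }), recursive = FALSE)
  m <- length(pieces)
  n <- min(lengths(pieces))
  if (m < 2 || n < 2) return(NA_real_)
  pieces <- lapply(pieces, function(v) v[seq_len(n)])
  means <- vapply(pieces, mean, numeric(1))
  vars <- vapply(pieces, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @export
print.tox_fit <- function(x, ...) {
  cat("<tox_fit> ", toupper(x$model), " model, ", nrow(x$data), " patients, ",
      nrow(x$draws), " draws (", x$mcmc$chains, " chain",
      if (x$mcmc$chains > 1) "s", ")\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a posterior fit
#'
#' One row per model parameter with the posterior median and central 95%
#' credible interval.
#'
#' @param x A `tox_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `conf.low`,
#'   `conf.high`.
#' @export
tidy.tox_fit <- function(x, ...) {
  purrr::map_dfr(x$parameters, function(p) {
    qs <- stats::quantile(x$draws[[p]], c(0.5, 0.025, 0.975), names = FALSE)
    tibble::tibble(term = p, estimate = qs[1], conf.low = qs[2],
                   conf.high = qs[3])
  })
}

#' Glance at a posterior fit
#'
#' @param x A `tox_fit`.
#' @param ... Unused.
#' @return A one-row tibble with sampler metadata and diagnostics.
#' @export
glance.tox_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, n_patients = nrow(x$data), n_draws = nrow(x$draws),
    chains = x$mcmc$chains, rhat_max = suppressWarnings(max(x$rhat, na.rm = TRUE)),
    accept_mean = mean(x$acceptance, na.rm = TRUE)
  )
}

#' Posterior summary of the dose-toxicity surface
#'
#' Transforms every retained draw into the full-cycle DLT probability
#' surface, then reports the per-combination posterior median
#' \eqn{\hat\pi_T(a_j, b_k)} and the early-stopping quantity
#' \eqn{P(\pi_T(a_1, b_1) > \Gamma)}, the posterior probability (strict
#' inequality) that even the lowest combination is above the target
#' toxicity level.
#'
#' @param fit A `tox_fit`.
#' @param Gamma Target toxicity level.
#' @return An object of class `tox_summary`: median surface (J x K matrix),
#'   exceedance probability at the lowest combination, parameter medians.
#' @export
posterior_summary <- function(fit, Gamma = 0.25) {
  grid <- fit$grid
  J <- length(grid$skeleton_p); K <- length(grid$skeleton_q)
  dm <- as.matrix(fit$draws[, c("alpha", "beta", "gamma")])
  surf_draws <- pi_surface_draws(dm, grid$skeleton_p, grid$skeleton_q)
  med <- matrix(apply(surf_draws, 2, stats::median), nrow = J,
                dimnames = list(a = seq_len(J), b = seq_len(K)))
  exceed <- mean(surf_draws[, 1] > Gamma)
  pmed <- vapply(fit$parameters, function(p) stats::median(fit$draws[[p]]),
                 numeric(1))
  structure(
    list(median_surface = med, exceedance_lowest = exceed,
         param_medians = pmed, Gamma = Gamma, grid = grid, model = fit$model),
    class = "tox_summary"
  )
}

#' @export
print.tox_summary <- function(x, ...) {
  cat("<tox_summary> posterior median DLT-probability surface (Gamma = ",
      x$Gamma, ")\n", sep = "")
  print(round(x$median_surface, 3))
  cat(sprintf("P(pi_T(a1, b1) > Gamma) = %.3f\n", x$exceedance_lowest))
  invisible(x)
}

#' Tidy a posterior surface summary
#'
#' @param x A `tox_summary`.
#' @param ... Unused.
#' @return A tibble with one row per dose combination: `a_idx`, `b_idx`,
#'   `median`, and `distance` (absolute distance of the median from the
#'   target toxicity level).
#' @export
tidy.tox_summary <- function(x, ...) {
  J <- nrow(x$median_surface); K <- ncol(x$median_surface)
  tibble::tibble(
    a_idx = rep(seq_len(J), times = K),
    b_idx = rep(seq_len(K), each = J),
    median = as.vector(x$median_surface),
    distance = abs(as.vector(x$median_surface) - x$Gamma)
  )
}

#' Export retained draws as CSV
#'
#' One row per retained iteration: chain, iteration, the sampled
#' parameters, and the implied DLT probability at the lowest combination.
#'
#' @param fit A `tox_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  g <- fit$grid
  pi11 <- fgm_pi(g$skeleton_p[1]^fit$draws$alpha,
                 g$skeleton_q[1]^fit$draws$beta, fit$draws$gamma)
  out <- dplyr::mutate(fit$draws, pi_T_11 = pi11)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
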