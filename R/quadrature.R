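#' Posterior summaries by dense-grid quadrature
#'
#' Deterministic cross-check of [sample_posterior()]: the parameter space is
#' discretised on a tensor grid of cell midpoints (`n_points` per
#' dimension; `gamma` truncated at six prior standard deviations) and the
#' posterior is represented by normalised weights
#' `prior x likelihood` on that grid. Intended for small datasets (the
#' cost grows with `n_points^3` times the number of patients); in tests it
#' serves as the independent oracle against which the Metropolis sampler is
#' validated.
#'
#' @inheritParams sample_posterior
#' @param n_points Grid points per dimension (at least 10).
#' @param Gamma Target toxicity level for the exceedance probability.
#'
#' @return An object of class `tox_summary` (as from
#'   [posterior_summary()]): posterior-median DLT surface, exceedance
#'   probability at the lowest combination, and per-parameter posterior
#'   medians.
#' @examples
#' q <- quadrature_posterior(patient_data(integer(), integer(), integer()),
#'                           default_grid(), prior_spec(), model = "na",
#'                           n_points = 30)
#' q$param_medians  # prior medians (1, 1, 0)
#' @export
quadrature_posterior <- function(data, grid, prior = prior_spec(),
                                 model = c("sa", "na"), n_points = 60,
                                 Gamma = 0.25) {
  model <- match.arg(model)
  if (n_points < 10) stop("`n_points` must be at least 10.", call. = FALSE)
  data <- patient_data(data$a_idx, data$b_idx, data$outcome,
                       data$b_administered %||% (data$outcome != 1L),
                       grid = grid)
  sa <- model == "sa"
  lam_est <- sa && prior$lambda_mode == "estimated"

  midpoints <- function(lo, hi) {
    w <- (hi - lo) / n_points
    lo + w * (seq_len(n_points) - 0.5)
  }
  g_sd <- sqrt(prior$gamma_var)
  a_grid <- midpoints(prior$alpha_range[1], prior$alpha_range[2])
  b_grid <- midpoints(prior$beta_range[1], prior$beta_range[2])
  g_grid <- midpoints(prior$gamma_mean - 6 * g_sd, prior$gamma_mean + 6 * g_sd)
  l_grid <- if (lam_est) midpoints(0, 1) else (if (sa) prior$lambda_fixed else 0)
  l_wt <- if (lam_est) {
    stats::dbeta(l_grid, prior$lambda_shapes[1], prior$lambda_shapes[2])
  } else {
    1
  }

  dims <- c(n_points, n_points, n_points)
  bcast <- function(v, dim_id) {
    # expand a per-dimension vector to the full (alpha, beta, gamma) array
    array(rep(v, each = n_points^(dim_id - 1)), dims)
  }
  tanh_g <- bcast(tanh(g_grid / 2), 3)

  n <- nrow(data)
  # per-patient pi_T over the theta grid; P arrays kept for SA terms
  log_lik <- array(0, dims)
  log_p_sep <- array(0, dims)     # separable part of Y = 1 contributions
  y2_pi <- list(); y2_P <- list() # non-separable Y = 2 pieces
  n_y1 <- 0L
  for (i in seq_len(n)) {
    P <- bcast(grid$skeleton_p[data$a_idx[i]]^a_grid, 1)
    Q <- bcast(grid$skeleton_q[data$b_idx[i]]^b_grid, 2)
    pi_T <- 1 - (1 - P) * (1 - Q) + P * (1 - P) * Q * (1 - Q) * tanh_g
    y <- data$outcome[i]
    if (!sa) {
      log_lik <- log_lik + log(if (y == 0L) 1 - pi_T else pi_T)
    } else if (y == 0L) {
      log_lik <- log_lik + log(1 - pi_T)
    } else if (y == 1L) {
      n_y1 <- n_y1 + 1L
      log_p_sep <- log_p_sep + log(P)
    } else {
      y2_pi[[length(y2_pi) + 1L]] <- pi_T
      y2_P[[length(y2_P) + 1L]] <- P
    }
  }

  # theta-grid weights, marginalising lambda; lambda marginal kept alongside
  g_prior <- bcast(stats::dnorm(g_grid, prior$gamma_mean, g_sd), 3)
  if (!sa) {
    w_theta <- g_prior * exp(log_lik - max(log_lik))
    l_marg <- 1
  } else {
    w_theta <- array(0, dims)
    l_marg <- numeric(length(l_grid))
    base <- log_lik + log_p_sep
    shift <- max(base)
    for (m in seq_along(l_grid)) {
      lam <- l_grid[m]
      ll <- base + n_y1 * log(lam)
      for (s in seq_along(y2_pi)) {
        ll <- ll + log(pmax(y2_pi[[s]] - lam * y2_P[[s]], 0))
      }
      w_m <- l_wt[m] * exp(ll - shift)
      w_theta <- w_theta + w_m
      l_marg[m] <- sum(g_prior * w_m)
    }
    w_theta <- g_prior * w_theta
  }
  total <- sum(w_theta)
  if (!is.finite(total) || total <= 0) {
    stop("Quadrature weights degenerate; data inconsistent with the prior.",
         call. = FALSE)
  }
  w_theta <- w_theta / total

  J <- length(grid$skeleton_p); K <- length(grid$skeleton_q)
  med <- matrix(0, J, K, dimnames = list(a = seq_len(J), b = seq_len(K)))
  exceed <- NA_real_
  w_vec <- as.vector(w_theta)
  for (k in seq_len(K)) {
    Q <- bcast(grid$skeleton_q[k]^b_grid, 2)
    for (j in seq_len(J)) {
      P <- bcast(grid$skeleton_p[j]^a_grid, 1)
      v <- as.vector(1 - (1 - P) * (1 - Q) + P * (1 - P) * Q * (1 - Q) * tanh_g)
      med[j, k] <- weighted_median(v, w_vec)
      if (j == 1L && k == 1L) exceed <- sum(w_vec[v > Gamma])
    }
  }
  marg <- function(dim_id) apply(w_theta, dim_id, sum)
  pmed <- c(alpha = weighted_median(a_grid, marg(1)),
            beta = weighted_median(b_grid, marg(2)),
            gamma = weighted_median(g_grid, marg(3)))
  if (lam_est) {
    pmed <- c(pmed, lambda = weighted_median(l_grid, l_marg / sum(l_marg)))
  }
  structure(
    list(median_surface = med, exceedance_lowest = exceed,
         param_medians = pmed, Gamma = Gamma, grid = grid, model = model,
         method = "quadrature"),
    class = "tox_summary"
  )
}

# Weighted median with linear interpolation of the cumulative distribution
# (mass centred on each support point), avoiding half-cell discretisation
# bias on midpoint grids.
weighted_median <- function(values, weights) {
  o <- order(values)
  v <- values[o]
  w <- weights[o] / sum(weights)
  f <- cumsum(w) - w / 2
  if (f[1] >= 0.5) return(v[1])
  if (f[length(f)] <= 0.5) return(v[length(v)])
  stats::approx(f, v, xout = 0.5, ties = "ordered")$y
}
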