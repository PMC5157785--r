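#' Prior specification for the dose-toxicity model
#'
#' Default priors: independent uniforms on `[0, 2]` for the marginal powers
#' `alpha` and `beta` (prior mean and median 1, so the skeletons are the
#' prior-central marginal probabilities), a normal with mean 0 and variance
#' 10 for the interaction `gamma`, and a Beta prior for the pre-`t_B`
#' fraction `lambda` whose shapes are determined by the cycle timing (see
#' [lambda_prior_shapes()]). `lambda` may instead be fixed at a constant,
#' e.g. `t_b / t_cycle`.
#'
#' @param alpha_range,beta_range Numeric length-2 supports of the uniform
#'   priors on the marginal powers.
#' @param gamma_mean,gamma_var Mean and variance of the normal prior on the
#'   interaction parameter.
#' @param lambda_mode `"estimated"` (Beta prior from the timing) or
#'   `"fixed"`.
#' @param lambda_fixed Value used when `lambda_mode = "fixed"`; defaults to
#'   `t_b / t_cycle`.
#' @param timing A [cycle_timing()].
#'
#' @return An object of class `prior_spec`.
#' @examples
#' prior_spec()  # the package defaults, with lambda ~ Beta(4/3, 1)
#' @export
prior_spec <- function(alpha_range = c(0, 2), beta_range = c(0, 2),
                       gamma_mean = 0, gamma_var = 10,
                       lambda_mode = c("estimated", "fixed"),
                       lambda_fixed = NULL,
                       timing = cycle_timing(4, 7)) {
  lambda_mode <- match.arg(lambda_mode)
  stopifnot(length(alpha_range) == 2L, length(beta_range) == 2L,
            alpha_range[1] >= 0, beta_range[1] >= 0,
            diff(alpha_range) > 0, diff(beta_range) > 0, gamma_var > 0)
  if (!inherits(timing, "cycle_timing")) stop("`timing` must be a cycle_timing.", call. = FALSE)
  if (is.null(lambda_fixed)) lambda_fixed <- timing$t_b / timing$t_cycle
  if (lambda_fixed < 0 || lambda_fixed >= 1) {
    stop("`lambda_fixed` must lie in [0, 1).", call. = FALSE)
  }
  structure(
    list(
      alpha_range = alpha_range, beta_range = beta_range,
      gamma_mean = gamma_mean, gamma_var = gamma_var,
      lambda_mode = lambda_mode, lambda_fixed = lambda_fixed,
      lambda_shapes = lambda_prior_shapes(timing),
      timing = timing
    ),
    class = "prior_spec"
  )
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("<prior_spec>\n")
  cat(sprintf("  alpha ~ U[%g, %g]; beta ~ U[%g, %g]; gamma ~ N(%g, var %g)\n",
              x$alpha_range[1], x$alpha_range[2], x$beta_range[1],
              x$beta_range[2], x$gamma_mean, x$gamma_var))
  if (x$lambda_mode == "estimated") {
    cat(sprintf("  lambda ~ Beta(%.4g, %.4g)\n",
                x$lambda_shapes[1], x$lambda_shapes[2]))
  } else {
    cat(sprintf("  lambda fixed at %.4g\n", x$lambda_fixed))
  }
  invisible(x)
}

#' Beta prior shapes for the pre-t_B fraction
#'
#' The prior on `lambda` is chosen so that its mean equals `t_b / t_cycle`
#' (the fraction of the cycle elapsed before drug B is given), its median is
#' close to that mean, and the distribution is invariant to the time units:
#' \deqn{\lambda \sim \mathrm{Beta}(t_B / (T - t_B),\, 1) \quad
#'   \text{if } t_B \ge T - t_B,} and
#' \eqn{\mathrm{Beta}(1,\, (T - t_B)/t_B)} otherwise. With drug B on day 4
#' of a 7-day cycle this gives Beta(4/3, 1), with mean 4/7 = 0.571 and
#' median \eqn{0.5^{3/4} = 0.595}.
#'
#' @param timing A [cycle_timing()].
#' @return Numeric vector `c(shape1, shape2)`.
#' @examples
#' lambda_prior_shapes(cycle_timing(4, 7))  # Beta(4/3, 1)
#' @export
lambda_prior_shapes <- function(timing) {
  t_b <- timing$t_b
  rest <- timing$t_cycle - timing$t_b
  if (t_b >= rest) c(t_b / rest, 1) else c(1, rest / t_b)
}

#' Log prior density of the model parameters
#'
#' Sum of log densities under a [prior_spec()]. Returns `-Inf` outside the
#' prior support. The `lambda` term is included only for the
#' semi-attributable model with `lambda_mode = "estimated"`; the
#' non-attributable model has no `lambda` parameter.
#'
#' @param params A [model_params()].
#' @param prior A [prior_spec()].
#' @param model `"sa"` (trinary, semi-attributable) or `"na"` (binary,
#'   non-attributable).
#' @return A single numeric log density.
#' @examples
#' log_prior(model_params(1, 1, 0, 0.5), prior_spec())
#' @export
log_prior <- function(params, prior, model = c("sa", "na")) {
  model <- match.arg(model)
  lp <- stats::dunif(params$alpha, prior$alpha_range[1], prior$alpha_range[2], log = TRUE) +
    stats::dunif(params$beta, prior$beta_range[1], prior$beta_range[2], log = TRUE) +
    stats::dnorm(params$gamma, prior$gamma_mean, sqrt(prior$gamma_var), log = TRUE)
  if (model == "sa" && prior$lambda_mode == "estimated") {
    lp <- lp + stats::dbeta(params$lambda, prior$lambda_shapes[1],
                            prior$lambda_shapes[2], log = TRUE)
  }
  lp
}
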