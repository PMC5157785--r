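#' Dose-combination grid with skeleton DLT probabilities
#'
#' Defines the J x K grid of dose combinations for a dual-agent trial. Each
#' dose level of drug A (given first in the cycle) and drug B (given at time
#' `t_B`, later in the cycle) carries a skeleton probability: the prior guess
#' of its single-agent dose-limiting-toxicity (DLT) probability over a full
#' cycle. The skeletons anchor the copula marginals `p_j^alpha` and
#' `q_k^beta`.
#'
#' @param skeleton_p Numeric vector of J skeleton DLT probabilities for drug
#'   A, strictly increasing, all in (0, 1).
#' @param skeleton_q Numeric vector of K skeleton DLT probabilities for drug
#'   B, strictly increasing, all in (0, 1).
#' @param levels_a Optional labels or doses for the levels of drug A
#'   (defaults to `1:J`).
#' @param levels_b Optional labels or doses for the levels of drug B
#'   (defaults to `1:K`).
#'
#' @return An object of class `dose_grid`.
#' @examples
#' grid <- dose_grid(c(0.10, 0.15, 0.20, 0.25), c(0.06, 0.12, 0.18, 0.25))
#' grid
#' @export
dose_grid <- function(skeleton_p, skeleton_q,
                      levels_a = seq_along(skeleton_p),
                      levels_b = seq_along(skeleton_q)) {
  check_skeleton(skeleton_p, "skeleton_p")
  check_skeleton(skeleton_q, "skeleton_q")
  if (length(levels_a) != length(skeleton_p)) {
    stop("`levels_a` must have one entry per element of `skeleton_p`.", call. = FALSE)
  }
  if (length(levels_b) != length(skeleton_q)) {
    stop("`levels_b` must have one entry per element of `skeleton_q`.", call. = FALSE)
  }
  structure(
    list(
      levels_a = levels_a, levels_b = levels_b,
      skeleton_p = as.numeric(skeleton_p),
      skeleton_q = as.numeric(skeleton_q)
    ),
    class = "dose_grid"
  )
}

check_skeleton <- function(x, name) {
  if (length(x) < 1L || !is.numeric(x) || anyNA(x)) {
    stop("`", name, "` must be a non-empty numeric vector.", call. = FALSE)
  }
  if (any(x <= 0) || any(x >= 1)) {
    stop("`", name, "` values must lie strictly in (0, 1).", call. = FALSE)
  }
  if (length(x) > 1L && any(diff(x) <= 0)) {
    stop("`", name, "` must be strictly increasing.", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.dose_grid <- function(x, ...) {
  cat("<dose_grid> ", length(x$skeleton_p), " x ", length(x$skeleton_q),
      " dose combinations\n", sep = "")
  cat("  drug A skeleton:", paste(format(x$skeleton_p), collapse = " "), "\n")
  cat("  drug B skeleton:", paste(format(x$skeleton_q), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.dose_grid <- function(x) {
  c(length(x$skeleton_p), length(x$skeleton_q))
}

#' The default 4 x 4 grid used throughout the package examples
#'
#' Skeletons \eqn{p = (0.10, 0.15, 0.20, 0.25)} for drug A and
#' \eqn{q = (0.06, 0.12, 0.18, 0.25)} for drug B: the highest dose of each
#' agent sits at its single-agent maximum tolerated dose for a target
#' toxicity level of 0.25.
#'
#' @return A `dose_grid`.
#' @export
default_grid <- function() {
  dose_grid(c(0.10, 0.15, 0.20, 0.25), c(0.06, 0.12, 0.18, 0.25))
}

#' Dose-toxicity model parameters
#'
#' Parameter vector of the copula dose-toxicity model: marginal powers
#' `alpha` (drug A) and `beta` (drug B), interaction `gamma`, and the
#' pre-`t_B` fraction `lambda` -- the fraction of drug A's full-cycle
#' toxicity probability realised before drug B is administered.
#'
#' @param alpha Non-negative marginal power for drug A.
#' @param beta Non-negative marginal power for drug B.
#' @param gamma Real interaction parameter; positive values are synergistic,
#'   negative antagonistic, zero independent action.
#' @param lambda Pre-`t_B` fraction in `[0, 1)`.
#'
#' @return An object of class `model_params`.
#' @examples
#' model_params(1, 1, 0, lambda = 4 / 7)
#' @export
model_params <- function(alpha = 1, beta = 1, gamma = 0, lambda = 0) {
  vals <- c(alpha = alpha, beta = beta, gamma = gamma, lambda = lambda)
  if (anyNA(vals) || any(!is.finite(vals))) {
    stop("All model parameters must be finite.", call. = FALSE)
  }
  if (alpha < 0 || beta < 0) {
    stop("`alpha` and `beta` must be non-negative.", call. = FALSE)
  }
  if (lambda < 0 || lambda >= 1) {
    stop("`lambda` must lie in [0, 1).", call. = FALSE)
  }
  structure(
    list(alpha = alpha, beta = beta, gamma = gamma, lambda = lambda),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<model_params> alpha = %g, beta = %g, gamma = %g, lambda = %g\n",
              x$alpha, x$beta, x$gamma, x$lambda))
  invisible(x)
}

#' Cycle timing for non-concurrent administration
#'
#' Drug A is given at time 0 of each treatment cycle; drug B is given at
#' time `t_b` provided no DLT has occurred before then; the cycle is
#' observed over `[0, t_cycle]`.
#'
#' @param t_b Time (e.g. days) at which drug B is administered; must satisfy
#'   `0 < t_b < t_cycle`.
#' @param t_cycle Cycle length in the same units.
#'
#' @return An object of class `cycle_timing`.
#' @examples
#' cycle_timing(4, 7)
#' @export
cycle_timing <- function(t_b = 4, t_cycle = 7) {
  if (!is.numeric(t_b) || !is.numeric(t_cycle) ||
      t_b <= 0 || t_cycle <= t_b) {
    stop("Require 0 < t_b < t_cycle.", call. = FALSE)
  }
  structure(list(t_b = t_b, t_cycle = t_cycle), class = "cycle_timing")
}

#' @export
print.cycle_timing <- function(x, ...) {
  cat(sprintf("<cycle_timing> drug B at day %g of a %g-day cycle\n",
              x$t_b, x$t_cycle))
  invisible(x)
}
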