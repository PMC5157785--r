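#' True dose-toxicity scenario for simulation
#'
#' A scenario fixes the *true* data-generating probabilities for a
#' simulated trial: the full-cycle DLT probability `true_pi` at every
#' combination and the pre-`t_B` DLT probability `true_pre` at every dose
#' of drug A. The pre-`t_B` vector can be given directly (allowing
#' dose-dependent fractions, as in the sensitivity scenario) or via a
#' scalar `lambda_tr` multiplying a supplied vector of single-agent
#' full-cycle probabilities.
#'
#' Construction validates the structural conditions: probabilities in
#' `[0, 1]`, `true_pi` non-decreasing in each drug's dose, and
#' `true_pre[j] <= min_k true_pi[j, k]` (a combination over the full cycle
#' is at least as toxic as drug A alone before `t_B`).
#'
#' @param name Scenario label.
#' @param grid A [dose_grid()].
#' @param true_pi J x K matrix of full-cycle DLT probabilities (rows index
#'   drug A, columns drug B).
#' @param true_pre Length-J vector of pre-`t_B` DLT probabilities. Exactly
#'   one of `true_pre` or (`lambda_tr`, `mono_pi_a`) must be supplied.
#' @param lambda_tr Scalar true pre-`t_B` fraction.
#' @param mono_pi_a Length-J vector of true single-agent full-cycle DLT
#'   probabilities for drug A, multiplied by `lambda_tr`.
#' @param true_params Optional named vector `c(alpha, beta, gamma)` of the
#'   generating parameters, enabling bias/RMSE summaries.
#'
#' @return An object of class `scenario`.
#' @examples
#' sc <- scenario("flat", dose_grid(c(0.1, 0.2), c(0.1, 0.2)),
#'                true_pi = matrix(c(0.10, 0.20, 0.20, 0.30), 2, 2),
#'                true_pre = c(0.05, 0.10))
#' @export
scenario <- function(name, grid, true_pi, true_pre = NULL, lambda_tr = NULL,
                     mono_pi_a = NULL, true_params = NULL) {
  J <- length(grid$skeleton_p); K <- length(grid$skeleton_q)
  true_pi <- matrix(as.numeric(true_pi), J, K)
  if (is.null(true_pre)) {
    if (is.null(lambda_tr) || is.null(mono_pi_a)) {
      stop("Supply `true_pre`, or both `lambda_tr` and `mono_pi_a`.",
           call. = FALSE)
    }
    true_pre <- lambda_tr * mono_pi_a
  }
  if (length(true_pre) != J) {
    stop("`true_pre` must have one entry per dose of drug A.", call. = FALSE)
  }
  if (any(true_pi < 0) || any(true_pi > 1) || any(true_pre < 0) ||
      any(true_pre > 1)) {
    stop("Scenario probabilities must lie in [0, 1].", call. = FALSE)
  }
  if (J > 1 && any(apply(true_pi, 2, diff) < 0)) {
    stop("`true_pi` must be non-decreasing in the dose of drug A.", call. = FALSE)
  }
  if (K > 1 && any(apply(true_pi, 1, diff) < 0)) {
    stop("`true_pi` must be non-decreasing in the dose of drug B.", call. = FALSE)
  }
  if (any(true_pre > apply(true_pi, 1, min))) {
    stop("`true_pre[j]` may not exceed any full-cycle probability at dose j.",
         call. = FALSE)
  }
  structure(
    list(name = name, grid = grid, true_pi = true_pi,
         true_pre = as.numeric(true_pre), true_params = true_params),
    class = "scenario"
  )
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario> ", x$name, "\n", sep = "")
  cat("full-cycle DLT probabilities (rows: drug A; cols: drug B):\n")
  print(x$true_pi)
  cat("pre-t_B DLT probabilities:", paste(format(x$true_pre), collapse = " "), "\n")
  invisible(x)
}

#' Build a scenario from generating parameters
#'
#' Evaluates the copula surface at fixed parameters to produce the true
#' probability tables of a parameter-generated scenario.
#'
#' @inheritParams scenario
#' @param params A [model_params()]; `lambda` supplies the true pre-`t_B`
#'   fraction.
#' @param round_dp Optional number of decimal places to round the tables to
#'   (the packaged scenarios use 2, treating the printed values as exact).
#' @return A `scenario`.
#' @export
scenario_from_params <- function(name, grid, params, round_dp = NULL) {
  true_pi <- prob_surface(grid, params)
  mono <- prob_dlt_cycle(grid, params, seq_along(grid$skeleton_p), 0)
  pre <- params$lambda * mono
  if (!is.null(round_dp)) {
    true_pi <- round(true_pi, round_dp)
    pre <- round(pre, round_dp)
  }
  scenario(name, grid, true_pi, true_pre = pre,
           true_params = c(alpha = params$alpha, beta = params$beta,
                           gamma = params$gamma))
}

# Truth tables for the six packaged scenarios, on the default 4 x 4 grid.
# Full-cycle probabilities: rows index the dose of drug A (j = 1..4),
# columns the dose of drug B (k = 1..4).
scenario_pi_tables <- function() {
  list(
    `1` = matrix(c(0.15, 0.20, 0.25, 0.30,
                   0.21, 0.25, 0.30, 0.34,
                   0.26, 0.30, 0.34, 0.38,
                   0.32, 0.36, 0.40, 0.44), 4, 4),
    `2` = matrix(c(0.06, 0.08, 0.12, 0.15,
                   0.08, 0.11, 0.14, 0.18,
                   0.12, 0.15, 0.17, 0.21,
                   0.17, 0.19, 0.22, 0.25), 4, 4),
    `3` = matrix(c(0.08, 0.11, 0.16, 0.20,
                   0.10, 0.14, 0.18, 0.22,
                   0.13, 0.17, 0.21, 0.25,
                   0.18, 0.22, 0.25, 0.29), 4, 4),
    `4` = matrix(c(0.17, 0.23, 0.29, 0.34,
                   0.20, 0.25, 0.31, 0.36,
                   0.23, 0.28, 0.33, 0.38,
                   0.27, 0.32, 0.36, 0.41), 4, 4),
    `5` = matrix(c(0.22, 0.28, 0.34, 0.39,
                   0.25, 0.31, 0.37, 0.42,
                   0.29, 0.34, 0.40, 0.45,
                   0.33, 0.39, 0.44, 0.48), 4, 4),
    `6` = matrix(c(0.22, 0.25, 0.28, 0.31,
                   0.31, 0.34, 0.36, 0.40,
                   0.39, 0.41, 0.43, 0.46,
                   0.46, 0.48, 0.51, 0.53), 4, 4)
  )
}

# Pre-t_B probabilities per scenario and true lambda fraction; each matrix
# has rows j = 1..4 and columns lambda_tr = 2/14, 8/14, 13/14.
scenario_pre_tables <- function() {
  list(
    `1` = matrix(c(0.01, 0.02, 0.03, 0.04,
                   0.06, 0.09, 0.11, 0.14,
                   0.09, 0.14, 0.19, 0.23), 4, 3),
    `2` = matrix(c(0.01, 0.01, 0.01, 0.02,
                   0.02, 0.04, 0.06, 0.08,
                   0.04, 0.06, 0.09, 0.13), 4, 3),
    `3` = matrix(c(0.01, 0.01, 0.02, 0.03,
                   0.04, 0.06, 0.08, 0.11,
                   0.06, 0.09, 0.13, 0.17), 4, 3),
    `4` = matrix(c(0.02, 0.03, 0.04, 0.05,
                   0.09, 0.13, 0.16, 0.19,
                   0.15, 0.20, 0.26, 0.31), 4, 3),
    `5` = matrix(c(0.03, 0.04, 0.05, 0.05,
                   0.11, 0.15, 0.19, 0.22,
                   0.19, 0.25, 0.30, 0.35), 4, 3),
    `6` = matrix(c(0.01, 0.01, 0.02, 0.02,
                   0.02, 0.04, 0.06, 0.08,
                   0.04, 0.07, 0.10, 0.13), 4, 3)
  )
}

#' Packaged true-toxicity scenarios
#'
#' Nineteen named scenarios on the default 4 x 4 grid: six full-cycle
#' probability tables, each paired with pre-`t_B` probabilities for a true
#' fraction of 2/14 (lower than the prior expects), 8/14 (as expected) or
#' 13/14 (higher), plus `"scenario5-sensitivity"`, in which the pre-`t_B`
#' probabilities (0.01, 0.06, 0.12, 0.22) are *not* proportional to drug
#' A's marginal toxicity, the fraction instead increasing with dose.
#' Scenario 1 is generated by the prior-central parameters
#' (`alpha = beta = 1`, `gamma = 0`) on the default skeletons and carries
#' them as `true_params`; all tables are treated as exact at two decimal
#' places.
#'
#' Names are `"scenario<s>-lam<x>"` with `<x>` in `2`, `8`, `13`
#' (fourteenths), e.g. `"scenario2-lam8"`.
#'
#' @return A named list of [scenario()] objects.
#' @examples
#' names(packaged_scenarios())
#' packaged_scenarios()[["scenario1-lam8"]]
#' @export
packaged_scenarios <- function() {
  grid <- default_grid()
  pis <- scenario_pi_tables()
  pres <- scenario_pre_tables()
  lam_tags <- c("lam2", "lam8", "lam13")
  out <- list()
  for (s in names(pis)) {
    for (m in 1:3) {
      nm <- paste0("scenario", s, "-", lam_tags[m])
      out[[nm]] <- scenario(
        nm, grid, pis[[s]], true_pre = pres[[s]][, m],
        true_params = if (s == "1") c(alpha = 1, beta = 1, gamma = 0)
      )
    }
  }
  out[["scenario5-sensitivity"]] <- scenario(
    "scenario5-sensitivity", grid, pis[["5"]],
    true_pre = c(0.01, 0.06, 0.12, 0.22)
  )
  out
}

#' Load one packaged scenario by name
#'
#' @param name A name from [packaged_scenarios()].
#' @return A `scenario`.
#' @export
load_scenario <- function(name) {
  sc <- packaged_scenarios()
  if (!name %in% names(sc)) {
    stop("Unknown scenario `", name, "`. Available: ",
         paste(names(sc), collapse = ", "), call. = FALSE)
  }
  sc[[name]]
}

#' Read / write a scenario as a YAML file
#'
#' The on-disk format is human-readable YAML with explicit probability
#' tables; a written file reads back to an identical scenario.
#'
#' @param sc A [scenario()].
#' @param path File path.
#' @return `read_scenario()` returns a `scenario`; `write_scenario()`
#'   returns `path` invisibly.
#' @export
write_scenario <- function(sc, path) {
  obj <- list(
    name = sc$name,
    skeleton_p = sc$grid$skeleton_p,
    skeleton_q = sc$grid$skeleton_q,
    true_pi = lapply(seq_len(nrow(sc$true_pi)), function(j) sc$true_pi[j, ]),
    true_pre = sc$true_pre
  )
  if (!is.null(sc$true_params)) obj$true_params <- as.list(sc$true_params)
  yaml::write_yaml(obj, path, precision = 12)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  obj <- yaml::read_yaml(path)
  grid <- dose_grid(obj$skeleton_p, obj$skeleton_q)
  true_pi <- do.call(rbind, lapply(obj$true_pi, as.numeric))
  tp <- if (!is.null(obj$true_params)) unlist(obj$true_params)
  scenario(obj$name, grid, true_pi, true_pre = as.numeric(obj$true_pre),
           true_params = tp)
}
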