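#' Design configuration for a dose-escalation trial
#'
#' Defaults follow the package's reference trial set-up: target toxicity
#' level 0.25, early-stopping threshold 0.80 (which, under the default
#' priors, also corresponds to stopping after two DLTs in the first cohort
#' of two), MTD window 0.025 (a 5% probability window around the target),
#' cohorts of two patients, and a maximum of 60 patients.
#'
#' @param Gamma Target toxicity level in (0, 1).
#' @param tau Early-stopping threshold in (0, 1): stop when the posterior
#'   probability that even the lowest combination exceeds `Gamma` is
#'   greater than `tau` (strict).
#' @param epsilon Half-width of the MTD recommendation window around
#'   `Gamma`.
#' @param cohort_size Patients per cohort.
#' @param max_patients Maximum number of patients; must be divisible by
#'   `cohort_size`.
#' @param tie_tolerance Two candidates whose distances to `Gamma` differ by
#'   no more than this are treated as tied.
#' @param neighbourhood If `TRUE` (default) the next combination is
#'   restricted to the 3 x 3 neighbourhood of the current one; `FALSE`
#'   allows any combination on the grid.
#'
#' @return An object of class `design_config`.
#' @export
design_config <- function(Gamma = 0.25, tau = 0.80, epsilon = 0.025,
                          cohort_size = 2, max_patients = 60,
                          tie_tolerance = 1e-6, neighbourhood = TRUE) {
  stopifnot(Gamma > 0, Gamma < 1, tau > 0, tau < 1, epsilon >= 0,
            cohort_size >= 1, max_patients >= cohort_size)
  if (max_patients %% cohort_size != 0) {
    stop("`max_patients` must be divisible by `cohort_size`.", call. = FALSE)
  }
  structure(
    list(Gamma = Gamma, tau = tau, epsilon = epsilon,
         cohort_size = as.integer(cohort_size),
         max_patients = as.integer(max_patients),
         tie_tolerance = tie_tolerance, neighbourhood = neighbourhood),
    class = "design_config"
  )
}

#' Neighbourhood of a dose combination
#'
#' All on-grid combinations at most one level away from `combo` in each
#' coordinate (vertically, horizontally and diagonally), *including* the
#' combination itself, so staying at the current combination is always an
#' available decision.
#'
#' @param grid A [dose_grid()].
#' @param combo Integer length-2 vector `(j, k)`.
#' @return A tibble with columns `a_idx`, `b_idx` (4 rows at a corner of
#'   the grid, up to 9 in the interior).
#' @examples
#' neighbourhood(default_grid(), c(1, 1))
#' @export
neighbourhood <- function(grid, combo) {
  J <- length(grid$skeleton_p); K <- length(grid$skeleton_q)
  j <- as.integer(combo[1]); k <- as.integer(combo[2])
  if (j < 1L || j > J || k < 1L || k > K) {
    stop("`combo` is not on the grid.", call. = FALSE)
  }
  out <- expand.grid(a_idx = (j - 1L):(j + 1L), b_idx = (k - 1L):(k + 1L))
  out <- out[out$a_idx >= 1L & out$a_idx <= J &
               out$b_idx >= 1L & out$b_idx <= K, ]
  tibble::as_tibble(out)
}

#' Select the next dose combination
#'
#' Among the candidate combinations (the neighbourhood of the previous
#' cohort's combination, or the full grid if the neighbourhood constraint
#' is disabled), chooses the one whose posterior-median DLT probability is
#' closest to the target `Gamma`. Ties (within `tie_tolerance`) are broken
#' by design:
#' * `"sa"`: the combination with the smallest dose of drug A (then the
#'   smallest dose of drug B), which minimises the chance of a pre-`t_B`
#'   DLT and so maximises the chance the patient receives both drugs;
#' * `"na"`: weighted randomisation with probability proportional to
#'   `1 / n_jk`, the inverse of the number of patients already treated at
#'   each tied candidate. If any tied candidate is untried
#'   (`n_jk = 0`, infinite weight), the draw is uniform among the untried
#'   candidates only. Randomness is consumed only when an NA tie occurs.
#'
#' @param summary A `tox_summary` (from [posterior_summary()] or
#'   [quadrature_posterior()]).
#' @param prev_combo Integer `(j, k)` given to the previous cohort.
#' @param config A [design_config()].
#' @param model `"sa"` or `"na"` (controls tie-breaking only).
#' @param counts J x K matrix of patients treated per combination (used for
#'   NA tie-breaking; defaults to all zeros).
#'
#' @return A list with `action = "continue"`, `next_combo` (integer
#'   `(j, k)`), and `candidates` (tibble of per-candidate medians and
#'   distances).
#' @export
select_next <- function(summary, prev_combo, config = design_config(),
                        model = c("sa", "na"), counts = NULL) {
  model <- match.arg(model)
  grid <- summary$grid
  J <- nrow(summary$median_surface); K <- ncol(summary$median_surface)
  if (is.null(counts)) counts <- matrix(0L, J, K)
  cand <- if (config$neighbourhood) {
    neighbourhood(grid, prev_combo)
  } else {
    tibble::tibble(a_idx = rep(seq_len(J), K), b_idx = rep(seq_len(K), each = J))
  }
  cand$median <- summary$median_surface[cbind(cand$a_idx, cand$b_idx)]
  cand$distance <- abs(cand$median - config$Gamma)
  cand$n_treated <- counts[cbind(cand$a_idx, cand$b_idx)]
  tied <- cand[cand$distance <= min(cand$distance) + config$tie_tolerance, ]
  if (nrow(tied) == 1L) {
    pick <- tied
  } else if (model == "sa") {
    pick <- tied[order(tied$a_idx, tied$b_idx), ][1, ]
  } else {
    untried <- tied[tied$n_treated == 0L, ]
    if (nrow(untried) > 0L) {
      pick <- untried[sample.int(nrow(untried), 1L), ]
    } else {
      w <- 1 / tied$n_treated
      pick <- tied[sample.int(nrow(tied), 1L, prob = w / sum(w)), ]
    }
  }
  list(action = "continue",
       next_combo = c(pick$a_idx[1], pick$b_idx[1]),
       candidates = cand)
}

#' Early-stopping rule
#'
#' The trial stops when the posterior probability that the lowest dose
#' combination is above the target toxicity level strictly exceeds the
#' threshold `tau`: `P(pi_T(a_1, b_1) > Gamma) > tau`.
#'
#' @inheritParams select_next
#' @return `TRUE` to stop, `FALSE` to continue.
#' @export
should_stop <- function(summary, config = design_config()) {
  summary$exceedance_lowest > config$tau
}

#' End-of-trial MTD recommendation set
#'
#' Recommends every dose combination that (a) was experimented on during
#' the trial (at least one patient treated) and (b) has posterior-median
#' DLT probability within `epsilon` of the target. Combinations close to
#' the target that were never tried are excluded; the set may be empty, in
#' which case the trial recommends no MTD.
#'
#' @inheritParams select_next
#' @param counts J x K matrix of patients treated per combination.
#' @return A tibble with columns `a_idx`, `b_idx`, `median`, `n_treated`
#'   (zero rows when no combination qualifies).
#' @export
recommend_mtd <- function(summary, counts, config = design_config()) {
  J <- nrow(summary$median_surface); K <- ncol(summary$median_surface)
  out <- tibble::tibble(
    a_idx = rep(seq_len(J), K), b_idx = rep(seq_len(K), each = J),
    median = as.vector(summary$median_surface),
    n_treated = as.vector(counts)
  )
  out[out$n_treated > 0L &
        abs(out$median - config$Gamma) <= config$epsilon, ]
}
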