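#' Assemble and validate per-patient trial data
#'
#' Trial data are tabular: one row per patient, in enrolment order, with the
#' dose indices assigned and the trinary outcome. When a patient experiences
#' a DLT before time `t_B` (`outcome = 1`), drug B is withheld for that
#' patient but `b_idx` still records the dose of drug B that *would* have
#' been given; the analysis of the binary (non-attributable) model uses that
#' planned dose.
#'
#' @param a_idx Integer vector of drug A dose indices (1-based).
#' @param b_idx Integer vector of planned drug B dose indices (1-based).
#' @param outcome Integer vector of trinary outcomes: 0 = no DLT in the
#'   cycle, 1 = DLT before `t_B`, 2 = DLT after `t_B`.
#' @param b_administered Logical; whether drug B was actually given.
#'   Defaults to `outcome != 1`, which is also enforced: a pre-`t_B` DLT
#'   prevents administration of drug B.
#' @param grid Optional [dose_grid()] used to bounds-check the indices.
#'
#' @return A tibble with columns `patient`, `a_idx`, `b_idx`,
#'   `b_administered`, `outcome`.
#' @examples
#' patient_data(a_idx = c(1, 1), b_idx = c(1, 1), outcome = c(0, 1))
#' @export
patient_data <- function(a_idx, b_idx, outcome,
                         b_administered = outcome != 1L, grid = NULL) {
  n <- length(a_idx)
  if (length(b_idx) != n || length(outcome) != n || length(b_administered) != n) {
    stop("`a_idx`, `b_idx`, `outcome` and `b_administered` must share a length.",
         call. = FALSE)
  }
  a_idx <- as.integer(a_idx); b_idx <- as.integer(b_idx)
  outcome <- as.integer(outcome)
  if (n > 0 && (any(outcome < 0L) || any(outcome > 2L))) {
    stop("`outcome` must be 0, 1 or 2.", call. = FALSE)
  }
  if (any((outcome == 1L) != !b_administered)) {
    stop("`outcome = 1` must coincide exactly with drug B being withheld.",
         call. = FALSE)
  }
  if (!is.null(grid)) {
    J <- length(grid$skeleton_p); K <- length(grid$skeleton_q)
    if (n > 0 && (any(a_idx < 1L) || any(a_idx > J) ||
                  any(b_idx < 1L) || any(b_idx > K))) {
      stop("Dose indices outside the grid.", call. = FALSE)
    }
  }
  tibble::tibble(
    patient = seq_len(n), a_idx = a_idx, b_idx = b_idx,
    b_administered = as.logical(b_administered), outcome = outcome
  )
}

#' Log-likelihood of the semi-attributable (trinary) model
#'
#' Each patient contributes the probability of their trinary outcome:
#' \eqn{1 - \pi_T(a, b)} for no DLT, \eqn{\lambda\,\pi_T(a, 0)} for a DLT
#' before drug B, and \eqn{\pi_T(a, b) - \lambda\,\pi_T(a, 0)} for a DLT
#' after both drugs. Returns `-Inf` when any observed outcome has
#' non-positive model probability (e.g. a pre-`t_B` DLT with
#' `lambda = 0`), and 0 for empty data.
#'
#' @param data A data frame as produced by [patient_data()].
#' @param grid A [dose_grid()].
#' @param params A [model_params()].
#' @return A single numeric log-likelihood.
#' @examples
#' d <- patient_data(c(1, 1), c(1, 1), c(0, 0))
#' loglik_sa(d, default_grid(), model_params(1, 1, 0, 4 / 7))
#' @export
loglik_sa <- function(data, grid, params) {
  if (nrow(data) == 0L) return(0)
  pi_full <- prob_dlt_cycle(grid, params, data$a_idx, data$b_idx)
  pre <- prob_dlt_pre(grid, params, data$a_idx)
  prob <- ifelse(data$outcome == 0L, 1 - pi_full,
                 ifelse(data$outcome == 1L, pre, pi_full - pre))
  if (any(prob <= 0)) return(-Inf)
  sum(log(prob))
}

#' Log-likelihood of the non-attributable (binary) model
#'
#' The comparator analysis ignores the timing of a DLT within the cycle:
#' each patient contributes \eqn{\pi_T(a, b)} if they had any DLT and
#' \eqn{1 - \pi_T(a, b)} otherwise, always evaluated at the *planned* dose
#' combination. `lambda` plays no role.
#'
#' @inheritParams loglik_sa
#' @return A single numeric log-likelihood.
#' @export
loglik_na <- function(data, grid, params) {
  if (nrow(data) == 0L) return(0)
  pi_full <- prob_dlt_cycle(grid, params, data$a_idx, data$b_idx)
  prob <- ifelse(data$outcome == 0L, 1 - pi_full, pi_full)
  if (any(prob <= 0)) return(-Inf)
  sum(log(prob))
}

#' Read / write patient data as CSV
#'
#' The on-disk exchange format is a plain CSV with mandatory header and
#' columns `patient`, `a_idx`, `b_idx`, `b_administered`, `outcome`
#' (1-based dose indices; outcome coded 0/1/2).
#'
#' @param path File path.
#' @param grid Optional [dose_grid()] for bounds checking on read.
#' @return `read_patient_data()` returns the validated tibble;
#'   `write_patient_data()` returns `path` invisibly.
#' @export
read_patient_data <- function(path, grid = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("a_idx", "b_idx", "outcome")
  if (!all(need %in% names(df))) {
    stop("Patient CSV must contain columns a_idx, b_idx, outcome.", call. = FALSE)
  }
  b_adm <- if ("b_administered" %in% names(df)) {
    as.logical(df$b_administered)
  } else {
    df$outcome != 1L
  }
  patient_data(df$a_idx, df$b_idx, df$outcome, b_adm, grid = grid)
}

#' @rdname read_patient_data
#' @param data A tibble from [patient_data()].
#' @export
write_patient_data <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
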