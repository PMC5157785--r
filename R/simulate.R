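#' Draw a patient outcome under a true scenario
#'
#' The trinary outcome is generated by inverting a single uniform draw
#' against the scenario's cut-points: `Y = 1` (pre-`t_B` DLT) if
#' `u <= true_pre[j]`, `Y = 2` (post-`t_B` DLT) if
#' `true_pre[j] < u <= true_pi[j, k]`, else `Y = 0`. Using one uniform per
#' patient couples the semi-attributable and non-attributable analyses of
#' the same simulated trial: with a shared seed they observe identical
#' outcomes wherever their dose paths agree.
#'
#' @param sc A [scenario()].
#' @param j,k Dose indices of the assigned combination.
#' @param u Uniform(0, 1) variate(s); defaults to fresh draws.
#' @return Integer vector of outcomes in `{0, 1, 2}`.
#' @export
sample_outcome <- function(sc, j, k, u = stats::runif(max(length(j), length(k)))) {
  J <- nrow(sc$true_pi); K <- ncol(sc$true_pi)
  if (any(j < 1L | j > J) || any(k < 1L | k > K)) {
    stop("Combination off the scenario grid.", call. = FALSE)
  }
  pre <- sc$true_pre[j]
  full <- sc$true_pi[cbind(j, k)]
  ifelse(u <= pre, 1L, ifelse(u <= full, 2L, 0L))
}

#' Simulate one dose-escalation trial
#'
#' Runs the cohort-wise adaptive design on a true scenario: the first
#' cohort is treated at the lowest combination \eqn{(a_1, b_1)}; drug B is
#' given to a patient only if no DLT occurs before `t_B` (outcome 1); after
#' each cohort the posterior is refitted on all accrued data, the trial
#' stops if the lowest combination is too likely to exceed the target, and
#' otherwise the next cohort is assigned by [select_next()] within the
#' neighbourhood of the current combination. When the patient limit is
#' reached the MTD set is recommended by [recommend_mtd()].
#'
#' All randomness derives from `seed`: the per-patient outcome uniforms
#' for the whole trial are drawn up front, so that the SA and NA analyses
#' of the same seed share outcome randomness, and the sampler (plus any NA
#' tie-breaking) consumes the stream afterwards.
#'
#' @param sc A [scenario()].
#' @param model `"sa"` or `"na"`: the analysis model and tie-breaking rule.
#' @param config A [design_config()].
#' @param prior A [prior_spec()].
#' @param mcmc An [mcmc_control()]; batch simulations typically use
#'   [mcmc_control_reduced()].
#' @param seed Integer seed for the trial.
#'
#' @return An object of class `trial_result`: `patients` (tibble: cohort,
#'   patient, dose indices, `b_administered`, outcome, true probability),
#'   `stopped_early`, `mtd` (tibble, zero rows if none), `counts`,
#'   `n_dlt`, `n_pre_tb`, `param_medians`, `decisions` (per-cohort log),
#'   `valid` (FALSE if a posterior fit failed after retries).
#' @export
run_trial <- function(sc, model = c("sa", "na"), config = design_config(),
                      prior = prior_spec(), mcmc = mcmc_control_reduced(),
                      seed = 1L) {
  model <- match.arg(model)
  set.seed(seed)
  u <- stats::runif(config$max_patients)
  J <- nrow(sc$true_pi); K <- ncol(sc$true_pi)
  counts <- matrix(0L, J, K)
  combo <- c(1L, 1L)
  rows <- vector("list", config$max_patients %/% config$cohort_size)
  decisions <- list()
  stopped <- FALSE
  mtd <- NULL
  summary <- NULL
  valid <- TRUE
  n <- 0L
  cohort <- 0L
  while (n < config$max_patients) {
    cohort <- cohort + 1L
    idx <- n + seq_len(config$cohort_size)
    y <- sample_outcome(sc, rep(combo[1], length(idx)),
                        rep(combo[2], length(idx)), u[idx])
    rows[[cohort]] <- tibble::tibble(
      cohort = cohort, patient = idx,
      a_idx = combo[1], b_idx = combo[2],
      b_administered = y != 1L, outcome = y
    )
    counts[combo[1], combo[2]] <- counts[combo[1], combo[2]] + length(idx)
    n <- n + length(idx)
    data <- dplyr::bind_rows(rows[seq_len(cohort)])
    fit <- tryCatch(
      sample_posterior(data, sc$grid, prior, model = model, mcmc = mcmc),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      valid <- FALSE
      break
    }
    summary <- posterior_summary(fit, Gamma = config$Gamma)
    stop_now <- should_stop(summary, config)
    decisions[[cohort]] <- list(
      cohort = cohort, combo = combo, outcomes = y,
      exceedance = summary$exceedance_lowest, stop = stop_now
    )
    if (stop_now) {
      stopped <- TRUE
      break
    }
    if (n >= config$max_patients) {
      mtd <- recommend_mtd(summary, counts, config)
      break
    }
    sel <- select_next(summary, combo, config, model = model, counts = counts)
    decisions[[cohort]]$next_combo <- sel$next_combo
    combo <- sel$next_combo
  }
  patients <- dplyr::bind_rows(rows[!vapply(rows, is.null, logical(1))])
  patients$true_pi <- sc$true_pi[cbind(patients$a_idx, patients$b_idx)]
  structure(
    list(
      patients = patients, stopped_early = stopped,
      mtd = mtd %||% recommend_mtd_empty(),
      counts = counts, n_dlt = sum(patients$outcome != 0L),
      n_pre_tb = sum(patients$outcome == 1L),
      param_medians = if (!is.null(summary)) summary$param_medians,
      decisions = decisions, valid = valid,
      scenario = sc$name, model = model, seed = seed
    ),
    class = "trial_result"
  )
}

#' Per-cohort decision log as JSON lines
#'
#' One JSON record per cohort: the combination treated, observed outcomes,
#' the early-stopping exceedance probability, the stop flag and (when the
#' trial continued) the combination selected for the next cohort.
#'
#' @param trial A `trial_result`.
#' @return Character vector of JSON lines.
#' @export
decision_log <- function(trial) {
  vapply(trial$decisions, function(d) {
    as.character(jsonlite::toJSON(d, auto_unbox = TRUE, digits = NA))
  }, character(1))
}

recommend_mtd_empty <- function() {
  tibble::tibble(a_idx = integer(), b_idx = integer(), median = numeric(),
                 n_treated = integer())
}

#' @export
print.trial_result <- function(x, ...) {
  cat("<trial_result> ", toupper(x$model), " on ", x$scenario, ": ",
      nrow(x$patients), " patients, ", x$n_dlt, " DLTs (",
      x$n_pre_tb, " pre-t_B)", sep = "")
  if (x$stopped_early) {
    cat("; stopped early\n")
  } else if (nrow(x$mtd) == 0L) {
    cat("; no MTD recommended\n")
  } else {
    cat("; MTD set: ",
        paste(sprintf("(%d,%d)", x$mtd$a_idx, x$mtd$b_idx), collapse = " "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Simulate a batch of trials
#'
#' Trial `i` runs under a seed derived deterministically from
#' (`base_seed`, `i`), so results are reproducible and independent of the
#' degree of parallelism.
#'
#' @inheritParams run_trial
#' @param n_trials Number of trials.
#' @param base_seed Base integer seed.
#' @param workers Number of parallel workers (forked; 1 = sequential).
#' @return An object of class `trial_batch`: a list of `trial_result`s
#'   plus the run metadata.
#' @export
run_batch <- function(sc, model = c("sa", "na"), config = design_config(),
                      prior = prior_spec(), mcmc = mcmc_control_reduced(),
                      n_trials = 1000, base_seed = 1L, workers = 1L) {
  model <- match.arg(model)
  seeds <- trial_seeds(base_seed, n_trials)
  one <- function(i) {
    run_trial(sc, model, config, prior, mcmc, seed = seeds[i])
  }
  results <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(n_trials), one, mc.cores = workers,
                       mc.preschedule = FALSE)
  } else {
    lapply(seq_len(n_trials), one)
  }
  structure(
    list(results = results, scenario = sc$name, model = model,
         config = config, n_trials = n_trials, base_seed = base_seed),
    class = "trial_batch"
  )
}

trial_seeds <- function(base_seed, n_trials) {
  (as.numeric(base_seed) + 7919 * seq_len(n_trials)) %% 2147483647
}

#' @export
print.trial_batch <- function(x, ...) {
  cat("<trial_batch> ", x$n_trials, " ", toupper(x$model), " trials on ",
      x$scenario, "\n", sep = "")
  invisible(x)
}

#' The true-DLT-probability bins of the operating-characteristic tables
#' @return Numeric vector of bin edges.
#' @export
oc_bins <- function() c(0, 0.2, 0.225, 0.275, 0.3, 0.4, 1)

#' Operating characteristics of a simulation batch
#'
#' Summarises a [run_batch()] result the way dose-finding simulation
#' studies report performance: the percentage of patients treated at
#' combinations whose *true* full-cycle DLT probability falls in each bin
#' (default bins `[0, 0.2]`, `(0.2, 0.225]`, `(0.225, 0.275]`,
#' `(0.275, 0.3]`, `(0.3, 0.4]`, `(0.4, 1]`); the mean and SD across
#' trials of the per-trial DLT rate; the mean and SD of the percentage of
#' a trial's DLTs occurring before `t_B` (over trials with at least one
#' DLT); the distribution of recommended MTDs over the same bins; counts
#' of early-stopped trials and of completed trials recommending no MTD;
#' the mean number of MTD recommendations per completed trial; and, when
#' the scenario carries generating parameters, the mean bias and RMSE of
#' the end-of-trial posterior-median parameter estimates over trials that
#' did not stop early.
#'
#' @param batch A `trial_batch` (or plain list of `trial_result`s).
#' @param sc The [scenario()] the batch was simulated from.
#' @param config The [design_config()] used.
#' @param bins Bin edges on the true DLT probability scale.
#' @return An object of class `tox_oc` (a list of tibbles and scalars).
#' @export
compute_oc <- function(batch, sc, config = design_config(), bins = oc_bins()) {
  results <- if (inherits(batch, "trial_batch")) batch$results else batch
  results <- Filter(function(r) isTRUE(r$valid), results)
  n_invalid <- (if (inherits(batch, "trial_batch")) batch$n_trials else length(batch)) -
    length(results)
  if (length(results) == 0L) stop("No valid trials to summarise.", call. = FALSE)

  bin_lab <- levels(cut(numeric(), bins, include.lowest = TRUE))
  bin_of <- function(p) cut(p, bins, include.lowest = TRUE)

  patients <- dplyr::bind_rows(lapply(results, `[[`, "patients"))
  exp_tab <- table(bin_of(patients$true_pi))
  experimentation <- tibble::tibble(
    bin = bin_lab, pct = 100 * as.numeric(exp_tab) / nrow(patients)
  )

  dlt_rate <- vapply(results, function(r) 100 * r$n_dlt / nrow(r$patients),
                     numeric(1))
  pre_pct <- vapply(results, function(r) {
    if (r$n_dlt == 0L) NA_real_ else 100 * r$n_pre_tb / r$n_dlt
  }, numeric(1))

  stopped <- vapply(results, `[[`, logical(1), "stopped_early")
  mtds <- dplyr::bind_rows(lapply(results[!stopped], `[[`, "mtd"))
  if (nrow(mtds) > 0L) {
    true_at_mtd <- sc$true_pi[cbind(mtds$a_idx, mtds$b_idx)]
    mtd_tab <- table(bin_of(true_at_mtd))
    mtd_distribution <- tibble::tibble(
      bin = bin_lab, pct = 100 * as.numeric(mtd_tab) / nrow(mtds)
    )
  } else {
    mtd_distribution <- tibble::tibble(bin = bin_lab, pct = rep(0, length(bin_lab)))
  }
  n_mtd_per_trial <- vapply(results[!stopped], function(r) nrow(r$mtd), numeric(1))

  bias_rmse <- NULL
  if (!is.null(sc$true_params) && any(!stopped)) {
    est <- do.call(rbind, lapply(results[!stopped], function(r) {
      r$param_medians[c("alpha", "beta", "gamma")]
    }))
    err <- sweep(est, 2, sc$true_params[c("alpha", "beta", "gamma")])
    bias_rmse <- tibble::tibble(
      term = c("alpha", "beta", "gamma"),
      bias = unname(colMeans(err)),
      rmse = unname(sqrt(colMeans(err^2)))
    )
  }

  structure(
    list(
      experimentation = experimentation,
      dlt_rate_mean = mean(dlt_rate), dlt_rate_sd = stats::sd(dlt_rate),
      pre_tb_pct_mean = mean(pre_pct, na.rm = TRUE),
      pre_tb_pct_sd = stats::sd(pre_pct, na.rm = TRUE),
      mtd_distribution = mtd_distribution,
      n_early_stop = sum(stopped),
      n_no_mtd = sum(n_mtd_per_trial == 0),
      mean_n_mtd = mean(n_mtd_per_trial),
      bias_rmse = bias_rmse,
      n_trials = length(results), n_invalid = n_invalid,
      scenario = sc$name
    ),
    class = "tox_oc"
  )
}

#' @export
print.tox_oc <- function(x, ...) {
  cat("<tox_oc> ", x$n_trials, " trials on ", x$scenario, "\n", sep = "")
  cat("experimentation by true-DLT-probability bin (%):\n")
  print(as.data.frame(x$experimentation), row.names = FALSE)
  cat(sprintf("DLT rate: mean %.1f%% (SD %.1f)\n", x$dlt_rate_mean, x$dlt_rate_sd))
  if (!is.nan(x$pre_tb_pct_mean)) {
    cat(sprintf("DLTs before t_B: mean %.1f%% (SD %.1f)\n",
                x$pre_tb_pct_mean, x$pre_tb_pct_sd))
  }
  cat("MTD recommendations by bin (%):\n")
  print(as.data.frame(x$mtd_distribution), row.names = FALSE)
  cat(sprintf("early stops: %d; completed without MTD: %d; mean MTDs: %.2f\n",
              x$n_early_stop, x$n_no_mtd, x$mean_n_mtd))
  if (!is.null(x$bias_rmse)) {
    cat("parameter bias / RMSE over completed trials:\n")
    print(as.data.frame(x$bias_rmse), row.names = FALSE)
  }
  invisible(x)
}

#' Tidy operating characteristics
#'
#' @param x A `tox_oc`.
#' @param ... Unused.
#' @return A long tibble with columns `metric`, `bin` (NA for scalars),
#'   `value`.
#' @export
tidy.tox_oc <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$experimentation, metric = "experimentation_pct"),
    dplyr::mutate(x$mtd_distribution, metric = "mtd_pct"),
    tibble::tibble(
      metric = c("dlt_rate_mean", "dlt_rate_sd", "pre_tb_pct_mean",
                 "pre_tb_pct_sd", "n_early_stop", "n_no_mtd", "mean_n_mtd"),
      bin = NA_character_,
      pct = c(x$dlt_rate_mean, x$dlt_rate_sd, x$pre_tb_pct_mean,
              x$pre_tb_pct_sd, x$n_early_stop, x$n_no_mtd, x$mean_n_mtd)
    )
  ) |>
    dplyr::select(metric, bin, value = pct)
}

#' Export a batch as per-patient records
#'
#' @param batch A `trial_batch`.
#' @return A tibble with one row per patient across all trials.
#' @export
batch_patients <- function(batch) {
  dplyr::bind_rows(lapply(seq_along(batch$results), function(i) {
    dplyr::mutate(batch$results[[i]]$patients, trial = i, .before = 1)
  }))
}
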