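test_that("outcome generation follows the scenario's trinary probabilities", {
  sc <- load_scenario("scenario1-lam8")
  # direct cut-point checks at (4, 1): P(1) = 0.14, P(2) = 0.30 - 0.14
  expect_equal(sample_outcome(sc, 4, 1, u = 0.139), 1L)
  expect_equal(sample_outcome(sc, 4, 1, u = 0.141), 2L)
  expect_equal(sample_outcome(sc, 4, 1, u = 0.299), 2L)
  expect_equal(sample_outcome(sc, 4, 1, u = 0.301), 0L)
  set.seed(61)
  y <- sample_outcome(sc, rep(4L, 1e5), rep(1L, 1e5))
  p <- c(0.70, 0.14, 0.16)
  for (v in 0:2) {
    se <- sqrt(p[v + 1] * (1 - p[v + 1]) / 1e5)
    expect_lt(abs(mean(y == v) - p[v + 1]), 3.5 * se)
  }
  expect_error(sample_outcome(sc, 5, 1), "off the scenario grid")
})

test_that("a zero pre-t_B scenario never withholds drug B", {
  sc <- scenario("nopre", grid44, load_scenario("scenario1-lam8")$true_pi,
                 true_pre = rep(0, 4))
  set.seed(62)
  y <- sample_outcome(sc, rep(2L, 5e3), rep(2L, 5e3))
  expect_true(all(y %in% c(0L, 2L)))
})

test_that("a non-toxic scenario escalates without DLTs or stopping", {
  sc <- scenario("inert", grid44, matrix(1e-4, 4, 4), true_pre = rep(0, 4))
  tr <- run_trial(sc, "sa", design_config(max_patients = 12),
                  prior_spec(), mcmc_quick(), seed = 5)
  expect_false(tr$stopped_early)
  expect_equal(tr$n_dlt, 0L)
  expect_equal(nrow(tr$patients), 12L)
  # monotone escalation away from (1,1)
  last <- tr$patients[nrow(tr$patients), ]
  expect_gt(last$a_idx + last$b_idx, 2L)
})

test_that("an overly toxic lowest combination stops almost every trial", {
  hot <- matrix(0.95, 4, 4)
  sc <- scenario("hot", grid44, hot, true_pre = rep(0.5, 4))
  stops <- vapply(1:20, function(i) {
    run_trial(sc, "na", design_config(), prior_spec(), mcmc_quick(),
              seed = 100 + i)$stopped_early
  }, logical(1))
  expect_gte(mean(stops), 0.95)
})

test_that("a seeded trial replays identically", {
  sc <- load_scenario("scenario3-lam8")
  t1 <- run_trial(sc, "sa", design_config(max_patients = 8), prior_spec(),
                  mcmc_quick(), seed = 99)
  t2 <- run_trial(sc, "sa", design_config(max_patients = 8), prior_spec(),
                  mcmc_quick(), seed = 99)
  expect_identical(t1$patients, t2$patients)
  expect_identical(t1$mtd, t2$mtd)
  expect_identical(t1$param_medians, t2$param_medians)
})

test_that("SA and NA analyses share outcome randomness on a common path", {
  # Flat truth: every decision leads to similar dosing; compare the first
  # cohort, whose combination is fixed by design, and any later patients
  # dosed at the same combination under both analyses.
  sc <- load_scenario("scenario1-lam8")
  t_sa <- run_trial(sc, "sa", design_config(max_patients = 10), prior_spec(),
                    mcmc_quick(), seed = 123)
  t_na <- run_trial(sc, "na", design_config(max_patients = 10), prior_spec(),
                    mcmc_quick(), seed = 123)
  shared <- dplyr::inner_join(
    t_sa$patients[, c("patient", "a_idx", "b_idx", "outcome")],
    t_na$patients[, c("patient", "a_idx", "b_idx", "outcome")],
    by = c("patient", "a_idx", "b_idx")
  )
  expect_gte(nrow(shared), 2L)  # at least the first cohort coincides
  expect_equal(shared$outcome.x, shared$outcome.y)
})

test_that("trial bookkeeping is internally consistent", {
  sc <- load_scenario("scenario4-lam8")
  tr <- run_trial(sc, "na", design_config(max_patients = 16), prior_spec(),
                  mcmc_quick(), seed = 42)
  expect_lte(nrow(tr$patients), 16L)
  expect_equal(sum(tr$counts), nrow(tr$patients))
  expect_equal(tr$n_dlt, sum(tr$patients$outcome != 0))
  expect_equal(tr$n_pre_tb, sum(tr$patients$outcome == 1))
  expect_equal(tr$patients$b_administered, tr$patients$outcome != 1L)
  # consecutive cohorts stay within one dose level per drug
  combos <- unique(tr$patients[, c("cohort", "a_idx", "b_idx")])
  if (nrow(combos) > 1) {
    expect_true(all(abs(diff(combos$a_idx)) <= 1))
    expect_true(all(abs(diff(combos$b_idx)) <= 1))
  }
  expect_gt(length(decision_log(tr)), 0L)
  expect_true(all(grepl("^\\{", decision_log(tr))))
})

test_that("a single-cohort design recommends only the starting combination", {
  sc <- load_scenario("scenario1-lam8")
  cfg <- design_config(cohort_size = 2, max_patients = 2)
  recommended <- list()
  for (i in 1:5) {
    tr <- run_trial(sc, "sa", cfg, prior_spec(), mcmc_quick(), seed = 200 + i)
    expect_lte(nrow(tr$patients), 2L)
    expect_equal(unique(tr$patients[, c("a_idx", "b_idx")]),
                 tibble::tibble(a_idx = 1L, b_idx = 1L))
    if (!tr$stopped_early) recommended[[length(recommended) + 1]] <- tr$mtd
  }
  mtds <- dplyr::bind_rows(recommended)
  expect_true(all(mtds$a_idx == 1L & mtds$b_idx == 1L))
})

test_that("batch seeds are deterministic and order-independent", {
  sc <- load_scenario("scenario2-lam8")
  cfg <- design_config(max_patients = 6)
  b1 <- run_batch(sc, "na", cfg, prior_spec(), mcmc_quick(), n_trials = 3,
                  base_seed = 7, workers = 1)
  b2 <- run_batch(sc, "na", cfg, prior_spec(), mcmc_quick(), n_trials = 3,
                  base_seed = 7, workers = 2)
  for (i in 1:3) {
    expect_identical(b1$results[[i]]$patients, b2$results[[i]]$patients)
  }
  b0 <- run_batch(sc, "na", cfg, prior_spec(), mcmc_quick(), n_trials = 0,
                  base_seed = 7)
  expect_length(b0$results, 0L)
})

test_that("operating characteristics match a hand-computed fixture", {
  sc <- load_scenario("scenario1-lam8")
  mk_trial <- function(patients, stopped, mtd, medians) {
    structure(list(
      patients = patients, stopped_early = stopped, mtd = mtd,
      counts = matrix(0L, 4, 4), n_dlt = sum(patients$outcome != 0),
      n_pre_tb = sum(patients$outcome == 1),
      param_medians = medians, decisions = list(), valid = TRUE,
      scenario = sc$name, model = "sa", seed = 0
    ), class = "trial_result")
  }
  # trial 1: 4 patients at (1,1) [true 0.15], 2 at (2,2) [true 0.25];
  #          2 DLTs (one pre-t_B); recommends (2,2)
  p1 <- tibble::tibble(cohort = rep(1:3, each = 2), patient = 1:6,
                       a_idx = c(1, 1, 1, 1, 2, 2), b_idx = c(1, 1, 1, 1, 2, 2),
                       outcome = c(0, 1, 0, 0, 2, 0))
  p1$b_administered <- p1$outcome != 1
  p1$true_pi <- sc$true_pi[cbind(p1$a_idx, p1$b_idx)]
  mtd1 <- tibble::tibble(a_idx = 2L, b_idx = 2L, median = 0.25, n_treated = 2L)
  tr1 <- mk_trial(p1, FALSE, mtd1, c(alpha = 1.2, beta = 1.1, gamma = 0.4))
  # trial 2: stops early after 2 patients at (1,1), both DLTs post-t_B
  p2 <- tibble::tibble(cohort = 1L, patient = 1:2, a_idx = 1L, b_idx = 1L,
                       outcome = c(2, 2))
  p2$b_administered <- TRUE
  p2$true_pi <- sc$true_pi[cbind(p2$a_idx, p2$b_idx)]
  tr2 <- mk_trial(p2, TRUE, recommend_mtd(
    structure(list(median_surface = matrix(1, 4, 4), Gamma = 0.25),
              class = "tox_summary"), matrix(0L, 4, 4)),
    c(alpha = 0.4, beta = 0.5, gamma = 0.1))
  oc <- compute_oc(list(tr1, tr2), sc, design_config())
  # experimentation: 6 of 8 patients at 0.15 ([0, 0.2]), 2 at 0.25
  expect_equal(oc$experimentation$pct[1], 75)
  expect_equal(oc$experimentation$pct[3], 25)
  expect_equal(sum(oc$experimentation$pct), 100)
  # DLT rates: 2/6 and 2/2
  expect_equal(oc$dlt_rate_mean, mean(c(100 / 3, 100)))
  expect_equal(oc$dlt_rate_sd, sd(c(100 / 3, 100)))
  # pre-t_B percentages: 50% (trial 1), 0% (trial 2)
  expect_equal(oc$pre_tb_pct_mean, 25)
  # MTD distribution: the single recommendation sits in (0.225, 0.275]
  expect_equal(oc$mtd_distribution$pct[3], 100)
  expect_equal(oc$n_early_stop, 1L)
  expect_equal(oc$n_no_mtd, 0L)
  expect_equal(oc$mean_n_mtd, 1)
  # bias over the single completed trial
  expect_equal(oc$bias_rmse$bias, c(0.2, 0.1, 0.4))
  expect_equal(oc$bias_rmse$rmse, c(0.2, 0.1, 0.4))
})

test_that("trials with zero DLTs are excluded from the pre-t_B mean", {
  sc <- scenario("inert", grid44, matrix(1e-4, 4, 4), true_pre = rep(0, 4))
  tr <- run_trial(sc, "sa", design_config(max_patients = 4), prior_spec(),
                  mcmc_quick(), seed = 3)
  oc <- compute_oc(list(tr), sc, design_config())
  expect_true(is.nan(oc$pre_tb_pct_mean))
})
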