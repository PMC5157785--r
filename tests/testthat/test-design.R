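fake_summary <- function(m, exceed = 0, grid = grid44) {
  structure(list(median_surface = m, exceedance_lowest = exceed,
                 param_medians = c(alpha = 1, beta = 1, gamma = 0),
                 Gamma = 0.25, grid = grid, model = "sa"),
            class = "tox_summary")
}

test_that("neighbourhood is the 3x3 block clipped to the grid, self included", {
  n11 <- neighbourhood(grid44, c(1, 1))
  expect_equal(nrow(n11), 4L)
  expect_true(all(paste(n11$a_idx, n11$b_idx) %in%
                    c("1 1", "1 2", "2 1", "2 2")))
  expect_equal(nrow(neighbourhood(grid44, c(2, 2))), 9L)
  n44 <- neighbourhood(grid44, c(4, 4))
  expect_setequal(paste(n44$a_idx, n44$b_idx), c("3 3", "3 4", "4 3", "4 4"))
  n24 <- neighbourhood(grid44, c(2, 4))
  expect_equal(nrow(n24), 6L)
  expect_error(neighbourhood(grid44, c(0, 1)), "not on the grid")
})

test_that("the candidate closest to the target is selected", {
  m <- matrix(0.9, 4, 4)
  m[1, 1] <- 0.10; m[1, 2] <- 0.24; m[2, 1] <- 0.30; m[2, 2] <- 0.40
  sel <- select_next(fake_summary(m), c(1, 1), design_config(), "sa")
  expect_equal(sel$next_combo, c(1L, 2L))
  expect_true(all(abs(sel$candidates$a_idx - 1) <= 1))
  expect_true(all(abs(sel$candidates$b_idx - 1) <= 1))
})

test_that("SA ties prefer the smallest dose of drug A, then of drug B", {
  m <- matrix(0.9, 4, 4)
  m[1, 1] <- 0.05; m[1, 2] <- 0.24; m[2, 1] <- 0.26; m[2, 2] <- 0.50
  sel <- select_next(fake_summary(m), c(1, 1), design_config(), "sa")
  expect_equal(sel$next_combo, c(1L, 2L))
  # equal smallest dose of drug A: fall back to the smallest dose of drug B
  m2 <- matrix(0.9, 4, 4)
  m2[2, 1] <- 0.24; m2[2, 3] <- 0.26; m2[2, 2] <- 0.05
  sel2 <- select_next(fake_summary(m2), c(2, 2), design_config(), "sa")
  expect_equal(sel2$next_combo, c(2L, 1L))
})

test_that("NA ties randomise inversely to patient counts", {
  m <- matrix(0.9, 4, 4)
  m[1, 2] <- 0.24; m[2, 1] <- 0.26
  counts <- matrix(0L, 4, 4); counts[1, 2] <- 4L; counts[2, 1] <- 2L
  set.seed(88)
  picks <- replicate(1e4, select_next(fake_summary(m), c(1, 1),
                                      design_config(), "na",
                                      counts)$next_combo[1])
  frac21 <- mean(picks == 2L)
  se <- sqrt(2 / 3 * 1 / 3 / 1e4)
  expect_lt(abs(frac21 - 2 / 3), 4 * se)
})

test_that("untried tied candidates are drawn uniformly among themselves", {
  m <- matrix(0.9, 4, 4)
  m[1, 2] <- 0.24; m[2, 1] <- 0.26; m[2, 2] <- 0.26
  counts <- matrix(0L, 4, 4); counts[1, 2] <- 10L  # (2,1), (2,2) untried
  set.seed(89)
  picks <- replicate(4e3, paste(select_next(fake_summary(m), c(1, 1),
                                            design_config(), "na",
                                            counts)$next_combo,
                                collapse = ","))
  expect_setequal(unique(picks), c("2,1", "2,2"))
  expect_lt(abs(mean(picks == "2,1") - 0.5), 0.03)
})

test_that("stopping uses a strict threshold at the lowest combination", {
  cfg <- design_config()
  expect_true(should_stop(fake_summary(matrix(0.5, 4, 4), exceed = 0.85), cfg))
  expect_false(should_stop(fake_summary(matrix(0.5, 4, 4), exceed = 0.80), cfg))
})

test_that("two DLTs in the first cohort trigger the stop rule", {
  for (model in c("na", "sa")) {
    y <- if (model == "na") c(2, 2) else c(1, 2)
    d <- patient_data(c(1, 1), c(1, 1), y)
    fit <- sample_posterior(d, grid44, prior_spec(), model,
                            mcmc_control(chains = 1, keep = 2000), seed = 17)
    expect_true(should_stop(posterior_summary(fit), design_config()))
  }
})

test_that("MTD set is experimented combos within the window", {
  m <- matrix(0.9, 4, 4)
  m[1, 1] <- 0.26   # tried, inside window
  m[1, 2] <- 0.25   # untried, inside window
  m[2, 1] <- 0.30   # tried, outside window
  counts <- matrix(0L, 4, 4); counts[1, 1] <- 6L; counts[2, 1] <- 2L
  mtd <- recommend_mtd(fake_summary(m), counts, design_config())
  expect_equal(nrow(mtd), 1L)
  expect_equal(c(mtd$a_idx, mtd$b_idx), c(1L, 1L))
  # all experimented medians outside the window -> empty set
  counts2 <- matrix(0L, 4, 4); counts2[2, 1] <- 6L
  expect_equal(nrow(recommend_mtd(fake_summary(m), counts2, design_config())), 0L)
})

test_that("design configuration is validated", {
  expect_error(design_config(max_patients = 61), "divisible")
  expect_error(design_config(Gamma = 1.2))
})

test_that("disabling the neighbourhood constraint searches the whole grid", {
  m <- matrix(0.9, 4, 4); m[4, 4] <- 0.25
  cfg <- design_config(neighbourhood = FALSE)
  sel <- select_next(fake_summary(m), c(1, 1), cfg, "sa")
  expect_equal(sel$next_combo, c(4L, 4L))
})
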