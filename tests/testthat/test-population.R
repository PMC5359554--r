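test_that("repair-time assignment is seeded, truncated and unbiased", {
  # degenerate sd collapses onto the means
  tight <- repair_time_distribution(sigma_fast_h = 1e-9, sigma_slow_h = 1e-9)
  taus <- assign_repair_times(10, tight, seed = 1)
  expect_equal(taus$tau1_h, rep(0.25, 10), tolerance = 1e-6)
  expect_equal(taus$tau2_h, rep(8, 10), tolerance = 1e-6)
  # same seed, same draws
  d <- repair_time_distribution()
  expect_identical(assign_repair_times(100, d, seed = 42),
                   assign_repair_times(100, d, seed = 42))
  # sample means agree with the truncated-normal mean oracle
  n <- 1e5
  big <- assign_repair_times(n, d, seed = 3)
  trunc_mean <- function(mu, sigma, floor) {
    a <- (floor - mu) / sigma
    mu + sigma * dnorm(a) / (1 - pnorm(a))
  }
  expect_lt(abs(mean(big$tau1_h) - trunc_mean(0.25, 0.1, 0.01)),
            3 * 0.1 / sqrt(n))
  expect_lt(abs(mean(big$tau2_h) - trunc_mean(8, 1, 0.01)), 3 * 1 / sqrt(n))
  expect_true(all(big$tau1_h >= 0.01))
  expect_error(repair_time_distribution(mu_fast_h = -1), "mu_fast_h")
})

test_that("an undamaged population survives with certainty", {
  states <- tibble::tibble(nucleus_id = 1:20, dose_gy = 0, L1_0 = 0, L2_0 = 0,
                           oxygen_pct = 21)
  res <- population_survival(states, params = tlk_params(), T_h = 4,
                             dt_h = 0.01, seed = 1)
  expect_equal(res$sf, 1)
  expect_equal(res$stderr, 0)
  expect_equal(res$mean_survival_prob, 1)
  expect_error(population_survival(states[0, ]), "empty")
})

test_that("Bernoulli survival reproduces the closed-form probability", {
  # one lesion, fully lethal linear channel: L_lethal(T) ~ 1, p ~ exp(-1)
  n <- 1e5
  states <- tibble::tibble(nucleus_id = seq_len(n), dose_gy = 1,
                           L1_0 = 1, L2_0 = 0, oxygen_pct = 21)
  p <- tlk_params(tau1_h = 0.25, beta1 = 1, beta2 = 0, eta_per_h = 0)
  res <- population_survival(states, params = p, T_h = 6, dt_h = 0.01,
                             seed = 17)
  expect_equal(res$mean_survival_prob, exp(-1), tolerance = 1e-6)
  expect_lt(abs(res$sf - exp(-1)), 3 * res$stderr)
})

test_that("the expectation is seed-invariant while the draw fluctuates", {
  states <- tibble::tibble(nucleus_id = 1:500, dose_gy = 1,
                           L1_0 = 30, L2_0 = 25, oxygen_pct = 21)
  taus <- assign_repair_times(500, seed = 2)
  a <- population_survival(states, taus, tlk_params(), T_h = 12, dt_h = 0.01,
                           seed = 1)
  b <- population_survival(states, taus, tlk_params(), T_h = 12, dt_h = 0.01,
                           seed = 2)
  expect_identical(a$mean_survival_prob, b$mean_survival_prob)
  expect_lt(abs(a$sf - b$sf), 8 * a$stderr)
  # identical seed, identical result
  a2 <- population_survival(states, taus, tlk_params(), T_h = 12, dt_h = 0.01,
                            seed = 1)
  expect_identical(a$sf, a2$sf)
})

test_that("replicate summaries behave like binomial sampling theory", {
  states <- tibble::tibble(nucleus_id = 1:400, dose_gy = 1,
                           L1_0 = 25, L2_0 = 20, oxygen_pct = 21)
  taus <- assign_repair_times(400, seed = 5)
  reps <- replicate_runs(3, states, taus, tlk_params(), T_h = 12, dt_h = 0.01,
                         seeds = c(11, 12, 13))
  expect_equal(nrow(reps$replicates), 3)
  # replicate scatter is on the order of the binomial standard error
  expect_lt(reps$sd_sf, 10 * reps$replicates$stderr[1])
  # both of two disjoint-seed replicates near the expectation
  two <- replicate_runs(2, states, taus, tlk_params(), T_h = 12, dt_h = 0.01,
                        seeds = c(21, 22))
  expect_true(all(abs(two$replicates$sf - two$mean_survival_prob) <
                    4 * two$replicates$stderr))
  # degenerate replicates with identical seeds
  same <- replicate_runs(3, states, taus, tlk_params(), T_h = 12, dt_h = 0.01,
                         seeds = c(7, 7, 7))
  expect_equal(same$sd_sf, 0)
  expect_error(replicate_runs(3, states, taus, seeds = 1:2), "seeds")
  expect_error(replicate_runs(1, states, taus, seeds = 1:3), "replicates")
})

test_that("survival results serialise and tidy into the documented shapes", {
  states <- tibble::tibble(nucleus_id = 1:10, dose_gy = 1,
                           L1_0 = 10, L2_0 = 10, oxygen_pct = 21)
  res <- population_survival(states, params = tlk_params(), T_h = 4,
                             dt_h = 0.01, seed = 1)
  cells <- tidy(res)
  expect_named(cells, c("nucleus_id", "dose_gy", "L1_0", "L2_0", "tau1_h",
                        "tau2_h", "L_lethal_T", "p", "survived"))
  g <- glance(res)
  expect_equal(g$sf, res$sf)
  json <- withr::local_tempfile(fileext = ".json")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_survival_result(res, json, csv)
  back <- jsonlite::read_json(json)
  expect_equal(back$sf, res$sf)
  expect_equal(nrow(readr::read_csv(csv, show_col_types = FALSE)), 10)
})
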