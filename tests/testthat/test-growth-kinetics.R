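# Interval rates, the best-window fitness estimator, transfer accounting
# and redox slopes.

test_that("interval rates reproduce closed forms and scale invariance", {
  t <- seq(0, 10, by = 0.5)
  cv <- growth_curve(t, 0.01 * exp(0.5 * t))
  r <- interval_rates(cv)
  expect_equal(r$rate, rep(0.5, length(t) - 1))

  flat <- growth_curve(t, rep(0.2, length(t)))
  expect_equal(interval_rates(flat)$rate, rep(0, length(t) - 1))

  # a transfer-style two-point curve
  two <- growth_curve(c(0, 12), c(0.01, 0.08))
  expect_equal(interval_rates(two)$rate, log(8) / 12)

  # scaling all ODs leaves rates unchanged
  cvs <- growth_curve(t, 5 * (0.01 * exp(0.5 * t)))
  expect_equal(interval_rates(cvs)$rate, r$rate)

  # sub-floor reads are excluded and counted
  od <- c(0.001, 0.002, 0.01, 0.02, 0.04)
  rf <- interval_rates(growth_curve(1:5, od), od_floor = 0.003)
  expect_equal(rf$interval, 3:4)
  expect_equal(attr(rf, "n_excluded"), 2)
  expect_error(interval_rates(growth_curve(1:2, c(0.001, 0.002))),
               "insufficient")
})

test_that("window selection picks the five-rate run with the best mean", {
  est <- max_growth_rate(c(0, 0, 1, 1, 1, 1, 1, 0, 0), window = 5)
  expect_equal(est$mu_max, 1.0)
  expect_equal(est$window_start_index, 3)
  expect_equal(est$n_rates_in_window, 5)
  expect_equal(est$window_sd, 0)

  expect_error(max_growth_rate(c(1, 2, 3), window = 5), "insufficient")

  # windows never straddle excluded intervals
  ser <- data.frame(interval = c(1:5, 8:12), t_mid = NA,
                    rate = c(rep(10, 5), rep(1, 5)))
  est2 <- max_growth_rate(ser, window = 5)
  expect_equal(est2$mu_max, 10)
})

test_that("window selection matches exhaustive enumeration on random series", {
  set.seed(202)
  for (i in 1:200) {
    n <- sample(6:40, 1)
    rates <- stats::rnorm(n, mean = stats::runif(1, -0.1, 0.8), sd = 0.2)
    got <- max_growth_rate(rates, window = 5)
    want <- oracle_best_window(rates, 5)
    expect_equal(got$mu_max, want$mean, tolerance = 1e-12)
    expect_equal(got$window_start_index, want$start)
  }
})

test_that("adding a constant to all rates shifts mu_max by that constant", {
  set.seed(7)
  for (i in 1:25) {
    rates <- stats::rnorm(20, 0.3, 0.1)
    delta <- stats::runif(1, 0.01, 1)
    base <- max_growth_rate(rates)$mu_max
    shifted <- max_growth_rate(rates + delta)$mu_max
    expect_equal(shifted, base + delta, tolerance = 1e-10)
  }
})

test_that("generation and transfer-rate accounting is consistent", {
  expect_equal(generations(0.05, 0.05), 0)
  expect_equal(generations(10^4, 1), 13.2877, tolerance = 1e-4)
  expect_equal(transfer_rate(exp(1) * 0.01, 0.01, 1, 0), 1.0)
  expect_equal(transfer_rate(0.08, 0.01, 12, 0), log(8) / 12)
  expect_error(generations(-1, 1), "positive")
  expect_error(transfer_rate(1, 1, 0, 0), "exceed")

  # gen = mu * dt / ln(2) exactly, and Eq.2 equals Eq.3 on two points
  set.seed(3)
  for (i in 1:20) {
    ci <- stats::runif(1, 0.01, 0.2)
    cj <- stats::runif(1, 0.001, 0.01)
    dt <- stats::runif(1, 1, 24)
    expect_equal(generations(ci, cj),
                 transfer_rate(ci, cj, dt, 0) * dt / log(2))
    expect_equal(transfer_rate(ci, cj, dt, 0),
                 interval_rates(growth_curve(c(0, dt), c(cj, ci)),
                                od_floor = 1e-6)$rate)
  }

  # additivity over a chain of transfers
  set.seed(9)
  ratios <- stats::runif(50, 1, 30)
  ods <- 0.05 * cumprod(ratios)
  total <- sum(generations(ods, c(0.05, ods[-50])))
  expect_equal(total, log2(prod(ratios)), tolerance = 1e-8)
})

test_that("replicate aggregation gives mean and standard error", {
  expect_equal(mean_fitness(c(0.4, 0.6)), list(mean = 0.5, se = 0.1, n = 2))
  same <- mean_fitness(rep(0.37, 6))
  expect_equal(same$se, 0)
  expect_error(mean_fitness(numeric(0)), "insufficient")
  set.seed(15)
  x <- stats::rnorm(8, 0.5, 0.05)
  mf <- mean_fitness(x)
  expect_equal(mf$se, sqrt(sum((x - sum(x) / 8)^2) / 7) / sqrt(8))
})

test_that("redox activity equals the OLS slope divided by OD600", {
  t <- seq(0, 30, by = 2)
  expect_equal(redox_activity(0.1 + 0.002 * t, t, 0.05)$activity, 0.04)
  expect_equal(redox_activity(rep(0.3, length(t)), t, 0.1)$activity, 0)
  expect_error(redox_activity(1:5, rep(1, 5), 0.1), "distinct")

  # normal-equation oracle on noisy lines
  set.seed(21)
  for (i in 1:50) {
    y <- 0.05 + 0.003 * t + stats::rnorm(length(t), 0, 0.004)
    got <- redox_activity(y, t, 0.08)$per_series
    tc <- t - mean(t)
    slope <- sum(tc * (y - mean(y))) / sum(tc^2)
    expect_equal(unname(got), slope / 0.08, tolerance = 1e-10)
  }
})

test_that("fitness tables aggregate a curve collection by design cell", {
  d <- build_design_matrix()
  ls <- fitness_landscape(d, genomes = data.frame(genome = "N0",
                                                  deletion_kb = 0))
  cu <- simulate_study(d, ls, replicates = 3, seed = 8,
                       populations = "Anc")
  reps <- fitness_replicates(cu)
  expect_equal(nrow(reps), 29 * 3)
  tab <- fitness_table(reps)
  expect_equal(nrow(tab), 29)
  expect_true(all(tab$n == 3))
  # aggregation agrees with mean_fitness on one cell
  cell <- reps[reps$combination_id == "C0", ]
  expect_equal(tab$mu_mean[tab$combination_id == "C0"],
               mean(cell$mu))
})
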