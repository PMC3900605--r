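test_that("noiseless adsorption data recover k to machine precision", {
  k <- 5e-9; B <- 3e8
  s <- simulate_titer_series("adsorption",
                             params = list(k = k, cell_density = B, cv = 0),
                             design = list(times = 0:10, replicates = 3))
  fit <- adsorption_rate(s, host_density = B)
  # the estimator uses the 2.303/log10 form of the exponential solution
  expect_equal(fit$k, k, tolerance = 1e-4)
  expect_equal(nrow(fit$per_replicate), 3)
  expect_equal(fit$window_end, 10)
})

test_that("the decay window stops where the titre stalls", {
  # decay for 5 min, then a flat background plateau
  times <- 0:10
  pfu <- c(1e6 * exp(-0.3 * 0:5), rep(1e6 * exp(-0.3 * 5) * 1.01, 5))
  s <- tibble::tibble(time_min = times, replicate = 1, pfu_per_ml = pfu)
  fit <- adsorption_rate(s, host_density = 3e8)
  expect_equal(fit$window_end, 5)
  expect_true(all(fit$per_timepoint$time_min <= 5))
  expect_equal(fit$k, 0.3 / 3e8, tolerance = 1e-4)
})

test_that("non-decaying series raise the documented error", {
  s <- tibble::tibble(time_min = 0:5, replicate = 1,
                      pfu_per_ml = seq(1e6, 2e6, length.out = 6))
  expect_error(adsorption_rate(s, host_density = 3e8), "no adsorption")
  s0 <- tibble::tibble(time_min = 1:5, replicate = 1, pfu_per_ml = 10^(6:2))
  expect_error(adsorption_rate(s0, host_density = 3e8), "time-zero")
})

test_that("noisy adsorption estimates are unbiased near the truth", {
  k <- 6.44e-9; B <- 3e8
  ks <- vapply(1:40, function(seed) {
    s <- simulate_titer_series("adsorption",
                               params = list(k = k, cell_density = B,
                                             cv = 0.1),
                               seed = seed)
    adsorption_rate(s, host_density = B)$k
  }, numeric(1))
  expect_equal(median(ks), k, tolerance = 0.1)
})

test_that("noiseless one-step data give exact latent, eclipse and burst", {
  s <- simulate_titer_series("one_step",
                             params = list(burst = 153, latent_min = 35,
                                           eclipse_min = 25, cv = 0),
                             design = list(times = seq(0, 80, 10),
                                           replicates = 2))
  fit <- one_step_analysis(s)
  # the curve first exceeds 3x baseline at the first sample after onset
  expect_equal(fit$latent_min, 40)
  expect_equal(fit$eclipse_min, 30)
  expect_equal(fit$burst_size, 153, tolerance = 1e-12)
  expect_false(fit$censored)
})

test_that("a finer sampling grid pins the latent period to the truth", {
  s <- simulate_titer_series("one_step",
                             params = list(burst = 100, latent_min = 35,
                                           eclipse_min = 25, cv = 0),
                             design = list(times = seq(0, 80, 5),
                                           replicates = 1))
  fit <- one_step_analysis(s)
  expect_equal(fit$latent_min, 35)
  expect_equal(fit$eclipse_min, 25)
})

test_that("burst recovery works under 10% noise", {
  s <- simulate_titer_series("one_step", params = list(burst = 153),
                             seed = 42)
  fit <- one_step_analysis(s)
  expect_equal(fit$burst_size, 153, tolerance = 0.15)
})

test_that("eclipse can never exceed latent", {
  # chloroform series rising later than the total series is clamped
  untreated <- tidyr::expand_grid(time_min = seq(0, 60, 10), replicate = 1) |>
    dplyr::mutate(pfu_per_ml = ifelse(time_min >= 30, 1e7, 1e5))
  treated <- dplyr::mutate(
    untreated, pfu_per_ml = ifelse(time_min >= 50, 1e7, 1e5))
  fit <- one_step_analysis(untreated, treated = treated)
  expect_lte(fit$eclipse_min, fit$latent_min)
})

test_that("a still-rising curve is flagged censored", {
  s <- tibble::tibble(time_min = seq(0, 50, 10), replicate = 1,
                      pfu_per_ml = c(1e5, 1e5, 1e5, 4e5, 1.6e6, 6.4e6))
  fit <- one_step_analysis(s)
  expect_true(fit$censored)
})

test_that("a curve with no rise errors", {
  s <- tibble::tibble(time_min = seq(0, 50, 10), replicate = 1,
                      pfu_per_ml = rep(1e5, 6))
  expect_error(one_step_analysis(s), "no rise")
})

test_that("lognormal noise is unbiased on the mean", {
  mu <- 1e6
  vals <- withr::with_seed(1, phagephylo:::lognoise(rep(mu, 20000), 0.2))
  expect_equal(mean(vals), mu, tolerance = 0.01)
  expect_equal(stats::sd(vals) / mean(vals), 0.2, tolerance = 0.05)
})

test_that("titer simulation is seed-deterministic and validated", {
  a <- simulate_titer_series("adsorption", seed = 1)
  b <- simulate_titer_series("adsorption", seed = 1)
  expect_identical(a$pfu_per_ml, b$pfu_per_ml)
  expect_error(simulate_titer_series("adsorption", params = list(k = -1)),
               "positive")
  expect_error(simulate_titer_series("one_step",
                                     params = list(eclipse_min = 50,
                                                   latent_min = 35)),
               "eclipse")
})

test_that("the one-step series carries both treatments", {
  s <- simulate_titer_series("one_step", seed = 2)
  expect_setequal(unique(s$treatment), c("total", "chloroform"))
  expect_s3_class(s, "titer_series")
})
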