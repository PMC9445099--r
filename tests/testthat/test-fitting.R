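test_that("noiseless feedback pairs are recovered exactly", {
  w <- c(5, 15, 30, 45, 55)
  pairs <- tibble::tibble(width = w, growth_rate = 1.0 * (1 - w / 60))
  fit <- fit_proliferation_feedback(pairs)
  expect_equal(fit$kd0, 1.0, tolerance = 1e-12)
  expect_equal(fit$w0, 60, tolerance = 1e-12)
  expect_true(fit$w0_valid)
  expect_equal(fit$r2, 1)
  # broom-style accessors
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "w0"], 60)
  expect_equal(glance(fit)$nobs, 5L)
})

test_that("two pairs give the exact interpolating line", {
  fit <- fit_proliferation_feedback(
    tibble::tibble(width = c(10, 50), growth_rate = c(1.2, 0.4)))
  expect_equal(fit$slope, -0.02)
  expect_equal(fit$kd0, 1.4)
})

test_that("degenerate or inverted designs are flagged", {
  expect_error(fit_proliferation_feedback(
    tibble::tibble(width = c(10, 10, 10), growth_rate = c(1, 2, 3))),
    "degenerate")
  up <- fit_proliferation_feedback(
    tibble::tibble(width = c(10, 30, 50), growth_rate = c(0.1, 0.5, 0.9)))
  expect_false(up$w0_valid)
  expect_true(is.na(up$w0))
})

test_that("bootstrap intervals cover the generating parameters", {
  set.seed(99)
  w <- runif(85, 10, 55)
  pairs <- tibble::tibble(
    width = w,
    growth_rate = 1.5 * (1 - w / 60) * exp(rnorm(85, 0, 0.1))
  )
  fit <- fit_proliferation_feedback(pairs, bootstrap = 500, seed = 7)
  expect_true(fit$ci_kd0[1] < 1.5 && 1.5 < fit$ci_kd0[2])
  expect_true(fit$ci_w0[1] < 60 && 60 < fit$ci_w0[2])
})

test_that("exact exponential counts return the generating rate", {
  fit <- fit_branching_rate(
    tibble::tibble(time = 0:9, count = exp(0.55 * (0:9))))
  expect_equal(fit$rate, 0.55, tolerance = 1e-12)
  expect_equal(fit$rate_fixed_intercept, 0.55, tolerance = 1e-12)
  flat <- fit_branching_rate(tibble::tibble(time = 0:5, count = rep(4, 6)))
  expect_equal(flat$rate, 0, tolerance = 1e-12)
})

test_that("non-positive counts are rejected with the offending row", {
  expect_error(
    fit_branching_rate(tibble::tibble(time = 0:3, count = c(1, 2, 0, 4))),
    "row\\(s\\): 3")
  expect_error(
    fit_branching_rate(tibble::tibble(time = 0:1, count = c(1, 2))),
    "at least 3")
})

test_that("tip-speed regression recovers exact and stationary tracks", {
  one <- tibble::tibble(track_id = 1, time = 0:2, position = c(0, 80, 160))
  fit <- fit_tip_speed(one)
  expect_equal(fit$v0_hat, 80)
  expect_equal(fit$n_tracks, 1)
  still <- tibble::tibble(track_id = 1, time = 0:3, position = rep(5, 4))
  expect_equal(fit_tip_speed(still)$v0_hat, 0)
  short <- dplyr::bind_rows(one,
    tibble::tibble(track_id = 2, time = 0:1, position = c(0, 10)))
  expect_warning(fit2 <- fit_tip_speed(short), "skipped")
  expect_equal(fit2$n_tracks, 1)
  expect_error(suppressWarnings(fit_tip_speed(
    tibble::tibble(track_id = 1, time = 0:1, position = 0:1))), "3 samples")
})

test_that("simulated tip path lengths regress to v0 despite heading noise", {
  cfg <- sim_config(duration = 9, seed = 250, dtheta = 0.5)
  sim <- simulate_organoid(cfg, track_times = seq(7, 9, 0.1),
                           record_nodes = FALSE)
  counts <- table(sim$tip_tracks$branch_id)
  keep <- names(counts)[counts >= 3]
  expect_gte(length(keep), 20)
  fit <- suppressWarnings(fit_tip_speed(sim$tip_tracks))
  expect_equal(fit$v0_hat, 80, tolerance = 0.01)
})

test_that("cell-count comparison scores rmse and coverage", {
  p <- growth_params()
  traj <- integrate_meanfield(p, t_end = 9, dt = 0.1)
  obs_t <- 1:9
  pred <- approx(traj$t, traj$Nc, xout = obs_t)$y
  exact <- tibble::tibble(time = obs_t, mean_nc = pred, sd_nc = pred * 0.2)
  res <- compare_cellcount_prediction(traj, exact)
  expect_equal(res$rmse_log, 0, tolerance = 1e-12)
  expect_equal(res$coverage, 1)
  # prediction exactly one sd above the mean still counts as covered
  shifted <- tibble::tibble(time = obs_t, mean_nc = pred / 1.2,
                            sd_nc = 0.2 * pred / 1.2)
  res2 <- compare_cellcount_prediction(traj, shifted)
  expect_equal(res2$coverage, 1)
  expect_error(compare_cellcount_prediction(
    traj, tibble::tibble(time = 100, mean_nc = 1, sd_nc = 1)), "overlap")
})

test_that("mean-field predictions cover noisy observations of themselves", {
  p <- growth_params()
  traj <- integrate_meanfield(p, t_end = 9, dt = 0.1)
  set.seed(123)
  obs_t <- 1:9
  pred <- approx(traj$t, traj$Nc, xout = obs_t)$y
  n_org <- 55
  draws <- purrr::map(obs_t, ~ pred[.x] * exp(rnorm(n_org, 0, 0.15)))
  obs <- tibble::tibble(
    time = obs_t,
    mean_nc = purrr::map_dbl(draws, mean),
    sd_nc = purrr::map_dbl(draws, sd)
  )
  res <- compare_cellcount_prediction(traj, obs)
  expect_gte(res$coverage, 0.8)
})

test_that("estimators converge to truth as noise shrinks and n grows", {
  set.seed(2024)
  spread <- function(n, cv) {
    reps <- purrr::map_dbl(1:20, function(r) {
      w <- runif(n, 10, 55)
      pairs <- tibble::tibble(
        width = w,
        growth_rate = 1.5 * (1 - w / 60) * exp(rnorm(n, 0, cv)))
      fit_proliferation_feedback(pairs)$kd0
    })
    sd(reps)
  }
  s_small <- spread(200, 0.02)
  s_mid <- spread(85, 0.1)
  s_large_noise <- spread(85, 0.3)
  expect_lt(s_small, s_mid)
  expect_lt(s_mid, s_large_noise)
})
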