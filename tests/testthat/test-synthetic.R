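test_that("datasets are byte-identical under the same seed", {
  small <- function() generate_morphometric_dataset(
    n_organoids = 2, t_grid = 0:4, pair_window = c(3, 4),
    track_window = c(3, 4), noise = observation_noise(seed = 5))
  a <- small(); b <- small()
  expect_identical(a$growth_pairs, b$growth_pairs)
  expect_identical(a$tip_tracks, b$tip_tracks)
  d1 <- tempfile(); d2 <- tempfile()
  write_dataset(a, d1); write_dataset(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("an explicit seed is mandatory", {
  expect_error(observation_noise(seed = NULL), "seed")
  expect_error(observation_noise(seed = NA), "seed")
  expect_error(sim_config(seed = NULL), "seed")
})

test_that("lognormal measurement noise is unbiased", {
  set.seed(1)
  n <- 1e4
  fac <- orgbranch:::lognormal_factor(n, 0.2)
  se <- sd(fac) / sqrt(n)
  expect_lt(abs(mean(fac) - 1), 3 * se)
  expect_equal(sd(fac), 0.2, tolerance = 0.05)
  expect_identical(orgbranch:::lognormal_factor(5, 0), rep(1, 5))
})

test_that("near-noiseless datasets recover the generating parameters", {
  ds <- generate_morphometric_dataset(
    n_organoids = 8,
    noise = observation_noise(width_cv = 0, growth_rate_cv = 0,
                              count_cv = 0, track_jitter_sd = 0,
                              seed = 31),
    pair_dt = 0.02
  )
  fit <- suppressWarnings(fit_growth_parameters(ds))
  err <- fit$estimates$rel_error
  names(err) <- fit$estimates$term
  expect_lt(abs(err[["v0"]]), 1e-6)    # path length advances at exactly v0
  expect_lt(abs(err[["kb"]]), 0.1)     # Yule sampling noise, 8 organoids
  expect_lt(abs(err[["kd0"]]), 0.03)   # finite-interval rate bias ~kd^2 dt/2
  expect_lt(abs(err[["w0"]]), 0.02)
})

test_that("full-loop recovery succeeds at the study's noise level", {
  # one seeded repeat of the n = 60, CV 10% recovery; the acceptance
  # suite runs the 100-repeat version
  ds <- generate_morphometric_dataset(
    n_organoids = 60, noise = observation_noise(seed = 202))
  fit <- suppressWarnings(fit_growth_parameters(ds))
  expect_true(all(abs(fit$estimates$rel_error) < 0.1))
})

test_that("parameter spread shrinks with the number of organoids", {
  spread_kb <- purrr::map_dbl(c(5, 15, 45), function(n) {
    reps <- purrr::map_dbl(1:6, function(r) {
      ds <- generate_morphometric_dataset(
        n_organoids = n, t_grid = 0:6, pair_window = c(5, 6),
        track_window = c(5, 6),
        noise = observation_noise(seed = 4000 + 97 * r + n))
      counts <- ds$branch_counts |>
        dplyr::group_by(time) |>
        dplyr::summarise(count = mean(n_terminal), .groups = "drop")
      fit_branching_rate(counts)$rate
    })
    sd(reps)
  })
  expect_lt(spread_kb[3], spread_kb[1])
})

test_that("the worked fixture is deterministic and demands a seed", {
  f1 <- generate_worked_fixture()
  f2 <- generate_worked_fixture()
  expect_identical(f1$growth_pairs, f2$growth_pairs)
  expect_equal(f1$n_organoids, 3)
  expect_error(generate_worked_fixture(seed = NULL), "seed")
})

test_that("the worked fixture reproduces its committed fit report", {
  ds <- generate_worked_fixture()
  fit <- suppressWarnings(fit_growth_parameters(ds, bootstrap = 200,
                                                seed = 42))
  path <- tempfile(fileext = ".json")
  save_fit_report(fit, path, seed = 42)
  ref <- system.file("extdata", "worked_fixture_report.json",
                     package = "orgbranch")
  expect_identical(readLines(path), readLines(ref))
})

test_that("dataset round-trips through its CSV directory", {
  ds <- generate_morphometric_dataset(
    n_organoids = 2, t_grid = 0:3, pair_window = c(2, 3),
    track_window = c(2, 3), noise = observation_noise(seed = 9))
  dir <- tempfile()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(back$truth$kb, ds$truth$kb)
  expect_equal(nrow(back$growth_pairs), nrow(ds$growth_pairs))
  expect_equal(back$growth_pairs$width, ds$growth_pairs$width,
               tolerance = 1e-9)
  file.remove(file.path(dir, "branch_counts.csv"))
  expect_error(read_dataset(dir), "missing table")
})
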