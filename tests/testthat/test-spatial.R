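test_that("deterministic elongation without branching or growth", {
  p <- suppressWarnings(growth_params(v0 = 80, kb = 0, kd0 = 0))
  cfg <- sim_config(params = p, duration = 5, seed = 9)
  sim <- simulate_organoid(cfg)
  tree <- sim$trees[[1]]
  expect_equal(nrow(tree), 1)
  expect_true(tree$terminal[1])
  expect_equal(tree$length[1], p$l_init + 400, tolerance = 1e-9)
  # path length equals arc length of the recorded polyline (within the
  # chord shortening of angular diffusion at the node spacing)
  nd <- tree$nodes[[1]]
  arc <- sum(sqrt(rowSums((nd[-1, , drop = FALSE] -
                             nd[-nrow(nd), , drop = FALSE])^2)))
  expect_equal(arc, tree$length[1], tolerance = 5e-3)
})

test_that("identical seeds give bit-identical simulations", {
  cfg <- quick_cfg(duration = 4, seed = 77)
  a <- simulate_organoid(cfg)
  b <- simulate_organoid(cfg)
  expect_identical(a$branch_samples, b$branch_samples)
  expect_identical(a$events, b$events)
  expect_identical(a$trees[[1]]$nodes, b$trees[[1]]$nodes)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  save_tree(a$trees[[1]], f1); save_tree(b$trees[[1]], f2)
  expect_identical(readLines(f1), readLines(f2))
  # and a different seed gives a different realisation
  cfg2 <- quick_cfg(duration = 4, seed = 78)
  expect_false(identical(simulate_organoid(cfg2)$branch_samples,
                         a$branch_samples))
})

test_that("volume bookkeeping follows the division rate between events", {
  p <- growth_params(kb = 0)  # no branching: a single growing branch
  cfg <- sim_config(params = p, duration = 3, seed = 5)
  sim <- simulate_organoid(cfg, sample_times = seq(0, 3, 0.01),
                           record_nodes = FALSE)
  s <- sim$branch_samples
  dlogv <- diff(log(s$volume))
  kd <- division_rate(s$width, p)[-nrow(s)]
  expect_equal(dlogv / 0.01, kd, tolerance = 0.02)
  # volume stays consistent with the cylindrical closure
  expect_equal(s$volume, (pi / 4) * s$width^2 * s$length,
               tolerance = 1e-6)
})

test_that("tip counts reproduce Yule statistics when feedback is off", {
  p <- growth_params(w0 = Inf, w_min = 0)
  cfg <- sim_config(params = p, duration = 2, seed = 400)
  ens <- simulate_ensemble(cfg, 300, sample_times = c(0, 2))
  st <- branch_count_statistics(ens, c(0, 2))
  expect_equal(st$mean_nb[1], 1)
  expect_equal(st$sd_nb[1], 0)
  m <- exp(0.55 * 2)
  se_mean <- sqrt(m * (m - 1)) / sqrt(300)
  expect_lt(abs(st$mean_nb[2] - m), 3 * se_mean)
  # sd of the same order as the mean (stochastic branching signature)
  expect_gt(st$sd_nb[2] / st$mean_nb[2], 0.5)
})

test_that("division-coupled branching precedes every branching event", {
  cfg <- quick_cfg(duration = 6, seed = 31)
  sim <- simulate_organoid(cfg, record_nodes = FALSE)
  prec <- division_precedence(sim$events)
  expect_gte(prec$fraction, 0.9)
  expect_equal(prec$n_events, nrow(sim$events))
  cls <- classify_branching_events(sim$events, sim$divisions)
  expect_equal(cls$true_yes + cls$true_no, nrow(sim$events))
  expect_gt(cls$false_yes, 0)  # most divisions do not trigger branching
})

test_that("trees stay single-rooted with consistent terminal flags", {
  cfg <- quick_cfg(duration = 6, seed = 13)
  sim <- simulate_organoid(cfg)
  tree <- sim$trees[[1]]
  expect_silent(validate_organoid_tree(tree))
  expect_equal(sum(is.na(tree$parent_id)), 1)
  # binary branching: terminal = non-terminal + 1
  expect_equal(sum(tree$terminal), sum(!tree$terminal) + 1)
  # every branch with children is non-terminal
  expect_true(all(!tree$terminal[tree$id %in% tree$parent_id]))
})

test_that("an empty schedule is a no-op", {
  cfg <- quick_cfg(duration = 3, seed = 21)
  a <- simulate_organoid(cfg, record_nodes = FALSE)
  b <- simulate_organoid(cfg, schedule = perturbation_schedule(),
                         record_nodes = FALSE)
  expect_identical(a$branch_samples, b$branch_samples)
})

test_that("schedules validate override names and event times", {
  expect_error(perturbation_schedule(1, list(list(vmax = 3))), "unknown")
  expect_error(perturbation_schedule(c(3, 1), list(list(), list())),
               "non-decreasing")
  cfg <- quick_cfg(duration = 3, seed = 1)
  expect_error(
    simulate_organoid(cfg, schedule = perturbation_schedule(
      5, list(list(v0 = 0)))),
    "within"
  )
  expect_error(perturbation_preset("nocodazole", at = 1),
               "'arg' should be one")
})

test_that("batimastat preset thickens branches once invasion stops", {
  p <- growth_params()
  cfg <- sim_config(params = p, duration = 12, seed = 61)
  sched <- perturbation_preset("batimastat", at = 8, params = p)
  expect_equal(sched$overrides[[1]]$v0, 0)
  expect_equal(sched$overrides[[1]]$kd0, 0.23 * p$kd0)
  sim <- simulate_organoid(cfg, schedule = sched, record_nodes = FALSE,
                           sample_times = seq(8, 12, 0.5))
  w <- width_by_class(sim$branch_samples)
  wt <- w[w$class == "terminal", ]
  expect_true(all(diff(wt$mean_width) >= -1e-9))
  expect_gt(wt$mean_width[nrow(wt)], wt$mean_width[1])
  expect_lte(max(sim$branch_samples$width), p$w0 * (1 + 1e-6))
})

test_that("aphidicolin preset thins every elongating branch", {
  p <- growth_params(w_min = 5)
  cfg <- sim_config(params = p, duration = 9, seed = 62)
  sched <- perturbation_preset("aphidicolin", at = 5, params = p)
  sim <- simulate_organoid(cfg, schedule = sched, record_nodes = FALSE,
                           sample_times = seq(5, 9, 0.5))
  bs <- sim$branch_samples[sim$branch_samples$terminal &
                             !sim$branch_samples$broken, ]
  bs <- bs[order(bs$branch_id, bs$time), ]
  same <- bs$branch_id[-1] == bs$branch_id[-nrow(bs)]
  expect_true(all(diff(bs$width)[same] <= 1e-9))
})

test_that("ensemble means track the mean-field model", {
  # Nb matches directly; total length matches once the documented l_init
  # seeding of daughters (2 * l_init per branching event) is added to the
  # bare elongation equation; cell number is only loosely captured by the
  # single-width mean-field closure (see the methods vignette) and is
  # checked as an order-of-magnitude bound.
  p <- growth_params()
  cfg <- quick_cfg(duration = 8, seed = 700)
  ens <- simulate_ensemble(cfg, 500, sample_times = c(2, 4, 6, 8))
  traj <- integrate_meanfield(p, t_end = 8, dt = 0.1)
  for (tt in c(2, 4, 6, 8)) {
    sub <- ens$summary[ens$summary$time == tt, ]
    mf <- traj[which.min(abs(traj$t - tt)), ]
    expect_equal(mean(sub$n_terminal), mf$Nb, tolerance = 0.1,
                 label = sprintf("Nb(t=%g)", tt))
    ltot_seeded <- mf$Ltot + 2 * p$l_init * (mf$Nb - 1)
    expect_equal(mean(sub$total_length), ltot_seeded, tolerance = 0.1,
                 label = sprintf("Ltot(t=%g)", tt))
    ratio <- mean(sub$n_cells) / mf$Nc
    expect_gt(ratio, 0.3)
    expect_lt(ratio, 2.6)
  }
})

test_that("branch count statistics validate their inputs", {
  expect_error(branch_count_statistics(list(summary = NULL), 1), "no summary")
  cfg <- quick_cfg(duration = 1, seed = 2)
  ens <- simulate_ensemble(cfg, 3, sample_times = c(0, 1))
  expect_error(branch_count_statistics(ens, 0.37), "no ensemble records")
  st <- branch_count_statistics(ens, c(0, 1))
  expect_equal(st$n, c(3, 3))
})
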