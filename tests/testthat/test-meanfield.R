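test_that("zero-rate growth reduces to linear elongation", {
  p <- suppressWarnings(growth_params(v0 = 80, kb = 0, kd0 = 0))
  init <- meanfield_init(p, Ltot = 10)
  traj <- integrate_meanfield(p, init, t_end = 5)
  expect_equal(tail(traj$Ltot, 1), 410, tolerance = 1e-8)
  expect_equal(tail(traj$Nc, 1), 1, tolerance = 1e-10)
})

test_that("total length matches the closed-form antiderivative", {
  # dLtot/dt = v0 exp(kb t)  =>  Ltot(T) - L0 = (v0/kb)(exp(kb T) - 1)
  p <- growth_params(v0 = 80, kb = 0.55, kd0 = 1.5)
  traj <- integrate_meanfield(p, t_end = 5)
  gain <- tail(traj$Ltot, 1) - traj$Ltot[1]
  expect_equal(gain, (80 / 0.55) * (exp(0.55 * 5) - 1), tolerance = 1e-3)
})

test_that("width converges to the plateau fixed point", {
  p <- growth_params(kd0 = 1.5, kb = 0.55, w0 = 60)
  traj <- integrate_meanfield(p, t_end = 30)
  expect_equal(tail(traj$w, 1), 38, tolerance = 0.02)
})

test_that("plateau is reached within 2% across a rate grid", {
  for (kd0 in c(0.8, 1.5, 2.5)) {
    for (kb in c(0.1, 0.3, 0.55)) {
      p <- growth_params(kd0 = kd0, kb = kb, w0 = 60)
      t_end <- max(30, 3 * 20 / kd0)
      traj <- integrate_meanfield(p, t_end = t_end, dt = 0.05)
      expect_equal(tail(traj$w, 1), plateau_width(p), tolerance = 0.02,
                   label = sprintf("w(kd0=%g, kb=%g)", kd0, kb))
      # monotone approach after the last extremum
      w <- traj$w
      ext <- which(diff(sign(diff(w))) != 0)
      tail_w <- if (length(ext) > 0) w[(max(ext) + 1):length(w)] else w
      gap <- abs(tail_w - plateau_width(p))
      expect_true(all(diff(gap) <= 1e-8))
    }
  }
})

test_that("width closure is conserved along the trajectory", {
  p <- growth_params()
  traj <- integrate_meanfield(p, t_end = 10)
  resid <- abs(traj$Nc * p$v_cell - (pi / 4) * traj$w^2 * traj$Ltot) /
    (traj$Nc * p$v_cell)
  expect_lt(max(resid), 1e-9)
})

test_that("cell number and length are non-decreasing", {
  traj <- integrate_meanfield(growth_params(), t_end = 15)
  expect_true(all(diff(traj$Nc) >= -1e-9))
  expect_true(all(diff(traj$Ltot) >= -1e-9))
  expect_equal(traj$Nb, exp(growth_params()$kb * traj$t))
})

test_that("halving the reporting grid leaves states unchanged", {
  p <- growth_params()
  a <- integrate_meanfield(p, t_end = 8, dt = 0.02)
  b <- integrate_meanfield(p, t_end = 8, dt = 0.01)
  common <- b[match(a$t, b$t), ]
  expect_equal(a$Nc, common$Nc, tolerance = 1e-6)
  expect_equal(a$Ltot, common$Ltot, tolerance = 1e-6)
})

test_that("plateau value is independent of the closure geometry", {
  # sheet closure: Nc v_cell = w * Ltot * h  (linear in w); the feedback
  # zero kd(w*) = kb does not move
  p <- growth_params(kd0 = 1.5, kb = 0.55, w0 = 60)
  h <- 10
  sheet <- function(Nc, Ltot) Nc * p$v_cell / (h * Ltot)
  init <- meanfield_init(p)
  init$w <- sheet(init$Nc, init$Ltot)
  traj <- integrate_meanfield(p, init, t_end = 40, closure = sheet)
  expect_equal(tail(traj$w, 1), plateau_width(p), tolerance = 0.02)
})

test_that("integration rejects invalid grids and inconsistent states", {
  p <- growth_params()
  expect_error(integrate_meanfield(p, t_end = -1), "t_end")
  expect_error(integrate_meanfield(p, t_end = 5, dt = 0), "dt")
  bad <- meanfield_init(p)
  bad$w <- bad$w * 2
  expect_error(integrate_meanfield(p, bad, t_end = 1), "closure")
})

test_that("two growth phases bracket kd0 and kb", {
  # init width must be far below w0 for the early phase to run at kd0
  p <- growth_params(kd0 = 1.5, kb = 0.55, w0 = 600)
  traj <- integrate_meanfield(p, t_end = 40, dt = 0.02)
  rates <- growth_phase_rates(traj, c(0, 4), c(36, 40))
  expect_equal(rates$rate[rates$phase == "early"], 1.5, tolerance = 0.05)
  expect_equal(rates$rate[rates$phase == "late"], 0.55, tolerance = 0.05)
})

test_that("phase rates are zero without proliferation", {
  p <- suppressWarnings(growth_params(kd0 = 0, kb = 0))
  traj <- integrate_meanfield(p, t_end = 10)
  rates <- growth_phase_rates(traj, c(0, 1), c(9, 10))
  expect_equal(rates$rate, c(0, 0), tolerance = 1e-8)
})

test_that("phase windows are validated", {
  traj <- integrate_meanfield(growth_params(), t_end = 5)
  expect_error(growth_phase_rates(traj, c(0, 1), c(4, 6)), "span")
  expect_error(growth_phase_rates(traj, c(0, 0.015), c(4, 5)), "3 grid")
})
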