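test_that("growth parameter invariants are enforced", {
  p <- growth_params()
  expect_s3_class(p, "growth_params")
  expect_error(growth_params(v0 = -1), "v0")
  expect_error(growth_params(w0 = 0), "w0")
  expect_error(growth_params(w_min = 70, w0 = 60), "w_min")
  expect_error(growth_params(dim = 4), "dim")
  # no positive plateau when branching outpaces proliferation
  expect_warning(growth_params(kb = 2, kd0 = 1.5), "plateau")
  # an infinite w0 disables the feedback but is a valid configuration
  p_inf <- growth_params(w0 = Inf)
  expect_equal(division_rate(1e6, p_inf), p_inf$kd0)
})

test_that("plateau width matches w0 (1 - kb/kd0)", {
  expect_equal(plateau_width(growth_params(kb = 0, kd0 = 1.5, w0 = 60)), 60)
  expect_equal(plateau_width(growth_params(kd0 = 1.5, kb = 0.55, w0 = 60)),
               38)
  expect_warning(
    w <- plateau_width(suppressWarnings(growth_params(kb = 1.5, kd0 = 1.5))),
    "plateau"
  )
  expect_equal(w, 0)
  expect_error(plateau_width(suppressWarnings(growth_params(kd0 = 0, kb = 0))),
               "undefined")
})

test_that("parameter updates validate field names", {
  p <- growth_params()
  q <- update_growth_params(p, list(v0 = 10))
  expect_equal(q$v0, 10)
  expect_equal(q$kb, p$kb)
  expect_error(update_growth_params(p, list(speed = 10)), "unknown")
})

test_that("division rate is clamped at zero above w0", {
  p <- growth_params(kd0 = 1.5, w0 = 60)
  expect_equal(division_rate(0, p), 1.5)
  expect_equal(division_rate(30, p), 0.75)
  expect_equal(division_rate(90, p), 0)
})
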