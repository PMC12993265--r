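test_that("speed loop has unity DC gain and pure transport delay", {
  # matched initial state + constant reference: output pinned to the reference
  tr <- mech_response(rep(8000, 500), dt = DT)
  expect_equal(tr$n, rep(8000, 500), tolerance = 1e-12)

  # step at t = 0: output unchanged until the dead time has elapsed
  step <- mech_response(c(rep(7000, 1), rep(8000, 2499)), dt = DT, n0 = 7000)
  expect_true(all(abs(step$n[step$t < 0.002 + DT / 2] - 7000) < 1e-9))
  expect_gt(step$n[step$t > 0.004][1], 7000)
})

test_that("step response is overdamped and matches the analytic solution", {
  p <- mech_params()
  expect_gt(p$k1 / (2 * sqrt(p$k2)), 1)  # damping ratio ~1.18

  n_ref <- c(7000, rep(8000, 3000))
  tr <- mech_response(n_ref, dt = DT, n0 = 7000)
  # no overshoot, monotone rise
  expect_lte(max(tr$n), 8000 + 1e-9)
  expect_true(all(diff(tr$n) >= -1e-9))
  # settles on the reference
  expect_equal(tail(tr$n, 1), 8000, tolerance = 1e-9)
  # exact ZOH recurrence equals the continuous-time step response at samples
  # (the reference switches at the second sample)
  analytic <- 7000 + 1000 * mech_step_analytic(tr$t - DT, p)
  expect_equal(tr$n, analytic, tolerance = 1e-9)
})

test_that("hydraulic statics match hand-evaluated values", {
  expect_equal(steady_head(8000, 5), 73.4628, tolerance = 1e-6)
  # inversion returns the physical root (the negative root is ~ -32 L/min)
  expect_equal(steady_flow(8000, steady_head(8000, 5)), 5, tolerance = 1e-10)
  # zero-flow shutoff head
  expect_equal(steady_flow(7000, hydraulic_params()$b * 7000^2), 0,
               tolerance = 1e-10)
  # linear limit c = 0
  p0 <- hydraulic_params(c = 0)
  expect_equal(steady_flow(7500, steady_head(7500, 4, p0), p0), 4,
               tolerance = 1e-10)
  expect_error(steady_flow(9000, 1e6), "no real operating point")
})

test_that("hydraulic fixed point has zero flow derivative", {
  # dP equal to the static head leaves the flow unchanged
  tr <- hydraulic_response(rep(8000, 100), rep(steady_head(8000, 5), 100),
                           dt = DT)
  expect_equal(tr$q, rep(5, 100), tolerance = 1e-12)
})

test_that("explicit Euler agrees with a high-accuracy reference integration", {
  skip_if_not_installed("deSolve")
  p <- hydraulic_params()
  tt <- seq(0, 10, by = DT)
  dp_fun <- function(t) 70 + 10 * sin(2 * pi * 1.25 * t)
  n_fun <- function(t) 7500 + 500 * sin(2 * pi * 0.7 * t)
  sim <- hydraulic_response(n_fun(tt), dp_fun(tt), dt = DT, q0 = 4)
  ode <- deSolve::lsoda(
    c(Q = 4), tt,
    function(t, y, parms)
      list((p$a * y + p$b * n_fun(t)^2 + p$c * y^p$x * n_fun(t)^p$y -
              dp_fun(t)) / p$L),
    NULL, rtol = 1e-10, atol = 1e-10)
  expect_lt(max(abs(sim$q - ode[, "Q"]) / abs(ode[, "Q"])), 1e-3)
})

test_that("identification recovers the generating parameters exactly", {
  bench <- generate_bench_data()
  fit <- identify_hydraulic(bench)
  p <- fit$params; truth <- hydraulic_params()
  expect_identical(c(p$x, p$y), c(2L, 3L))
  expect_equal(p$a, truth$a, tolerance = 1e-6)
  expect_equal(p$b, truth$b, tolerance = 1e-6)
  expect_equal(p$c, truth$c, tolerance = 1e-6)
  expect_equal(p$L, truth$L, tolerance = 1e-6)
  # report is usable downstream
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$x, 2L)
})

test_that("identification survives pressure noise", {
  bench <- generate_bench_data(noise_sd = 1, seed = 7)
  fit <- identify_hydraulic(bench)
  g <- tidyr::expand_grid(n = seq(6000, 9000, 500),
                          q = seq(0.5, 8, length.out = 7))
  err <- steady_head(g$n, g$q, fit$params) -
    steady_head(g$n, g$q, hydraulic_params())
  expect_lt(sqrt(mean(err^2)), 2)
})

test_that("degenerate constant-condition bench data is rejected", {
  flat <- tibble::tibble(t_s = seq(0, 1, by = 0.01), n_rpm = 7000,
                         Q_lpm = 4, dP_mmHg = 80)
  expect_error(identify_hydraulic(flat), "not identifiable")
})
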