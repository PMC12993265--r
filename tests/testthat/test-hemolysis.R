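test_that("static power law matches hand-evaluated values and trends", {
  # unity ratios: HRI = hri_bar * c2
  expect_equal(static_hri(4.65, 7415), 43.22 * 0.740, tolerance = 1e-12)
  # exponent arithmetic: doubling speed at fixed flow
  expect_equal(static_hri(3, 8000) / static_hri(3, 4000), 2^5.45,
               tolerance = 1e-12)
  # higher speed and lower flow both raise HRI
  expect_gt(static_hri(3, 8000), static_hri(3, 7000))
  expect_gt(static_hri(2, 7000), static_hri(4, 7000))
  expect_error(static_hri(0, 7000), "backflow")
  expect_error(static_hri(-1, 7000), "backflow")
})

test_that("reduced exposure-time form is algebraically identical", {
  expect_equal(rp$a2_hat, 0.394, tolerance = 1e-12)
  expect_gt(rp$a2_hat, 0)
  withr::with_seed(42, {
    q <- runif(100, 0.5, 12)
    n <- runif(100, 6000, 9000)
  })
  texp <- geom$vi_ml / (q * 1000 / 60)  # seconds
  expect_equal(rp$c2_hat * texp^rp$a2_hat * n^rp$b2, static_hri(q, n, plp),
               tolerance = 1e-12)
})

test_that("particle counts at steady state reflect the washout time", {
  # N = Vi/(Q dt) +- 1
  tr <- lagrangian_hri(q = 0.5, n = 7000, steps = 2300, f = 1)
  expect_true(abs(tail(tr$n_particles, 1) - 2112) <= 1)
  tr <- lagrangian_hri(q = 12, n = 7000, steps = 300, f = 1)
  expect_true(abs(tail(tr$n_particles, 1) - 88) <= 1)
  # Q = 3 L/min: dl = 0.15625 mm -> 352 steps to traverse 55 mm
  tr <- lagrangian_hri(q = 3, n = 7000, steps = 400, f = 1, log_exits = TRUE)
  expect_equal(attr(tr, "exits")$t[1], 352 * DT, tolerance = 1e-12)
  expect_true(abs(tail(tr$n_particles, 1) - 352) <= 1)
})

test_that("exit damage at constant conditions equals the direct power law", {
  for (q in c(0.7, 3, 9)) {
    tr <- lagrangian_hri(q = q, n = 7800, steps = ceiling(1056 / q) + 60,
                         f = 1, log_exits = TRUE)
    exits <- attr(tr, "exits")
    expect_gt(nrow(exits), 10)
    # residence time is within one step of Vi/Q, so exit values match the
    # static law to the single-step discretization tolerance
    expect_equal(tail(exits$hri_exit, 1), static_hri(q, 7800),
                 tolerance = 3e-3)
  }
})

test_that("stepwise accumulation composes exactly over piecewise segments", {
  # speed step experienced mid-impeller at constant flow
  q <- 3                     # dl = 0.15625 mm -> 352 steps per transit
  n1 <- 7000; n2 <- 7900
  n_series <- c(rep(n1, 176), rep(n2, 400))
  tr <- lagrangian_hri(tibble::tibble(q_lpm = q, n_rpm = n_series),
                       f = 1, log_exits = TRUE)
  exits <- attr(tr, "exits")
  # first particle: 176 steps at n1, 176 at n2
  oracle <- compose_segments(list(list(n = n1, tau = 176 * DT),
                                  list(n = n2, tau = 176 * DT)), rp)
  expect_equal(exits$hri_exit[1], oracle, tolerance = 1e-6)

  # flow step mid-impeller at constant speed: effective time collapses to
  # total elapsed time, independent of the flow history
  q1 <- 3; q2 <- 6; n <- 7500
  q_series <- c(rep(q1, 176), rep(q2, 400))
  tr2 <- lagrangian_hri(tibble::tibble(q_lpm = q_series, n_rpm = n),
                        f = 1, log_exits = TRUE)
  ex2 <- attr(tr2, "exits")
  # first particle: 176 steps at q1 then 88 steps at q2 (dl doubles)
  t_total <- (176 + 88) * DT
  expect_equal(ex2$hri_exit[1], rp$c2_hat * t_total^rp$a2_hat * n^rp$b2,
               tolerance = 1e-6)
})

test_that("damage accumulation is monotone in time and in speed", {
  ramp <- tibble::tibble(q_lpm = 4, n_rpm = seq(6500, 8500, length.out = 600))
  tr <- lagrangian_hri(ramp, f = 1, log_exits = TRUE)
  # aggregate grows monotonically while speed rises
  expect_true(all(diff(tr$hri) > -1e-12))
  # a faster history never yields less exit damage
  tr_slow <- lagrangian_hri(q = 4, n = 6500, steps = 600, f = 1,
                            log_exits = TRUE)
  expect_true(all(attr(tr, "exits")$hri_exit >=
                    attr(tr_slow, "exits")$hri_exit[
                      seq_len(nrow(attr(tr, "exits")))] - 1e-12))
})

test_that("correction factor matches its stated value and analytic limit", {
  expect_equal(f_cal, 1.393, tolerance = 0.005 / 1.393)
  # continuous limit 1 + a2_hat as the step is refined 4x
  expect_lt(abs(calibrate_f(dt = DT / 4) - 1.394), 1e-3)
  # the speed cancels in the ratio
  f1 <- calibrate_f(dt = DT, n_cal = 6000)
  f2 <- calibrate_f(dt = DT, n_cal = 9000)
  expect_lt(abs(f1 / f2 - 1), 1e-9)
})

test_that("corrected aggregate reproduces the direct law at steady state", {
  for (q in c(0.5, 2, 6, 12)) {
    agg <- steady_lagrangian_hri(q, 7415, f = f_cal)
    expect_lt(abs(agg / static_hri(q, 7415) - 1), 0.007)
  }
})

test_that("backflow is rejected by the particle scheme", {
  expect_error(lagrangian_hri(q = -1, n = 7000, steps = 10, f = 1),
               "backflow|forward flow")
})
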