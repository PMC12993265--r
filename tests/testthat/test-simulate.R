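test_that("coupled simulation is deterministic", {
  a <- run_simulation(7000, cycles = 12, f = f_cal)
  b <- run_simulation(7000, cycles = 12, f = f_cal)
  expect_identical(a$hri, b$hri)
  expect_identical(a$pao, b$pao)
})

test_that("a trace replayed through the hemolysis module reproduces its HRI", {
  tr <- run_simulation(7200, cycles = 12, f = f_cal)
  replay <- lagrangian_hri(tibble::tibble(q_lpm = tr$q, n_rpm = tr$n),
                           dt = attr(tr, "dt"), f = attr(tr, "f"))
  expect_identical(replay$hri, tr$hri)
})

test_that("within a cycle HRI peaks where flow is lowest", {
  tr <- run_simulation(7000, cycles = 14, f = f_cal)
  post <- dplyr::filter(tr, !transient)
  # longer exposure at low flow raises the instantaneous HRI
  expect_lt(stats::cor(post$hri, post$q), -0.3)
  # and cycle metrics have settled
  cm <- cycle_metrics(tr)
  expect_lt(max(abs(diff(cm$mean_hri)) / cm$mean_hri[-1]), 0.001)
})

test_that("prescribed-flow cycle metrics match the static law", {
  # bypass the CVS: constant flow and speed through the hemolysis engine
  steps <- 5000
  tr <- lagrangian_hri(q = 4, n = 7500, steps = steps, f = f_cal)
  steady <- dplyr::filter(tr, !transient)
  expect_lt(abs(mean(steady$hri[2000:2500]) / static_hri(4, 7500) - 1),
            0.007)
})

test_that("cycle metric definitions behave on degenerate input", {
  fake <- tibble::tibble(
    cycle = rep(0:1, each = 10), hri = 1, pao = 90, plv = 10,
    q = 3, q_av = 1, transient = FALSE)
  attr(fake, "steps_per_cycle") <- 10L
  cm <- cycle_metrics(fake)
  expect_equal(cm$pulse_pressure, c(0, 0))
  expect_equal(cm$cardiac_output, c(4, 4))
  all_trans <- dplyr::mutate(fake, transient = TRUE)
  attr(all_trans, "steps_per_cycle") <- 10L
  expect_error(cycle_metrics(all_trans), "post-transient")
})

test_that("constant-speed sweep rows carry their condition and status", {
  sw <- constant_speed_sweep(speeds = c(6500, 8000), f = f_cal)
  expect_equal(nrow(sw), 2)
  expect_true(all(sw$status == "ok"))
  expect_gt(sw$mean_hri[2], sw$mean_hri[1])
  expect_lt(sw$pulse_pressure[2], sw$pulse_pressure[1])
})

test_that("modulation sweep reports references and relative changes", {
  specs <- enumerate_sweep(means = 7500, amplitudes = c(500, 1500),
                           cutoffs = 20, duty_grid = 0.5, phase_grid = 0)
  res <- modulation_sweep(specs, f = f_cal)
  expect_equal(sum(res$kind == "constant"), 1)
  expect_equal(res$d_hri[res$kind == "constant"], 0)
  smry <- summarize_modulation(res)
  expect_setequal(smry$role, c("constant", "min_hri", "max_hri", "max_pp"))
  expect_gte(smry$pulse_pressure[smry$role == "max_pp"],
             smry$pulse_pressure[smry$role == "constant"])
})
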