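make_samples <- function(hri, ...) generate_samples(hri, noise_sd = 0, ...)

test_that("interval HRI matches the hand-evaluated definition", {
  s <- tibble::tibble(t_h = 0:1, pfHb_mg_dl = c(5, 25), Hb_g_dl = 10,
                      HCT_pct = 35, V_ml = 450)
  expect_equal(hri_intervals(s)$hri, 58.5, tolerance = 1e-12)
  # no pfHb change, no hemolysis
  s0 <- dplyr::mutate(s, pfHb_mg_dl = 7)
  expect_equal(hri_intervals(s0)$hri, 0)
  # only differences enter: constant pfHb offsets cancel
  s_off <- dplyr::mutate(s, pfHb_mg_dl = pfHb_mg_dl + 100)
  expect_equal(hri_intervals(s_off)$hri, 58.5, tolerance = 1e-12)
  expect_error(hri_intervals(s[1, ]), "at least two")
  # decreasing pfHb is flagged, not rejected
  s_neg <- dplyr::mutate(s, pfHb_mg_dl = rev(pfHb_mg_dl))
  expect_true(hri_intervals(s_neg)$negative_delta)
})

test_that("sample generation and interval HRI are inverse operations", {
  withr::with_seed(11, hs <- runif(100, 0, 200))
  for (h in hs[1:5]) {
    iv <- hri_intervals(make_samples(h))
    expect_equal(iv$hri, rep(h, 6), tolerance = 1e-10)
  }
  # noisy round trip: mean over 6 intervals stays near the target
  errs <- vapply(hs, function(h) {
    mean(hri_intervals(generate_samples(h, noise_sd = 0.5, seed = round(h * 100)))$hri) - h
  }, numeric(1))
  expect_lt(median(abs(errs)), 2)   # ~3 sigma of the assay-noise propagation
})

test_that("trial-level HRI averages the six hourly intervals", {
  tr <- generate_trials(sigma_log = 0, device_factors = 1, samples = TRUE,
                        noise_sd = 0)
  out <- trial_hri(tr)
  expect_equal(nrow(out), 20)
  expect_equal(out$n_intervals, rep(6L, 20))
  expect_equal(out$hri, static_hri(out$Q_lpm, out$n_rpm), tolerance = 1e-8)
})

test_that("standardization maps every device mean onto hri_bar", {
  trials <- generate_trials(sigma_log = 0.15, seed = 3)
  std <- standardize_hri(trials, hri_bar = 43.22)
  means <- std |> dplyr::group_by(device_id) |>
    dplyr::summarise(m = mean(hri_std))
  expect_equal(means$m, rep(43.22, 3), tolerance = 1e-12)
  # devices with identical patterns at different scales coincide exactly
  two <- dplyr::bind_rows(
    tibble::tibble(device_id = "A", hri = c(10, 20, 40)),
    tibble::tibble(device_id = "B", hri = 2 * c(10, 20, 40)))
  std2 <- standardize_hri(two, hri_bar = 30)
  expect_equal(std2$hri_std[1:3], std2$hri_std[4:6], tolerance = 1e-12)
  expect_error(standardize_hri(tibble::tibble(device_id = "A", hri = c(-1, 0)),
                               hri_bar = 10), "non-positive")
})

test_that("noise-free fit recovers the generating parameters", {
  tr <- generate_trials(sigma_log = 0, device_factors = 1)
  fit <- fit_power_law(tr, q_bar = 4.65, n_bar = 7415, hri_bar = 43.22)
  expect_equal(fit$params$c2, 0.740, tolerance = 1e-6)
  expect_equal(fit$params$a2, -0.394, tolerance = 1e-6)
  expect_equal(fit$params$b2, 5.45, tolerance = 1e-6)
  expect_lt(fit$rmse, 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_equal(glance(fit)$n_obs, 20L)
  expect_setequal(tidy(fit)$term, c("c2", "a2", "b2"))
})

test_that("bisquare weighting suppresses a gross outlier", {
  tr <- generate_trials(sigma_log = 0.05, device_factors = 1, seed = 5)
  clean <- fit_power_law(tr, q_bar = 4.65, n_bar = 7415, hri_bar = 43.22)
  spoiled <- tr
  spoiled$hri[7] <- spoiled$hri[7] * 10
  rob <- fit_power_law(spoiled, q_bar = 4.65, n_bar = 7415, hri_bar = 43.22)
  expect_lt(rob$weights[7], 0.05)
  expect_lt(abs(rob$params$a2 / clean$params$a2 - 1), 0.05)
  expect_lt(abs(rob$params$b2 / clean$params$b2 - 1), 0.05)
})

test_that("fit is invariant to per-device rescaling after standardization", {
  trials <- generate_trials(sigma_log = 0.1, seed = 9)
  scaled <- trials |>
    dplyr::mutate(hri = ifelse(device_id == "LVAD2", hri * 3.7, hri))
  f1 <- fit_power_law(standardize_hri(trials, 43.22), q_bar = 4.65,
                      n_bar = 7415, hri_bar = 43.22, hri_col = "hri_std")
  f2 <- fit_power_law(standardize_hri(scaled, 43.22), q_bar = 4.65,
                      n_bar = 7415, hri_bar = 43.22, hri_col = "hri_std")
  expect_equal(f1$params$a2, f2$params$a2, tolerance = 1e-8)
  expect_equal(f1$params$b2, f2$params$b2, tolerance = 1e-8)
})

test_that("degenerate designs are reported", {
  one_flow <- tibble::tibble(n_rpm = c(6000, 7000, 8000, 9000), Q_lpm = 4,
                             hri = static_hri(4, c(6000, 7000, 8000, 9000)))
  expect_warning(fit_power_law(one_flow), "unidentifiable")
  expect_error(fit_power_law(one_flow[1:3, ]), "at least 4")
})

test_that("exponents are recovered under multiplicative noise", {
  reps <- purrr::map_dfr(1:50, function(i) {
    tr <- generate_trials(sigma_log = 0.2, seed = 1000 + i)
    std <- standardize_hri(tr, hri_bar = 43.22)
    fit <- suppressWarnings(
      fit_power_law(std, q_bar = 4.65, n_bar = 7415, hri_bar = 43.22,
                    hri_col = "hri_std"))
    tibble::tibble(a2 = fit$params$a2, b2 = fit$params$b2)
  })
  expect_lt(median(abs(reps$b2 - 5.45)), 0.5)
  expect_gte(mean(reps$a2 < 0), 0.95)
})

test_that("MIH converts to HRI by flow times six", {
  expect_equal(mih_to_hri(1, 5), 30)
  expect_equal(mih_to_hri(0, 3), 0)
  expect_equal(mih_to_hri(2 * 1.7, 4), 2 * mih_to_hri(1.7, 4))
  expect_error(mih_to_hri(1, 0), "positive")
})
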