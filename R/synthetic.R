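#' Default in vitro trial operating grid
#'
#' Twenty constant (speed, flow) conditions: 18 spread evenly over six
#' speeds between 6000 and 9000 rpm inside a speed-dependent physiological
#' flow band (interpolated between 0.5-4 L/min at 6000 rpm and 3-8 L/min at
#' 9000 rpm), plus two low-flow points at 1 L/min for 6000 and 7000 rpm.
#'
#' @return A tibble with columns `n_rpm`, `Q_lpm` (20 rows).
#' @export
trial_grid <- function() {
  speeds <- seq(6000, 9000, length.out = 6)
  band <- purrr::map_dfr(speeds, function(n) {
    lo <- 0.5 + (n - 6000) / 3000 * (3 - 0.5)
    hi <- 4 + (n - 6000) / 3000 * (8 - 4)
    tibble(n_rpm = n, Q_lpm = seq(lo, hi, length.out = 3))
  })
  dplyr::bind_rows(band, tibble(n_rpm = c(6000, 7000), Q_lpm = 1)) |>
    dplyr::arrange(.data$n_rpm, .data$Q_lpm)
}

#' Generate synthetic hemolysis trials for a device fleet
#'
#' True HRI per device and operating point is the static power law times a
#' per-device scale and multiplicative lognormal noise.  Device 1 is
#' elevated by default, reproducing the systematic device-to-device
#' differences that motivate standardization.
#'
#' @param grid operating grid with columns `n_rpm`, `Q_lpm`; default
#'   [trial_grid()].
#' @param params the generating [power_law_params()].
#' @param device_factors multiplicative per-device scales.
#' @param sigma_log lognormal noise sigma on HRI (0 for noise-free).
#' @param seed RNG seed (integer); generation is a pure function of the
#'   arguments.
#' @param samples if `TRUE`, emit full hourly blood-sample series (via
#'   [generate_samples()]) instead of trial-level HRIs.
#' @param ... passed to [generate_samples()] when `samples = TRUE`.
#' @return A tibble: trial-level (`device_id`, `n_rpm`, `Q_lpm`, `hri`) or
#'   the full sample schema when `samples = TRUE`.
#' @export
generate_trials <- function(grid = trial_grid(),
                            params = power_law_params(),
                            device_factors = c(1.5, 1, 0.95),
                            sigma_log = 0.2, seed = 1, samples = FALSE,
                            ...) {
  check_columns(grid, c("n_rpm", "Q_lpm"), "operating grid")
  if (any(grid$Q_lpm < 0.5))
    abort("all grid flows must be >= 0.5 L/min (blood-mixing floor)")
  trials <- withr::with_seed(seed, {
    purrr::imap_dfr(device_factors, function(fac, dev) {
      noise <- if (sigma_log > 0)
        exp(stats::rnorm(nrow(grid), 0, sigma_log)) else 1
      tibble(device_id = paste0("LVAD", dev), n_rpm = grid$n_rpm,
             Q_lpm = grid$Q_lpm,
             hri = fac * static_hri(grid$Q_lpm, grid$n_rpm, params) * noise)
    })
  })
  if (!samples) return(trials)
  withr::with_seed(seed + 1L, {
    purrr::pmap_dfr(trials, function(device_id, n_rpm, Q_lpm, hri) {
      dplyr::bind_cols(tibble(device_id = device_id, n_rpm = n_rpm,
                              Q_lpm = Q_lpm),
                       generate_samples(hri, seed = NULL, ...))
    })
  })
}

#' Generate an hourly blood-sample series for a given true HRI
#'
#' Inverts the interval HRI definition: plasma-free hemoglobin rises each
#' hour by the increment that makes every interval evaluate to `true_hri`,
#' plus optional additive assay noise on the measured pfHb.
#'
#' @param true_hri target hemolysis rate index, %·mL/h (>= 0).
#' @param v_ml loop volume, mL.
#' @param hct_pct hematocrit, %.
#' @param hb_g_dl total hemoglobin, g/dL.
#' @param hours trial duration, h (hourly samples, `hours + 1` rows).
#' @param pfhb0 initial plasma-free hemoglobin, mg/dL.
#' @param noise_sd additive Gaussian assay noise on pfHb, mg/dL.
#' @param seed RNG seed, or `NULL` to use the current RNG state.
#' @return A tibble with columns `t_h`, `pfHb_mg_dl`, `Hb_g_dl`,
#'   `HCT_pct`, `V_ml`.
#' @export
generate_samples <- function(true_hri, v_ml = 450, hct_pct = 35,
                             hb_g_dl = 10, hours = 6L, pfhb0 = 5,
                             noise_sd = 0.5, seed = NULL) {
  check_number(true_hri, "true_hri", lower = 0)
  dpf <- true_hri * hb_g_dl * 10 / (v_ml * (100 - hct_pct) / 100)
  pf_true <- pfhb0 + dpf * (0:hours)
  if (max(pf_true) >= hb_g_dl * 1000)
    abort("true_hri implies plasma-free hemoglobin exceeding total hemoglobin")
  gen <- function() {
    pf <- pf_true + if (noise_sd > 0)
      stats::rnorm(hours + 1, 0, noise_sd) else 0
    tibble(t_h = 0:hours, pfHb_mg_dl = pf, Hb_g_dl = hb_g_dl,
           HCT_pct = hct_pct, V_ml = v_ml)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Generate a synthetic hydraulic bench dataset
#'
#' Visits every (speed, flow) operating point of a grid with a hold phase
#' at the point and a smooth quintic-blend ramp between points (twice
#' continuously differentiable, so finite-difference flow derivatives stay
#' accurate across segment joints).  The head pressure is computed from
#' the flow ODE with the analytic flow derivative, so the noise-free
#' dataset satisfies the hydraulic model exactly; optional additive
#' Gaussian noise is applied to the pressure.
#'
#' @param params the generating [hydraulic_params()].
#' @param speeds,flows grid axes (rpm, L/min); the grid is traversed in
#'   snake order to keep ramps short.
#' @param dt sample time, s.
#' @param hold hold duration per point, s.
#' @param ramp ramp duration between points, s.
#' @param noise_sd additive pressure noise, mmHg.
#' @param seed RNG seed.
#' @return A tibble with columns `t_s`, `n_rpm`, `Q_lpm`, `dP_mmHg`.
#' @export
generate_bench_data <- function(params = hydraulic_params(),
                                speeds = seq(6000, 9000, by = 500),
                                flows = seq(0.5, 8, length.out = 7),
                                dt = 5e-4, hold = 1, ramp = 1,
                                noise_sd = 0, seed = 1) {
  if (length(speeds) < 3L || length(flows) < 3L)
    abort("the bench grid must span at least 3 speeds and 3 flows")
  pts <- purrr::map_dfr(seq_along(speeds), function(i) {
    fl <- if (i %% 2L == 1L) flows else rev(flows)  # snake order
    tibble(n = speeds[i], q = fl)
  })
  hold_n <- round(hold / dt); ramp_n <- round(ramp / dt)
  seg_t <- list(); seg_n <- list(); seg_q <- list(); seg_dq <- list()
  for (i in seq_len(nrow(pts))) {
    if (i > 1L) {  # ramp from previous point
      u <- (1:ramp_n) / ramp_n
      s <- 10 * u^3 - 15 * u^4 + 6 * u^5          # C2 smoothstep
      ds <- (30 * u^2 - 60 * u^3 + 30 * u^4) / ramp
      seg_n[[length(seg_n) + 1L]] <- pts$n[i - 1] + (pts$n[i] - pts$n[i - 1]) * s
      seg_q[[length(seg_q) + 1L]] <- pts$q[i - 1] + (pts$q[i] - pts$q[i - 1]) * s
      seg_dq[[length(seg_dq) + 1L]] <- (pts$q[i] - pts$q[i - 1]) * ds
    }
    seg_n[[length(seg_n) + 1L]] <- rep(pts$n[i], hold_n)
    seg_q[[length(seg_q) + 1L]] <- rep(pts$q[i], hold_n)
    seg_dq[[length(seg_dq) + 1L]] <- rep(0, hold_n)
  }
  n <- unlist(seg_n); q <- unlist(seg_q); dq <- unlist(seg_dq)
  dp <- params$a * q + params$b * n^2 +
    params$c * q^params$x * n^params$y - params$L * dq
  if (noise_sd > 0)
    dp <- dp + withr::with_seed(seed, stats::rnorm(length(dp), 0, noise_sd))
  tibble(t_s = seq_along(n) * dt - dt, n_rpm = n, Q_lpm = q, dP_mmHg = dp)
}
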