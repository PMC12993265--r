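#' Coupled LVAD-cardiovascular-hemolysis simulation
#'
#' Advances, at a single global step `dt`: the speed loop (reference to
#' actual speed), the hydraulic flow dynamics against the instantaneous
#' head pressure `pao - plv`, the cardiovascular model driven by the pump
#' flow, and the Lagrangian hemolysis scheme.  The trace is flagged
#' transient until one full impeller washout *and* `transient_cycles`
#' cardiac cycles have elapsed.
#'
#' The simulation is fully deterministic: identical inputs give
#' bit-identical traces.
#'
#' @param profile the reference-speed input: a single speed (rpm) for
#'   constant-speed mode, or a data frame with column `n_ref` holding one
#'   cardiac cycle sampled at `dt` (see [generate_profile()]), tiled over
#'   the run.
#' @param cycles number of cardiac cycles to simulate.
#' @param dt global step time, s.
#' @param mech,hyd pump parameter objects ([mech_params()],
#'   [hydraulic_params()]).
#' @param cvs a [cvs_params()] object.
#' @param params,geometry hemolysis model objects ([power_law_params()],
#'   [impeller_geometry()]).
#' @param f correction factor; `NULL` calibrates it once via
#'   [calibrate_f()].
#' @param transient_cycles minimum number of cycles discarded as transient.
#' @param v0 initial compartment volumes, mL.
#' @return A tibble of class `lvad_trace` with columns `t`, `n_ref`, `n`,
#'   `q` (LVAD flow, L/min), `dp`, `pao`, `plv`, `hri`, `q_av`, `volume`,
#'   `cycle`, `n_particles`, `transient`.
#' @export
run_simulation <- function(profile, cycles = 16, dt = 4e-4,
                           mech = mech_params(), hyd = hydraulic_params(),
                           cvs = cvs_params(),
                           params = power_law_params(),
                           geometry = impeller_geometry(), f = NULL,
                           transient_cycles = 10,
                           v0 = cvs_initial_volumes()) {
  t_cycle <- 60 / cvs$hr
  steps_cycle <- round(t_cycle / dt)
  if (is.data.frame(profile)) {
    check_columns(profile, "n_ref", "speed profile")
    if (nrow(profile) != steps_cycle)
      abort(sprintf(
        "profile has %d samples but one cardiac cycle at dt = %g s has %d",
        nrow(profile), dt, steps_cycle))
    n_ref <- rep(profile$n_ref, length.out = steps_cycle * cycles)
  } else {
    check_number(profile, "profile", lower = .Machine$double.xmin)
    n_ref <- rep(as.numeric(profile), steps_cycle * cycles)
  }
  if (is.null(f))
    f <- calibrate_f(params = params, geometry = geometry, dt = dt)
  d <- discretize_mech(mech, dt)
  rp <- reduce_params(params, geometry)
  # head pressure and flow at the initial (diastolic) state
  pao0 <- v0[["sa"]] / cvs$c_sa
  plv0 <- cvs$ed_lv * (v0[["lv"]] - cvs$v0_lv) +
    cvs$k_sept * cvs$ed_rv * (v0[["rv"]] - cvs$v0_rv)
  q0 <- tryCatch(steady_flow(n_ref[1], pao0 - plv0, hyd),
                 error = function(e) 1)
  if (!is.finite(q0) || q0 <= 0) q0 <- 0.5
  res <- cpp_coupled_run(n_ref, dt, d$Ad, d$Bd, c(n_ref[1], 0),
                         d$delay_steps,
                         c(hyd$L, hyd$a, hyd$b, hyd$c, hyd$x, hyd$y), q0,
                         cvs_param_vector(cvs), as.numeric(v0), 0,
                         hemo_vector(rp, geometry, f),
                         numeric(0), numeric(0))
  ns <- length(n_ref)
  cum_l <- cumsum(res$q * 1000 / 60 * geometry$li_mm / geometry$vi_ml * dt)
  w <- which(cum_l >= geometry$li_mm)
  washout_end <- if (length(w)) w[1] else ns + 1L
  transient_end <- max(washout_end, transient_cycles * steps_cycle)
  out <- tibble(t = seq_len(ns) * dt - dt, n_ref = n_ref, n = res$n,
                q = res$q, dp = res$dp, pao = res$pao, plv = res$plv,
                hri = res$hri, q_av = res$q_av, volume = res$volume,
                cycle = res$cycle, n_particles = res$count,
                transient = seq_len(ns) <= transient_end)
  attr(out, "dt") <- dt
  attr(out, "steps_per_cycle") <- steps_cycle
  attr(out, "f") <- f
  class(out) <- c("lvad_trace", class(out))
  out
}

#' Per-cycle metrics of a simulation trace
#'
#' For each complete post-transient cardiac cycle: the time-averaged HRI,
#' the pulse pressure (max minus min aortic pressure), the cardiac output
#' (cycle average of total forward aortic flow, aortic valve plus LVAD) and
#' the mean LVAD flow.
#'
#' @param trace an `lvad_trace` from [run_simulation()].
#' @return A tibble with one row per analysed cycle: `cycle`, `mean_hri`,
#'   `pulse_pressure`, `cardiac_output`, `mean_lvad_flow`, `min_lvad_flow`,
#'   `max_lvad_flow`, `mean_pao`.
#' @export
cycle_metrics <- function(trace) {
  check_columns(trace, c("cycle", "hri", "pao", "q", "q_av", "transient"),
                "simulation trace")
  steps_cycle <- attr(trace, "steps_per_cycle")
  d <- dplyr::filter(trace, !.data$transient)
  if (!is.null(steps_cycle)) {
    complete <- d |>
      dplyr::count(.data$cycle) |>
      dplyr::filter(.data$n == steps_cycle)
    d <- dplyr::semi_join(d, complete, by = "cycle")
  }
  if (!nrow(d))
    abort("no complete post-transient cycle in the trace; simulate longer")
  d |>
    dplyr::group_by(cycle = .data$cycle) |>
    dplyr::summarise(
      mean_hri = mean(.data$hri),
      pulse_pressure = max(.data$pao) - min(.data$pao),
      cardiac_output = mean(.data$q_av + .data$q),
      mean_lvad_flow = mean(.data$q),
      min_lvad_flow = min(.data$q),
      max_lvad_flow = max(.data$q),
      mean_pao = mean(.data$pao),
      .groups = "drop")
}

#' Physiological flow range over a speed grid
#'
#' For each speed, runs the coupled simulation across all combinations of
#' contractility (`cf_lv` 0.1/0.25/0.4), heart rate (60/90/120 bpm) and
#' systemic resistance scaling (`f_rsys` 0.75/1/1.25) to periodic steady
#' state and records the extreme LVAD flows over the analysed cycles.  The
#' lower bound is floored at `q_floor` (adequate blood mixing); any
#' combination aborting with backflow is excluded with a warning.
#'
#' @param speeds pump speeds, rpm.
#' @param cf_lv_grid,hr_grid,f_rsys_grid cardiovascular parameter grids.
#' @param q_floor lower flow bound, L/min.
#' @param ... passed on to [run_simulation()].
#' @return A tibble with one row per speed: `speed`, `q_min`, `q_max`,
#'   `mean_flow` (mean over combinations), `n_combos`, `n_excluded`.
#' @export
physiological_flow_range <- function(speeds,
                                     cf_lv_grid = c(0.1, 0.25, 0.4),
                                     hr_grid = c(60, 90, 120),
                                     f_rsys_grid = c(0.75, 1, 1.25),
                                     q_floor = 0.5, ...) {
  combos <- tidyr::expand_grid(cf_lv = cf_lv_grid, hr = hr_grid,
                               f_rsys = f_rsys_grid)
  purrr::map_dfr(speeds, function(sp) {
    res <- purrr::pmap(combos, function(cf_lv, hr, f_rsys) {
      tryCatch({
        tr <- run_simulation(sp, cvs = cvs_params(hr = hr, cf_lv = cf_lv,
                                                  f_rsys = f_rsys), ...)
        cm <- cycle_metrics(tr)
        tibble(q_min = min(cm$min_lvad_flow), q_max = max(cm$max_lvad_flow),
               q_mean = mean(cm$mean_lvad_flow))
      }, error = function(e) NULL)
    })
    ok <- purrr::compact(res)
    n_exc <- nrow(combos) - length(ok)
    if (n_exc > 0)
      warn(sprintf("%d parameter combination(s) at %g rpm aborted (backflow) and were excluded",
                   n_exc, sp))
    if (!length(ok))
      return(tibble(speed = sp, q_min = NA_real_, q_max = NA_real_,
                    mean_flow = NA_real_, n_combos = 0L,
                    n_excluded = n_exc))
    ok <- dplyr::bind_rows(ok)
    tibble(speed = sp, q_min = max(q_floor, min(ok$q_min)),
           q_max = max(ok$q_max), mean_flow = mean(ok$q_mean),
           n_combos = nrow(ok), n_excluded = n_exc)
  })
}

#' Constant-speed operating-mode sweep
#'
#' Simulates constant-speed support over a speed grid for one or more
#' cardiovascular variants and summarises the post-transient per-cycle
#' metrics.
#'
#' @param speeds pump speeds, rpm.
#' @param variants a data frame with columns `label`, `hr`, `cf_lv`,
#'   `f_rsys`, one row per cardiovascular condition; default is the
#'   baseline (HR 75, f_rsys 1, cf_lv 0.25).
#' @param f correction factor; calibrated once if `NULL`.
#' @param ... passed on to [run_simulation()].
#' @return A tibble with one row per (speed, variant): the cycle-averaged
#'   metrics of [cycle_metrics()], plus `speed`, `label`, `hr`, `cf_lv`,
#'   `f_rsys`, and `status` (`"ok"` or the abort message).
#' @export
constant_speed_sweep <- function(speeds = seq(6000, 9000, by = 100),
                                 variants = baseline_variants("baseline"),
                                 f = NULL, ...) {
  if (is.null(f)) f <- calibrate_f()
  tidyr::expand_grid(speed = speeds, variants) |>
    purrr::pmap_dfr(function(speed, label, hr, cf_lv, f_rsys) {
      base <- tibble(speed = speed, label = label, hr = hr, cf_lv = cf_lv,
                     f_rsys = f_rsys)
      tryCatch({
        tr <- run_simulation(speed, cvs = cvs_params(hr = hr, cf_lv = cf_lv,
                                                     f_rsys = f_rsys),
                             f = f, ...)
        cm <- cycle_metrics(tr)
        dplyr::bind_cols(base,
                         dplyr::summarise(cm, dplyr::across(-"cycle", mean)),
                         tibble(n_cycles = nrow(cm), status = "ok"))
      }, error = function(e) {
        dplyr::bind_cols(base, tibble(status = conditionMessage(e)))
      })
    })
}

#' Standard cardiovascular variants for sweeps
#'
#' The baseline heart-failure condition (HR 75 bpm, f_rsys 1, cf_lv 0.25)
#' plus, optionally, the one-at-a-time variations used in the
#' operating-mode study.
#'
#' @param which `"baseline"` for the baseline only, `"all"` to add the
#'   individual cf_lv (0.1/0.4), f_rsys (0.75/1.25) and HR (60/120)
#'   variations.
#' @return A tibble with columns `label`, `hr`, `cf_lv`, `f_rsys`.
#' @export
baseline_variants <- function(which = c("baseline", "all")) {
  which <- match.arg(which)
  base <- tibble(label = "baseline", hr = 75, cf_lv = 0.25, f_rsys = 1)
  if (which == "baseline") return(base)
  dplyr::bind_rows(
    base,
    tibble(label = c("cflv_0.1", "cflv_0.4"), hr = 75,
           cf_lv = c(0.1, 0.4), f_rsys = 1),
    tibble(label = c("frsys_0.75", "frsys_1.25"), hr = 75, cf_lv = 0.25,
           f_rsys = c(0.75, 1.25)),
    tibble(label = c("hr_60", "hr_120"), hr = c(60, 120), cf_lv = 0.25,
           f_rsys = 1))
}

#' Speed-modulation sweep
#'
#' Simulates every feasible modulation profile under baseline
#' cardiovascular conditions together with the constant-speed reference at
#' each mean speed, and reports cycle-averaged metrics with relative
#' changes against the reference.
#'
#' @param specs a tibble of profile specifications as produced by
#'   [enumerate_sweep()].
#' @param cvs a [cvs_params()] object (baseline conditions).
#' @param dt step time, s.
#' @param f correction factor; calibrated once if `NULL`.
#' @param ... passed on to [run_simulation()].
#' @return A tibble with one row per profile (plus one `constant` row per
#'   mean speed): spec columns, the averaged cycle metrics, `status`, and
#'   `d_hri`/`d_pp` (relative changes of mean HRI and pulse pressure vs.
#'   the constant-speed reference at the same mean speed).
#' @export
modulation_sweep <- function(specs, cvs = cvs_params(), dt = 4e-4, f = NULL,
                             ...) {
  if (!nrow(specs)) abort("empty specification list")
  if (is.null(f)) f <- calibrate_f(dt = dt)
  t_cycle <- 60 / cvs$hr

  run_one <- function(profile, meta) {
    tryCatch({
      tr <- run_simulation(profile, dt = dt, cvs = cvs, f = f, ...)
      cm <- cycle_metrics(tr)
      dplyr::bind_cols(meta,
                       dplyr::summarise(cm, dplyr::across(-"cycle", mean)),
                       tibble(status = "ok"))
    }, error = function(e) {
      dplyr::bind_cols(meta, tibble(status = conditionMessage(e)))
    })
  }

  refs <- purrr::map_dfr(unique(specs$mean_speed), function(ms) {
    run_one(ms, tibble(mean_speed = ms, amplitude = 0, cutoff = NA_real_,
                       duty = NA_real_, phase = NA_real_, kind = "constant"))
  })
  mods <- purrr::pmap_dfr(
    specs[, c("mean_speed", "amplitude", "cutoff", "duty", "phase")],
    function(mean_speed, amplitude, cutoff, duty, phase) {
      sp <- modulation_spec(mean_speed, amplitude, duty, phase, cutoff)
      prof <- generate_profile(sp, t_cycle = t_cycle, dt = dt)
      run_one(prof, tibble(mean_speed = mean_speed, amplitude = amplitude,
                           cutoff = cutoff, duty = duty, phase = phase,
                           kind = "modulated"))
    })
  ref_vals <- refs |>
    dplyr::select("mean_speed", ref_hri = "mean_hri",
                  ref_pp = "pulse_pressure")
  dplyr::bind_rows(refs, mods) |>
    dplyr::left_join(ref_vals, by = "mean_speed") |>
    dplyr::mutate(d_hri = (.data$mean_hri - .data$ref_hri) / .data$ref_hri,
                  d_pp = (.data$pulse_pressure - .data$ref_pp) / .data$ref_pp)
}

#' Summarise a modulation sweep
#'
#' Per mean speed: the constant-speed reference, the minimum- and
#' maximum-HRI profiles, and the maximum-pulse-pressure profile, with
#' their relative changes.
#'
#' @param results the tibble returned by [modulation_sweep()].
#' @return A tibble with one row per (mean speed, role), role one of
#'   `constant`, `min_hri`, `max_hri`, `max_pp`.
#' @export
summarize_modulation <- function(results) {
  ok <- dplyr::filter(results, .data$status == "ok")
  pick <- function(d, role, idx) {
    dplyr::mutate(d[idx, , drop = FALSE], role = role)
  }
  ok |>
    dplyr::group_by(.data$mean_speed) |>
    dplyr::group_modify(function(d, key) {
      m <- dplyr::filter(d, .data$kind == "modulated")
      dplyr::bind_rows(
        pick(d, "constant", which(d$kind == "constant")[1]),
        pick(m, "min_hri", which.min(m$mean_hri)),
        pick(m, "max_hri", which.max(m$mean_hri)),
        pick(m, "max_pp", which.max(m$pulse_pressure)))
    }) |>
    dplyr::ungroup() |>
    dplyr::select("mean_speed", "role", "amplitude", "cutoff", "duty",
                  "phase", "mean_hri", "pulse_pressure", "mean_lvad_flow",
                  "cardiac_output", "d_hri", "d_pp")
}

#' Plot a simulation trace
#'
#' Stacked panels of HRI, LVAD flow, and aortic/ventricular pressures over
#' time (post-transient part highlighted).
#'
#' @param object an `lvad_trace`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot lvad_trace
#' @export
autoplot.lvad_trace <- function(object, ...) {
  long <- dplyr::bind_rows(
    tibble(t = object$t, value = object$hri, panel = "HRI (%*mL/h)",
           series = "HRI", transient = object$transient),
    tibble(t = object$t, value = object$q, panel = "LVAD flow (L/min)",
           series = "Q", transient = object$transient),
    tibble(t = object$t, value = object$pao, panel = "pressure (mmHg)",
           series = "aortic", transient = object$transient),
    tibble(t = object$t, value = object$plv, panel = "pressure (mmHg)",
           series = "left ventricle", transient = object$transient))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                     colour = .data$series,
                                     alpha = !.data$transient)) +
    ggplot2::geom_line() +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35),
                                guide = "none") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
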