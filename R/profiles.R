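#' Speed-modulation profile specification
#'
#' A cardiac-cycle-synchronised filtered rectangular speed profile.  The
#' rectangular wave is anchored so that its time average equals
#' `mean_speed` exactly: the high level is `mean + (1 - duty) * amplitude`
#' and the low level `mean - duty * amplitude`, held for fractions `duty`
#' and `1 - duty` of the cycle.  A first-order low-pass (one-pole
#' Butterworth) with the given cutoff shapes the wave, and the result is
#' circularly shifted by `phase` cycle fractions.
#'
#' @param mean_speed cycle-mean reference speed, rpm.
#' @param amplitude peak-to-peak modulation `n_high - n_low`, rpm (>= 0).
#' @param duty high-speed fraction of the cycle, in (0, 1).
#' @param phase time shift as a fraction of the cycle, in \[0, 1).
#' @param cutoff low-pass cutoff frequency, Hz.
#' @param n_min,n_max admissible speed bounds, rpm; the unfiltered wave must
#'   stay inside them.
#' @return An object of class `modulation_spec`.
#' @export
modulation_spec <- function(mean_speed, amplitude = 0, duty = 0.5,
                            phase = 0, cutoff = 20, n_min = 6000,
                            n_max = 9000) {
  check_number(mean_speed, "mean_speed", lower = .Machine$double.xmin)
  check_number(amplitude, "amplitude", lower = 0)
  check_number(duty, "duty", lower = 1e-9, upper = 1 - 1e-9)
  check_number(phase, "phase", lower = 0, upper = 1 - 1e-12)
  check_number(cutoff, "cutoff", lower = .Machine$double.xmin)
  n_high <- mean_speed + (1 - duty) * amplitude
  n_low <- mean_speed - duty * amplitude
  if (n_high > n_max)
    abort(sprintf("infeasible profile: n_high = %g rpm exceeds the upper bound %g rpm",
                  n_high, n_max))
  if (n_low < n_min)
    abort(sprintf("infeasible profile: n_low = %g rpm violates the lower bound %g rpm",
                  n_low, n_min))
  structure(list(mean_speed = mean_speed, amplitude = amplitude,
                 duty = duty, phase = phase, cutoff = cutoff,
                 n_high = n_high, n_low = n_low, n_min = n_min,
                 n_max = n_max), class = "modulation_spec")
}

#' Generate one periodic cycle of a speed-modulation profile
#'
#' Builds the rectangular wave, runs the causal first-order low-pass over
#' repeated cycles until periodic steady state (so the emitted cycle is the
#' periodic response, not a filter transient), then applies the phase shift
#' as a circular rotation.  The filter has unity DC gain, so the cycle mean
#' of the output equals `mean_speed` exactly.
#'
#' @param spec a [modulation_spec()] object.
#' @param t_cycle cardiac cycle duration, s.
#' @param dt sample time, s.
#' @return A tibble with columns `t` and `n_ref` covering one cycle.
#' @export
generate_profile <- function(spec, t_cycle = 0.8, dt = 4e-4) {
  check_number(t_cycle, "t_cycle", lower = .Machine$double.xmin)
  check_number(dt, "dt", lower = .Machine$double.xmin)
  ns <- round(t_cycle / dt)
  if (abs(ns * dt - t_cycle) > dt)
    abort("`dt` must divide the cycle duration to within one sample")
  n_high_steps <- round(spec$duty * ns)
  u <- c(rep(spec$n_high, n_high_steps), rep(spec$n_low, ns - n_high_steps))
  # exact one-pole discretization; DC gain 1
  alpha <- exp(-2 * pi * spec$cutoff * dt)
  y <- u[1]
  n_warm <- 50L
  for (cycle in seq_len(n_warm)) {
    y_start <- y
    for (i in seq_len(ns)) y <- alpha * y + (1 - alpha) * u[i]
    if (abs(y - y_start) < 1e-10 * spec$mean_speed && cycle >= 3L) break
  }
  out <- numeric(ns)
  for (i in seq_len(ns)) {
    y <- alpha * y + (1 - alpha) * u[i]
    out[i] <- y
  }
  shift <- round(spec$phase * ns) %% ns
  if (shift > 0) out <- c(out[(ns - shift + 1):ns], out[1:(ns - shift)])
  tibble(t = seq_len(ns) * dt - dt, n_ref = out)
}

#' Enumerate a speed-modulation sweep
#'
#' Cartesian product of mean speeds, peak-to-peak amplitudes, filter
#' cutoffs, duty fractions and phase shifts, keeping only profiles whose
#' unfiltered levels stay inside \[`n_min`, `n_max`\].  The defaults follow
#' the modulation study design: means 6500-8500 rpm in 1000 rpm steps,
#' amplitudes 500-3000 rpm in 500 rpm steps, cutoffs 20/5/2 Hz, duty and
#' phase on 5 % grids.
#'
#' @param means mean speeds, rpm.
#' @param amplitudes peak-to-peak amplitudes, rpm.
#' @param cutoffs filter cutoffs, Hz.
#' @param duty_grid,phase_grid duty and phase grids (fractions).
#' @param n_min,n_max admissible speed bounds, rpm.
#' @return A tibble of feasible specifications, one row each, with the
#'   realised `n_high`/`n_low`.
#' @export
enumerate_sweep <- function(means = c(6500, 7500, 8500),
                            amplitudes = seq(500, 3000, by = 500),
                            cutoffs = c(20, 5, 2),
                            duty_grid = seq(0.05, 0.95, by = 0.05),
                            phase_grid = seq(0, 0.95, by = 0.05),
                            n_min = 6000, n_max = 9000) {
  grid <- tidyr::expand_grid(mean_speed = means, amplitude = amplitudes,
                             cutoff = cutoffs, duty = duty_grid,
                             phase = phase_grid)
  grid |>
    dplyr::mutate(n_high = .data$mean_speed + (1 - .data$duty) * .data$amplitude,
                  n_low = .data$mean_speed - .data$duty * .data$amplitude) |>
    dplyr::filter(.data$n_high <= n_max, .data$n_low >= n_min)
}
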