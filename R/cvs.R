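#' Lumped-parameter cardiovascular model parameters
#'
#' Eight compliance compartments — left/right ventricle, left/right atrium,
#' systemic arterial, systemic venous, pulmonary arterial and pulmonary
#' venous — interconnected by resistances and ideal diode valves.  The
#' ventricles follow a double-Hill time-varying elastance; the atria are
#' passive compliances; ventricular interdependence is a linear septal
#' pressure coupling.  The defaults describe a dilated, hypocontractile
#' left heart (the population an assist device supports): with `cf_lv`
#' at its baseline 0.25 the unsupported model produces a low-output,
#' low-pulse-pressure circulation.
#'
#' Units: elastances mmHg/mL, compliances mL/mmHg, resistances mmHg·s/mL,
#' volumes mL, heart rate bpm.
#'
#' @param hr heart rate, bpm.
#' @param cf_lv left-ventricular contractility factor in (0, 1]; multiplies
#'   the end-systolic LV elastance.
#' @param f_rsys multiplicative scaling of the systemic vascular resistance.
#' @param ees_lv reference (healthy) LV end-systolic elastance.
#' @param ed_lv LV end-diastolic elastance.
#' @param v0_lv LV unstressed volume.
#' @param ees_rv,ed_rv,v0_rv right-ventricular analogues.
#' @param c_la,v0_la,c_ra,v0_ra atrial compliances and unstressed volumes.
#' @param c_sa,c_sv,c_pa,c_pv systemic arterial/venous and pulmonary
#'   arterial/venous compliances (stressed-volume convention, V0 = 0).
#' @param r_mv,r_av,r_tv,r_pvalve valve series resistances (mitral, aortic,
#'   tricuspid, pulmonary).
#' @param r_sys systemic vascular resistance (scaled by `f_rsys`).
#' @param r_vr venous-return resistance (systemic veins to right atrium).
#' @param r_pul pulmonary vascular resistance.
#' @param r_pvla pulmonary-vein-to-left-atrium resistance.
#' @param k_sept septal pressure-coupling coefficient (dimensionless).
#' @return An object of class `cvs_params`.
#' @export
cvs_params <- function(hr = 75, cf_lv = 0.25, f_rsys = 1,
                       ees_lv = 2.8, ed_lv = 0.09, v0_lv = 20,
                       ees_rv = 0.6, ed_rv = 0.04, v0_rv = 20,
                       c_la = 10, v0_la = 10, c_ra = 12, v0_ra = 10,
                       c_sa = 1.4, c_sv = 70, c_pa = 4.2, c_pv = 9,
                       r_mv = 0.005, r_av = 0.01, r_sys = 1.05,
                       r_vr = 0.03, r_tv = 0.005, r_pvalve = 0.005,
                       r_pul = 0.08, r_pvla = 0.01, k_sept = 0.02) {
  check_number(hr, "hr", lower = .Machine$double.xmin)
  check_number(cf_lv, "cf_lv", lower = .Machine$double.xmin, upper = 1)
  check_number(f_rsys, "f_rsys", lower = .Machine$double.xmin)
  vals <- list(ees_lv = ees_lv, ed_lv = ed_lv, v0_lv = v0_lv,
               ees_rv = ees_rv, ed_rv = ed_rv, v0_rv = v0_rv,
               c_la = c_la, v0_la = v0_la, c_ra = c_ra, v0_ra = v0_ra,
               c_sa = c_sa, c_sv = c_sv, c_pa = c_pa, c_pv = c_pv,
               r_mv = r_mv, r_av = r_av, r_sys = r_sys, r_vr = r_vr,
               r_tv = r_tv, r_pvalve = r_pvalve, r_pul = r_pul,
               r_pvla = r_pvla)
  for (nm in setdiff(names(vals), c("v0_lv", "v0_rv", "v0_la", "v0_ra")))
    check_number(vals[[nm]], nm, lower = .Machine$double.xmin)
  if (cf_lv * ees_lv <= ed_lv)
    abort("cf_lv * ees_lv must exceed ed_lv (systolic above diastolic elastance)")
  structure(c(vals, list(k_sept = k_sept, hr = hr, cf_lv = cf_lv,
                         f_rsys = f_rsys)), class = "cvs_params")
}

# double-Hill activation shape constants (fractions of the cardiac cycle)
.act_shape <- c(a1 = 0.303, n1 = 1.9, a2 = 0.508, n2 = 21.9)

#' @noRd
act_raw <- function(phase, sh = .act_shape) {
  g1 <- (phase / sh[["a1"]])^sh[["n1"]]
  g2 <- (phase / sh[["a2"]])^sh[["n2"]]
  (g1 / (1 + g1)) / (1 + g2)
}

#' @noRd
cvs_param_vector <- function(p) {
  norm <- max(act_raw(seq(0, 1, by = 1e-4)))
  c(p$ees_lv, p$ed_lv, p$v0_lv, p$ees_rv, p$ed_rv, p$v0_rv,
    p$c_la, p$v0_la, p$c_ra, p$v0_ra,
    p$c_sa, p$c_sv, p$c_pa, p$c_pv,
    p$r_mv, p$r_av, p$r_sys, p$r_vr, p$r_tv, p$r_pvalve,
    p$r_pul, p$r_pvla,
    p$k_sept, p$hr, p$cf_lv, p$f_rsys,
    .act_shape[["a1"]], .act_shape[["n1"]], .act_shape[["a2"]],
    .act_shape[["n2"]], norm)
}

#' Baseline initial compartment volumes
#'
#' Order: LV, LA, RV, RA, systemic arterial, systemic venous, pulmonary
#' arterial, pulmonary venous (mL).
#'
#' @return A named numeric vector of length 8.
#' @export
cvs_initial_volumes <- function() {
  c(lv = 160, la = 70, rv = 130, ra = 70, sa = 110, sv = 380, pa = 70,
    pv = 90)
}

#' Simulate the cardiovascular model under a prescribed LVAD flow
#'
#' Advances all eight compartments with explicit Euler at step `dt`; the
#' LVAD flow is drawn from the left ventricle and returned to the systemic
#' arterial (aortic) compartment.
#'
#' @param q_lvad LVAD flow, L/min: a scalar (constant, including 0 for the
#'   unsupported circulation) or a series with one value per step.
#' @param duration simulated time, s (used when `q_lvad` is scalar).
#' @param dt step time, s.
#' @param params a [cvs_params()] object.
#' @param v0 initial compartment volumes (mL), as [cvs_initial_volumes()].
#' @param phase0 initial cardiac phase in \[0, 1).
#' @return A tibble with columns `t`, `q_lvad`, `pao`, `plv`, `q_av`
#'   (aortic-valve flow, L/min), `volume` (total blood volume, mL), `cycle`.
#' @export
cvs_simulate <- function(q_lvad = 0, duration = 10, dt = 4e-4,
                         params = cvs_params(),
                         v0 = cvs_initial_volumes(), phase0 = 0) {
  if (length(q_lvad) == 1L)
    q_lvad <- rep(as.numeric(q_lvad), ceiling(duration / dt))
  res <- cpp_cvs_run(as.numeric(q_lvad), dt, cvs_param_vector(params),
                     as.numeric(v0), phase0)
  tibble(t = seq_along(q_lvad) * dt - dt, q_lvad = as.numeric(q_lvad),
         pao = res$pao, plv = res$plv, q_av = res$q_av,
         volume = res$volume, cycle = res$cycle)
}
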