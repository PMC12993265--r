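#' Mechanical speed-loop parameters
#'
#' The closed-loop speed dynamics from reference speed to actual speed are
#' modelled as a second-order lag (PT2) with unity DC gain and a transport
#' dead time:
#' \deqn{\frac{n(s)}{n_{ref}(s)} = \frac{1}{k_2 s^2 + k_1 s + 1}\,e^{-T_d s}}
#' Defaults are the identified Sputnik1 coefficients.
#'
#' @param k2 coefficient of \eqn{s^2} in the denominator (s^2); must be > 0.
#' @param k1 coefficient of \eqn{s} in the denominator (s); must be > 0.
#' @param dead_time transport delay in seconds; must be >= 0.
#' @return An object of class `mech_params`.
#' @examples
#' p <- mech_params()
#' # damping ratio of the default coefficients (overdamped, no overshoot)
#' p$k1 / (2 * sqrt(p$k2))
#' @export
mech_params <- function(k2 = 3.3e-6, k1 = 0.0043, dead_time = 0.002) {
  check_number(k2, "k2", lower = .Machine$double.xmin)
  check_number(k1, "k1", lower = .Machine$double.xmin)
  check_number(dead_time, "dead_time", lower = 0)
  structure(list(k2 = k2, k1 = k1, dead_time = dead_time),
            class = "mech_params")
}

#' Hydraulic pressure-flow parameters
#'
#' The pump hydraulics relate speed n (rpm), flow Q (L/min) and head
#' pressure dP (mmHg) through
#' \deqn{L\,\dot Q = a Q + b n^2 + c Q^x n^y - \Delta P}
#' Defaults are the identified Sputnik1 values.
#'
#' @param L inertance, mmHg·s·min/L; must be > 0.
#' @param a linear flow coefficient, mmHg·min/L.
#' @param b speed-squared coefficient, mmHg/rpm^2.
#' @param c cross-term coefficient, mmHg·min^x/(L^x·rpm^y).
#' @param x,y integer exponents of the cross term, each in \[-2, 4\].
#' @return An object of class `hydraulic_params`.
#' @export
hydraulic_params <- function(L = 0.74, a = -7.71, b = 1.86e-6, c = -5.49e-13,
                             x = 2L, y = 3L) {
  check_number(L, "L", lower = .Machine$double.xmin)
  check_number(a, "a"); check_number(b, "b"); check_number(c, "c")
  for (nm in c("x", "y")) {
    v <- get(nm)
    if (length(v) != 1L || !is.finite(v) || v != round(v) || v < -2 || v > 4)
      abort(sprintf("`%s` must be a single integer in [-2, 4]", nm))
  }
  structure(list(L = L, a = a, b = b, c = c, x = as.integer(x),
                 y = as.integer(y)), class = "hydraulic_params")
}

#' Exact zero-order-hold discretization of the PT2 state-space model
#'
#' Returns the discrete state matrices for step `dt` together with the
#' dead-time buffer length `round(dead_time / dt)`.
#' @noRd
discretize_mech <- function(p, dt) {
  check_number(dt, "dt", lower = .Machine$double.xmin)
  A <- matrix(c(0, -1 / p$k2, 1, -p$k1 / p$k2), 2, 2)
  B <- c(0, 1 / p$k2)
  ev <- eigen(A)
  V <- ev$vectors
  lam <- ev$values
  Vi <- solve(V)
  Ad <- Re(V %*% diag(exp(lam * dt)) %*% Vi)
  Bd <- Re(V %*% diag(expm1(lam * dt) / lam) %*% Vi %*% B)
  list(Ad = Ad, Bd = as.numeric(Bd), delay_steps = as.integer(round(p$dead_time / dt)))
}

#' Simulate the closed-loop speed response
#'
#' Advances the dead-time PT2 speed loop over a reference-speed series using
#' the exact zero-order-hold recurrence.  The state is initialized matched to
#' `n0` (steady at `n0` with a delay buffer full of `n0`), so a constant
#' reference equal to `n0` reproduces itself exactly.
#'
#' @param n_ref reference speed series, rpm.
#' @param dt sample time, s (> 0).
#' @param params a [mech_params()] object.
#' @param n0 initial actual speed, rpm; defaults to the first reference value.
#' @return A tibble with columns `t`, `n_ref`, `n`.
#' @examples
#' tr <- mech_response(rep(c(7000, 8000), each = 2500), dt = 4e-4)
#' tail(tr, 1)$n  # settled at the new reference
#' @export
mech_response <- function(n_ref, dt = 4e-4, params = mech_params(),
                          n0 = n_ref[1]) {
  if (!length(n_ref)) abort("`n_ref` must be non-empty")
  d <- discretize_mech(params, dt)
  res <- cpp_mech_run(as.numeric(n_ref), dt, d$Ad, d$Bd, c(n0, 0),
                      d$delay_steps)
  tibble(t = seq_along(n_ref) * dt - dt, n_ref = as.numeric(n_ref),
         n = res$n)
}

#' Static head pressure of the hydraulic model
#'
#' Evaluates the zero-acceleration head pressure
#' `a*Q + b*n^2 + c*Q^x*n^y` (mmHg). Vectorized over `n` and `q`.
#'
#' @param n pump speed, rpm.
#' @param q pump flow, L/min.
#' @param params a [hydraulic_params()] object.
#' @return Head pressure dP in mmHg.
#' @export
steady_head <- function(n, q, params = hydraulic_params()) {
  params$a * q + params$b * n^2 + params$c * q^params$x * n^params$y
}

#' Steady-state pump flow at a given speed and head pressure
#'
#' Inverts the static pressure-flow relation for flow.  Requires the
#' quadratic dialect `x = 2`; the root returned is the physical operating
#' branch, i.e. the root continuous with the linear solution
#' `(dP - b*n^2)/a` as `c -> 0`.
#'
#' @param n pump speed, rpm.
#' @param dp head pressure, mmHg.
#' @param params a [hydraulic_params()] object with `x = 2`.
#' @return Steady flow in L/min.
#' @examples
#' steady_flow(8000, steady_head(8000, 5))  # recovers 5 L/min
#' @export
steady_flow <- function(n, dp, params = hydraulic_params()) {
  if (params$x != 2L)
    abort("steady_flow() requires the quadratic flow exponent x = 2")
  A <- params$c * n^params$y
  B <- params$a
  C <- params$b * n^2 - dp
  disc <- B^2 - 4 * A * C
  if (any(disc < 0))
    abort("no real operating point for the requested (n, dP)")
  # Citardauq form: continuous in A as c -> 0 (then Q = -C/B)
  denom <- -B + sqrt(disc)
  if (any(denom == 0))
    abort("no operating point: degenerate quadratic")
  2 * C / denom
}

#' Simulate the hydraulic flow dynamics
#'
#' Integrates `L dQ/dt = a Q + b n^2 + c Q^x n^y - dP` with explicit Euler
#' at step `dt` over prescribed speed and head-pressure series.
#'
#' @param n speed series, rpm.
#' @param dp head-pressure series, mmHg.
#' @param dt step time, s.
#' @param params a [hydraulic_params()] object.
#' @param q0 initial flow, L/min; defaults to the steady flow at the first
#'   sample.
#' @return A tibble with columns `t`, `n`, `dp`, `q`.
#' @export
hydraulic_response <- function(n, dp, dt = 4e-4, params = hydraulic_params(),
                               q0 = NULL) {
  if (length(n) != length(dp)) abort("`n` and `dp` must have equal length")
  if (!all(is.finite(n)) || !all(is.finite(dp)))
    abort("`n` and `dp` must be finite")
  check_number(dt, "dt", lower = .Machine$double.xmin)
  if (is.null(q0)) q0 <- steady_flow(n[1], dp[1], params)
  res <- cpp_hyd_run(as.numeric(n), as.numeric(dp), dt, params$L, params$a,
                     params$b, params$c, params$x, params$y, q0)
  tibble(t = seq_along(n) * dt - dt, n = as.numeric(n),
         dp = as.numeric(dp), q = res$q)
}

#' Identify hydraulic parameters from bench data
#'
#' Grid search over the integer exponents (x, y), each ranging over
#' \[-2, 4\].  For each exponent pair the linear parameters (L, a, b, c) are
#' identified by linear least squares on the head-pressure residual of the
#' flow ODE, with `dQ/dt` obtained by central finite differences.  Each
#' candidate model is then re-simulated over the bench series (flow
#' integrated from the measured speed and head pressure) and the pair with
#' the smallest flow RMSE is selected.
#'
#' @param bench a data frame with columns `t_s`, `n_rpm`, `Q_lpm`, `dP_mmHg`
#'   sampled uniformly in time (see [generate_bench_data()]).
#' @param x_grid,y_grid integer exponent candidates.
#' @return An object of class `hydraulic_fit`: a list with elements
#'   `params` (the selected [hydraulic_params()]), `report` (a tibble of all
#'   candidate fits with their pressure and flow RMSEs) and `n_obs`.
#' @seealso [tidy.hydraulic_fit()], [glance.hydraulic_fit()]
#' @export
identify_hydraulic <- function(bench, x_grid = -2:4, y_grid = -2:4) {
  check_columns(bench, c("t_s", "n_rpm", "Q_lpm", "dP_mmHg"), "bench dataset")
  t <- bench$t_s; n <- bench$n_rpm; q <- bench$Q_lpm; dp <- bench$dP_mmHg
  if (is.unsorted(t, strictly = TRUE))
    abort("bench time stamps must be strictly increasing")
  steps <- diff(t)
  dt <- median(steps)
  if (max(abs(steps - dt)) > 1e-6 * dt)
    abort("bench dataset must be uniformly sampled")
  if (sd(n) == 0 || sd(q) == 0)
    abort(paste("bench dataset is not identifiable: speed and flow must",
                "both vary (constant-condition design is rank deficient)"))
  dqdt <- finite_diff(q, dt)

  rows <- list()
  for (x in x_grid) for (y in y_grid) {
    cross <- q^x * n^y
    X <- cbind(q = q, n2 = n^2, cross = cross, mdqdt = -dqdt)
    if (!all(is.finite(cross))) next
    fit <- lm.fit(X, dp)
    if (fit$rank < 4L) next  # collinear candidate (e.g. x=1,y=0)
    cf <- fit$coefficients
    L <- cf[["mdqdt"]]
    rmse_dp <- sqrt(mean(fit$residuals^2))
    rmse_q <- Inf
    if (is.finite(L) && L > 0) {
      sim <- tryCatch(
        cpp_hyd_run(n, dp, dt, L, cf[["q"]], cf[["n2"]], cf[["cross"]],
                    x, y, q[1]),
        error = function(e) NULL)
      if (!is.null(sim)) rmse_q <- sqrt(mean((sim$q - q)^2))
    }
    rows[[length(rows) + 1L]] <- tibble(
      x = as.integer(x), y = as.integer(y), L = L, a = cf[["q"]],
      b = cf[["n2"]], c = cf[["cross"]], rmse_dp = rmse_dp, rmse_q = rmse_q)
  }
  if (!length(rows))
    abort("no identifiable exponent pair: check the bench dataset")
  report <- dplyr::arrange(dplyr::bind_rows(rows), .data$rmse_q)
  best <- report[1L, ]
  if (!is.finite(best$rmse_q))
    abort("no candidate model could be simulated stably: identification failed")
  structure(
    list(params = hydraulic_params(L = best$L, a = best$a, b = best$b,
                                   c = best$c, x = best$x, y = best$y),
         report = report, n_obs = length(t), dt = dt),
    class = "hydraulic_fit")
}

#' @export
print.hydraulic_fit <- function(x, ...) {
  p <- x$params
  cat("Hydraulic model identification (", x$n_obs, " samples)\n", sep = "")
  cat(sprintf("  selected exponents: x = %d, y = %d\n", p$x, p$y))
  cat(sprintf("  L = %.4g mmHg*s*min/L, a = %.4g, b = %.4g, c = %.4g\n",
              p$L, p$a, p$b, p$c))
  cat(sprintf("  RMSE: %.3g mmHg (dP), %.3g L/min (Q)\n",
              x$report$rmse_dp[1], x$report$rmse_q[1]))
  invisible(x)
}

#' Tidy the hydraulic identification report
#'
#' @param x a `hydraulic_fit` object.
#' @param ... unused.
#' @return A tibble with one row per exponent candidate (x, y, L, a, b, c,
#'   rmse_dp, rmse_q), best first.
#' @method tidy hydraulic_fit
#' @export
tidy.hydraulic_fit <- function(x, ...) x$report

#' One-row summary of a hydraulic identification
#'
#' @param x a `hydraulic_fit` object.
#' @param ... unused.
#' @method glance hydraulic_fit
#' @export
glance.hydraulic_fit <- function(x, ...) {
  best <- x$report[1L, ]
  n_obs <- x$n_obs
  tibble(x = best$x, y = best$y, rmse_dp = best$rmse_dp,
         rmse_q = best$rmse_q, n_obs = n_obs)
}
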