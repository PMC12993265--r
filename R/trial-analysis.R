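#' Per-interval hemolysis rate index from hourly blood samples
#'
#' For each interval between consecutive samples the hemolysis rate index is
#' \deqn{HRI = \frac{\Delta pfHb}{Hb} \cdot 100 \cdot \frac{V}{\Delta T}
#'   \cdot \frac{100 - HCT}{100}}
#' with pfHb in mg/dL and Hb in g/dL (converted to mg/dL before the ratio).
#' Loop volume `V` (mL), hematocrit and Hb are taken at the interval start.
#' Negative pfHb increments are permitted (assay noise) but flagged.
#'
#' @param samples a data frame for one trial with columns `t_h`,
#'   `pfHb_mg_dl`, `Hb_g_dl`, `HCT_pct`, `V_ml`, time-ordered.
#' @return A tibble with one row per interval: `t_start`, `t_end`, `hri`
#'   (%·mL/h) and `negative_delta`.
#' @examples
#' s <- tibble::tibble(t_h = 0:1, pfHb_mg_dl = c(5, 25), Hb_g_dl = 10,
#'                     HCT_pct = 35, V_ml = 450)
#' hri_intervals(s)$hri  # 58.5
#' @export
hri_intervals <- function(samples) {
  check_columns(samples, c("t_h", "pfHb_mg_dl", "Hb_g_dl", "HCT_pct", "V_ml"),
                "blood-sample series")
  if (nrow(samples) < 2L)
    abort("at least two blood samples are needed to form an interval")
  if (is.unsorted(samples$t_h, strictly = TRUE))
    abort("blood samples must be strictly time-ordered")
  with(samples, {
    if (any(HCT_pct <= 0 | HCT_pct >= 100)) abort("HCT must be in (0, 100) %")
    if (any(Hb_g_dl <= 0)) abort("Hb must be positive")
    if (any(V_ml <= 0)) abort("loop volume must be positive")
  })
  k <- nrow(samples)
  dpf <- diff(samples$pfHb_mg_dl)
  dtv <- diff(samples$t_h)
  hb_mg <- samples$Hb_g_dl[-k] * 1000
  tibble(
    t_start = samples$t_h[-k], t_end = samples$t_h[-1],
    hri = dpf / hb_mg * 100 * samples$V_ml[-k] / dtv *
      (100 - samples$HCT_pct[-k]) / 100,
    negative_delta = dpf < 0)
}

#' Trial-level HRI from a table of hourly blood samples
#'
#' Applies [hri_intervals()] per trial (one trial = one combination of
#' `device_id`, `n_rpm`, `Q_lpm`) and averages the interval values, giving
#' one HRI per constant-condition trial.
#'
#' @param samples a data frame in the trial CSV schema: `device_id`,
#'   `n_rpm`, `Q_lpm`, `t_h`, `pfHb_mg_dl`, `Hb_g_dl`, `HCT_pct`, `V_ml`.
#' @return A tibble with one row per trial: `device_id`, `n_rpm`, `Q_lpm`,
#'   `hri`, `n_intervals`, `n_negative`.
#' @export
trial_hri <- function(samples) {
  check_columns(samples, c("device_id", "n_rpm", "Q_lpm", "t_h",
                           "pfHb_mg_dl", "Hb_g_dl", "HCT_pct", "V_ml"),
                "trial sample table")
  out <- samples |>
    dplyr::group_by(.data$device_id, .data$n_rpm, .data$Q_lpm) |>
    dplyr::group_modify(function(d, key) {
      iv <- hri_intervals(d)
      tibble(hri = mean(iv$hri), n_intervals = nrow(iv),
             n_negative = sum(iv$negative_delta))
    }) |>
    dplyr::ungroup()
  if (any(out$n_negative > 0))
    warn(sprintf("%d trial(s) contain intervals with decreasing pfHb",
                 sum(out$n_negative > 0)))
  out
}

#' Standardize trial HRIs across devices
#'
#' Device-to-device hemolysis magnitudes differ even for identical pump
#' builds; before pooling, each device's HRI values are divided by that
#' device's mean HRI and multiplied by the common scaling constant
#' `hri_bar`, so every device's mean maps onto `hri_bar`.
#'
#' @param trials a data frame with columns `device_id` and `hri`.
#' @param hri_bar the common HRI scaling constant, %·mL/h; defaults to the
#'   grand mean of `hri`.
#' @return The input with an added column `hri_std`.
#' @export
standardize_hri <- function(trials, hri_bar = mean(trials$hri)) {
  check_columns(trials, c("device_id", "hri"), "trial table")
  out <- trials |>
    dplyr::group_by(.data$device_id) |>
    dplyr::mutate(.dev_mean = mean(.data$hri)) |>
    dplyr::ungroup()
  if (any(out$.dev_mean <= 0))
    abort("standardization failed: a device has non-positive mean HRI")
  out |>
    dplyr::mutate(hri_std = .data$hri / .data$.dev_mean * hri_bar) |>
    dplyr::select(-".dev_mean")
}

#' Robust power-law fit to standardized trial HRIs
#'
#' Fits the modified power law
#' `hri = hri_bar * c2 * (Q/q_bar)^a2 * (n/n_bar)^b2` on the linear
#' (untransformed) scale by iteratively reweighted nonlinear least squares
#' with Tukey bisquare weights (tuning constant 4.685), starting from an
#' ordinary log-log linear regression.  RMSE and R² are reported on the
#' data with unit weights.
#'
#' @param trials a data frame with columns `n_rpm`, `Q_lpm` and the HRI
#'   response named by `hri_col`.
#' @param q_bar,n_bar,hri_bar scaling constants; default to the data means.
#' @param hri_col name of the response column (use `"hri_std"` after
#'   [standardize_hri()]).
#' @param max_iter maximum reweighting iterations.
#' @return An object of class `power_law_fit` with elements `params`
#'   (a [power_law_params()] object), `rmse`, `r2`, `weights`, `fitted`,
#'   `data`, `iterations`, `converged`.
#' @seealso [tidy.power_law_fit()], [glance.power_law_fit()],
#'   [autoplot.power_law_fit()]
#' @export
fit_power_law <- function(trials, q_bar = mean(trials$Q_lpm),
                          n_bar = mean(trials$n_rpm),
                          hri_bar = NULL, hri_col = "hri",
                          max_iter = 50L) {
  check_columns(trials, c("n_rpm", "Q_lpm", hri_col), "trial table")
  q <- trials$Q_lpm; n <- trials$n_rpm; y <- trials[[hri_col]]
  if (is.null(hri_bar)) hri_bar <- mean(y)
  pts <- unique(cbind(q, n))
  if (nrow(pts) < 4L)
    abort("need at least 4 distinct (Q, n) operating points to fit")
  # a constant axis makes its exponent unidentifiable (and its gradient
  # exactly singular): warn and fit with that exponent fixed at 0
  fix_a2 <- sd(q) == 0
  fix_b2 <- sd(n) == 0
  if (fix_a2)
    warn("all trials share one flow rate: the flow exponent a2 is unidentifiable")
  if (fix_b2)
    warn("all trials share one speed: the speed exponent b2 is unidentifiable")

  # log-log start (positive responses only)
  pos <- y > 0
  if (sum(pos) < 4L) abort("too few positive HRI values to fit")
  ll <- lm(log(y[pos] / hri_bar) ~ log(q[pos] / q_bar) + log(n[pos] / n_bar))
  start <- list(c2 = exp(coef(ll)[[1]]), a2 = coef(ll)[[2]],
                b2 = coef(ll)[[3]])
  start <- lapply(start, function(v) if (is.finite(v)) v else 0)
  if (fix_a2) start$a2 <- NULL
  if (fix_b2) start$b2 <- NULL
  form <- y ~ hri_bar * c2 * (q / q_bar)^a2 * (n / n_bar)^b2
  if (fix_a2) form <- y ~ hri_bar * c2 * (n / n_bar)^b2
  if (fix_b2) form <- y ~ hri_bar * c2 * (q / q_bar)^a2
  if (fix_a2 && fix_b2) form <- y ~ hri_bar * c2

  dat <- data.frame(y = y, q = q, n = n)
  w <- rep(1, length(y))
  fit <- NULL
  converged <- FALSE
  iter <- 0L
  prev <- unlist(start)
  for (iter in seq_len(max_iter)) {
    fit <- minpack.lm::nlsLM(
      form, data = dat, start = start, weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 200))
    start <- as.list(coef(fit))
    # convergence on the coefficients, not the weights: near-clean data
    # leaves individual bisquare weights dithering while the estimate is
    # long settled
    delta <- max(abs(unlist(start) - prev) / pmax(abs(prev), 1e-8))
    prev <- unlist(start)
    if (iter > 1L && delta < 1e-6) {
      converged <- TRUE
      break
    }
    r <- y - predict(fit, dat)
    s <- median(abs(r - median(r))) / 0.6745
    if (s <= .Machine$double.eps^0.5 * max(abs(y))) {
      converged <- TRUE  # essentially perfect fit; weights are moot
      w <- rep(1, length(y))
      break
    }
    u <- r / (4.685 * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  }
  if (!converged)
    warn(sprintf("bisquare reweighting did not settle within %d iterations",
                 max_iter))
  cf <- coef(fit)
  params <- power_law_params(
    c2 = cf[["c2"]],
    a2 = if (fix_a2) 0 else cf[["a2"]],
    b2 = if (fix_b2) 0 else cf[["b2"]],
    hri_bar = hri_bar, q_bar = q_bar, n_bar = n_bar)
  fitted <- static_hri(q, n, params)
  r <- y - fitted
  structure(list(
    params = params,
    rmse = sqrt(mean(r^2)),
    r2 = 1 - sum(r^2) / sum((y - mean(y))^2),
    weights = w, fitted = fitted,
    data = tibble(Q_lpm = q, n_rpm = n, hri = y, fitted = fitted,
                  weight = w),
    iterations = iter, converged = converged, nls = fit),
    class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  p <- x$params
  cat("Modified power-law fit (bisquare IRLS, ", x$iterations,
      " iteration(s))\n", sep = "")
  cat(sprintf("  c2 = %.4g, a2 = %.4g, b2 = %.4g\n", p$c2, p$a2, p$b2))
  cat(sprintf("  scaling: hri_bar = %.4g %%*mL/h, q_bar = %.4g L/min, n_bar = %.4g rpm\n",
              p$hri_bar, p$q_bar, p$n_bar))
  cat(sprintf("  RMSE = %.4g %%*mL/h, R2 = %.3f (n = %d)\n", x$rmse, x$r2,
              nrow(x$data)))
  invisible(x)
}

#' Tidy a power-law fit
#'
#' @param x a `power_law_fit` object.
#' @param ... unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`.
#' @method tidy power_law_fit
#' @export
tidy.power_law_fit <- function(x, ...) {
  sm <- summary(x$nls)$coefficients
  tibble(term = rownames(sm), estimate = sm[, "Estimate"],
         std.error = sm[, "Std. Error"])
}

#' One-row summary of a power-law fit
#'
#' @param x a `power_law_fit` object.
#' @param ... unused.
#' @method glance power_law_fit
#' @export
glance.power_law_fit <- function(x, ...) {
  tibble(rmse = x$rmse, r2 = x$r2, n_obs = nrow(x$data),
         iterations = x$iterations, converged = x$converged,
         min_weight = min(x$weights))
}

#' Plot a power-law fit against the trial data
#'
#' Standardized trial HRIs against flow, one fitted curve per observed
#' speed; down-weighted points (bisquare weight < 0.5) are hollow.
#'
#' @param object a `power_law_fit` object.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot power_law_fit
#' @export
autoplot.power_law_fit <- function(object, ...) {
  d <- object$data
  speeds <- sort(unique(d$n_rpm))
  curves <- purrr::map_dfr(speeds, function(nn) {
    qq <- seq(min(d$Q_lpm), max(d$Q_lpm), length.out = 80)
    tibble(Q_lpm = qq, n_rpm = nn,
           hri = static_hri(qq, nn, object$params))
  })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$Q_lpm, colour = factor(.data$n_rpm))) +
    ggplot2::geom_line(data = curves, ggplot2::aes(y = .data$hri)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$hri,
                                     shape = .data$weight < 0.5), size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                guide = "none") +
    ggplot2::labs(x = "pump flow (L/min)", y = "HRI (%*mL/h)",
                  colour = "speed (rpm)") +
    ggplot2::theme_minimal()
}

#' Convert a Modified Index of Hemolysis to an HRI
#'
#' The MIH obtained from a constant-flow in vitro study is comparable to an
#' HRI after multiplication by the constant pump flow and a factor of 6.
#'
#' @param mih Modified Index of Hemolysis (dimensionless).
#' @param q_const constant pump flow of the study, L/min (> 0).
#' @return HRI in %·mL/h.
#' @export
mih_to_hri <- function(mih, q_const) {
  if (any(q_const <= 0)) abort("`q_const` must be positive")
  mih * q_const * 6
}
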