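# Shared model objects and small analytic oracles used across test files.

plp <- power_law_params()
geom <- impeller_geometry()
rp <- reduce_params(plp, geom)
DT <- 4e-4

# correction factor at the default step, computed once per test run
f_cal <- calibrate_f(dt = DT)

# closed-form segment-wise composition of the effective-time accumulation:
# segs is a list of list(n = speed, tau = duration in s); returns the final
# damage of a particle experiencing those segments in order.
compose_segments <- function(segs, rp) {
  h <- 0
  for (s in segs) {
    nb <- s$n^rp$b2
    te <- if (h > 0) (h / (rp$c2_hat * nb))^(1 / rp$a2_hat) else 0
    h <- rp$c2_hat * (te + s$tau)^rp$a2_hat * nb
  }
  h
}

# analytic unit step response of the overdamped PT2 with dead time
mech_step_analytic <- function(t, p = mech_params()) {
  disc <- sqrt(p$k1^2 - 4 * p$k2)
  p1 <- (-p$k1 + disc) / (2 * p$k2)
  p2 <- (-p$k1 - disc) / (2 * p$k2)
  ts <- pmax(t - p$dead_time, 0)
  ifelse(t < p$dead_time, 0,
         1 - (p2 * exp(p1 * ts) - p1 * exp(p2 * ts)) / (p2 - p1))
}
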