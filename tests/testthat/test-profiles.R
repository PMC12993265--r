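test_that("profile construction anchors the mean and respects bounds", {
  # zero amplitude degenerates to a constant profile
  p0 <- generate_profile(modulation_spec(7500, 0), t_cycle = 0.8, dt = DT)
  expect_equal(p0$n_ref, rep(7500, 2000), tolerance = 1e-12)
  # boundary-feasible construction
  sp <- modulation_spec(7500, 3000, duty = 0.5)
  expect_equal(sp$n_high, 9000)
  expect_equal(sp$n_low, 6000)
  # asymmetric duty still yields the exact mean
  for (duty in c(0.25, 0.5, 0.7)) {
    sp <- modulation_spec(7000, 1200, duty = duty, cutoff = 5)
    prof <- generate_profile(sp, t_cycle = 0.8, dt = DT)
    expect_lt(abs(mean(prof$n_ref) - 7000), 0.1)
  }
  expect_error(modulation_spec(8500, 3000, duty = 0.5), "upper bound")
  expect_error(modulation_spec(6500, 3000, duty = 0.75), "lower bound")
})

test_that("phase shift is a pure rotation and the cycle wraps continuously", {
  sp0 <- modulation_spec(7500, 2000, duty = 0.4, phase = 0, cutoff = 5)
  sp1 <- modulation_spec(7500, 2000, duty = 0.4, phase = 0.35, cutoff = 5)
  a <- generate_profile(sp0, dt = DT)$n_ref
  b <- generate_profile(sp1, dt = DT)$n_ref
  expect_equal(sort(a), sort(b), tolerance = 1e-12)
  # periodic steady state: with the switching edge rotated away from the
  # cycle boundary, the wrap step is no larger than the largest interior step
  wrap <- abs(b[1] - b[length(b)])
  expect_lte(wrap, max(abs(diff(b))) + 1e-9)
})

test_that("cutoff frequency shapes the harmonic content as intended", {
  harmonic_ratio <- function(x) {
    sp <- Mod(stats::fft(x - mean(x)))[2:41]  # fundamental + 39 harmonics
    sum(sp[-1]) / sp[1]
  }
  filt <- function(cutoff)
    harmonic_ratio(generate_profile(modulation_spec(7500, 2000,
                                                    cutoff = cutoff),
                                    dt = DT)$n_ref)
  raw <- harmonic_ratio(c(rep(8500, 1000), rep(6500, 1000)))
  # 20 Hz stays near-rectangular: most of the harmonic content survives
  expect_gt(filt(20) / raw, 0.75)
  # 2 Hz is almost sinusoidal: the bulk of the harmonic content is gone,
  # and the above-fundamental content is attenuated several-fold more than
  # at 20 Hz (the one-pole rolloff bounds this factor by the cutoff ratio)
  expect_lt(filt(2) / raw, 0.3)
  expect_gt((raw / filt(2)) / (raw / filt(20)), 3)
})

test_that("the sweep enumerator emits exactly the feasible grid", {
  sw <- enumerate_sweep(duty_grid = c(0.25, 0.5, 0.75),
                        phase_grid = c(0, 0.5))
  expect_true(all(sw$n_high <= 9000))
  expect_true(all(sw$n_low >= 6000))
  # mean 8500, amplitude 3000, duty 0.5 -> n_high 10000: excluded
  expect_false(any(sw$mean_speed == 8500 & sw$amplitude == 3000 &
                     sw$duty == 0.5))
  # mean 7500, amplitude 500 is feasible at every duty
  sub <- dplyr::filter(sw, mean_speed == 7500, amplitude == 500)
  expect_equal(nrow(sub), 3 * 2 * 3)  # duty x phase x cutoff
})
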