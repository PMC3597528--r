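mk_trace <- function(y, dt = 0.1, vrest = -65, onset = 100) {
  rgc_trace(y, dt = dt, vrest = vrest,
            annotations = list(stimuli = data.frame(onset = onset,
                                                    duration = 0)))
}

test_that("summation ratios follow their definition", {
  f <- make_summation_fixture(1, "charge", noise_sd = 0)
  expect_equal(summation_ratio(f$summed, f$single, 3, "charge"), 1,
               tolerance = 1e-6)

  # exact superposition of three shifted singles is linear at any delay
  for (delay in c(10, 50, 110)) {
    t <- seq(0, 1500, by = 0.1)
    one <- function(on) ifelse(t > on, exp(-(t - on) / 109) -
                                 exp(-(t - on) / 35), 0)
    s3 <- one(100) + one(100 + delay) + one(100 + 2 * delay)
    expect_equal(summation_ratio(mk_trace(-65 + s3), mk_trace(-65 + one(100)),
                                 3, "charge"), 1, tolerance = 1e-3)
  }

  # charge 4.17x a single, three pulses -> ratio 1.39
  single <- make_epsp(noise_sd = 0)
  summed <- single
  summed$values <- -65 + (single$values + 65) * 4.17
  expect_equal(summation_ratio(summed, single, 3, "charge"), 4.17 / 3,
               tolerance = 1e-9)

  flat <- mk_trace(rep(-65, 5000))
  expect_error(summation_ratio(flat, flat, 3, "charge"), "undefined")
})

test_that("summation ratio is invariant to a shared baseline offset", {
  f <- make_summation_fixture(1.25, "charge", noise_sd = 0)
  r0 <- summation_ratio(f$summed, f$single, 3, "charge")
  f$summed$values <- f$summed$values + 7
  f$summed$vrest <- f$summed$vrest + 7
  f$single$values <- f$single$values + 7
  f$single$vrest <- f$single$vrest + 7
  expect_equal(summation_ratio(f$summed, f$single, 3, "charge"), r0,
               tolerance = 1e-9)
})

test_that("directional selectivity implements the printed formulas", {
  tr <- make_epsp(noise_sd = 0)
  expect_equal(directional_selectivity(tr, tr, "amplitude"), 0)
  expect_equal(directional_selectivity(tr, tr, "charge"), 0)

  away <- mk_trace(c(rep(-66, 500), rep(-60, 100), rep(-66, 500)),
                   vrest = -66, onset = 10)
  toward <- mk_trace(c(rep(-66, 500), rep(-61, 100), rep(-66, 500)),
                     vrest = -66, onset = 10)
  # (Vpeak_away - Vpeak_toward)/(Vpeak_toward - Vrest) * 100 = (1/5)*100
  expect_equal(directional_selectivity(away, toward, "amplitude"), 20)

  # charge mode: (1.2 - 1.0)/1.0 * 100
  q_away <- away; q_away$values <- -66 + (away$values + 66) * 1.2 / 1.0
  expect_equal(directional_selectivity(q_away, away, "charge"), 20,
               tolerance = 1e-9)
})

test_that("charge-mode DS obeys its exact antisymmetry relation", {
  set.seed(4)
  for (i in 1:5) {
    a <- make_epsp(amplitude = runif(1, 1, 4), noise_sd = 0.05,
                   seed = i)
    b <- make_epsp(amplitude = runif(1, 1, 4), noise_sd = 0.05,
                   seed = i + 100)
    qa <- charge(a)
    qb <- charge(b)
    ds_ab <- directional_selectivity(a, b, "charge")
    ds_ba <- directional_selectivity(b, a, "charge")
    expect_equal(ds_ab, -ds_ba * qa / qb, tolerance = 1e-9)
  }
})

test_that("EPSP kinetics recover the parameters of ideal waveforms", {
  tr <- make_epsp(amplitude = 3, tau_rise = 20, tau_fall = 120,
                  noise_sd = 0, sample_rate = 50)
  k <- epsp_kinetics(tr)
  # independent oracle: dense-grid evaluation of the analytic waveform
  tt <- seq(0, 2000, by = 1e-3)
  w <- exp(-tt / 120) - exp(-tt / 20)
  w <- w / max(w)
  t10 <- tt[min(which(w >= 0.1))]
  t90 <- tt[min(which(w >= 0.9))]
  expect_equal(k$rise_10_90, t90 - t10, tolerance = 0.01)
  expect_equal(k$peak, 3, tolerance = 1e-6)
  # the falling phase of the slow/fast bi-exponential is close to, but a
  # little faster than, the slow time constant
  expect_equal(k$decay_tau, 120, tolerance = 0.05)

  # scale invariance
  tr2 <- tr
  tr2$values <- -65 + (tr$values + 65) * 2.5
  k2 <- epsp_kinetics(tr2)
  expect_equal(k2$rise_10_90, k$rise_10_90)
  expect_equal(k2$decay_tau, k$decay_tau)

  # a pure step rises within one sample
  step <- mk_trace(c(rep(-65, 1000), rep(-60, 2000)), dt = 0.1, onset = 50)
  expect_lt(epsp_kinetics(step)$rise_10_90, 0.1 + 1e-9)

  expect_error(epsp_kinetics(mk_trace(rep(-65, 100) - (1:100) * 0.01)),
               "peak")
})

test_that("spike probability counts suprathreshold trials", {
  ramp <- function(to) c(rep(-65, 100), seq(-65, to, length.out = 200),
                         rep(to, 100))
  sub <- mk_trace(ramp(-60))      # slow subthreshold depolarization
  supra <- mk_trace(ramp(-10))    # crosses the -20 mV threshold
  trials <- c(rep(list(sub), 6), rep(list(supra), 2))
  expect_equal(spike_probability(trials), 0.25)
  expect_equal(spike_probability(list(sub, sub)), 0)
})

test_that("the Gaussian resolution fit returns the half-maximal width", {
  x <- seq(-8, 8, by = 1)
  amp <- 120 * exp(-x^2 / (2 * 2.42^2))
  fit <- gaussian_resolution_fit(x, amp)
  expect_equal(fit$fwhm, 2 * sqrt(2 * log(2)) * 2.42, tolerance = 1e-6)
  expect_equal(fit$fwhm, 5.7, tolerance = 0.01)

  # translation invariance
  fit2 <- gaussian_resolution_fit(x + 13.7, amp)
  expect_equal(fit2$fwhm, fit$fwhm, tolerance = 1e-6)
  expect_equal(fit2$mu, fit$mu + 13.7, tolerance = 1e-6)

  expect_error(gaussian_resolution_fit(x, rep(1, length(x))), "degenerate")
  expect_error(gaussian_resolution_fit(1:3, 1:3), "at least 4")
})

test_that("tail-current analysis nulls identical families and normalizes", {
  t <- seq(0, 500, by = 0.5)
  mk_i <- function(amp) rgc_trace(amp * exp(-pmax(t - 400, 0) / 40) *
                                    (t >= 100), dt = 0.5, unit = "nA")
  control <- lapply(c(-1, -0.5, -0.1), mk_i)
  expect_error(tail_current_iv(control, control[1:2], c(-100, -70, -40),
                               100, 400), "mismatched")
  iv0 <- tail_current_iv(control, control, c(-100, -70, -40), 100, 400)
  expect_true(all(iv0$tail == 0))

  blocked <- lapply(c(0, 0, 0), mk_i)
  iv <- tail_current_iv(control, blocked, c(-100, -70, -40), 100, 400)
  expect_equal(max(iv$tail_norm), 1)
  expect_equal(iv$tail_norm[1], 1)
  expect_lt(iv$tail_norm[3], iv$tail_norm[2])
})

test_that("stored DS statistics are reproducible from the stored traces", {
  ds <- cached("ds_full_distal",
               run_direction_pair(std_model(), select_sites(std_model(), "distal"),
                                  state = std_eq()$state))
  expect_equal(directional_selectivity(ds$away, ds$toward, "amplitude",
                                       ds$vrest),
               ds$ds_amplitude)
  expect_equal(directional_selectivity(ds$away, ds$toward, "charge",
                                       ds$vrest),
               ds$ds_charge)
  expect_equal(max(ds$away$values), ds$vpeak_away)
  expect_equal(charge(ds$away, baseline = ds$vrest), ds$charge_away)
})
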