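test_that("an isopotential patch follows the analytic RC charging curve", {
  m <- standard_model(0, include = character(0))   # soma only, leak only
  eq <- equilibrate(m)
  r <- advance(m, eq$state, 150, record_dt = 0.5,
               i_inj = data.frame(compartment_id = 1, amp = 0.01))
  tr <- r$traces[[1]]
  t_rel <- trace_time(tr) - eq$state$t
  g <- m$morphology$compartments$area[1] * 1e6 / 28000   # uS
  tau_m <- 28  # Rm * Cm = 28000 ohm cm2 * 1 uF/cm2 = 28 ms
  pred <- -68 + 0.01 / g * (1 - exp(-t_rel / tau_m))
  expect_lt(max(abs(tr$values - pred)) / (0.01 / g), 0.01)
})

test_that("an equilibrated state is a fixed point of the dynamics", {
  eq <- equilibrate(passive_model(), tol = 1e-10, max_duration = 60000)
  r <- advance(passive_model(), eq$state, 1000)
  expect_lt(max(abs(r$traces[[1]]$values - eq$vrest)), 1e-6)
})

test_that("steady-state attenuation matches the sealed-end cable solution", {
  m <- standard_model(400, diameter = 0.6, include = character(0))
  # remove synapses so the cable is purely passive
  m <- rgc_model(m$morphology, m$channels,
                 synapse_model(g_max = 0), dt = m$dt)
  eq <- equilibrate(m)
  r <- advance(m, eq$state, 600, record_dt = 5,
               i_inj = data.frame(compartment_id = 1, amp = 0.005))
  st <- r$state
  cc <- m$morphology$compartments
  lam <- space_constant(0.6, 28000, 200)
  L <- 400 / lam
  x <- cc$path_distance[-1] / lam
  v_rel <- (st$v[-1] - (-68)) / (st$v[2] - (-68))
  pred <- cosh(L - x) / cosh(L - x[1])
  expect_lt(max(abs(v_rel - pred)), 0.01)
})

test_that("passive summation is linear and transfer is reciprocal", {
  m <- passive_model()
  eq <- passive_eq()
  s2 <- sites_near(m, c(100, 300))
  one <- function(sites) {
    r <- advance(m, eq$state, 500,
                 stimuli = data.frame(site = sites, onset = 50,
                                      duration = 3, contrast = 10))
    r$traces[[1]]$values - eq$vrest
  }
  va <- one(s2[1]); vb <- one(s2[2]); vab <- one(s2)
  expect_lt(max(abs(vab - (va + vb))) / max(vab), 0.02)

  # reciprocity: voltage at B from current at A equals voltage at A from
  # current at B
  ca <- m$synapse_sites$compartment_id[s2[1]]
  cb <- m$synapse_sites$compartment_id[s2[2]]
  ia <- match(ca, m$morphology$compartments$id)
  ib <- match(cb, m$morphology$compartments$id)
  rab <- advance(m, eq$state, 400, record = cb,
                 i_inj = data.frame(compartment_id = ca, amp = 0.002))
  rba <- advance(m, eq$state, 400, record = ca,
                 i_inj = data.frame(compartment_id = cb, amp = 0.002))
  # compare the perturbations about each site's own resting level
  expect_equal(rab$traces[[1]]$values - eq$state$v[ib],
               rba$traces[[1]]$values - eq$state$v[ia],
               tolerance = 1e-6)
})

test_that("gate variables relax to their closed-form equilibria under clamp", {
  m <- std_model()
  tip <- nrow(m$morphology$compartments)   # distal tip carries all channels
  tip_id <- m$morphology$compartments$id[tip]
  r <- advance(m, init_state(m, -68), 2500,
               clamp = list(compartment_id = tip_id, v = -55))
  st <- r$state
  expect_equal(unname(st$gates[tip, ]),
               unname(gating_steady_state(-55, m$channels)),
               tolerance = 1e-4)
  expect_true(all(st$gates >= 0 & st$gates <= 1))
})

test_that("save/restore reproduces trajectories exactly", {
  m <- std_model()
  eq <- std_eq()
  snap <- save_state(eq$state)
  stim <- data.frame(site = sites_near(m, 200), onset = 50, duration = 3)
  r1 <- advance(m, restore_state(m, snap), 400, stimuli = stim)
  r2 <- advance(m, restore_state(m, snap), 400, stimuli = stim)
  expect_identical(r1$traces[[1]]$values, r2$traces[[1]]$values)

  # disk round trip continues identically
  tf <- withr::local_tempfile(fileext = ".rds")
  save_state_file(eq$state, tf)
  r3 <- advance(m, restore_state(m, load_state_file(tf)), 400,
                stimuli = stim)
  expect_identical(r3$traces[[1]]$values, r1$traces[[1]]$values)

  # a snapshot from a different model is rejected
  other <- standard_model(200)
  expect_error(restore_state(other, snap), "does not match")
})

test_that("without restore a preceding stimulus alters the next response", {
  m <- std_model()
  eq <- std_eq()
  sites <- select_sites(m, "middle")
  with_restore <- run_direction_pair(m, sites, use_restore = TRUE,
                                     do_singles = FALSE, state = eq$state)
  without <- run_direction_pair(m, sites, use_restore = FALSE, tail = 300,
                                do_singles = FALSE, state = eq$state)
  # direction 2 runs ~460 ms after direction 1 without restore; the
  # lingering first response changes the second measurably
  expect_gt(abs(without$vpeak_toward - with_restore$vpeak_toward), 0.05)
  expect_equal(with_restore$vpeak_away, without$vpeak_away)
})

test_that("halving the time step leaves the somatic peak nearly unchanged", {
  mk <- function(dt) standard_model(dt = dt)
  peak <- vapply(c(0.025, 0.0125), function(dt) {
    m <- mk(dt)
    eq <- equilibrate(m)
    single_epsp_peak(m, eq, 220)
  }, numeric(1))
  expect_lt(abs(peak[2] - peak[1]) / peak[1], 0.005)
})

test_that("equilibrate reports convergence failures", {
  m <- passive_model()
  expect_error(equilibrate(m, tol = 0, max_duration = 300),
               "did not converge")
})

test_that("resting potentials: leak-only exact, full model ~-64 mV, HCN bound", {
  # leak-only equilibrium sits exactly at the leak reversal
  m0 <- standard_model(300, include = character(0))
  m0 <- rgc_model(m0$morphology, m0$channels, synapse_model(g_max = 0),
                  dt = m0$dt)
  expect_equal(equilibrate(m0)$vrest, -68, tolerance = 1e-6 / 68)

  expect_equal(std_eq()$vrest, -64, tolerance = 1.5 / 64)
  expect_lt(hcn_eq()$vrest - passive_eq()$vrest, 5)
  expect_gt(hcn_eq()$vrest, passive_eq()$vrest)
})
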