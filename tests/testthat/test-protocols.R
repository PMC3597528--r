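test_that("site presets map onto the dendrite as documented", {
  m <- std_model()
  prox <- select_sites(m, "proximal")
  expect_true(all(m$synapse_sites$path_distance[prox] < 100))
  dst <- select_sites(m, "distal")
  expect_true(all(m$synapse_sites$path_distance[dst] > 200))
  alt <- select_sites(m, "alternating")
  expect_true(diff(range(m$synapse_sites$path_distance[alt])) > 200)
  # minimum separation ~20 um
  for (s in list(prox, dst, alt)) {
    expect_true(all(diff(m$synapse_sites$path_distance[s]) >= 15))
  }
  expect_error(run_direction_pair(m, c(1, 9999)), "sites")
})

test_that("with state restore the direction order cannot matter", {
  m <- std_model()
  eq <- std_eq()
  snap <- save_state(eq$state)
  sites <- select_sites(m, "middle")
  stim <- function(idx) data.frame(site = idx, onset = 100 + (0:2) * 20,
                                   duration = 3)
  a1 <- advance(m, restore_state(m, snap), 600, stimuli = stim(sites))
  t1 <- advance(m, restore_state(m, snap), 600, stimuli = stim(rev(sites)))
  # opposite execution order
  t2 <- advance(m, restore_state(m, snap), 600, stimuli = stim(rev(sites)))
  a2 <- advance(m, restore_state(m, snap), 600, stimuli = stim(sites))
  expect_identical(a1$traces[[1]]$values, a2$traces[[1]]$values)
  expect_identical(t1$traces[[1]]$values, t2$traces[[1]]$values)
})

test_that("the full model prefers centrifugal sequences at mid/distal sites", {
  ds <- cached("ds_full_distal",
               run_direction_pair(std_model(), select_sites(std_model(), "distal"),
                                  state = std_eq()$state))
  expect_gt(ds$ds_amplitude, 0)
  expect_gt(ds$ds_charge, 0)
  # summation statistics are attached when singles are run
  expect_gt(ds$summation_charge_away, ds$summation_charge_toward)
})

test_that("the passive cable prefers centripetal sequences in amplitude", {
  ds <- run_direction_pair(passive_model(),
                           select_sites(passive_model(), "middle"),
                           do_singles = FALSE, state = passive_eq()$state)
  expect_lt(ds$ds_amplitude, 0)
  expect_lt(abs(ds$ds_charge), 2)
})

test_that("HCN alone leaves charge direction-neutral", {
  ds <- run_direction_pair(hcn_model(), select_sites(hcn_model(), "middle"),
                           do_singles = FALSE, state = hcn_eq()$state)
  expect_lt(abs(ds$ds_charge), 2)
})

test_that("proximal-only sequences fail to elicit direction selectivity", {
  ds <- run_direction_pair(std_model(), select_sites(std_model(), "proximal"),
                           do_singles = FALSE, state = std_eq()$state)
  expect_lt(abs(ds$ds_amplitude), 2)
  expect_lt(abs(ds$ds_charge), 2)
})

test_that("removing HCN emulates ZD7288 and abolishes the centrifugal bias", {
  m <- std_model()
  mx <- apply_pharmacology(m, "hcn")
  expect_true(all(mx$channels$densities["hcn", ] == 0))
  ds <- run_direction_pair(mx, select_sites(mx, "distal"),
                           do_singles = FALSE)
  expect_true(ds$ds_charge <= 0 ||
                (abs(ds$ds_charge) < 2 && abs(ds$ds_amplitude) < 2))
  expect_error(apply_pharmacology(m, "nmda"), "unknown conductance")
})

test_that("removing an absent conductance is a no-op", {
  m <- nak_model()
  eq <- nak_eq()
  m2 <- apply_pharmacology(m, "hcn")
  sites <- select_sites(m, "middle")
  r1 <- run_direction_pair(m, sites, do_singles = FALSE, state = eq$state)
  r2 <- run_direction_pair(m2, sites, do_singles = FALSE,
                           state = restore_state(m2, eq$state))
  expect_identical(r1$away$values, r2$away$values)
})

test_that("same-site trains show more summation at short delays", {
  m <- std_model()
  st <- std_eq()$state
  site <- sites_near(m, 220)
  r25 <- run_same_site_train(m, site, delay = 25, state = st)
  r125 <- run_same_site_train(m, site, delay = 125, state = st)
  expect_gte(summation_ratio(r25$summed, r25$single, 3, "amplitude"),
             summation_ratio(r125$summed, r125$single, 3, "amplitude"))
  expect_false(r25$spiked)

  # passive membrane, non-overlapping responses sum linearly
  mp <- passive_model()
  rp <- run_same_site_train(mp, site, delay = 120, tail = 900,
                            state = passive_eq()$state)
  expect_equal(summation_ratio(rp$summed, rp$single, 3, "charge"), 1,
               tolerance = 0.05)
})

test_that("near-threshold spiking favours the centrifugal order", {
  m <- std_model()
  st <- std_eq()$state
  dsts <- select_sites(m, "distal")
  trials <- function(order_sites) {
    lapply(seq(20.2, 21, by = 0.2), function(con) {
      advance(m, st, 700,
              stimuli = data.frame(site = order_sites,
                                   onset = 100 + (0:2) * 20,
                                   duration = 3,
                                   contrast = con))$traces[[1]]
    })
  }
  p_away <- spike_probability(trials(dsts))
  p_toward <- spike_probability(trials(rev(dsts)))
  expect_gte(p_away, p_toward)
  expect_gt(p_away, 0)
})

test_that("the voltage-step family isolates the HCN tail current", {
  fam <- cached("iv_family",
                run_voltage_step_family(hcn_model(),
                                        steps = seq(-40, -100, by = -10),
                                        step_dur = 1200))
  iv <- fam$iv
  # at -40 mV the channel stays closed: difference tail ~ 0 after
  # normalization
  expect_lt(iv$tail_norm[iv$step == -40], 0.05)
  # monotone activation with hyperpolarization
  expect_true(all(diff(iv$tail_norm[order(-iv$step)]) >= -0.02))
  expect_equal(max(iv$tail_norm), 1)

  # matches the channel model's analytic activation curve
  spec <- hcn_model()$channels$hcn
  pinf <- hcn_steady_state(iv$step, spec)
  expect_lt(max(abs(iv$tail_norm - pinf / max(pinf))), 0.06)

  # determinism: control family re-run is identical
  fam2 <- run_voltage_step_family(hcn_model(), steps = c(-60),
                                  step_dur = 1200)
  fam3 <- run_voltage_step_family(hcn_model(), steps = c(-60),
                                  step_dur = 1200)
  expect_identical(fam2$control[[1]]$values, fam3$control[[1]]$values)
})

test_that("parameter scans sweep densities and survive failing runs", {
  m <- std_model()
  scan <- run_parameter_scan(m, "hcn_scale", c(0.75, 1.25),
                             site_preset = "distal")
  expect_equal(nrow(scan), 2)
  expect_false(any(scan$failed))
  expect_true(all(scan$ds_charge > 0))

  bad <- run_parameter_scan(m, "diameter", c(-1, 0.6),
                            site_preset = "middle")
  expect_true(bad$failed[1])
  expect_false(bad$failed[2])
})
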