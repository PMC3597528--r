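#' Standard unbranched-cable ganglion cell model
#'
#' Soma plus a single dendrite with the standard parameter set:
#' per-region channel densities, an HCN gradient calibrated to 25 percent
#' availability at -65 mV, and uncaging-surrogate synapses placed at
#' statistically regular ~10 um intervals.
#'
#' @param dendrite_length dendrite length (um)
#' @param diameter dendrite diameter (um)
#' @param include which voltage-gated channels to keep ("na", "kdr",
#'   "hcn"); others have their densities set to zero. \code{character(0)}
#'   gives the passive model
#' @param channels a \code{\link{channel_distribution}}; defaults to the
#'   standard set
#' @param synapse a \code{\link{synapse_model}}
#' @param dt integration step (ms)
#' @param max_electrotonic_step compartment-size criterion
#' @param spacing,regularity,seed synapse placement parameters
#' @param region_boundaries c(proximal_max, distal_min) in um
#' @return an \code{\link{rgc_model}} carrying its build arguments (used
#'   by \code{\link{run_parameter_scan}} for geometry scans)
#' @export
standard_model <- function(dendrite_length = 400, diameter = 0.6,
                           include = c("na", "kdr", "hcn"),
                           channels = NULL, synapse = synapse_model(),
                           dt = 0.025, max_electrotonic_step = 0.1,
                           spacing = 10, regularity = 8, seed = 1,
                           region_boundaries = c(50, 100)) {
  if (is.null(channels)) channels <- channel_distribution()
  for (chan in setdiff(c("na", "kdr", "hcn"), include)) {
    channels$densities[chan, ] <- 0
  }
  morph <- build_unbranched_cable(dendrite_length, diameter,
                                  region_boundaries,
                                  max_electrotonic_step,
                                  Rm = channels$Rm, Ri = channels$Ri)
  sites <- place_synapses(morph, spacing, regularity, seed = seed)
  model <- rgc_model(morph, channels, synapse, sites, dt = dt)
  attr(model, "build_args") <- list(
    dendrite_length = dendrite_length, diameter = diameter,
    include = include, dt = dt,
    max_electrotonic_step = max_electrotonic_step, spacing = spacing,
    regularity = regularity, seed = seed,
    region_boundaries = region_boundaries)
  model
}

#' Select stimulation sites by dendritic position preset
#'
#' Maps the presets used for directional protocols to actual synapse
#' sites: "proximal" places all three sites under 100 um from the soma,
#' "middle" around mid-dendrite, "distal" on the outer third, and
#' "alternating" spans proximal, middle and distal positions. Chosen sites
#' honour a minimum separation of about 20 um.
#'
#' @param model an \code{\link{rgc_model}} with synapses placed
#' @param which site preset
#' @param n number of sites (3 to 5)
#' @return integer site indices (rows of \code{model$synapse_sites})
#'   ordered by increasing path distance
#' @export
select_sites <- function(model,
                         which = c("middle", "proximal", "distal",
                                   "alternating"),
                         n = 3) {
  which <- match.arg(which)
  stopifnot(n >= 3, n <= 5)
  sites <- model$synapse_sites
  if (nrow(sites) < n) stop("model has fewer than ", n, " synapse sites")
  L <- total_dendrite_length(model$morphology)
  targets <- switch(which,
    proximal = c(30, 55, 80, 95, 99)[seq_len(n)],
    middle = L * seq(0.40, 0.70, length.out = n),
    distal = L * seq(0.60, 0.90, length.out = n),
    alternating = c(80, L * seq(0.55, 0.90,
                                length.out = n - 1)))
  idx <- integer(0)
  for (d in targets) {
    free <- setdiff(seq_len(nrow(sites)), idx)
    idx <- c(idx, free[which.min(abs(sites$path_distance[free] - d))])
  }
  idx <- idx[order(sites$path_distance[idx])]
  idx
}

dir_stimuli <- function(site_idx, first_onset, ipi, duration, contrast) {
  k <- length(site_idx)
  df <- data.frame(site = site_idx,
                   onset = first_onset + (seq_len(k) - 1) * ipi,
                   duration = duration)
  if (!is.null(contrast)) df$contrast <- contrast
  df
}

#' Run an away/toward directional stimulation pair
#'
#' Stimulates the given sites in order of increasing path distance
#' ("away", centrifugal) and decreasing path distance ("toward",
#' centripetal), restoring the equilibrated state between runs, and
#' quantifies the direction selectivity of the summed somatic EPSPs.
#'
#' @param model an \code{\link{rgc_model}}
#' @param sites site indices (rows of \code{model$synapse_sites}), e.g.
#'   from \code{\link{select_sites}}; must lie on one dendritic path
#' @param ipi inter-pulse interval (ms)
#' @param pulse_duration stimulus pulse duration (ms)
#' @param contrast presynaptic depolarization (mV); NULL uses the synapse
#'   model default
#' @param use_restore restore the saved equilibrium state between
#'   directions (and before each single-site run); turning this off lets
#'   the first sequence influence the second
#' @param pre baseline window before the first pulse (ms)
#' @param tail recording tail after the last pulse (ms)
#' @param do_singles also run each site alone (needed for summation
#'   ratios)
#' @param record compartment ids to record (soma is always included)
#' @param state optional pre-equilibrated state
#' @return object of class \code{rgc_dsresult} with the away/toward (and
#'   single-site) traces and DS statistics
#' @export
run_direction_pair <- function(model, sites, ipi = 20, pulse_duration = 3,
                               contrast = NULL, use_restore = TRUE,
                               pre = 100, tail = 500, do_singles = TRUE,
                               record = "soma", state = NULL) {
  sites <- check_sites(model, sites)
  ord <- order(model$synapse_sites$path_distance[sites])
  sites <- sites[ord]
  if (is.null(state)) state <- equilibrate(model)$state
  vrest <- state$v[1]
  snap <- save_state(state)
  k <- length(sites)
  duration <- pre + (k - 1) * ipi + pulse_duration + tail

  run_seq <- function(st, idx) {
    advance(model, st, duration,
            stimuli = dir_stimuli(idx, pre, ipi, pulse_duration, contrast),
            record = record)
  }
  away_run <- run_seq(restore_state(model, snap), sites)
  toward_start <- if (use_restore) restore_state(model, snap)
                  else away_run$state
  toward_run <- run_seq(toward_start, rev(sites))

  singles <- NULL
  if (do_singles) {
    singles <- lapply(sites, function(s1) {
      r <- advance(model, restore_state(model, snap), duration,
                   stimuli = dir_stimuli(s1, pre, ipi, pulse_duration,
                                         contrast),
                   record = record)
      tr <- r$traces[[1]]
      tr$vrest <- vrest
      tr
    })
  }
  away <- away_run$traces[[1]]; away$vrest <- vrest
  toward <- toward_run$traces[[1]]; toward$vrest <- vrest

  res <- list(away = away, toward = toward, singles = singles,
              traces_extra = list(away = away_run$traces,
                                  toward = toward_run$traces),
              sites = sites,
              site_distances = model$synapse_sites$path_distance[sites],
              vrest = vrest,
              vpeak_away = max(away$values),
              vpeak_toward = max(toward$values),
              charge_away = charge(away, baseline = vrest),
              charge_toward = charge(toward, baseline = vrest),
              ds_amplitude = directional_selectivity(away, toward,
                                                     "amplitude", vrest),
              ds_charge = directional_selectivity(away, toward, "charge",
                                                  vrest))
  if (do_singles) {
    qs <- sum(vapply(singles, charge, numeric(1), baseline = vrest))
    as <- sum(vapply(singles, peak_amplitude, numeric(1),
                     baseline = vrest))
    res$summation_charge_away <- res$charge_away / qs
    res$summation_charge_toward <- res$charge_toward / qs
    res$summation_amplitude_away <- (res$vpeak_away - vrest) / as
    res$summation_amplitude_toward <- (res$vpeak_toward - vrest) / as
  }
  structure(res, class = "rgc_dsresult")
}

check_sites <- function(model, sites) {
  sites <- as.integer(sites)
  if (length(sites) < 2 ||
      any(sites < 1 | sites > nrow(model$synapse_sites))) {
    stop("sites must be >= 2 valid row indices of model$synapse_sites")
  }
  sites
}

#' @export
print.rgc_dsresult <- function(x, ...) {
  cat(sprintf("rgc_dsresult: %d sites at %s um\n", length(x$sites),
              paste(round(x$site_distances, 1), collapse = ", ")))
  cat(sprintf("  Vrest %.2f mV | peak away %.2f, toward %.2f mV\n",
              x$vrest, x$vpeak_away, x$vpeak_toward))
  cat(sprintf("  DS amplitude %.2f %% | DS charge %.2f %%\n",
              x$ds_amplitude, x$ds_charge))
  invisible(x)
}

#' Same-site summation train
#'
#' Delivers \code{n_pulses} pulses at one site with the given delay, plus
#' a single-pulse reference run from the same restored state, for
#' summation-ratio analysis.
#'
#' @param model an \code{\link{rgc_model}}
#' @param site site index (row of \code{model$synapse_sites})
#' @param n_pulses pulses in the train
#' @param delay inter-pulse delay (ms), 1-125 in the experiments
#' @param pulse_duration pulse duration (ms)
#' @param contrast presynaptic depolarization (mV)
#' @param pre,tail baseline and tail windows (ms)
#' @param state optional pre-equilibrated state
#' @return list with \code{summed} and \code{single} traces, \code{vrest},
#'   and \code{spiked} (TRUE when a nominally subthreshold run crossed
#'   spike threshold; also raised as a warning)
#' @export
run_same_site_train <- function(model, site, n_pulses = 3, delay = 50,
                                pulse_duration = 3, contrast = NULL,
                                pre = 100, tail = 600, state = NULL) {
  stopifnot(n_pulses >= 2, delay > 0)
  site <- as.integer(site)
  if (site < 1 || site > nrow(model$synapse_sites)) {
    stop("site is not a row of model$synapse_sites")
  }
  if (is.null(state)) state <- equilibrate(model)$state
  vrest <- state$v[1]
  snap <- save_state(state)
  duration <- pre + (n_pulses - 1) * delay + pulse_duration + tail
  summed_run <- advance(model, restore_state(model, snap), duration,
                        stimuli = dir_stimuli(rep(site, n_pulses), pre,
                                              delay, pulse_duration,
                                              contrast))
  single_run <- advance(model, restore_state(model, snap), duration,
                        stimuli = dir_stimuli(site, pre, delay,
                                              pulse_duration, contrast))
  summed <- summed_run$traces[[1]]; summed$vrest <- vrest
  single <- single_run$traces[[1]]; single$vrest <- vrest
  spiked <- spike_probability(list(summed, single)) > 0
  if (spiked) {
    warning("suprathreshold response in a subthreshold summation protocol")
  }
  list(summed = summed, single = single, vrest = vrest,
       n_pulses = n_pulses, delay = delay, spiked = spiked)
}

#' Remove a conductance, emulating pharmacological blockade
#'
#' Sets the named channel's density to zero in every region (the model
#' analog of applying ZD7288 for HCN or TTX for Na); everything else is
#' untouched.
#'
#' @param model an \code{\link{rgc_model}}
#' @param remove one of "hcn", "na", "kdr"
#' @return a new \code{rgc_model}
#' @export
apply_pharmacology <- function(model, remove) {
  if (!remove %in% c("hcn", "na", "kdr")) {
    stop("unknown conductance '", remove,
         "'; expected one of hcn, na, kdr")
  }
  ch <- model$channels
  ch$densities[remove, ] <- 0
  out <- rgc_model(model$morphology, ch, model$synapse,
                   model$synapse_sites, dt = model$dt)
  ba <- attr(model, "build_args")
  if (!is.null(ba)) {
    ba$include <- setdiff(ba$include, remove)
    attr(out, "build_args") <- ba
  }
  out
}

#' Somatic voltage-step family with and without a channel
#'
#' Clamps the soma, applies steps from a holding potential, and records
#' clamp-current families for the intact model and for the model with the
#' named conductance removed; the difference family isolates that
#' channel's current for tail-current I-V analysis.
#'
#' @param model an \code{\link{rgc_model}}
#' @param steps step command voltages (mV)
#' @param holding holding potential (mV); kept where HCN is nearly closed
#'   so tails index activation reached during the step
#' @param pre,step_dur,post pre-step, step, and post-step durations (ms);
#'   the step must be long relative to the channel's time constant
#' @param remove channel removed in the comparison family
#' @param space_clamp clamp every compartment (ideal whole-cell clamp,
#'   default) rather than the soma alone; tail-current analysis assumes
#'   the command potential is reached everywhere, which a somatic point
#'   clamp cannot achieve on a thin dendrite within the tail window
#' @param record_dt current sampling interval (ms)
#' @param tail_window tail measurement window after step offset (ms)
#' @return object of class \code{rgc_ivfamily}: the control and blocked
#'   current-trace lists, timing, and the \code{\link{tail_current_iv}}
#'   table in \code{$iv}
#' @export
run_voltage_step_family <- function(model, steps = seq(-40, -100, by = -5),
                                    holding = -40, pre = 200,
                                    step_dur = 1200, post = 200,
                                    remove = "hcn", space_clamp = TRUE,
                                    record_dt = 0.5, tail_window = 5) {
  blocked_model <- apply_pharmacology(model, remove)
  clamp_ids <- if (space_clamp) model$morphology$compartments$id else 1L
  run_family <- function(mod) {
    hold <- advance(mod, init_state(mod, holding), 2000,
                    clamp = list(compartment_id = clamp_ids, v = holding))
    hold_state <- hold$state
    hold_state$t <- 0
    lapply(steps, function(vstep) {
      n_steps <- round((pre + step_dur + post) / mod$dt)
      cmd <- rep(holding, n_steps)
      tms <- (seq_len(n_steps) - 1) * mod$dt
      cmd[tms >= pre & tms < pre + step_dur] <- vstep
      r <- advance(mod, hold_state, pre + step_dur + post,
                   record_dt = record_dt,
                   clamp = list(compartment_id = clamp_ids, v = cmd))
      r$i_clamp
    })
  }
  control <- run_family(model)
  blocked <- run_family(blocked_model)
  iv <- tail_current_iv(control, blocked, steps, step_onset = pre,
                        step_offset = pre + step_dur,
                        window = tail_window)
  structure(list(steps = steps, control = control, blocked = blocked,
                 holding = holding, step_onset = pre,
                 step_offset = pre + step_dur, iv = iv),
            class = "rgc_ivfamily")
}

#' Directional-selectivity parameter scan
#'
#' Reruns the directional protocol across a sweep of one model parameter.
#' Density scans multiply the channel's densities everywhere
#' ("hcn_scale", "kdr_scale", "na_scale") or set the dendritic Na density
#' in mS/cm^2 with the soma scaled in proportion ("na_density");
#' "diameter" rebuilds the cable (only for models built by
#' \code{\link{standard_model}}).
#'
#' @param model an \code{\link{rgc_model}}
#' @param parameter one of "na_density", "na_scale", "kdr_scale",
#'   "hcn_scale", "diameter"
#' @param values parameter values to scan
#' @param site_preset preset passed to \code{\link{select_sites}}
#' @param ... further arguments to \code{\link{run_direction_pair}}
#' @return data.frame with one row per value: vrest, ds_amplitude,
#'   ds_charge and a \code{failed} flag (failures do not stop the scan)
#' @export
run_parameter_scan <- function(model, parameter, values,
                               site_preset = "middle", ...) {
  parameter <- match.arg(parameter, c("na_density", "na_scale",
                                      "kdr_scale", "hcn_scale",
                                      "diameter"))
  rows <- lapply(values, function(val) {
    out <- tryCatch({
      mod <- scan_variant(model, parameter, val)
      ds <- run_direction_pair(mod, select_sites(mod, site_preset),
                               do_singles = FALSE, ...)
      data.frame(value = val, vrest = ds$vrest,
                 ds_amplitude = ds$ds_amplitude,
                 ds_charge = ds$ds_charge, failed = FALSE)
    }, error = function(e) {
      data.frame(value = val, vrest = NA_real_, ds_amplitude = NA_real_,
                 ds_charge = NA_real_, failed = TRUE)
    })
    out
  })
  do.call(rbind, rows)
}

scan_variant <- function(model, parameter, value) {
  if (parameter == "diameter") {
    ba <- attr(model, "build_args")
    if (is.null(ba)) {
      stop("diameter scans need a model built by standard_model()")
    }
    ba$diameter <- value
    ba$channels <- model$channels
    return(do.call(standard_model, ba))
  }
  ch <- model$channels
  if (parameter == "na_density") {
    ch$densities["na", ] <- ch$densities["na", ] * value /
      ch$densities["na", "dendrite"]
  } else {
    chan <- sub("_scale", "", parameter)
    ch$densities[chan, ] <- ch$densities[chan, ] * value
  }
  rgc_model(model$morphology, ch, model$synapse, model$synapse_sites,
            dt = model$dt)
}
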