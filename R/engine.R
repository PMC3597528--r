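#' Bind morphology, channels and synapses into a simulatable model
#'
#' @param morphology an \code{\link{rgc_morphology}}
#' @param channels a \code{\link{channel_distribution}}
#' @param synapse a \code{\link{synapse_model}}
#' @param synapse_sites data.frame of synapse sites as returned by
#'   \code{\link{place_synapses}} (may be empty)
#' @param dt integration time step (ms); default 0.025
#' @return object of class \code{rgc_model}
#' @export
rgc_model <- function(morphology, channels = channel_distribution(),
                      synapse = synapse_model(),
                      synapse_sites = NULL, dt = 0.025) {
  stopifnot(inherits(morphology, "rgc_morphology"),
            inherits(channels, "channel_distribution"),
            inherits(synapse, "synapse_model"), dt > 0)
  if (is.null(synapse_sites)) {
    synapse_sites <- data.frame(compartment_id = integer(),
                                offset = numeric(),
                                path_distance = numeric())
  }
  cc <- morphology$compartments
  if (nrow(synapse_sites) &&
      !all(synapse_sites$compartment_id %in% cc$id)) {
    stop("synapse site refers to a compartment not in the morphology")
  }
  m <- structure(list(morphology = morphology, channels = channels,
                      synapse = synapse, synapse_sites = synapse_sites,
                      dt = dt),
                 class = "rgc_model")
  m$pars <- build_engine_pars(m)
  m
}

#' @export
print.rgc_model <- function(x, ...) {
  cat("rgc_model:", nrow(x$morphology$compartments), "compartments,",
      nrow(x$synapse_sites), "synapses, dt =", x$dt, "ms\n")
  invisible(x)
}

# Precompute the per-compartment arrays the C++ solver consumes.
# Units: uS, nF; axial conductance couples compartment midpoints through
# the half-lengths of each neighbour.
build_engine_pars <- function(model) {
  cc <- model$morphology$compartments
  ch <- model$channels
  n <- nrow(cc)
  region_col <- match(cc$region, colnames(ch$densities))
  area <- cc$area
  g_leak <- area * 1e6 / ch$Rm
  cm <- ch$Cm * area * 1e3
  gbar_na <- ch$densities["na", region_col] * area * 1e3
  gbar_k <- ch$densities["kdr", region_col] * area * 1e3
  gbar_hcn <- ch$densities["hcn", region_col] * area * 1e3
  parent <- match(cc$parent_id, cc$id)
  g_ax <- numeric(n)
  xsec <- pi * (cc$diameter * 1e-4)^2 / 4
  half_r <- ifelse(cc$length > 0,
                   ch$Ri * (cc$length * 1e-4 / 2) / xsec, 0)
  for (i in seq_len(n)) {
    if (is.na(parent[i])) next
    r <- half_r[i] + half_r[parent[i]]
    if (r <= 0) r <- 1   # two zero-length compartments: tight coupling
    g_ax[i] <- 1e6 / r
  }
  list(n = n, parent0 = ifelse(is.na(parent), -1L, parent - 1L),
       g_ax = g_ax, cm = cm, g_leak = g_leak,
       gbar_na = gbar_na, gbar_k = gbar_k, gbar_hcn = gbar_hcn,
       hcn_pars = with(ch$hcn, c(v_half, slope, rate_max, mult_alpha,
                                 mult_beta, voltage_offset)),
       nap_pars = with(ch$na_persistent, c(frac, v_half, slope, tau)),
       fingerprint = list(n = n, total_length = sum(cc$length),
                          densities = ch$densities, dt = model$dt,
                          n_syn = nrow(model$synapse_sites)))
}

#' Initialize a simulation state
#'
#' Voltages are set to \code{v0} and all gates and synapse states to their
#' steady state at \code{v0} (tonic baseline release for the synapses).
#'
#' @param model an \code{\link{rgc_model}}
#' @param v0 initial voltage (mV); defaults to the leak reversal
#' @return object of class \code{rgc_state}
#' @export
init_state <- function(model, v0 = model$channels$e_leak) {
  n <- model$pars$n
  g <- gating_steady_state(v0, model$channels)
  gates <- matrix(rep(g, each = n), nrow = n,
                  dimnames = list(NULL, c("hcn", "m", "h", "n", "nap")))
  m <- nrow(model$synapse_sites)
  syn <- list(filter = rep(model$synapse$r0, m),
              ampa = matrix(rep(ampa_steady_state(model$synapse$r0,
                                                  model$synapse$ampa),
                                each = m), nrow = m))
  structure(list(t = 0, v = rep(v0, n), gates = gates, syn = syn,
                 fingerprint = model$pars$fingerprint),
            class = "rgc_state")
}

#' Advance the model state through time
#'
#' Integrates the compartmental cable equation with all bound channels and
#' synapses: implicit (backward-Euler) voltage update on the tree and
#' exact exponential (Rush-Larsen) gate updates.
#'
#' @param model an \code{\link{rgc_model}}
#' @param state an \code{rgc_state} (see \code{\link{init_state}})
#' @param duration simulated time (ms)
#' @param stimuli optional data.frame with columns \code{site} (row index
#'   into \code{model$synapse_sites}), \code{onset} (ms, relative to the
#'   start of this call), \code{duration} (ms) and optionally
#'   \code{contrast} (mV)
#' @param record compartment ids to record, or "soma" (id 1); recorded
#'   voltages are returned as \code{\link{rgc_trace}} objects
#' @param record_dt recording sample interval (ms)
#' @param i_inj optional constant current injection: data.frame with
#'   \code{compartment_id} and \code{amp} (nA)
#' @param clamp optional voltage clamp: list with
#'   \code{compartment_id} (one or more compartments; all of them follow
#'   the same command) and \code{v} (scalar or per-step command, mV);
#'   the returned clamp current is summed over the clamped compartments
#' @return list with the advanced \code{state}, \code{traces} (named list
#'   of voltage traces) and, when clamped, \code{i_clamp} (current trace,
#'   nA)
#' @export
advance <- function(model, state, duration, stimuli = NULL,
                    record = "soma", record_dt = 0.1, i_inj = NULL,
                    clamp = NULL) {
  stopifnot(inherits(state, "rgc_state"), duration > 0)
  p <- model$pars
  ch <- model$channels
  dt <- model$dt
  record_every <- max(1L, round(record_dt / dt))
  n_steps <- max(record_every,
                 record_every * round(duration / (dt * record_every)))
  m <- nrow(model$synapse_sites)

  # per-synapse conductance traces from the presynaptic chain
  g_syn <- matrix(0, n_steps, max(m, 1))
  syn_comp0 <- integer(0)
  filter_end <- state$syn$filter
  ampa_end <- state$syn$ampa
  if (m > 0) {
    syn_comp0 <- match(model$synapse_sites$compartment_id,
                       model$morphology$compartments$id) - 1L
    for (s in seq_len(m)) {
      ons <- numeric(0); dur <- 3; con <- NULL
      if (!is.null(stimuli) && nrow(stimuli)) {
        rows <- stimuli[stimuli$site == s, , drop = FALSE]
        if (nrow(rows)) {
          ons <- rows$onset
          dur <- rows$duration[1]
          if (!is.null(rows$contrast)) con <- rows$contrast[1]
        }
      }
      sc <- synaptic_conductance(n_steps, dt, ons, dur, con,
                                 model$synapse,
                                 filter_y0 = state$syn$filter[s],
                                 ampa_state0 = state$syn$ampa[s, ])
      g_syn[, s] <- sc$g
      filter_end[s] <- sc$filter_end
      ampa_end[s, ] <- sc$ampa_end
    }
  }

  inj <- numeric(p$n)
  if (!is.null(i_inj)) {
    idx <- match(i_inj$compartment_id, model$morphology$compartments$id)
    inj[idx] <- i_inj$amp
  }
  clamp_comps <- integer(0)
  clamp_v <- numeric(0)
  if (!is.null(clamp)) {
    clamp_comps <- match(clamp$compartment_id,
                         model$morphology$compartments$id) - 1L
    if (any(is.na(clamp_comps))) stop("clamp refers to unknown compartments")
    clamp_v <- rep_len(clamp$v, n_steps)
  }
  if (identical(record, "soma")) record <- 1L
  rec_idx <- match(record, model$morphology$compartments$id)
  if (any(is.na(rec_idx))) stop("record refers to unknown compartment ids")

  out <- cable_advance_cpp(state$v, state$gates,
                           p$parent0, p$g_ax, p$cm, p$g_leak,
                           p$gbar_na, p$gbar_k, p$gbar_hcn,
                           ch$e_leak, ch$e_na, ch$e_k, ch$e_hcn,
                           ch$na_shift, ch$na_h_shift, ch$kdr_shift,
                           ch$kdr_rate_mult, p$hcn_pars,
                           p$nap_pars, dt, n_steps,
                           syn_comp0, g_syn, model$synapse$e_ampa,
                           inj, clamp_comps, clamp_v, 1e4,
                           rec_idx - 1L, record_every)

  new_state <- state
  new_state$t <- state$t + n_steps * dt
  new_state$v <- out$v
  new_state$gates <- state$gates
  new_state$gates[, ] <- out$gates
  new_state$syn$filter <- filter_end
  new_state$syn$ampa <- ampa_end

  ann <- list()
  if (!is.null(stimuli) && nrow(stimuli)) {
    st <- stimuli
    st$onset <- st$onset + state$t
    if (m > 0) {
      st$path_distance <- model$synapse_sites$path_distance[st$site]
    }
    ann$stimuli <- st
  }
  sample_dt <- dt * record_every
  traces <- lapply(seq_along(rec_idx), function(r) {
    rgc_trace(out$vrec[, r], dt = sample_dt,
              t0 = state$t + sample_dt, unit = "mV", annotations = ann)
  })
  names(traces) <- ifelse(rec_idx == 1, "soma", paste0("comp", record))
  res <- list(state = new_state, traces = traces)
  if (length(clamp_comps) > 0) {
    res$i_clamp <- rgc_trace(out$irec, dt = sample_dt,
                             t0 = state$t + sample_dt, unit = "nA",
                             annotations = ann)
  }
  res
}

#' Equilibrate a model to rest
#'
#' Runs the model without stimuli in blocks until the largest per-step
#' voltage change anywhere in the cell corresponds to |dV/dt| below
#' \code{tol}.
#'
#' @param model an \code{\link{rgc_model}}
#' @param state optional starting state; defaults to
#'   \code{\link{init_state}}
#' @param tol convergence tolerance on |dV/dt| (mV/ms)
#' @param block block length between convergence checks (ms)
#' @param max_duration give up after this much simulated time (ms)
#' @return list with the equilibrated \code{state} and \code{vrest}, the
#'   somatic resting potential (mV)
#' @export
equilibrate <- function(model, state = NULL, tol = 1e-4, block = 100,
                        max_duration = 20000) {
  if (is.null(state)) state <- init_state(model)
  elapsed <- 0
  dvdt <- Inf
  while (elapsed < max_duration) {
    res <- advance(model, state, block, record = 1L, record_dt = block)
    v_before <- res$state$v
    probe <- advance(model, res$state, model$dt, record = 1L,
                     record_dt = model$dt)
    dvdt <- max(abs(probe$state$v - v_before)) / model$dt
    state <- probe$state
    elapsed <- elapsed + block + model$dt
    if (dvdt < tol) {
      return(list(state = state, vrest = state$v[1]))
    }
  }
  stop("equilibrate did not converge within ", max_duration,
       " ms; final max |dV/dt| = ", signif(dvdt, 4), " mV/ms")
}

#' Snapshot a simulation state
#' @param state an \code{rgc_state}
#' @return a snapshot object that \code{\link{restore_state}} accepts
#' @export
save_state <- function(state) {
  stopifnot(inherits(state, "rgc_state"))
  state
}

#' Restore a snapshot, verifying it belongs to this model
#' @param model the \code{\link{rgc_model}} the snapshot must match
#' @param snapshot object from \code{\link{save_state}} or
#'   \code{\link{load_state_file}}
#' @return the restored \code{rgc_state}
#' @export
restore_state <- function(model, snapshot) {
  stopifnot(inherits(snapshot, "rgc_state"))
  if (!isTRUE(all.equal(snapshot$fingerprint, model$pars$fingerprint))) {
    stop("snapshot does not match this model's configuration")
  }
  snapshot
}

#' Write a state snapshot to disk
#' @param state an \code{rgc_state}
#' @param path output file
#' @export
save_state_file <- function(state, path) {
  saveRDS(save_state(state), path)
  invisible(path)
}

#' Read a state snapshot from disk
#' @param path file written by \code{\link{save_state_file}}
#' @return an \code{rgc_state} snapshot
#' @export
load_state_file <- function(path) {
  readRDS(path)
}
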