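#' Uncaging-surrogate synapse model
#'
#' The stimulation chain that stands in for glutamate uncaging: an ideally
#' voltage-clamped presynaptic compartment drives an exponential release
#' function (2 mV per e-fold change), the released transmitter is shaped by
#' a first-order temporal filter with separate rise and fall time
#' constants (75 and 125 ms), and the filtered transmitter gates a
#' three-state AMPA-receptor scheme whose open fraction scales a maximal
#' conductance with 0 mV reversal.
#'
#' @param e_fold_voltage presynaptic voltage change per e-fold change in
#'   release (mV)
#' @param baseline_presyn_v resting potential of the presynaptic
#'   compartment (mV); release is r0 at this voltage
#' @param contrast_depolarization default stimulus depolarization of the
#'   presynaptic compartment (mV)
#' @param tau_rise,tau_fall filter time constants (ms)
#' @param e_ampa AMPA reversal potential (mV)
#' @param g_max maximal AMPA conductance per synapse (uS)
#' @param r0 baseline (tonic) release at the presynaptic resting potential,
#'   arbitrary units absorbed into \code{g_max}
#' @param ampa AMPA kinetic scheme, see \code{\link{ampa_scheme}}
#' @return object of class \code{synapse_model}
#' @export
synapse_model <- function(e_fold_voltage = 2, baseline_presyn_v = -45,
                          contrast_depolarization = 20,
                          tau_rise = 75, tau_fall = 125,
                          e_ampa = 0, g_max = 0.012, r0 = 1e-7,
                          ampa = ampa_scheme()) {
  stopifnot(e_fold_voltage > 0, tau_rise > 0, tau_fall > 0, g_max >= 0,
            r0 >= 0)
  structure(list(e_fold_voltage = e_fold_voltage,
                 baseline_presyn_v = baseline_presyn_v,
                 contrast_depolarization = contrast_depolarization,
                 tau_rise = tau_rise, tau_fall = tau_fall,
                 e_ampa = e_ampa, g_max = g_max, r0 = r0, ampa = ampa),
            class = "synapse_model")
}

#' Three-state AMPA receptor kinetic scheme
#'
#' Closed -> open binding at \code{kon} per unit transmitter, unbinding at
#' \code{koff}, open -> desensitized at \code{kdes}, desensitized ->
#' closed recovery at \code{kres}. The default rates are fast relative to
#' the 75/125 ms release filter, which therefore sets the EPSP time
#' course.
#'
#' @param kon opening rate per unit transmitter (1/ms)
#' @param koff closing rate (1/ms)
#' @param kdes desensitization rate from open (1/ms)
#' @param kres recovery rate from desensitized (1/ms)
#' @return object of class \code{ampa_scheme}
#' @export
ampa_scheme <- function(kon = 2, koff = 0.08, kdes = 0.004, kres = 0.002) {
  stopifnot(kon > 0, koff > 0, kdes >= 0, kres >= 0)
  structure(list(kon = kon, koff = koff, kdes = kdes, kres = kres),
            class = "ampa_scheme")
}

#' Generator matrix of the AMPA scheme at fixed transmitter level
#'
#' Returns Q with Q[i, j] the rate from state i to state j (states C, O,
#' D) and rows summing to zero; the occupancy ODE is dx/dt = Q^T x.
#'
#' @param scheme an \code{\link{ampa_scheme}}
#' @param glu transmitter level (a.u.)
#' @return 3 x 3 generator matrix
#' @export
ampa_generator <- function(scheme, glu) {
  a <- scheme$kon * glu
  q <- matrix(0, 3, 3, dimnames = list(c("C", "O", "D"), c("C", "O", "D")))
  q["C", "O"] <- a
  q["O", "C"] <- scheme$koff
  q["O", "D"] <- scheme$kdes
  q["D", "C"] <- scheme$kres
  diag(q) <- -rowSums(q)
  q
}

#' Relative transmitter release as a function of presynaptic voltage
#' @param v_pre presynaptic voltage (mV)
#' @param model a \code{\link{synapse_model}}
#' @return release rate r0 * exp((v_pre - baseline)/e_fold_voltage)
#' @export
release_rate <- function(v_pre, model = synapse_model()) {
  model$r0 * exp((v_pre - model$baseline_presyn_v) / model$e_fold_voltage)
}

#' Asymmetric first-order release filter
#'
#' First-order low-pass whose time constant is \code{tau_rise} while the
#' input exceeds the output and \code{tau_fall} otherwise. DC gain is 1.
#'
#' @param x uniformly sampled raw release
#' @param dt sample interval (ms)
#' @param tau_rise,tau_fall time constants (ms)
#' @param y0 initial output value
#' @return list with the filtered trace \code{y} and final value
#'   \code{y_end}
#' @export
filter_release <- function(x, dt, tau_rise = 75, tau_fall = 125, y0 = 0) {
  stopifnot(dt > 0, tau_rise > 0, tau_fall > 0)
  if (dt >= min(tau_rise, tau_fall) / 5) {
    warning("sample interval dt = ", dt,
            " ms is coarse relative to the filter time constants")
  }
  filter_asym_cpp(as.numeric(x), dt, tau_rise, tau_fall, y0)
}

#' AMPA conductance from a transmitter time course
#'
#' Integrates the three-state receptor scheme (occupancy-conserving
#' backward-Euler update) driven by the transmitter trace and returns the
#' conductance \code{g_max * open fraction}.
#'
#' @param glu transmitter trace (a.u., >= 0)
#' @param dt sample interval (ms)
#' @param model a \code{\link{synapse_model}}
#' @param state0 initial occupancy (C, O, D); defaults to all closed
#' @return list with conductance trace \code{g} (uS), open-fraction trace
#'   \code{open}, and final occupancy \code{state_end}
#' @export
ampa_conductance <- function(glu, dt, model = synapse_model(),
                             state0 = c(1, 0, 0)) {
  if (any(glu < 0)) stop("transmitter trace must be non-negative")
  s <- model$ampa
  r <- ampa_integrate_cpp(as.numeric(glu), dt, s$kon, s$koff, s$kdes,
                          s$kres, state0)
  list(g = model$g_max * r$open, open = r$open, state_end = r$state_end)
}

#' Presynaptic voltage waveform for a pulse train
#'
#' @param n_steps number of samples
#' @param dt sample interval (ms)
#' @param onsets pulse onset times (ms)
#' @param duration pulse duration (ms), default 3
#' @param contrast depolarization during the pulse (mV)
#' @param model a \code{\link{synapse_model}}
#' @return numeric vector of presynaptic voltage (mV)
#' @export
presyn_waveform <- function(n_steps, dt, onsets, duration = 3,
                            contrast = NULL, model = synapse_model()) {
  stopifnot(duration > 0)
  if (is.null(contrast)) contrast <- model$contrast_depolarization
  t <- (seq_len(n_steps) - 1) * dt
  v <- rep(model$baseline_presyn_v, n_steps)
  for (on in onsets) {
    v[t >= on & t < on + duration] <- model$baseline_presyn_v + contrast
  }
  v
}

#' Synaptic conductance trace for one synapse given its stimulus train
#'
#' Runs the full presynaptic chain (clamped voltage -> exponential release
#' -> asymmetric filter -> AMPA scheme).
#'
#' @inheritParams presyn_waveform
#' @param filter_y0 initial filter state
#' @param ampa_state0 initial receptor occupancy
#' @return list with \code{g} (uS), \code{filter_end}, \code{ampa_end}
#' @export
synaptic_conductance <- function(n_steps, dt, onsets, duration = 3,
                                 contrast = NULL, model = synapse_model(),
                                 filter_y0 = NULL, ampa_state0 = NULL) {
  vpre <- presyn_waveform(n_steps, dt, onsets, duration, contrast, model)
  raw <- release_rate(vpre, model)
  if (is.null(filter_y0)) filter_y0 <- model$r0   # tonic release baseline
  f <- filter_release(raw, dt, model$tau_rise, model$tau_fall, filter_y0)
  if (is.null(ampa_state0)) {
    ampa_state0 <- ampa_steady_state(model$r0, model$ampa)
  }
  a <- ampa_conductance(f$y, dt, model, ampa_state0)
  list(g = a$g, filter_end = f$y_end, ampa_end = a$state_end)
}

#' Steady-state occupancy of the AMPA scheme at constant transmitter
#' @param glu transmitter level
#' @param scheme an \code{\link{ampa_scheme}}
#' @return occupancy vector (C, O, D) summing to 1
#' @export
ampa_steady_state <- function(glu, scheme = ampa_scheme()) {
  q <- ampa_generator(scheme, glu)
  a <- rbind(t(q)[1:2, ], rep(1, 3))
  drop(solve(a, c(0, 0, 1)))
}
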