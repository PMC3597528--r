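#' HCN rate-function specification
#'
#' Two-state (closed/open) HCN gate with Boltzmann-sigmoid opening and
#' closing rates:
#' \deqn{\alpha(V) = m_\alpha r_{max} / (1 + e^{(V - off - V_{1/2})/k})}
#' \deqn{\beta(V)  = m_\beta  r_{max} / (1 + e^{-(V - off - V_{1/2})/k})}
#' With equal multipliers the steady-state activation is an inverted
#' Boltzmann with half-activation \code{v_half}; the default multipliers
#' slow activation by a factor 0.33 and speed deactivation by a factor 2,
#' which left-shifts and de-saturates the activation curve. The voltage
#' offset is the calibration knob (see \code{\link{calibrate_hcn_offset}}).
#'
#' @param v_half half-activation voltage of the base rates (mV)
#' @param slope Boltzmann slope factor (mV)
#' @param rate_max maximum transition rate (1/ms); sets the kinetic
#'   time scale (tau is about 1/rate_max near rest)
#' @param mult_alpha,mult_beta kinetic rate multipliers applied to the
#'   activation and deactivation rates
#' @param voltage_offset offset voltage applied to both rate functions (mV)
#' @return object of class \code{hcn_spec}
#' @export
hcn_rate_spec <- function(v_half = -82, slope = 5, rate_max = 0.01,
                          mult_alpha = 0.33, mult_beta = 2,
                          voltage_offset = 0) {
  stopifnot(slope > 0, rate_max > 0, mult_alpha > 0, mult_beta > 0)
  structure(list(v_half = v_half, slope = slope, rate_max = rate_max,
                 mult_alpha = mult_alpha, mult_beta = mult_beta,
                 voltage_offset = voltage_offset),
            class = "hcn_spec")
}

#' HCN opening and closing rates
#' @param v membrane potential (mV)
#' @param spec an \code{\link{hcn_rate_spec}}
#' @return list with components \code{alpha} and \code{beta} (1/ms)
#' @export
hcn_rates <- function(v, spec = hcn_rate_spec()) {
  x <- (v - spec$voltage_offset - spec$v_half) / spec$slope
  list(alpha = spec$mult_alpha * spec$rate_max / (1 + exp(x)),
       beta = spec$mult_beta * spec$rate_max / (1 + exp(-x)))
}

#' Steady-state HCN open fraction
#' @inheritParams hcn_rates
#' @return open probability alpha/(alpha+beta)
#' @export
hcn_steady_state <- function(v, spec = hcn_rate_spec()) {
  r <- hcn_rates(v, spec)
  r$alpha / (r$alpha + r$beta)
}

#' HCN relaxation time constant 1/(alpha+beta)
#' @inheritParams hcn_rates
#' @export
hcn_tau <- function(v, spec = hcn_rate_spec()) {
  r <- hcn_rates(v, spec)
  1 / (r$alpha + r$beta)
}

#' Calibrate the HCN voltage offset to a target open fraction
#'
#' Finds, by bisection, the voltage offset at which the steady-state open
#' fraction at \code{at_voltage} equals \code{target_open_fraction}. Used
#' to pin the channel to the experimentally observed availability (about
#' 25 percent open at -65 mV).
#'
#' @param target_open_fraction target steady-state open fraction in (0, 1)
#' @param at_voltage voltage at which the target must hold (mV)
#' @param spec base \code{\link{hcn_rate_spec}} (its current offset is
#'   ignored)
#' @param bounds offset search bracket (mV)
#' @param tol tolerance on the open fraction
#' @return the calibrated offset (mV)
#' @export
calibrate_hcn_offset <- function(target_open_fraction, at_voltage = -65,
                                 spec = hcn_rate_spec(),
                                 bounds = c(-100, 100), tol = 1e-4) {
  stopifnot(target_open_fraction > 0, target_open_fraction < 1)
  p_at <- function(off) {
    s <- spec
    s$voltage_offset <- off
    hcn_steady_state(at_voltage, s)
  }
  lo <- bounds[1]; hi <- bounds[2]
  # p is monotonically increasing in the offset
  if (p_at(lo) > target_open_fraction || p_at(hi) < target_open_fraction) {
    stop("target open fraction ", target_open_fraction,
         " not reachable with offsets in [", lo, ", ", hi, "] mV")
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    p <- p_at(mid)
    if (abs(p - target_open_fraction) < tol) return(mid)
    if (p < target_open_fraction) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Na channel (m3h) rate functions
#'
#' Hodgkin-Huxley style activation/inactivation rates with voltage shifts;
#' a positive shift moves the gate to more depolarized potentials. The
#' inactivation (h) shift defaults to 10 mV depolarized relative to the
#' activation shift so that inactivation stays out of the subthreshold
#' range and availability is roughly constant around rest.
#'
#' @param v membrane potential (mV)
#' @param shift activation (m) voltage shift (mV)
#' @param h_shift inactivation (h) voltage shift (mV)
#' @return list with alpha_m, beta_m, alpha_h, beta_h (1/ms)
#' @export
na_rates <- function(v, shift = 0, h_shift = shift + 10) {
  vs <- v - shift
  vh <- v - h_shift
  list(alpha_m = 0.1 * vtrap_r(-(vs + 40), 10),
       beta_m = 4 * exp(-(vs + 65) / 18),
       alpha_h = 0.07 * exp(-(vh + 65) / 20),
       beta_h = 1 / (1 + exp(-(vh + 35) / 10)))
}

#' Delayed-rectifier K channel (n4) rate functions
#'
#' @param v membrane potential (mV)
#' @param shift voltage shift (mV)
#' @param rate_mult kinetic rate multiplier applied to both rates; values
#'   above 1 speed the rectifier so that it clips regenerative Na events
#'   while leaving slower subthreshold dynamics nearly unchanged
#' @return list with alpha_n, beta_n (1/ms)
#' @export
kdr_rates <- function(v, shift = 0, rate_mult = 1) {
  vs <- v - shift
  list(alpha_n = rate_mult * 0.01 * vtrap_r(-(vs + 55), 10),
       beta_n = rate_mult * 0.125 * exp(-(vs + 65) / 80))
}

vtrap_r <- function(x, y) {
  ifelse(abs(x / y) < 1e-6, y * (1 - x / y / 2), x / (expm1(x / y)))
}

#' Persistent (non-inactivating) Na component
#'
#' A small fraction of the Na conductance gated by a single shallow
#' Boltzmann activation gate. This subthreshold persistent component
#' depolarizes the resting potential stably (its activation is shallow
#' enough that the leak slope dominates) and gently amplifies EPSPs,
#' while the transient m3h gate stays out of range until much stronger
#' depolarization.
#'
#' @param frac persistent conductance as a fraction of the Na density
#' @param v_half activation half voltage (mV)
#' @param slope Boltzmann slope (mV); shallow by design
#' @param tau activation time constant (ms)
#' @return object of class \code{nap_spec}
#' @export
na_persistent_spec <- function(frac = 3.8e-4, v_half = -52, slope = 16,
                               tau = 5) {
  stopifnot(frac >= 0, slope > 0, tau > 0)
  structure(list(frac = frac, v_half = v_half, slope = slope, tau = tau),
            class = "nap_spec")
}

#' Steady-state activation of the persistent Na gate
#' @param v membrane potential (mV)
#' @param spec a \code{\link{na_persistent_spec}}
#' @export
nap_steady_state <- function(v, spec = na_persistent_spec()) {
  1 / (1 + exp(-(v - spec$v_half) / spec$slope))
}

#' Steady-state gate values for all channels at a clamped voltage
#' @param v membrane potential (mV)
#' @param dist a \code{\link{channel_distribution}}
#' @return named vector of steady-state hcn, m, h, n, nap
#' @export
gating_steady_state <- function(v, dist = channel_distribution()) {
  na <- na_rates(v, dist$na_shift, dist$na_h_shift)
  k <- kdr_rates(v, dist$kdr_shift, dist$kdr_rate_mult)
  c(hcn = hcn_steady_state(v, dist$hcn),
    m = na$alpha_m / (na$alpha_m + na$beta_m),
    h = na$alpha_h / (na$alpha_h + na$beta_h),
    n = k$alpha_n / (k$alpha_n + k$beta_n),
    nap = nap_steady_state(v, dist$na_persistent))
}

REGIONS <- c("soma", "proximal", "dendrite", "distal")

#' Standard per-region channel densities
#'
#' Default densities (mS/cm^2) of the standard parameter set: Na 20 on all
#' dendritic regions and 5 at the soma, delayed-rectifier K 5 (2 at the
#' soma), and an HCN gradient rising from 0.0005 proximally through 0.001
#' on the middle dendrite to 0.005 distally, with none at the soma.
#'
#' @return 3 x 4 matrix, rows na/kdr/hcn, columns soma/proximal/dendrite/distal
#' @export
standard_densities <- function() {
  m <- rbind(na = c(5, 20, 20, 20),
             kdr = c(2, 5, 5, 5),
             hcn = c(0, 5e-4, 1e-3, 5e-3))
  colnames(m) <- REGIONS
  m
}

#' Channel distribution and passive membrane properties
#'
#' Bundles per-region channel densities, passive properties, reversal
#' potentials and channel kinetics into the single configuration object
#' consumed by the simulation engine.
#'
#' @param densities 3 x 4 density matrix (mS/cm^2), rows na/kdr/hcn,
#'   columns soma/proximal/dendrite/distal; see
#'   \code{\link{standard_densities}}
#' @param e_leak leak reversal potential (mV)
#' @param Rm specific membrane resistance (ohm cm^2)
#' @param Ri axial resistivity (ohm cm)
#' @param Cm specific membrane capacitance (uF/cm^2)
#' @param e_na,e_k,e_hcn channel reversal potentials (mV)
#' @param na_shift,kdr_shift voltage shifts of the Na and K kinetics (mV);
#'   the defaults place the transient Na gate and the K activation so
#'   that the standard model rests near -64 mV without firing under
#'   standard stimuli
#' @param na_persistent a \code{\link{na_persistent_spec}}; the
#'   subthreshold Na component that, balanced against K and leak, sets
#'   the depolarized resting potential
#' @param hcn an \code{\link{hcn_rate_spec}}; by default calibrated so
#'   about 25 percent of channels are open at -65 mV
#' @return object of class \code{channel_distribution}
#' @export
channel_distribution <- function(densities = standard_densities(),
                                 e_leak = -68, Rm = 28000, Ri = 200, Cm = 1,
                                 e_na = 50, e_k = -77, e_hcn = -20,
                                 na_shift = 8, na_h_shift = na_shift + 10,
                                 kdr_shift = 15, kdr_rate_mult = 1,
                                 na_persistent = na_persistent_spec(),
                                 hcn = calibrated_hcn_spec()) {
  densities <- as.matrix(densities)
  if (!all(rownames(densities) == c("na", "kdr", "hcn")) ||
      !all(colnames(densities) == REGIONS)) {
    stop("densities must have rows na/kdr/hcn and columns ",
         paste(REGIONS, collapse = "/"))
  }
  if (any(densities < 0)) stop("channel densities must be >= 0")
  stopifnot(Rm > 0, Ri > 0, Cm > 0)
  structure(list(densities = densities, e_leak = e_leak, Rm = Rm, Ri = Ri,
                 Cm = Cm, e_na = e_na, e_k = e_k, e_hcn = e_hcn,
                 na_shift = na_shift, na_h_shift = na_h_shift,
                 kdr_shift = kdr_shift, kdr_rate_mult = kdr_rate_mult,
                 na_persistent = na_persistent, hcn = hcn),
            class = "channel_distribution")
}

#' HCN spec calibrated to 25 percent availability at -65 mV
#' @param target_open_fraction availability target
#' @param at_voltage voltage of the target (mV)
#' @param spec base spec whose offset is calibrated
#' @return \code{hcn_spec} with the calibrated offset
#' @export
calibrated_hcn_spec <- function(target_open_fraction = 0.25,
                                at_voltage = -65, spec = hcn_rate_spec()) {
  spec$voltage_offset <- calibrate_hcn_offset(target_open_fraction,
                                              at_voltage, spec)
  spec
}

#' Ionic current density through a conductance
#' @param open_fraction channel open fraction in [0, 1]
#' @param v membrane potential (mV)
#' @param density maximal conductance density (mS/cm^2)
#' @param e_rev reversal potential (mV)
#' @return current density (uA/cm^2), outward positive
#' @export
channel_current <- function(open_fraction, v, density, e_rev) {
  if (any(density < 0)) stop("negative channel density")
  density * open_fraction * (v - e_rev)
}

#' Write a channel distribution to a YAML config file
#' @param dist a \code{\link{channel_distribution}}
#' @param path output file
#' @export
write_channel_config <- function(dist, path) {
  x <- list(
    densities = lapply(as.data.frame(t(dist$densities)), as.list),
    passive = list(e_leak = dist$e_leak, Rm = dist$Rm, Ri = dist$Ri,
                   Cm = dist$Cm),
    reversals = list(e_na = dist$e_na, e_k = dist$e_k, e_hcn = dist$e_hcn),
    kinetics = list(na_shift = dist$na_shift,
                    na_h_shift = dist$na_h_shift,
                    kdr_shift = dist$kdr_shift,
                    na_persistent = unclass(dist$na_persistent),
                    hcn = unclass(dist$hcn)))
  names(x$densities) <- rownames(dist$densities)
  for (i in seq_along(x$densities)) names(x$densities[[i]]) <- REGIONS
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a channel distribution from a YAML config file
#' @param path config file; the bundled \code{table1_std.yaml} (see
#'   \code{system.file("extdata", package = "rgcds")}) holds the standard
#'   parameter set
#' @return a \code{\link{channel_distribution}}
#' @export
read_channel_config <- function(path) {
  x <- yaml::read_yaml(path)
  dens <- do.call(rbind, lapply(x$densities, function(r) unlist(r[REGIONS])))
  colnames(dens) <- REGIONS
  hcn <- do.call(hcn_rate_spec, x$kinetics$hcn)
  nap <- do.call(na_persistent_spec, x$kinetics$na_persistent)
  channel_distribution(densities = dens[c("na", "kdr", "hcn"), ],
                       e_leak = x$passive$e_leak, Rm = x$passive$Rm,
                       Ri = x$passive$Ri, Cm = x$passive$Cm,
                       e_na = x$reversals$e_na, e_k = x$reversals$e_k,
                       e_hcn = x$reversals$e_hcn,
                       na_shift = x$kinetics$na_shift,
                       na_h_shift = x$kinetics$na_h_shift,
                       kdr_shift = x$kinetics$kdr_shift,
                       kdr_rate_mult = x$kinetics$kdr_rate_mult,
                       na_persistent = nap, hcn = hcn)
}
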