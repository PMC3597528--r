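#' Synthetic EPSP trace
#'
#' Bi-exponential waveform a * (exp(-t/tau_fall) - exp(-t/tau_rise))
#' scaled to the requested peak amplitude, riding on a resting baseline,
#' with additive white Gaussian recording noise. Defaults emulate
#' subthreshold uncaging EPSPs: 1-4 mV amplitude and kinetics giving
#' roughly 48 ms 10-90 rise and 109 ms decay.
#'
#' @param amplitude peak amplitude above baseline (mV)
#' @param tau_rise,tau_fall bi-exponential time constants (ms); note the
#'   10-90 rise time is roughly 1.4 * tau_rise for these defaults
#' @param onset EPSP onset time (ms)
#' @param duration trace duration (ms)
#' @param baseline resting level (mV)
#' @param noise_sd Gaussian noise SD (mV)
#' @param sample_rate sampling rate (kHz)
#' @param seed RNG seed for the noise
#' @return an \code{\link{rgc_trace}}; ground-truth parameters are stored
#'   in \code{annotations$ground_truth}
#' @export
make_epsp <- function(amplitude = 2.5, tau_rise = 35, tau_fall = 109,
                      onset = 100, duration = 800, baseline = -65,
                      noise_sd = 0, sample_rate = 10, seed = NULL) {
  stopifnot(amplitude > 0, tau_rise > 0, tau_fall > 0, sample_rate > 0)
  if (tau_rise >= tau_fall) {
    warning("tau_rise >= tau_fall gives a degenerate bi-exponential shape")
  }
  dt <- 1 / sample_rate
  t <- seq(0, duration, by = dt)
  y <- biexp_waveform(t - onset, amplitude, tau_rise, tau_fall)
  if (noise_sd > 0) {
    y <- y + with_seed(seed, stats::rnorm(length(y), 0, noise_sd))
  }
  rgc_trace(baseline + y, dt = dt, t0 = 0, unit = "mV", vrest = baseline,
            annotations = list(
              stimuli = data.frame(onset = onset, duration = 0),
              ground_truth = list(amplitude = amplitude,
                                  tau_rise = tau_rise,
                                  tau_fall = tau_fall,
                                  noise_sd = noise_sd)))
}

# peak-normalized bi-exponential, 0 before time 0
biexp_waveform <- function(t, amplitude, tau_rise, tau_fall) {
  tp <- tau_rise * tau_fall / (tau_fall - tau_rise) *
    log(tau_fall / tau_rise)
  pk <- exp(-tp / tau_fall) - exp(-tp / tau_rise)
  y <- ifelse(t > 0, exp(-t / tau_fall) - exp(-t / tau_rise), 0)
  amplitude * y / pk
}

#' Closed-form peak time of the bi-exponential EPSP
#' @param tau_rise,tau_fall time constants (ms)
#' @return time of the maximum after onset (ms)
#' @export
biexp_peak_time <- function(tau_rise, tau_fall) {
  tau_rise * tau_fall / (tau_fall - tau_rise) * log(tau_fall / tau_rise)
}

#' Synthetic summed/single trace pair with an imposed summation ratio
#'
#' Builds a single EPSP and a train of \code{n_pulses} superposed copies,
#' then rescales the summed trace so its true summation ratio (in the
#' requested mode) equals \code{target_ratio} exactly in the noiseless
#' waveform; recovery of the target by \code{\link{summation_ratio}} is
#' the analysis-validation check.
#'
#' @param target_ratio imposed summation ratio (> 0)
#' @param mode "charge" or "amplitude"
#' @param n_pulses pulses in the train
#' @param delay inter-pulse delay (ms)
#' @param amplitude,tau_rise,tau_fall,baseline,noise_sd,sample_rate,seed
#'   as in \code{\link{make_epsp}}
#' @return list with \code{summed} and \code{single} traces; ground truth
#'   in each trace's annotations
#' @export
make_summation_fixture <- function(target_ratio, mode = c("charge",
                                                          "amplitude"),
                                   n_pulses = 3, delay = 50,
                                   amplitude = 2.5, tau_rise = 35,
                                   tau_fall = 109, baseline = -65,
                                   noise_sd = 0, sample_rate = 10,
                                   seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(target_ratio > 0)
  onset <- 100
  duration <- 100 + (n_pulses - 1) * delay + 8 * tau_fall
  dt <- 1 / sample_rate
  t <- seq(0, duration, by = dt)
  one <- biexp_waveform(t - onset, amplitude, tau_rise, tau_fall)
  summed_raw <- Reduce(`+`, lapply(seq_len(n_pulses) - 1, function(k) {
    biexp_waveform(t - onset - k * delay, amplitude, tau_rise, tau_fall)
  }))
  q1 <- trapz_sum(one, dt)
  scale <- switch(mode,
                  charge = target_ratio * n_pulses * q1 /
                    trapz_sum(summed_raw, dt),
                  amplitude = target_ratio * n_pulses * max(one) /
                    max(summed_raw))
  summed <- summed_raw * scale
  gt <- list(target_ratio = target_ratio, mode = mode,
             n_pulses = n_pulses, delay = delay, noise_sd = noise_sd)
  noises <- with_seed(seed, list(stats::rnorm(length(t), 0, noise_sd),
                                 stats::rnorm(length(t), 0, noise_sd)))
  if (noise_sd == 0) noises <- list(0, 0)
  st <- data.frame(onset = onset + (seq_len(n_pulses) - 1) * delay,
                   duration = 0)
  list(summed = rgc_trace(baseline + summed + noises[[1]], dt, 0, "mV",
                          vrest = baseline,
                          annotations = list(stimuli = st,
                                             ground_truth = gt)),
       single = rgc_trace(baseline + one + noises[[2]], dt, 0, "mV",
                          vrest = baseline,
                          annotations = list(stimuli = st[1, ],
                                             ground_truth = gt)))
}

trapz_sum <- function(y, dt) (sum(y) - (y[1] + y[length(y)]) / 2) * dt

#' Synthetic away/toward trace pair with imposed direction selectivity
#'
#' The toward trace is a summed EPSP train; the away trace is the same
#' waveform amplitude-scaled by (1 + ds_amplitude/100) and time-scaled so
#' that its charge is (1 + ds_charge/100) times the toward charge. Both
#' imposed DS values are recovered exactly by
#' \code{\link{directional_selectivity}} on the noiseless waveforms.
#'
#' @param target_ds_amplitude,target_ds_charge imposed DS (percent); both
#'   must be > -100
#' @param n_pulses,delay train structure
#' @param amplitude,tau_rise,tau_fall,baseline,noise_sd,sample_rate,seed
#'   as in \code{\link{make_epsp}}
#' @return list with \code{away} and \code{toward} traces
#' @export
make_direction_fixture <- function(target_ds_amplitude = 0,
                                   target_ds_charge = 0,
                                   n_pulses = 3, delay = 50,
                                   amplitude = 2.5, tau_rise = 35,
                                   tau_fall = 109, baseline = -65,
                                   noise_sd = 0, sample_rate = 10,
                                   seed = NULL) {
  if (target_ds_amplitude <= -100 || target_ds_charge <= -100) {
    stop("imposed DS targets must exceed -100 percent")
  }
  onset <- 100
  gamma <- 1 + target_ds_amplitude / 100
  s <- gamma / (1 + target_ds_charge / 100)  # time-axis compression
  duration <- 100 + ((n_pulses - 1) * delay + 10 * tau_fall) /
    min(1, s)
  dt <- 1 / sample_rate
  t <- seq(0, duration, by = dt)
  train <- function(tt) {
    Reduce(`+`, lapply(seq_len(n_pulses) - 1, function(k) {
      biexp_waveform(tt - k * delay, amplitude, tau_rise, tau_fall)
    }))
  }
  toward <- train(t - onset)
  away <- gamma * train((t - onset) * s)
  gt <- list(ds_amplitude = target_ds_amplitude,
             ds_charge = target_ds_charge, noise_sd = noise_sd)
  noises <- with_seed(seed, list(stats::rnorm(length(t), 0, noise_sd),
                                 stats::rnorm(length(t), 0, noise_sd)))
  if (noise_sd == 0) noises <- list(0, 0)
  st <- data.frame(onset = onset + (seq_len(n_pulses) - 1) * delay,
                   duration = 0)
  list(away = rgc_trace(baseline + away + noises[[1]], dt, 0, "mV",
                        vrest = baseline,
                        annotations = list(stimuli = st,
                                           ground_truth = gt)),
       toward = rgc_trace(baseline + toward + noises[[2]], dt, 0, "mV",
                          vrest = baseline,
                          annotations = list(stimuli = st,
                                             ground_truth = gt)))
}
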