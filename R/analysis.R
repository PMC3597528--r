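#' Peak response amplitude relative to baseline
#' @param trace an \code{\link{rgc_trace}}
#' @param baseline baseline value; defaults to the trace's resting level
#' @return peak deflection (trace unit)
#' @export
peak_amplitude <- function(trace, baseline = NULL) {
  if (is.null(baseline)) baseline <- trace_baseline(trace)
  max(trace$values) - baseline
}

#' Baseline-subtracted charge (trapezoidal integral) of a response
#'
#' Integrates (value - baseline) over [from, to]. The default window runs
#' from the first stimulus onset to the end of the trace; protocol traces
#' carry enough tail (several decay time constants) for the integral to be
#' insensitive to the right edge.
#'
#' @param trace an \code{\link{rgc_trace}}
#' @param from,to integration window (ms)
#' @param baseline baseline value; defaults to the trace's resting level
#' @return integral in unit * ms (mV ms for voltage traces)
#' @export
charge <- function(trace, from = NULL, to = NULL, baseline = NULL) {
  if (is.null(baseline)) baseline <- trace_baseline(trace)
  t <- trace_time(trace)
  if (is.null(from)) from <- first_onset(trace)
  if (is.null(to)) to <- t[length(t)]
  sel <- t >= from & t <= to
  y <- trace$values[sel] - baseline
  n <- length(y)
  if (n < 2) stop("charge window contains fewer than 2 samples")
  (sum(y) - (y[1] + y[n]) / 2) * trace$dt
}

#' Summation ratio of a summed multi-pulse response
#'
#' Ratio of the summed response to n_pulses times the single-pulse
#' response; 1 indicates linear summation, larger values supralinear
#' summation.
#'
#' @param summed trace of the summed (train) response
#' @param single trace of the single-pulse response
#' @param n_pulses number of pulses in the train
#' @param mode "amplitude" (peak) or "charge" (baseline-subtracted
#'   integral)
#' @return the summation ratio
#' @export
summation_ratio <- function(summed, single, n_pulses = 3,
                            mode = c("charge", "amplitude")) {
  mode <- match.arg(mode)
  stopifnot(n_pulses >= 2)
  denom_one <- switch(mode,
                      amplitude = peak_amplitude(single),
                      charge = charge(single))
  if (abs(denom_one) < 1e-12) {
    stop("single-response ", mode, " is ~0; summation ratio undefined")
  }
  num <- switch(mode,
                amplitude = peak_amplitude(summed),
                charge = charge(summed))
  num / (n_pulses * denom_one)
}

#' Directional selectivity of paired away/toward responses
#'
#' Signed percentage, positive for a centrifugal (away) preference:
#' amplitude mode uses (Vpeak_away - Vpeak_toward)/(Vpeak_toward - Vrest)
#' * 100 on absolute peak voltages; charge mode uses (Charge_away -
#' Charge_toward)/Charge_toward * 100 on baseline-subtracted integrals.
#'
#' @param away,toward traces for the two activation orders (shared
#'   baseline convention)
#' @param mode "amplitude" or "charge"
#' @param vrest shared resting potential; defaults to the away trace's
#'   baseline
#' @return DS in percent
#' @export
directional_selectivity <- function(away, toward,
                                    mode = c("amplitude", "charge"),
                                    vrest = NULL) {
  mode <- match.arg(mode)
  if (is.null(vrest)) vrest <- trace_baseline(away)
  if (mode == "amplitude") {
    vpa <- max(away$values)
    vpt <- max(toward$values)
    denom <- vpt - vrest
    if (abs(denom) < 1e-12) stop("Vpeak_toward equals Vrest; DS undefined")
    100 * (vpa - vpt) / denom
  } else {
    qa <- charge(away, baseline = vrest)
    qt <- charge(toward, baseline = vrest)
    if (abs(qt) < 1e-12) stop("toward charge is ~0; DS undefined")
    100 * (qa - qt) / qt
  }
}

#' EPSP kinetics: 10-90 percent rise time, decay constant, peak
#'
#' Rise time is measured between the 10 and 90 percent crossings of the
#' baseline-to-peak amplitude (linear interpolation between samples).
#' Decay is the time constant of a mono-exponential fitted (log-linear
#' least squares) to the falling phase between 90 and 10 percent of the
#' peak amplitude.
#'
#' @param trace an \code{\link{rgc_trace}} with a single dominant peak
#' @param baseline baseline value; defaults to the trace's resting level
#' @return list with \code{rise_10_90} (ms), \code{decay_tau} (ms; NA
#'   when the trace has no falling phase), \code{peak} (amplitude above
#'   baseline) and \code{t_peak} (ms)
#' @export
epsp_kinetics <- function(trace, baseline = NULL) {
  if (is.null(baseline)) baseline <- trace_baseline(trace)
  t <- trace_time(trace)
  y <- trace$values - baseline
  ipk <- which.max(y)
  peak <- y[ipk]
  if (peak <= 0) stop("no positive peak above baseline")
  cross_up <- function(level) {
    below <- which(y[seq_len(ipk)] < level)
    if (length(below) == 0) return(t[1])
    i <- max(below)
    if (i == ipk) return(t[ipk])
    t[i] + (level - y[i]) / (y[i + 1] - y[i]) * trace$dt
  }
  t10 <- cross_up(0.1 * peak)
  t90 <- cross_up(0.9 * peak)
  if (t90 < t10) stop("rise-phase 10/90 crossings not found")
  post <- seq(ipk, length(y))
  dec <- post[y[post] <= 0.9 * peak & y[post] >= 0.1 * peak & y[post] > 0]
  if (length(dec) < 3) {
    tau <- NA_real_   # no falling phase (e.g. step-like trace)
  } else {
    fit <- stats::lm(log(y[dec]) ~ t[dec])
    tau <- -1 / stats::coef(fit)[[2]]
  }
  list(rise_10_90 = t90 - t10, decay_tau = tau, peak = peak,
       t_peak = t[ipk])
}

#' Spike probability across trials
#'
#' A trial is suprathreshold when its voltage crosses \code{v_thresh} or
#' its derivative exceeds \code{dvdt_thresh} anywhere in the trace.
#'
#' @param trials list of \code{\link{rgc_trace}} voltage traces
#' @param v_thresh voltage threshold (mV)
#' @param dvdt_thresh slope threshold (mV/ms)
#' @return fraction of suprathreshold trials
#' @export
spike_probability <- function(trials, v_thresh = -20, dvdt_thresh = 20) {
  stopifnot(length(trials) >= 1)
  supra <- vapply(trials, function(tr) {
    dv <- diff(tr$values) / tr$dt
    any(tr$values > v_thresh) || any(dv > dvdt_thresh)
  }, logical(1))
  mean(supra)
}

#' Gaussian fit of the lateral stimulation-resolution profile
#'
#' Least-squares fit of a Gaussian a * exp(-(x - mu)^2 / (2 sigma^2)) to
#' response amplitude versus lateral distance; the half-maximal width
#' (FWHM = 2 sqrt(2 log 2) sigma) indexes the spatial resolution of the
#' stimulus.
#'
#' @param distances lateral offsets (um)
#' @param amplitudes response amplitudes at each offset
#' @return list with \code{fwhm} (um), \code{sigma}, \code{mu}, \code{a},
#'   and the fit object
#' @export
gaussian_resolution_fit <- function(distances, amplitudes) {
  stopifnot(length(distances) == length(amplitudes))
  if (length(distances) < 4) stop("need at least 4 points to fit")
  if (stats::sd(amplitudes) < 1e-12) {
    stop("amplitudes are constant; Gaussian fit is degenerate")
  }
  a0 <- max(amplitudes)
  mu0 <- distances[which.max(amplitudes)]
  w <- pmax(amplitudes, 0)
  sigma0 <- sqrt(sum(w * (distances - mu0)^2) / sum(w))
  if (!is.finite(sigma0) || sigma0 <= 0) sigma0 <- diff(range(distances)) / 4
  # fit in coordinates shifted so no start value sits at zero (a location
  # start of exactly 0 breaks the relative-step numeric derivative)
  x0 <- mu0 - sigma0
  xs <- distances - x0
  fit <- minpack.lm::nlsLM(
    amplitudes ~ a * exp(-(xs - mu)^2 / (2 * sigma^2)),
    start = list(a = 1.1 * a0, mu = sigma0, sigma = 1.3 * sigma0),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!fit$convInfo$isConv) {
    stop("Gaussian fit did not converge; residual sum of squares = ",
         signif(sum(stats::resid(fit)^2), 4))
  }
  cf <- stats::coef(fit)
  sigma <- abs(cf[["sigma"]])
  list(fwhm = 2 * sqrt(2 * log(2)) * sigma, sigma = sigma,
       mu = x0 + cf[["mu"]], a = cf[["a"]], fit = fit)
}

#' Tail-current I-V curve from paired voltage-step families
#'
#' Subtracts the channel-removed family from the control family and
#' measures, for every step, the mean difference current over the first
#' \code{window} ms after step offset, baseline-subtracted (mean
#' difference current over the pre-step baseline window). Amplitudes are
#' normalized to the largest magnitude in the family.
#'
#' @param control,blocked lists of \code{\link{rgc_trace}} current traces,
#'   one per step, on identical grids
#' @param steps step voltages (mV), same length as the trace lists
#' @param step_onset,step_offset step timing (ms)
#' @param window tail measurement window after offset (ms)
#' @param baseline_window length of the pre-step baseline window (ms)
#' @return data.frame with step, tail (nA) and tail_norm in [0, 1]
#' @export
tail_current_iv <- function(control, blocked, steps, step_onset,
                            step_offset, window = 5, baseline_window = 20) {
  if (length(control) != length(steps) || length(blocked) != length(steps)) {
    stop("control/blocked families and step list have mismatched lengths")
  }
  tails <- vapply(seq_along(steps), function(i) {
    tc <- control[[i]]; tb <- blocked[[i]]
    if (length(tc$values) != length(tb$values) || tc$dt != tb$dt) {
      stop("control and blocked traces are on different grids at step ",
           steps[i])
    }
    d <- tc$values - tb$values
    t <- trace_time(tc)
    base <- mean(d[t >= step_onset - baseline_window & t < step_onset])
    # strictly after the offset: the sample recorded at the offset itself
    # still reflects the step potential
    tail <- mean(d[t > step_offset & t <= step_offset + window])
    tail - base
  }, numeric(1))
  m <- max(abs(tails))
  data.frame(step = steps, tail = tails,
             tail_norm = if (m > 0) abs(tails) / m else tails)
}
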