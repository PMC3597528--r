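#' Uniformly sampled recording trace
#'
#' Container for a membrane-potential (mV) or clamp-current (nA) time
#' series on a uniform grid, with stimulus annotations and the resting
#' baseline used by the summation and direction-selectivity statistics.
#'
#' @param values sample values
#' @param dt sample interval (ms)
#' @param t0 time of the first sample (ms)
#' @param unit "mV" or "nA"
#' @param vrest resting baseline (same unit as values); NA if unknown
#' @param annotations list of stimulus annotations; the element
#'   \code{stimuli} is a data.frame with at least \code{onset} (ms)
#' @return object of class \code{rgc_trace}
#' @export
rgc_trace <- function(values, dt, t0 = 0, unit = "mV", vrest = NA_real_,
                      annotations = list()) {
  stopifnot(dt > 0, is.numeric(values))
  structure(list(values = as.numeric(values), dt = dt, t0 = t0,
                 unit = unit, vrest = vrest, annotations = annotations),
            class = "rgc_trace")
}

#' Time axis of a trace
#' @param trace an \code{rgc_trace}
#' @return numeric vector of sample times (ms)
#' @export
trace_time <- function(trace) {
  trace$t0 + (seq_along(trace$values) - 1) * trace$dt
}

#' @export
print.rgc_trace <- function(x, ...) {
  cat(sprintf("rgc_trace: %d samples @ %.4g ms (%.4g ms), unit %s\n",
              length(x$values), x$dt,
              length(x$values) * x$dt, x$unit))
  if (!is.na(x$vrest)) cat(sprintf("  baseline: %.3f %s\n", x$vrest, x$unit))
  st <- x$annotations$stimuli
  if (!is.null(st) && nrow(st)) {
    cat("  stimuli at", paste(round(st$onset, 1), collapse = ", "), "ms\n")
  }
  invisible(x)
}

#' @export
as.data.frame.rgc_trace <- function(x, ...) {
  data.frame(t = trace_time(x), value = x$values)
}

#' Write a trace to a tab-separated text file
#' @param trace an \code{rgc_trace}
#' @param path output file
#' @export
write_trace <- function(trace, path) {
  header <- sprintf("# unit=%s dt=%.17g t0=%.17g vrest=%.17g",
                    trace$unit, trace$dt, trace$t0, trace$vrest)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(as.data.frame(trace), con, row.names = FALSE,
                     quote = FALSE, sep = "\t")
  invisible(path)
}

#' Read a trace written by \code{\link{write_trace}}
#' @param path input file
#' @return an \code{rgc_trace}
#' @export
read_trace <- function(path) {
  header <- readLines(path, n = 1)
  kv <- regmatches(header, gregexpr("[a-z0-9]+=[^ ]+", header))[[1]]
  meta <- stats::setNames(
    lapply(kv, function(s) sub("^[a-z0-9]+=", "", s)),
    sub("=.*", "", kv))
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1)
  rgc_trace(df$value, dt = as.numeric(meta$dt), t0 = as.numeric(meta$t0),
            unit = meta$unit, vrest = as.numeric(meta$vrest))
}

trace_baseline <- function(trace) {
  if (!is.na(trace$vrest)) return(trace$vrest)
  st <- trace$annotations$stimuli
  t <- trace_time(trace)
  if (!is.null(st) && nrow(st) && any(t < min(st$onset))) {
    return(mean(trace$values[t < min(st$onset)]))
  }
  # fall back: first 10 percent of samples
  mean(trace$values[seq_len(max(1, length(trace$values) %/% 10))])
}

first_onset <- function(trace) {
  st <- trace$annotations$stimuli
  if (!is.null(st) && nrow(st)) min(st$onset) else trace$t0
}
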