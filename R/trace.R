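#' Construct a magnetic-tweezers trace object
#'
#' A trace is a data frame with columns `time` (s, uniform grid), `force`
#' (pN) and `extension` (nm), carrying the sampling rate, assay type, seed
#' and other metadata as attributes. Generators may additionally attach a
#' `truth` attribute (a list of ground-truth events) for recovery tests.
#'
#' @param time,force,extension equal-length numeric vectors.
#' @param sampling_rate sampling rate in Hz (>= 100).
#' @param assay assay label (e.g. "force_ramp", "force_jump",
#'   "strand_separation", "hopping").
#' @param seed RNG seed recorded for reproducibility.
#' @param metadata named list of additional metadata.
#' @param truth optional ground-truth list.
#' @return an object of class `mt_trace` (also a data frame).
#' @export
mt_trace <- function(time, force, extension, sampling_rate, assay = "generic",
                     seed = NA_integer_, metadata = list(), truth = NULL) {
  n <- length(time)
  stopifnot(length(force) == n, length(extension) == n)
  if (sampling_rate < 100)
    stop("sampling rate must be at least 100 Hz")
  dt <- diff(time)
  if (n > 1 && (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-6 / sampling_rate))
    stop("time must be a strictly increasing uniform grid")
  out <- data.frame(time = time, force = force, extension = extension)
  attr(out, "sampling_rate") <- sampling_rate
  attr(out, "assay") <- assay
  attr(out, "seed") <- seed
  attr(out, "metadata") <- metadata
  attr(out, "truth") <- truth
  class(out) <- c("mt_trace", "data.frame")
  out
}

#' @export
print.mt_trace <- function(x, ...) {
  cat(sprintf("<mt_trace> %s assay: %d samples at %g Hz (%.2f s), force %.2f-%.2f pN\n",
              attr(x, "assay"), nrow(x), attr(x, "sampling_rate"),
              nrow(x) / attr(x, "sampling_rate"),
              min(x$force), max(x$force)))
  invisible(x)
}

#' Sampling rate of a trace
#' @param trace an `mt_trace`.
#' @return rate in Hz.
#' @export
sampling_rate <- function(trace) attr(trace, "sampling_rate")

#' Ground-truth annotation of a synthetic trace
#' @param trace an `mt_trace`.
#' @return the generator's truth list, or `NULL`.
#' @export
trace_truth <- function(trace) attr(trace, "truth")

#' Build a force protocol from segments
#'
#' A protocol is an ordered table of segments, each holding a constant force
#' or ramping linearly between two forces over its duration. Force jumps are
#' represented as short ramps (default transition 0.39 s, the measured
#' jump time of the instrument protocol).
#'
#' @param kind character vector: "constant", "ramp" or "jump".
#' @param f_start,f_end forces at segment start/end, pN (equal for constant).
#' @param duration segment durations, s (> 0).
#' @return a data frame of class `force_protocol`.
#' @export
force_protocol <- function(kind, f_start, f_end = f_start, duration) {
  stopifnot(length(kind) == length(f_start), length(f_start) == length(f_end),
            length(duration) == length(f_start))
  if (any(duration <= 0)) stop("segment durations must be positive")
  if (any(f_start < 0) || any(f_end < 0)) stop("forces must be non-negative")
  out <- data.frame(kind = kind, f_start = f_start, f_end = f_end,
                    duration = duration)
  class(out) <- c("force_protocol", "data.frame")
  out
}

#' @rdname force_protocol
#' @param f_min,f_max force range of a ramp cycle, pN.
#' @param loading_rate ramp loading rate, pN/s.
#' @param cycles number of stretch-relax cycles.
#' @export
ramp_protocol <- function(f_min = 0.1, f_max = 17, loading_rate = 4,
                          cycles = 1) {
  dur <- (f_max - f_min) / loading_rate
  seg <- data.frame(kind = c("ramp", "ramp"), f_start = c(f_min, f_max),
                    f_end = c(f_max, f_min), duration = c(dur, dur))
  seg <- seg[rep(seq_len(2), cycles), ]
  force_protocol(seg$kind, seg$f_start, seg$f_end, seg$duration)
}

#' @rdname force_protocol
#' @param f_rest,f_test,f_high,f_max_jump the four force levels of a
#'   force-jump cycle (must be strictly increasing).
#' @param t_rest,t_test,t_high,t_max dwell durations at each level, s.
#' @param transition jump transition time, s.
#' @export
force_jump_protocol <- function(f_rest = 0, f_test = 8, f_high = 10,
                                f_max_jump = 20, t_rest = 120, t_test = 30,
                                t_high = 2, t_max = 2, transition = 0.39) {
  if (!(f_rest < f_test && f_test < f_high && f_high < f_max_jump))
    stop("force levels must satisfy F_rest < F_test < F_high < F_max")
  force_protocol(
    kind = c("constant", "jump", "constant", "jump", "constant", "jump",
             "constant", "jump"),
    f_start = c(f_rest, f_rest, f_test, f_test, f_high, f_high, f_max_jump,
                f_max_jump),
    f_end = c(f_rest, f_test, f_test, f_high, f_high, f_max_jump, f_max_jump,
              f_rest),
    duration = c(t_rest, transition, t_test, transition, t_high, transition,
                 t_max, transition))
}

#' Evaluate a protocol's force at given times
#'
#' @param protocol a [force_protocol()].
#' @param t times in s (0 at protocol start).
#' @return forces in pN (piecewise linear).
#' @export
protocol_force <- function(protocol, t) {
  ends <- cumsum(protocol$duration)
  starts <- c(0, ends[-length(ends)])
  idx <- findInterval(t, starts, rightmost.closed = FALSE)
  idx[idx < 1] <- 1L
  idx[idx > nrow(protocol)] <- nrow(protocol)
  frac <- (t - starts[idx]) / protocol$duration[idx]
  frac <- pmin(pmax(frac, 0), 1)
  protocol$f_start[idx] + frac * (protocol$f_end[idx] - protocol$f_start[idx])
}

#' Total duration of a protocol
#' @param protocol a [force_protocol()].
#' @return duration in s.
#' @export
protocol_duration <- function(protocol) sum(protocol$duration)

#' Force-dependent bead noise model
#'
#' Default Gaussian noise amplitude of the synthetic traces: 8 nm at forces
#' up to 8 pN, 3 nm at 14 pN and above, linearly interpolated in between.
#' Bead fluctuations shrink with tension; these amplitudes keep ~10-bp
#' unzipping steps resolvable at 100 Hz.
#'
#' @param force force in pN.
#' @return noise SD in nm.
#' @export
bead_noise_sd <- function(force) {
  lo <- 8; hi <- 3
  sd <- ifelse(force <= 8, lo,
               ifelse(force >= 14, hi, lo + (force - 8) * (hi - lo) / 6))
  sd
}

#' Probability of observing TRF1 binding per protocol cycle
#'
#' Lookup of the observed per-cycle binding probabilities at the tested
#' dimer concentrations: 38%, 50%, 76% and 60% at 10, 20, 25 and 40 nM.
#'
#' @param conc_nM dimer concentration, one of 10, 20, 25, 40.
#' @return probability in [0, 1].
#' @export
binding_probability <- function(conc_nM) {
  tab <- c(`10` = 0.38, `20` = 0.50, `25` = 0.76, `40` = 0.60)
  key <- as.character(conc_nM)
  if (!all(key %in% names(tab)))
    stop("no binding-probability preset for concentration ", conc_nM, " nM")
  unname(tab[key])
}
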