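# Step fitting by greedy recursive segmentation with a counter-fit quality
# stopping rule, plus the downstream rupture and residence-map analyses.

# Best single split of y: index t such that plateaus [1,t], [t+1,n] give the
# largest SSE reduction. Ties take the earlier index.
best_split <- function(y) {
  n <- length(y)
  if (n < 2) return(list(gain = 0, idx = NA_integer_))
  cs <- cumsum(y)
  tot <- cs[n]
  t <- seq_len(n - 1)
  m1 <- cs[t] / t
  m2 <- (tot - cs[t]) / (n - t)
  gain <- (m1 - m2)^2 * t * (n - t) / n
  i <- which.max(gain)
  list(gain = gain[i], idx = i)
}

# residual SSE of a partition given cumulative sums
partition_sse <- function(cs, css, bounds) {
  # bounds: plateau end indices including n; starts derived
  starts <- c(1L, head(bounds, -1L) + 1L)
  s <- css[bounds + 1L] - css[starts]
  m <- cs[bounds + 1L] - cs[starts]
  len <- bounds - starts + 1L
  sum(s - m^2 / len)
}

#' Fit plateaus and steps in a constant-force trace segment
#'
#' Greedy recursive segmentation in the style of step-fitting algorithms
#' for molecular-motor traces: repeatedly place the single step that
#' maximally reduces the residual sum of squares. The number of steps is
#' selected by a counter-fit quality measure -- for each candidate step
#' count the residual SSE of a counter staircase with steps at the fitted
#' plateau midpoints is compared with the fit's own residual SSE, and the
#' step count maximising that ratio is kept (a ratio never exceeding the
#' quality threshold yields zero steps). Plateaus whose levels differ by
#' less than a noise-derived threshold are merged, as are plateaus shorter
#' than the minimum dwell (the Nyquist filter: pauses of 20 ms or less at
#' 100 Hz are not resolvable).
#'
#' @param x an `mt_trace` at constant force, or a numeric vector of
#'   extensions (then `rate` must be given).
#' @param rate sampling rate in Hz (taken from the trace if omitted).
#' @param max_steps maximum number of steps to place.
#' @param min_dwell minimum retained plateau dwell, s.
#' @param quality_threshold counter-fit quality ratio below which no steps
#'   are accepted.
#' @param merge_sd_mult plateau-level merge threshold in units of the
#'   estimated noise SD.
#' @param force_tol maximal force excursion allowed in a "constant-force"
#'   trace segment, pN.
#' @return an object of class `step_fit`: `$plateaus` (start, end, level,
#'   dwell), `$steps` (index, time, size, level_before, level_after, dwell
#'   of the preceding plateau), `$sse`, `$sigma`, `$sampling_rate`.
#' @export
fit_steps <- function(x, rate = NULL, max_steps = 30, min_dwell = 0.02,
                      quality_threshold = 1, merge_sd_mult = 1,
                      force_tol = 0.5) {
  if (inherits(x, "mt_trace")) {
    if (max(x$force) - min(x$force) > force_tol)
      stop("segment is not at constant force")
    rate <- sampling_rate(x)
    y <- x$extension
  } else y <- as.numeric(x)
  if (is.null(rate)) stop("sampling rate required")
  n <- length(y)
  if (n < 10) stop("need at least 10 samples")

  cs <- c(0, cumsum(y))
  css <- c(0, cumsum(y^2))
  sse0 <- partition_sse(cs, css, n)

  bounds <- n  # plateau end indices
  fits <- list()
  quality <- numeric(0)
  cache <- new.env(parent = emptyenv())
  split_of <- function(a, b) {
    key <- paste0(a, ":", b)
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    res <- best_split(y[a:b])
    res$idx <- if (is.na(res$idx)) NA_integer_ else res$idx + a - 1L
    cache[[key]] <- res
    res
  }
  k <- 0
  while (k < max_steps) {
    starts <- c(1L, head(bounds, -1L) + 1L)
    cand <- lapply(seq_along(bounds), function(i) split_of(starts[i], bounds[i]))
    gains <- vapply(cand, `[[`, numeric(1), "gain")
    if (all(gains <= 0)) break
    best <- which.max(gains)
    bounds <- sort(c(bounds, cand[[best]]$idx))
    k <- k + 1
    # counter staircase: steps at fitted plateau midpoints
    st <- c(1L, head(bounds, -1L) + 1L)
    mids <- floor((st + bounds) / 2)
    mids <- sort(unique(mids[mids >= 1 & mids < n]))
    cb <- sort(unique(c(mids, n)))
    sse_fit <- partition_sse(cs, css, bounds)
    sse_counter <- partition_sse(cs, css, cb)
    fits[[k]] <- bounds
    quality[k] <- if (sse_fit < 1e-10 * max(sse0, 1)) Inf
                  else sse_counter / sse_fit
  }
  if (k == 0) {
    best_k <- 0
  } else {
    # the counter-fit ratio rises until the true step count and flattens
    # once extra steps chase noise; prefer the fewest steps within 5% of
    # the best quality (parsimony tie-break on the plateau)
    qmax <- max(quality)
    best_k <- if (qmax <= quality_threshold) 0
              else min(which(quality >= 0.95 * qmax))
  }
  bounds <- if (best_k == 0) n else fits[[best_k]]

  # local refinement: re-optimise each step position between its neighbour
  # boundaries (exact SSE search) until stable -- tightens the greedy
  # placements to a local optimum of the full segmentation SSE
  if (length(bounds) > 1) {
    for (sweep in 1:20) {
      changed <- FALSE
      for (j in seq_len(length(bounds) - 1L)) {
        a <- if (j == 1) 1L else bounds[j - 1L] + 1L
        b <- bounds[j + 1L]
        res <- best_split(y[a:b])
        idx <- res$idx + a - 1L
        if (!is.na(idx) && idx != bounds[j]) {
          bounds[j] <- idx
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }

  levels_of <- function(bounds) {
    starts <- c(1L, head(bounds, -1L) + 1L)
    (cs[bounds + 1L] - cs[starts]) / (bounds - starts + 1L)
  }
  lv <- levels_of(bounds)
  sse_fit <- partition_sse(cs, css, bounds)
  sigma <- sqrt(max(sse_fit, 0) / max(n - length(bounds), 1))

  # merge plateaus with nearly equal levels, then sub-Nyquist plateaus
  merge_pass <- function(bounds, drop_short) {
    repeat {
      if (length(bounds) == 1) break
      lv <- levels_of(bounds)
      starts <- c(1L, head(bounds, -1L) + 1L)
      len <- bounds - starts + 1L
      level_gap <- abs(diff(lv))
      small_level <- if (sigma > 0) which(level_gap < merge_sd_mult * sigma) else integer(0)
      if (length(small_level)) {
        i <- small_level[1]
        bounds <- bounds[-i]  # fuse plateau i with i+1
        next
      }
      if (drop_short) {
        short <- which(len <= min_dwell * rate)
        if (length(short)) {
          i <- short[1]
          lv <- levels_of(bounds)
          # fuse the short plateau into the neighbour with the closer level
          if (i == 1) bounds <- bounds[-1]
          else if (i == length(bounds)) bounds <- bounds[-(length(bounds) - 1L)]
          else if (abs(lv[i] - lv[i - 1]) <= abs(lv[i] - lv[i + 1]))
            bounds <- bounds[-(i - 1L)]
          else bounds <- bounds[-i]
          next
        }
      }
      break
    }
    bounds
  }
  bounds <- merge_pass(bounds, drop_short = TRUE)
  lv <- levels_of(bounds)
  starts <- c(1L, head(bounds, -1L) + 1L)
  len <- bounds - starts + 1L
  plateaus <- data.frame(start = starts, end = bounds, level = lv,
                         dwell = len / rate)
  nstep <- length(bounds) - 1L
  steps <- if (nstep > 0) data.frame(
    index = bounds[seq_len(nstep)],
    time = bounds[seq_len(nstep)] / rate,
    size = diff(lv),
    level_before = lv[seq_len(nstep)],
    level_after = lv[-1],
    dwell = plateaus$dwell[seq_len(nstep)]
  ) else data.frame(index = integer(0), time = numeric(0), size = numeric(0),
                    level_before = numeric(0), level_after = numeric(0),
                    dwell = numeric(0))
  structure(list(plateaus = plateaus, steps = steps,
                 sse = partition_sse(cs, css, bounds), sigma = sigma,
                 n = n, sampling_rate = rate),
            class = "step_fit")
}

#' @export
print.step_fit <- function(x, ...) {
  cat(sprintf("step fit: %d plateaus, %d steps, residual sigma %.3g\n",
              nrow(x$plateaus), nrow(x$steps), x$sigma))
  invisible(x)
}

# contiguous index runs where |force - f| <= tol
force_windows <- function(trace, f, tol = 0.3, min_samples = 10) {
  sel <- abs(trace$force - f) <= tol
  r <- rle(sel)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_samples
  data.frame(start = starts[keep], end = ends[keep])
}

#' Extract loop-rupture events from a force-jump trace
#'
#' Runs the step fitter on every test-force window of the trace, keeps the
#' upward steps, converts their sizes to base pairs with the
#' force-dependent dsDNA WLC factor at F_test, and reports the dwell of
#' each event: time since arrival at F_test for the first rupture, time
#' since the previous rupture otherwise.
#'
#' @param trace an `mt_trace` from a force-jump assay.
#' @param f_test test force, pN (default: from the trace metadata).
#' @param f_tol window tolerance around F_test, pN.
#' @param min_size_nm smallest step size counted as a rupture; default
#'   three noise SDs of the step fit (at least 1e-6 nm).
#' @param ds dsDNA WLC parameters.
#' @param ... passed to [fit_steps()].
#' @return data frame of rupture events (`molecule`, `window`, `f_test`,
#'   `time`, `delta_L_bp`, `dwell`); empty if no steps are found.
#' @export
extract_ruptures <- function(trace, f_test = NULL, f_tol = 0.3,
                             min_size_nm = NULL, ds = ds_wlc_params(), ...) {
  stopifnot(inherits(trace, "mt_trace"))
  md <- attr(trace, "metadata")
  if (is.null(f_test)) f_test <- md$f_test
  if (is.null(f_test)) stop("f_test must be given or present in the metadata")
  rate <- sampling_rate(trace)
  win <- force_windows(trace, f_test, f_tol)
  nm_per_bp <- ds_nm_per_bp(f_test, ds)
  out <- NULL
  for (w in seq_len(nrow(win))) {
    seg <- trace$extension[win$start[w]:win$end[w]]
    sf <- fit_steps(seg, rate = rate, ...)
    if (!nrow(sf$steps)) next
    thr <- if (is.null(min_size_nm)) max(3 * sf$sigma, 1e-6) else min_size_nm
    up <- sf$steps[sf$steps$size > thr, , drop = FALSE]
    if (!nrow(up)) next
    t0 <- trace$time[win$start[w]]
    times <- t0 + up$index / rate
    out <- rbind(out, data.frame(
      molecule = if (!is.null(md$molecule_id)) md$molecule_id else NA,
      window = w, f_test = f_test, time = times,
      delta_L_bp = up$size / nm_per_bp,
      dwell = c(times[1] - t0, diff(times))))
  }
  if (is.null(out))
    out <- data.frame(molecule = character(0), window = integer(0),
                      f_test = numeric(0), time = numeric(0),
                      delta_L_bp = numeric(0), dwell = numeric(0))
  out
}

#' Zero-correct a strand-separation trace into released-bp units
#'
#' Re-references a hairpin trace to the fully-open level at F_test: the
#' extension is subtracted from the open-plateau level and divided by the
#' ssDNA release factor (2 nt per unzipped bp times the ssDNA nm/nt at
#' F_test), so that 0 means fully open and positive values count the base
#' pairs still to unzip (the closed hairpin maps to the stem length). When
#' the construct is supplied, the loop nucleotides released at full opening
#' are accounted for so the closed level lands exactly on the stem length.
#'
#' @param trace an `mt_trace` from a strand-separation assay.
#' @param f_test test force, pN (default: metadata).
#' @param construct optional [build_hairpin()] object (for the loop-length
#'   correction and the stem length stored in the result).
#' @param f_tol window tolerance around F_test.
#' @param min_open_dwell minimal dwell of the fully-open plateau, s.
#' @param ss ssDNA WLC parameters.
#' @param ... passed to [fit_steps()].
#' @return the trace with an added `bp_remaining` column and attributes
#'   `open_level` (nm) and `nm_per_bp_released`.
#' @export
zero_correct <- function(trace, f_test = NULL, construct = NULL, f_tol = 0.3,
                         min_open_dwell = 0.1, ss = ss_wlc_params(), ...) {
  stopifnot(inherits(trace, "mt_trace"))
  md <- attr(trace, "metadata")
  if (is.null(f_test)) f_test <- md$f_test
  if (is.null(f_test)) stop("f_test must be given or present in the metadata")
  rate <- sampling_rate(trace)
  win <- force_windows(trace, f_test, f_tol)
  if (!nrow(win)) stop("trace has no samples at F_test")
  # fit the longest F_test window to locate the fully-open plateau
  w <- which.max(win$end - win$start)
  seg <- trace$extension[win$start[w]:win$end[w]]
  sf <- fit_steps(seg, rate = rate, ...)
  top <- which.max(sf$plateaus$level)
  if (sf$plateaus$dwell[top] < min_open_dwell)
    stop("no fully-open plateau detectable at F_test")
  open_level <- sf$plateaus$level[top]
  nm_per_bp <- 2 * ss_nm_per_nt(f_test, ss)
  loop_bp <- if (!is.null(construct)) nchar(construct$loop) / 2 else 0
  if (!is.null(construct)) {
    expected_open <- (2 * construct$stem_length + nchar(construct$loop)) *
      ss_nm_per_nt(f_test, ss)
    if (open_level < 0.5 * expected_open)
      stop("no fully-open plateau detectable at F_test")
  }
  # within the stem this places the closed hairpin at the stem length and a
  # fork paused after u unzipped bp at L - u; the fully-open level (which
  # also releases the loop nucleotides) is clamped to the zero reference
  bp_remaining <- pmax((open_level - trace$extension) / nm_per_bp - loop_bp, 0)
  out <- trace
  out$bp_remaining <- bp_remaining
  attr(out, "open_level") <- open_level
  attr(out, "nm_per_bp_released") <- nm_per_bp
  md$f_test <- f_test
  if (!is.null(construct)) md$stem_length <- construct$stem_length
  attr(out, "metadata") <- md
  out
}

#' Site-specific residence map from zero-corrected traces
#'
#' Accumulates, per base pair of the hairpin stem, the time the fork spends
#' blocked at that position across an ensemble of zero-corrected
#' strand-separation traces. Positions are 1-based from the fork end in the
#' unzipping direction: a sample with `b` base pairs still to unzip is
#' binned at the blocking site `L - round(b) + 1` (the first still-paired
#' base). Sample counts within the F_test window are divided by the
#' sampling rate and averaged over traces; fully-open samples fall outside
#' the stem and are excluded.
#'
#' @param traces list of zero-corrected traces ([zero_correct()]) sharing
#'   one construct.
#' @param stem_length stem length L in bp (default: metadata of the first
#'   trace).
#' @param f_tol tolerance around F_test when selecting samples.
#' @return object of class `residence_map`: data frame `$map` with
#'   `position_bp`, `time_s` (mean per trace), `se`, plus `$n_traces` and
#'   `$total_time`.
#' @export
residence_map <- function(traces, stem_length = NULL, f_tol = 0.3) {
  stopifnot(length(traces) >= 1)
  mds <- lapply(traces, attr, "metadata")
  constructs <- vapply(mds, function(m)
    if (is.null(m$construct)) NA_character_ else m$construct, character(1))
  if (length(unique(stats::na.omit(constructs))) > 1)
    stop("traces come from mixed constructs")
  if (is.null(stem_length)) stem_length <- mds[[1]]$stem_length
  if (is.null(stem_length)) stop("stem length unknown")
  L <- as.integer(stem_length)
  counts <- matrix(0, nrow = length(traces), ncol = L)
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    if (is.null(tr$bp_remaining)) stop("traces must be zero-corrected first")
    f_test <- attr(tr, "metadata")$f_test
    sel <- abs(tr$force - f_test) <= f_tol
    site <- L - round(tr$bp_remaining[sel]) + 1L
    site <- site[site >= 1L & site <= L]
    tab <- tabulate(site, nbins = L)
    counts[i, ] <- tab / sampling_rate(tr)
  }
  m <- colMeans(counts)
  se <- if (length(traces) > 1) apply(counts, 2, stats::sd) / sqrt(length(traces))
        else rep(NA_real_, L)
  structure(list(map = data.frame(position_bp = seq_len(L), time_s = m, se = se),
                 n_traces = length(traces), total_time = sum(counts)),
            class = "residence_map")
}

#' @export
print.residence_map <- function(x, ...) {
  cat(sprintf("residence map over %d bp from %d traces, %.2f s total occupancy\n",
              nrow(x$map), x$n_traces, x$total_time))
  invisible(x)
}
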