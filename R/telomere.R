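# Telomere-length measurement from force-ramp traces and population
# summaries.

#' Measure telomere length from a force-ramp trace
#'
#' Takes the median extension within a window around the reference force on
#' the stretching phase and converts it to base pairs via the extensible
#' WLC (~0.33 nm/bp at the default 17 pN). The median is robust to residual
#' rupture leaps near the reference force. If a relaxing phase is present,
#' the stretch and relax extensions are compared: a relative difference
#' above 5% flags possible unruptured compaction.
#'
#' @param trace an `mt_trace` from a force-ramp assay.
#' @param reference_force reference force, pN.
#' @param window half-width of the force window, pN.
#' @param ds dsDNA WLC parameters.
#' @return object of class `tl_measurement` with `tl_bp`, `extension_nm`,
#'   `reference_force`, `molecule` and `qc` (flag + stretch/relax values).
#' @export
measure_tl <- function(trace, reference_force = 17, window = 0.5,
                       ds = ds_wlc_params()) {
  stopifnot(inherits(trace, "mt_trace"))
  if (max(trace$force) < reference_force - window)
    stop("reference force never reached in this trace")
  imax <- which.max(trace$force)
  stretch <- seq_len(imax)
  sel_s <- stretch[abs(trace$force[stretch] - reference_force) <= window]
  if (!length(sel_s)) stop("no stretching-phase samples in the force window")
  ext_s <- stats::median(trace$extension[sel_s])
  ext_r <- NA_real_
  if (imax < nrow(trace)) {
    relax <- (imax + 1):nrow(trace)
    sel_r <- relax[abs(trace$force[relax] - reference_force) <= window]
    if (length(sel_r)) ext_r <- stats::median(trace$extension[sel_r])
  }
  qc_fail <- FALSE
  if (is.finite(ext_r) && ext_s > 0)
    qc_fail <- abs(ext_s - ext_r) / ext_s > 0.05
  if (ext_s <= 0) qc_fail <- TRUE
  md <- attr(trace, "metadata")
  structure(list(tl_bp = extension_to_bp(max(ext_s, 0), reference_force, ds),
                 extension_nm = ext_s,
                 reference_force = reference_force,
                 molecule = if (!is.null(md$molecule_id)) md$molecule_id else NA,
                 qc = list(flag = qc_fail, stretch_nm = ext_s,
                           relax_nm = ext_r)),
            class = "tl_measurement")
}

#' @export
print.tl_measurement <- function(x, ...) {
  cat(sprintf("TL = %.0f bp (extension %.1f nm at %g pN)%s\n", x$tl_bp,
              x$extension_nm, x$reference_force,
              if (x$qc$flag) " [QC flag]" else ""))
  invisible(x)
}

#' Summarise a telomere-length distribution
#'
#' Descriptive summary of a set of telomere-length measurements: mean, SD,
#' range, histogram, and the fraction of short telomeres below a
#' user-defined threshold (short telomeres, not the average, determine
#' chromosome stability).
#'
#' @param tl a numeric vector of lengths (bp) or a list of
#'   [measure_tl()] results.
#' @param short_threshold short-telomere threshold, bp.
#' @param bin_width histogram bin width, bp.
#' @return object of class `tl_distribution` with `mean`, `sd` (0 with
#'   `sd_undefined` flag when n = 1), `n`, `min`, `max`, `frac_short` and
#'   the histogram table `$histogram` (bin midpoints and counts).
#' @export
tl_distribution <- function(tl, short_threshold = 1000, bin_width = 250) {
  if (is.list(tl)) tl <- vapply(tl, function(m) m$tl_bp, numeric(1))
  n <- length(tl)
  if (n < 1) stop("need at least one measurement")
  sd_undef <- n == 1
  breaks <- seq(floor(min(tl) / bin_width) * bin_width,
                ceiling(max(tl) / bin_width) * bin_width + bin_width,
                by = bin_width)
  h <- graphics::hist(tl, breaks = breaks, plot = FALSE)
  structure(list(mean = mean(tl), sd = if (sd_undef) 0 else stats::sd(tl),
                 sd_undefined = sd_undef, n = n, min = min(tl), max = max(tl),
                 frac_short = mean(tl < short_threshold),
                 short_threshold = short_threshold,
                 histogram = data.frame(mid = h$mids, count = h$counts)),
            class = "tl_distribution")
}

#' @export
print.tl_distribution <- function(x, ...) {
  cat(sprintf("telomere lengths: %.2f +/- %.2f kb (mean +/- SD, n = %d), range %.2f-%.2f kb\n",
              x$mean / 1000, x$sd / 1000, x$n, x$min / 1000, x$max / 1000))
  cat(sprintf("  fraction below %g kb: %.3f\n", x$short_threshold / 1000,
              x$frac_short))
  invisible(x)
}
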