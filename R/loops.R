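# Loop-size population model: Gaussian mixtures of loop sizes truncated by
# the telomere-length budget, which induces the negative correlation
# between loop number and loop size.

#' Gaussian-mixture presets for TRF1-mediated loop sizes
#'
#' Loop-size (delta L, bp) mixture components observed at each tested dimer
#' concentration and telomere-length class. At 20 nM and TL 2.5-3.5 kb the
#' centers are 258 and 470 bp; at 20 nM and TL 1.5-2.5 kb, 172 and 415 bp;
#' the 40 nM and 10 nM presets follow the corresponding measured centers.
#'
#' @param conc_nM dimer concentration: 10, 20 or 40.
#' @param tl_kb telomere length in kb, used to pick the length class
#'   (1.5-2.5, 2.5-3.5 or 3.5-4.5; values outside are clamped to the
#'   nearest class).
#' @return data frame with columns `weight`, `mean`, `sd` (bp).
#' @export
loop_mixture_preset <- function(conc_nM, tl_kb = 3) {
  cls <- if (tl_kb < 2.5) "short" else if (tl_kb < 3.5) "mid" else "long"
  key <- paste(conc_nM, cls, sep = "_")
  presets <- list(
    `10_short` = data.frame(weight = c(0.5, 0.5), mean = c(250, 640), sd = c(100, 212)),
    `10_mid`   = data.frame(weight = c(0.5, 0.5), mean = c(250, 640), sd = c(100, 212)),
    `10_long`  = data.frame(weight = c(0.5, 0.5), mean = c(250, 640), sd = c(100, 212)),
    `20_short` = data.frame(weight = c(0.5, 0.5), mean = c(172, 415), sd = c(170, 157)),
    `20_mid`   = data.frame(weight = c(0.5, 0.5), mean = c(258, 470), sd = c(117, 120)),
    `20_long`  = data.frame(weight = c(0.4, 0.4, 0.2), mean = c(442, 785, 1266),
                            sd = c(171, 223, 164)),
    `40_short` = data.frame(weight = 1, mean = 340, sd = 207),
    `40_mid`   = data.frame(weight = c(0.5, 0.5), mean = c(290, 538), sd = c(134, 212)),
    `40_long`  = data.frame(weight = c(0.5, 0.5), mean = c(277, 725), sd = c(135, 181))
  )
  p <- presets[[key]]
  if (is.null(p)) stop("no loop-mixture preset for ", conc_nM, " nM")
  p
}

#' Sample a population of loop sizes for one telomere
#'
#' Draws loop sizes delta L from a truncated (delta L > 0) Gaussian mixture,
#' sequentially accepting draws while the accumulated loop size stays within
#' the telomere-length budget (sum delta L <= TL). Draws that would exceed
#' the budget are rejected, so telomeres that happen to draw large loops
#' accommodate fewer of them -- the mechanism behind the negative
#' correlation between loop number and loop size.
#'
#' @param tl_bp telomere length, bp (the budget).
#' @param mixture data frame with `weight`, `mean`, `sd` columns (bp);
#'   weights are normalised. An `sd` of 0 gives a point mass.
#' @param n_attempts number of binding attempts.
#' @return numeric vector of accepted loop sizes (possibly empty).
#' @export
sample_loop_population <- function(tl_bp, mixture, n_attempts = 12) {
  stopifnot(tl_bp > 0, n_attempts >= 0)
  w <- mixture$weight / sum(mixture$weight)
  if (all(mixture$mean - 2 * mixture$sd > tl_bp))
    stop("infeasible mixture: essentially all mass above the telomere length")
  draws <- numeric(0)
  budget <- tl_bp
  for (i in seq_len(n_attempts)) {
    comp <- sample.int(nrow(mixture), 1, prob = w)
    val <- -1
    tries <- 0
    while (val <= 0 && tries < 100) {
      val <- stats::rnorm(1, mixture$mean[comp], mixture$sd[comp])
      if (mixture$sd[comp] == 0) val <- mixture$mean[comp]
      tries <- tries + 1
    }
    if (val <= 0) next
    if (val <= budget) {
      draws <- c(draws, val)
      budget <- budget - val
    }
  }
  draws
}

#' Sample telomere lengths from the measured population distribution
#'
#' Truncated normal emulating the single-molecule telomere-length
#' distribution: mean 2.5 kb, SD 0.9 kb, truncated to the observed extremes
#' of 0.3 and 7.4 kb.
#'
#' @param n number of molecules.
#' @param mean_bp,sd_bp normal parameters, bp.
#' @param min_bp,max_bp truncation bounds, bp.
#' @return telomere lengths in bp.
#' @export
sample_tl_population <- function(n, mean_bp = 2500, sd_bp = 900,
                                 min_bp = 300, max_bp = 7400) {
  lo <- stats::pnorm((min_bp - mean_bp) / sd_bp)
  hi <- stats::pnorm((max_bp - mean_bp) / sd_bp)
  u <- stats::runif(n, lo, hi)
  mean_bp + sd_bp * stats::qnorm(u)
}

#' Simulate a multi-molecule loop ensemble for correlation analysis
#'
#' Draws `n_molecules` telomeres (lengths from the truncated population
#' distribution, concentrations assigned round-robin across the tested
#' regimes) and samples each molecule's loop population from its preset
#' mixture under the length-budget constraint. Returns per-molecule and
#' per-event tables in the layout used for the loop-number versus loop-size
#' correlation analysis.
#'
#' @param n_molecules number of telomeres.
#' @param conc_levels dimer concentrations to cycle through, nM.
#' @param n_attempts mean number of binding attempts per molecule (Poisson).
#' @param tl_range telomere-length truncation range, bp.
#' @param seed mandatory RNG seed.
#' @return list with `molecules` (molecule, conc_nM, tl_bp, n_loops) and
#'   `events` (molecule, conc_nM, tl_bp, n_loops, delta_L).
#' @export
simulate_loop_ensemble <- function(n_molecules = 131,
                                   conc_levels = c(10, 20, 40),
                                   n_attempts = 12,
                                   tl_range = c(1500, 4500), seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is required for reproducibility")
  set.seed(seed)
  tl <- sample_tl_population(n_molecules, min_bp = tl_range[1],
                             max_bp = tl_range[2])
  conc <- rep_len(conc_levels, n_molecules)
  molecules <- data.frame(molecule = seq_len(n_molecules), conc_nM = conc,
                          tl_bp = tl, n_loops = 0L)
  events <- NULL
  for (i in seq_len(n_molecules)) {
    mix <- loop_mixture_preset(conc[i], tl[i] / 1000)
    att <- stats::rpois(1, n_attempts)
    dl <- sample_loop_population(tl[i], mix, n_attempts = att)
    molecules$n_loops[i] <- length(dl)
    if (length(dl))
      events <- rbind(events, data.frame(molecule = i, conc_nM = conc[i],
                                         tl_bp = tl[i],
                                         n_loops = length(dl), delta_L = dl))
  }
  list(molecules = molecules, events = events)
}
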