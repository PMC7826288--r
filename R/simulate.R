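# Synthetic trace generators emulating the instrument assays. All generators
# require an explicit seed and attach their ground truth to the trace.

safe_ds_xrel <- function(force, ds) {
  x <- numeric(length(force))
  pos <- force > 0
  if (any(pos)) x[pos] <- pmax(0, ds_relative_extension(force[pos], ds))
  x
}

clamp_extension <- function(ext, contour_nm) {
  pmin(pmax(ext, 0), contour_nm * 1.05)
}

#' Simulate a force-ramp (force-extension) trace of a telomere
#'
#' Emulates a force-ramp assay on a telomeric dsDNA molecule, optionally
#' compacted by protein-mediated loops. The extension follows the extensible
#' WLC of the currently extended contour (telomere length minus the summed
#' sizes of still-compacted loops); each loop ruptures stochastically along
#' the ramp with a force-dependent rate k(F) = k0 exp(F x_dagger / kBT),
#' sampled by integrating the hazard over the force protocol. Gaussian bead
#' noise is added with a force-dependent amplitude.
#'
#' @param tl_bp telomere length in base pairs.
#' @param loops `NULL` or a data frame with columns `delta_L` (bp) and
#'   optionally `k0` (s^-1) and `x_dagger` (nm) per loop.
#' @param protocol a [force_protocol()] containing ramp segments.
#' @param sampling_rate Hz (>= 100).
#' @param noise_sd `NULL` for the force-dependent default ([bead_noise_sd()]),
#'   or a fixed value in nm (0 disables noise).
#' @param seed mandatory RNG seed.
#' @param ds dsDNA WLC parameters.
#' @param molecule_id identifier stored in the metadata.
#' @return an `mt_trace` with truth `$loops` (delta_L, rupture_time,
#'   rupture_force).
#' @export
simulate_force_extension <- function(tl_bp, loops = NULL,
                                     protocol = ramp_protocol(),
                                     sampling_rate = 200, noise_sd = NULL,
                                     seed, ds = ds_wlc_params(),
                                     molecule_id = "mol1") {
  if (missing(seed) || is.null(seed)) stop("a seed is required for reproducibility")
  if (!any(protocol$kind == "ramp")) stop("protocol must contain ramp segments")
  if (!is.null(loops) && sum(loops$delta_L) > tl_bp)
    stop("summed loop sizes exceed the telomere length")
  set.seed(seed)
  dt <- 1 / sampling_rate
  t <- seq(0, protocol_duration(protocol) - dt, by = dt)
  f <- protocol_force(protocol, t)
  xrel <- safe_ds_xrel(f, ds)

  rupture <- data.frame(delta_L = numeric(0), rupture_time = numeric(0),
                        rupture_force = numeric(0))
  compacted <- rep(0, length(t))
  if (!is.null(loops) && nrow(loops) > 0) {
    k0 <- if ("k0" %in% names(loops)) loops$k0 else rep(0.04, nrow(loops))
    xd <- if ("x_dagger" %in% names(loops)) loops$x_dagger else rep(0.7, nrow(loops))
    for (i in seq_len(nrow(loops))) {
      hazard <- k0[i] * exp(f * xd[i] / ds$kbt)
      cumhaz <- cumsum(hazard * dt)
      u <- stats::runif(1)
      idx <- which(cumhaz >= -log(u))[1]
      rt <- if (is.na(idx)) Inf else t[idx]
      rupture <- rbind(rupture, data.frame(
        delta_L = loops$delta_L[i], rupture_time = rt,
        rupture_force = if (is.finite(rt)) f[idx] else NA_real_))
      compacted <- compacted + loops$delta_L[i] * (t < rt)
    }
  }
  ext <- (tl_bp - compacted) * ds$rise_per_bp * xrel
  if (is.null(noise_sd)) noise_sd <- bead_noise_sd(f)
  if (any(noise_sd > 0)) ext <- ext + stats::rnorm(length(t), 0, noise_sd)
  ext <- clamp_extension(ext, tl_bp * ds$rise_per_bp)
  mt_trace(t, f, ext, sampling_rate, assay = "force_ramp", seed = seed,
           metadata = list(molecule_id = molecule_id, tl_bp = tl_bp),
           truth = list(loops = rupture, tl_bp = tl_bp))
}

#' Exponential rupture-dwell sampler at a fixed test force
#'
#' Draws dissociation dwell times at a constant force from the Bell-Evans
#' law, Exp(rate = k0 exp(F x_dagger / kBT)). This is the elementary waiting
#' time used by the force-jump generator; exposed so that dwell ensembles
#' can be generated directly for kinetic-recovery studies.
#'
#' @param n number of draws.
#' @param force test force, pN.
#' @param k0 zero-force dissociation rate, s^-1.
#' @param x_dagger activation distance, nm.
#' @param kbt thermal energy, pN.nm.
#' @return dwell times in s.
#' @export
draw_rupture_dwells <- function(n, force, k0 = 0.04, x_dagger = 0.7,
                                kbt = kbt_default) {
  stats::rexp(n, rate = bell_evans_rate(force, k0, x_dagger, kbt))
}

#' Simulate a force-jump trace with loop-rupture leaps
#'
#' Emulates the four-level force-jump assay (F_rest, F_test, F_high, F_max).
#' During the resting phase the molecule coils at low force and each
#' candidate loop binds with the configured per-cycle probability. On the
#' jump to F_test the bound loops rupture sequentially, each after an
#' exponential waiting time with Bell-Evans rate k(F_test); loops still
#' bound when the protocol moves on rupture at the higher forces. Each
#' rupture produces an upward extension leap of delta_L converted at the
#' instantaneous force.
#'
#' @inheritParams simulate_force_extension
#' @param loops data frame with column `delta_L` (bp), the candidate loops.
#' @param k0,x_dagger Bell-Evans parameters shared by all loops.
#' @param protocol a [force_jump_protocol()].
#' @param bind_prob per-cycle probability that a candidate loop is bound.
#' @param cycles number of protocol repetitions.
#' @return an `mt_trace`; truth `$events` has one row per rupture with
#'   `cycle`, `delta_L`, `time`, `force` and `dwell` (time since arrival at
#'   F_test or since the previous rupture).
#' @export
simulate_force_jump <- function(tl_bp, loops, k0 = 0.04, x_dagger = 0.7,
                                protocol = force_jump_protocol(),
                                bind_prob = 1, cycles = 1,
                                sampling_rate = 200, noise_sd = NULL,
                                seed, ds = ds_wlc_params(),
                                molecule_id = "mol1") {
  if (missing(seed) || is.null(seed)) stop("a seed is required for reproducibility")
  if (sum(loops$delta_L) > tl_bp)
    stop("summed loop sizes exceed the telomere length")
  set.seed(seed)
  dt <- 1 / sampling_rate
  cyc_dur <- protocol_duration(protocol)
  t <- seq(0, cycles * cyc_dur - dt, by = dt)
  f <- protocol_force(protocol, (t %% cyc_dur))
  xrel <- safe_ds_xrel(f, ds)

  # arrival time at F_test within a cycle: end of the first jump segment
  f_test <- protocol$f_end[which(protocol$kind == "jump")[1]]
  seg_ends <- cumsum(protocol$duration)
  test_seg <- which(protocol$kind == "constant" & protocol$f_start == f_test)[1]
  test_start <- if (test_seg == 1) 0 else seg_ends[test_seg - 1]
  test_end <- seg_ends[test_seg]
  f_after <- max(protocol$f_end)  # residual ruptures at the strongest force

  events <- NULL
  compacted <- rep(0, length(t))
  for (cy in seq_len(cycles)) {
    bound <- which(stats::runif(nrow(loops)) < bind_prob)
    if (!length(bound)) next
    k_test <- bell_evans_rate(f_test, k0, x_dagger, ds$kbt)
    gaps <- stats::rexp(length(bound), rate = k_test)
    rel <- cumsum(gaps)  # rupture times relative to F_test arrival
    # events that would fall beyond the F_test window rupture quickly at
    # the strongest force instead
    over <- rel > (test_end - test_start)
    if (any(over)) {
      k_hi <- bell_evans_rate(f_after, k0, x_dagger, ds$kbt)
      extra <- cumsum(stats::rexp(sum(over), rate = k_hi))
      rel[over] <- (test_end - test_start) + extra
    }
    abs_time <- (cy - 1) * cyc_dur + test_start + rel
    dwell <- c(rel[1], diff(rel))
    ev <- data.frame(cycle = cy, delta_L = loops$delta_L[bound],
                     time = abs_time,
                     force = protocol_force(protocol, pmin(test_start + rel,
                                                           cyc_dur - 1e-9)),
                     dwell = dwell)
    events <- rbind(events, ev)
    cyc_idx <- t >= (cy - 1) * cyc_dur & t < cy * cyc_dur
    for (j in seq_along(bound)) {
      compacted <- compacted +
        loops$delta_L[bound[j]] * (cyc_idx & t >= (cy - 1) * cyc_dur + test_start &
                                     t < abs_time[j])
    }
  }
  ext <- (tl_bp - compacted) * ds$rise_per_bp * xrel
  if (is.null(noise_sd)) noise_sd <- bead_noise_sd(f)
  if (any(noise_sd > 0)) ext <- ext + stats::rnorm(length(t), 0, noise_sd)
  ext <- clamp_extension(ext, tl_bp * ds$rise_per_bp)
  mt_trace(t, f, ext, sampling_rate, assay = "force_jump", seed = seed,
           metadata = list(molecule_id = molecule_id, tl_bp = tl_bp,
                           f_test = f_test, test_window = c(test_start, test_end),
                           cycle_duration = cyc_dur),
           truth = list(events = events, tl_bp = tl_bp, k0 = k0,
                        x_dagger = x_dagger))
}

#' Simulate a hairpin strand-separation trace with bound dimers
#'
#' Emulates the three-level unzipping protocol (F_low, F_test, F_high) on a
#' telomeric hairpin. Below the critical melting force the stem stays
#' closed. On arrival at F_test the fork advances instantly to the first
#' bound dimer footprint, pauses there for an exponential dwell, then hops
#' to the next, releasing 2 nt of ssDNA per unzipped bp converted to nm via
#' the ssDNA WLC at the instantaneous force. After the last pause the stem
#' opens fully (releasing the loop nucleotides as well), which defines the
#' zero-correction reference level.
#'
#' @param construct a [build_hairpin()] object.
#' @param bound_sites dimer footprint start positions (bp from the fork
#'   end); validated against [telomeric_sites()].
#' @param tau mean pause dwell, s.
#' @param f_low,f_test,f_high protocol force levels, pN.
#' @param t_low,t_high,t_open durations of the low-force phase, high-force
#'   phase and of the fully-open tail at F_test, s.
#' @param transition force-jump time, s.
#' @param sampling_rate Hz.
#' @param noise_sd Gaussian bead noise, nm (0 disables).
#' @param seed mandatory RNG seed.
#' @param ss ssDNA WLC parameters.
#' @param molecule_id identifier stored in the metadata.
#' @return an `mt_trace`; truth `$pauses` holds one row per bound site with
#'   its blocking position (first protected base) and dwell.
#' @export
simulate_strand_separation <- function(construct, bound_sites = integer(0),
                                       tau = 0.36, f_low = 6, f_test = 17,
                                       f_high = 22, t_low = 1, t_high = 1,
                                       t_open = 2, transition = 0.39,
                                       sampling_rate = 100, noise_sd = 3,
                                       seed, ss = ss_wlc_params(),
                                       molecule_id = "mol1") {
  if (missing(seed) || is.null(seed)) stop("a seed is required for reproducibility")
  stopifnot(inherits(construct, "hairpin_construct"))
  bound_sites <- if (length(bound_sites)) validate_dimer_sites(construct, bound_sites)
                 else integer(0)
  set.seed(seed)
  L <- construct$stem_length
  loop_nt <- nchar(construct$loop)
  dwells <- if (length(bound_sites)) stats::rexp(length(bound_sites), 1 / tau)
            else numeric(0)
  t_test <- sum(dwells) + t_open

  protocol <- force_protocol(
    kind = c("constant", "jump", "constant", "jump", "constant", "jump",
             "constant", "jump"),
    f_start = c(f_low, f_low, f_test, f_test, f_high, f_high, f_test, f_test),
    f_end = c(f_low, f_test, f_test, f_high, f_high, f_test, f_test, f_low),
    duration = c(t_low, transition, t_test, transition, t_high, transition,
                 max(t_open, 0.5), transition))
  dt <- 1 / sampling_rate
  t <- seq(0, protocol_duration(protocol) - dt, by = dt)
  f <- protocol_force(protocol, t)

  # unzipped bp as a function of time: fork blocked at each bound dimer in
  # ascending order, transit between sites instantaneous. The fork invades
  # the proximal motif of the 12-bp footprint and rests at its midpoint
  # (the proximal Myb grip yields before the dimer core does), so a dimer
  # whose footprint starts at s pauses the fork at s + 5 unzipped bp.
  arrive <- t_low + transition
  open_from <- arrive + sum(dwells)
  unzipped <- rep(0, length(t))
  in_test_or_later <- t >= arrive & t < protocol_duration(protocol) - transition
  if (length(bound_sites)) {
    pause_start <- arrive + cumsum(c(0, dwells[-length(dwells)]))
    pause_end <- arrive + cumsum(dwells)
    for (j in seq_along(bound_sites)) {
      sel <- t >= pause_start[j] & t < pause_end[j]
      unzipped[sel] <- bound_sites[j] + 5L
    }
  }
  unzipped[t >= open_from & in_test_or_later] <- L
  unzipped[!in_test_or_later] <- 0
  # during the low-force tail the hairpin re-zips; at the final transition
  # back to f_low leave it closed (no bound protein left)
  released_nt <- 2 * unzipped + ifelse(unzipped >= L, loop_nt, 0)
  nm_per_nt <- ss$contour_per_nt * vapply(f, function(ff)
    if (ff <= 0) 0 else ss_relative_extension(ff, ss), numeric(1))
  ext <- released_nt * nm_per_nt
  if (noise_sd > 0) ext <- ext + stats::rnorm(length(t), 0, noise_sd)
  ext <- pmax(ext, 0)
  pauses <- data.frame(site = bound_sites,
                       unzipped_bp = if (length(bound_sites)) bound_sites + 5L else integer(0),
                       dwell = dwells)
  mt_trace(t, f, ext, sampling_rate, assay = "strand_separation", seed = seed,
           metadata = list(molecule_id = molecule_id,
                           construct = construct$type,
                           stem_length = L, f_test = f_test, tau = tau),
           truth = list(pauses = pauses, stem_length = L,
                        open_level_nt = 2 * L + loop_nt))
}

#' Randomly place bound dimers on a hairpin stem
#'
#' Walks the candidate footprints from the fork end, binding each with the
#' given probability while skipping footprints that would overlap an
#' already-bound dimer.
#'
#' @param construct a [build_hairpin()] object.
#' @param prob binding probability per candidate footprint.
#' @param footprint footprint length, bp.
#' @return footprint start positions (possibly empty).
#' @export
bind_dimer_sites <- function(construct, prob = 0.3, footprint = 12L) {
  sites <- telomeric_sites(construct, footprint)
  bound <- integer(0)
  last_end <- -Inf
  for (s in sites) {
    if (s <= last_end) next
    if (stats::runif(1) < prob) {
      bound <- c(bound, s)
      last_end <- s + footprint - 1L
    }
  }
  bound
}

#' Simulate a constant-force two-state hopping trace
#'
#' Emulates a telomeric fork hopping between a backward (more zipped) and a
#' forward (more open) state at constant force. The telegraph process obeys
#' detailed balance with k_open / k_close = exp((F - F_half) dx / kBT), so
#' the stationary open probability follows the Boltzmann relation; the
#' attempt rate sets the absolute time scale (both rates equal the attempt
#' rate at F_half). Emission is the state level (amplitude dx, in nm at the
#' probed force) plus Gaussian noise.
#'
#' @param force probed force, pN (should be within ~1 pN of `f_half`).
#' @param f_half force of half-opening, pN.
#' @param delta_x opening distance, nm (> 0).
#' @param attempt_rate rate scale, s^-1.
#' @param duration trace duration, s.
#' @param sampling_rate Hz.
#' @param noise_sd emission noise SD, nm.
#' @param baseline backward-state extension level, nm.
#' @param seed mandatory RNG seed.
#' @param kbt thermal energy, pN.nm.
#' @return an `mt_trace`; truth holds the state path, dwell list and rates.
#'   If the duration covers fewer than 20 expected dwells the metadata flag
#'   `short_trace` is set.
#' @export
simulate_hopping <- function(force, f_half = 14.7, delta_x = 14,
                             attempt_rate = 1, duration = 200,
                             sampling_rate = 200, noise_sd = 2,
                             baseline = 0, seed, kbt = kbt_default) {
  if (missing(seed) || is.null(seed)) stop("a seed is required for reproducibility")
  stopifnot(delta_x > 0, duration > 0)
  set.seed(seed)
  d <- (force - f_half) * delta_x / kbt
  k_open <- attempt_rate * exp(d / 2)   # backward -> forward
  k_close <- attempt_rate * exp(-d / 2) # forward -> backward
  p_open <- 1 / (1 + exp(-d))
  mean_cycle <- 1 / k_open + 1 / k_close
  short_trace <- duration < 20 * mean_cycle / 2

  state <- as.integer(stats::runif(1) < p_open) # 1 = forward/open
  switch_times <- numeric(0)
  states <- integer(0)
  tt <- 0
  while (tt < duration) {
    states <- c(states, state)
    rate <- if (state == 1L) k_close else k_open
    dwell <- stats::rexp(1, rate)
    tt <- tt + dwell
    switch_times <- c(switch_times, tt)
    state <- 1L - state
  }
  dt <- 1 / sampling_rate
  t <- seq(0, duration - dt, by = dt)
  idx <- findInterval(t, c(0, switch_times), rightmost.closed = FALSE)
  path <- states[pmin(idx, length(states))]
  ext <- baseline + path * delta_x
  if (noise_sd > 0) ext <- ext + stats::rnorm(length(t), 0, noise_sd)
  dwell_list <- diff(c(0, switch_times))
  mt_trace(t, rep(force, length(t)), ext, sampling_rate, assay = "hopping",
           seed = seed,
           metadata = list(f_half = f_half, delta_x = delta_x,
                           attempt_rate = attempt_rate,
                           short_trace = short_trace),
           truth = list(path = path, states = states,
                        switch_times = switch_times, dwells = dwell_list,
                        k_open = k_open, k_close = k_close, p_open = p_open))
}

#' Hopping-condition presets with and without TRF1
#'
#' Two-state fork presets sharing F_half = 14.7 pN, with opening free
#' energies of 61 kBT (TRF1 present) and 50 kBT (bare fork); the opening
#' distance is back-calculated as delta_x = delta_G kBT / F_half.
#'
#' @param trf1 logical; TRF1 present?
#' @param kbt thermal energy, pN.nm.
#' @return list with `f_half`, `delta_x`, `delta_g_kbt`.
#' @export
hopping_preset <- function(trf1 = FALSE, kbt = kbt_default) {
  dg <- if (trf1) 61 else 50
  f_half <- 14.7
  list(f_half = f_half, delta_x = dg * kbt / f_half, delta_g_kbt = dg)
}
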