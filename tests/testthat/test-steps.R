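test_that("noiseless staircases are recovered exactly", {
  lv <- c(0, 10, 22, 30, 45, 52, 60)
  dur <- c(60, 50, 70, 55, 80, 50, 65)
  sf <- fit_steps(make_staircase(lv, dur), rate = 100)
  expect_equal(nrow(sf$steps), 6)
  expect_equal(sf$steps$index, cumsum(dur)[1:6], ignore_attr = TRUE)
  expect_equal(sf$plateaus$level, lv, tolerance = 1e-12)
  expect_equal(sf$sse, 0, tolerance = 1e-9)
})

test_that("fit_steps matches the exhaustive change-point oracle", {
  # noiseless traces with up to 4 steps, <= 200 samples
  cases <- list(
    list(lv = c(0, 8), dur = c(90, 110)),
    list(lv = c(5, -3, 12), dur = c(40, 70, 60)),
    list(lv = c(0, 6, 2, 14), dur = c(30, 60, 50, 40)),
    list(lv = c(1, 9, 4, 16, 10), dur = c(35, 40, 45, 40, 40))
  )
  for (cs in cases) {
    y <- make_staircase(cs$lv, cs$dur)
    k <- length(cs$lv) - 1
    sf <- fit_steps(y, rate = 100)
    oracle <- dp_segment_oracle(y, k)
    expect_equal(sf$steps$index, oracle$bounds, ignore_attr = TRUE)
  }
})

test_that("noisy staircases are localised near the exhaustive optimum", {
  n_within2 <- 0; n_steps <- 0; count_ok <- 0
  for (s in 1:10) {
    set.seed(s)
    dur <- rep(60, 7)
    y <- make_staircase(seq(0, 60, by = 10), dur, noise_sd = 5)
    sf <- fit_steps(y, rate = 100)
    if (nrow(sf$steps) == 6) {
      count_ok <- count_ok + 1
      err <- abs(sf$steps$index - cumsum(dur)[1:6])
      n_within2 <- n_within2 + sum(err <= 2)
      n_steps <- n_steps + 6
      expect_lte(max(err), 12)
    }
  }
  expect_gte(count_ok, 9)
  expect_gte(n_within2 / n_steps, 0.85)
})

test_that("sub-Nyquist plateaus are merged away", {
  # a 1-sample plateau (10 ms at 100 Hz) cannot be a retained dwell
  y <- c(rep(0, 60), rep(20, 1), rep(10, 60))
  sf <- fit_steps(y, rate = 100, min_dwell = 0.02)
  expect_true(all(sf$plateaus$dwell > 0.02))
  expect_lte(nrow(sf$steps), 1)
})

test_that("fit_steps is idempotent and conserves the net change", {
  set.seed(7)
  y <- make_staircase(c(0, 12, 25, 18, 40), rep(70, 5), noise_sd = 3)
  sf <- fit_steps(y, rate = 100)
  replay <- rep(sf$plateaus$level, sf$plateaus$end - sf$plateaus$start + 1)
  sf2 <- fit_steps(replay, rate = 100)
  expect_equal(sf2$plateaus$end, sf$plateaus$end)
  expect_equal(sf2$plateaus$level, sf$plateaus$level, tolerance = 1e-9)
  # sum of step sizes equals the net level change
  expect_equal(sum(sf$steps$size),
               sf$plateaus$level[nrow(sf$plateaus)] - sf$plateaus$level[1],
               tolerance = 1e-9)
})

test_that("fit_steps refuses non-constant force and tiny segments", {
  tr <- simulate_force_extension(1000, seed = 1)
  expect_error(fit_steps(tr), "constant force")
  expect_error(fit_steps(rnorm(5), rate = 100), "10 samples")
})

test_that("rupture extraction recovers generator ground truth", {
  tr <- simulate_force_jump(2500, loops = data.frame(delta_L = c(250, 640)),
                            protocol = force_jump_protocol(t_rest = 2,
                                                           t_test = 30),
                            seed = 4, noise_sd = 3)
  ev <- extract_ruptures(tr)
  truth <- trace_truth(tr)$events
  expect_equal(nrow(ev), 2)
  expect_equal(sort(ev$delta_L_bp), sort(truth$delta_L), tolerance = 0.1)
  expect_equal(ev$dwell, truth$dwell, tolerance = 0.1)
  # protein-free trace yields an empty table, not an error
  tr0 <- simulate_force_jump(2500, loops = data.frame(delta_L = numeric(0)),
                             protocol = force_jump_protocol(t_rest = 2,
                                                            t_test = 10),
                             seed = 5, noise_sd = 3)
  expect_equal(nrow(extract_ruptures(tr0)), 0)
})

test_that("zero correction maps closed to stem length and open to zero", {
  hp <- build_hairpin("long")
  tr <- simulate_strand_separation(hp, bound_sites = c(31, 88, 124),
                                   tau = 0.5, noise_sd = 2, seed = 3)
  zc <- zero_correct(tr, construct = hp)
  sel <- abs(zc$force - 17) <= 0.3
  sf <- fit_steps(zc$bp_remaining[sel], rate = sampling_rate(zc))
  lv <- sort(sf$plateaus$level, decreasing = TRUE)
  # pause plateaus sit at L - (site + 5), fully open near 0
  expect_equal(lv[1:3], 169 - (c(31, 88, 124) + 5), tolerance = 0.03)
  expect_lt(abs(lv[length(lv)]), 2)
  # closed stem before unzipping maps to ~stem length
  closed <- zc$bp_remaining[abs(zc$force - 6) <= 0.3]
  expect_equal(stats::median(closed), 169, tolerance = 0.02)
  # a trace that never opens cannot be corrected
  tr_closed <- simulate_strand_separation(hp, noise_sd = 0, seed = 6)
  tr_closed$extension[] <- 0
  expect_error(zero_correct(tr_closed, construct = hp), "open plateau")
})

test_that("residence maps accumulate pause time at the blocking site", {
  hp <- build_hairpin("long")
  tr <- simulate_strand_separation(hp, bound_sites = 88, tau = 1,
                                   noise_sd = 0, seed = 1)
  zc <- zero_correct(tr, construct = hp)
  rm1 <- residence_map(list(zc))
  m <- rm1$map
  truth <- trace_truth(tr)$pauses
  # occupancy concentrates at the footprint centre (transit is instant)
  expect_equal(m$position_bp[which.max(m$time_s)], 88 + 6)
  expect_equal(max(m$time_s), truth$dwell, tolerance = 0.05)
  # total map time matches the occupancy of the F_test window inside the stem
  expect_equal(rm1$total_time, sum(m$time_s))
  # mixed constructs are rejected
  hp2 <- build_hairpin("short")
  tr2 <- simulate_strand_separation(hp2, noise_sd = 0, seed = 11)
  zc2 <- zero_correct(tr2, construct = hp2)
  expect_error(residence_map(list(zc, zc2)), "mixed")
})
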