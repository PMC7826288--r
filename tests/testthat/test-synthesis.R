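test_that("generators are reproducible and require a seed", {
  expect_error(simulate_force_extension(2500), "seed")
  expect_error(simulate_hopping(14.7, duration = 30), "seed")
  a <- simulate_force_extension(2500, loops = data.frame(delta_L = 400),
                                seed = 5)
  b <- simulate_force_extension(2500, loops = data.frame(delta_L = 400),
                                seed = 5)
  expect_identical(a$extension, b$extension)
  h1 <- simulate_hopping(14.7, duration = 30, seed = 9)
  h2 <- simulate_hopping(14.7, duration = 30, seed = 9)
  expect_identical(h1$extension, h2$extension)
})

test_that("noise-free plateau extension equals the WLC prediction", {
  pr <- force_protocol("constant", 17, 17, 2)
  pr <- rbind(ramp_protocol(0.1, 17, 4), pr)
  class(pr) <- c("force_protocol", "data.frame")
  tr <- simulate_force_extension(2500, protocol = pr, noise_sd = 0, seed = 1)
  plateau <- tr$extension[abs(tr$force - 17) < 1e-9]
  expect_equal(unique(round(plateau, 6)),
               round(2500 * ds_nm_per_bp(17), 6))
})

test_that("ramp rupture times follow the integrated Bell-Evans hazard", {
  # single loop, no noise: the leap time must match the analytic
  # inverse-CDF oracle for the same uniform draw
  seed <- 21
  tr <- simulate_force_extension(2500, loops = data.frame(delta_L = 640),
                                 protocol = ramp_protocol(0.1, 17, 4),
                                 noise_sd = 0, seed = seed)
  truth <- trace_truth(tr)$loops
  set.seed(seed)
  u <- stats::runif(1)
  t_oracle <- ramp_rupture_oracle(u, 0.04, 0.7, kbt_default, rate = 4,
                                  f0 = 0.1)
  expect_equal(truth$rupture_time, t_oracle, tolerance = 0.02)
  # exactly one upward leap of delta_L * rise * xrel(F_rupture)
  jumps <- diff(tr$extension)
  i <- which.max(jumps)
  expect_equal(jumps[i],
               640 * ds_nm_per_bp(truth$rupture_force),
               tolerance = 1)
})

test_that("force-jump dwells are exponential with the Bell-Evans mean", {
  tr <- simulate_force_jump(
    5000, loops = data.frame(delta_L = rep(100, 40)), k0 = 0.04,
    x_dagger = 0.7,
    protocol = force_jump_protocol(t_rest = 1, t_test = 500),
    seed = 3, noise_sd = 0)
  dw <- trace_truth(tr)$events$dwell
  k8 <- bell_evans_rate(8, 0.04, 0.7)
  expect_equal(mean(dw), 1 / k8, tolerance = 0.35)
  # one-sample exponentiality check at alpha = 0.01
  ks <- stats::ks.test(dw, "pexp", rate = 1 / mean(dw))
  expect_gt(ks$p.value, 0.01)
  # a short window with k * duration << 1 leaves most loops unruptured
  tr2 <- simulate_force_jump(
    2500, loops = data.frame(delta_L = 200),
    protocol = force_jump_protocol(f_test = 2, t_rest = 1, t_test = 2),
    seed = 4, noise_sd = 0)
  ev2 <- trace_truth(tr2)$events
  expect_gt(mean(ev2$force), 2)
})

test_that("hopping obeys detailed balance and the Boltzmann occupancy", {
  h <- simulate_hopping(14.7, f_half = 14.7, delta_x = 14, duration = 200,
                        sampling_rate = 100, noise_sd = 0, seed = 11)
  truth <- trace_truth(h)
  expect_equal(truth$k_open, truth$k_close)
  expect_equal(mean(h$extension > 7), 0.5, tolerance = 0.05)
  expect_equal(sort(unique(h$extension)), c(0, 14))
  # +0.2 pN at dx = 14 nm biases the open state to ~0.66
  h2 <- simulate_hopping(14.9, f_half = 14.7, delta_x = 14, duration = 400,
                         sampling_rate = 100, noise_sd = 0, seed = 12)
  p_th <- 1 / (1 + exp(-0.2 * 14 / kbt_default))
  expect_equal(mean(h2$extension > 7), p_th, tolerance = 0.05)
  # short traces are flagged
  hs <- simulate_hopping(14.7, delta_x = 14, attempt_rate = 0.05,
                         duration = 30, seed = 13)
  expect_true(attr(hs, "metadata")$short_trace)
})

test_that("strand separation releases 2 nt/bp at the ssDNA WLC factor", {
  hp <- build_hairpin("long")
  tr <- simulate_strand_separation(hp, bound_sites = integer(0),
                                   noise_sd = 0, seed = 2)
  # single cooperative step: closed at F_low, one open level at F_test
  at_test <- tr$extension[abs(tr$force - 17) < 1e-9]
  open_nm <- (2 * 169 + 4) * ss_nm_per_nt(17)
  expect_equal(unique(round(at_test, 6)), round(open_nm, 6))
  expect_equal(unique(tr$extension[abs(tr$force - 6) < 1e-9]), 0)
  # bound dimers pause the fork at their footprint start
  tr2 <- simulate_strand_separation(hp, bound_sites = c(31, 88), tau = 0.4,
                                    noise_sd = 0, seed = 8)
  pauses <- trace_truth(tr2)$pauses
  expect_equal(pauses$unzipped_bp, c(31, 88) + 5)
  expect_error(simulate_strand_separation(hp, bound_sites = 78, seed = 1),
               "spacer")
})

test_that("trace extensions stay within physical bounds", {
  for (s in 1:3) {
    tr <- simulate_force_extension(3000,
                                   loops = data.frame(delta_L = c(250, 640)),
                                   seed = s)
    expect_true(all(tr$extension >= 0))
    expect_true(all(tr$extension <= 3000 * 0.34 * 1.05))
  }
})

test_that("loop populations honour the telomere-length budget", {
  set.seed(1)
  delta <- data.frame(weight = 1, mean = 250, sd = 0)
  expect_true(all(sample_loop_population(2500, delta, 5) == 250))
  expect_error(sample_loop_population(300, data.frame(weight = 1, mean = 5000,
                                                      sd = 10), 5),
               "infeasible")
  for (i in 1:20) {
    mix <- loop_mixture_preset(20, 2.8)
    dl <- sample_loop_population(2800, mix, 15)
    expect_true(all(dl > 0))
    expect_lte(sum(dl), 2800)
  }
})

test_that("dwell sampler matches its exponential law", {
  set.seed(2)
  d <- draw_rupture_dwells(1000, 8, 0.04, 0.7)
  k <- bell_evans_rate(8, 0.04, 0.7)
  expect_lt(abs(mean(d) - 1 / k), 3 * (1 / k) / sqrt(1000))
})

test_that("binding probabilities follow the measured lookup", {
  expect_equal(binding_probability(c(10, 20, 25, 40)),
               c(0.38, 0.50, 0.76, 0.60))
  expect_error(binding_probability(15), "preset")
})
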