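test_that("noiseless telegraph signals are decoded exactly", {
  h <- simulate_hopping(14.7, delta_x = 14, duration = 30,
                        sampling_rate = 100, noise_sd = 0, seed = 1)
  fit <- fit_two_state_hmm(h, seed = 1)
  decoded <- as.integer(fit$path == "forward")
  expect_equal(decoded, trace_truth(h)$path)
  expect_equal(fit$means, c(0, 14), tolerance = 1e-6)
})

test_that("decoding stays accurate at realistic noise", {
  # noise SD = 0.3 x level separation
  h <- simulate_hopping(14.7, delta_x = 14, duration = 100,
                        sampling_rate = 100, noise_sd = 0.3 * 14, seed = 2)
  fit <- fit_two_state_hmm(h, seed = 2)
  acc <- mean((fit$path == "forward") == (trace_truth(h)$path == 1))
  expect_gte(acc, 0.99)
})

test_that("dwell means recover the generator rates", {
  h <- simulate_hopping(14.7, delta_x = 14, attempt_rate = 2, duration = 250,
                        sampling_rate = 100, noise_sd = 2, seed = 3)
  fit <- fit_two_state_hmm(h, seed = 3)
  expect_gt(length(fit$dwell_forward) + length(fit$dwell_backward), 200)
  expect_equal(mean(fit$dwell_forward), 0.5, tolerance = 0.1)
  expect_equal(mean(fit$dwell_backward), 0.5, tolerance = 0.1)
})

test_that("EM log-likelihood is non-decreasing and fits are affine-invariant", {
  h <- simulate_hopping(14.8, delta_x = 14, duration = 60,
                        sampling_rate = 100, noise_sd = 2, seed = 4)
  fit <- fit_two_state_hmm(h, seed = 4)
  expect_true(all(diff(fit$ll_trace) > -1e-6))
  # affine rescaling of the signal leaves the decoded path unchanged
  h2 <- h
  h2$extension <- 3.7 * h$extension - 120
  fit2 <- fit_two_state_hmm(h2, seed = 4)
  expect_equal(fit2$path, fit$path)
  expect_equal(fit2$means, 3.7 * fit$means - 120, tolerance = 1e-3)
})

test_that("degenerate traces are rejected", {
  expect_error(fit_two_state_hmm(rep(1, 1000), rate = 100),
               "fewer than two states")
  expect_error(fit_two_state_hmm(rnorm(100), rate = 100), "500 samples")
})

test_that("open probability is the forward time fraction", {
  h <- simulate_hopping(14.7, delta_x = 14, duration = 100,
                        sampling_rate = 100, noise_sd = 2, seed = 5)
  fit <- fit_two_state_hmm(h, seed = 5)
  po <- open_probability(fit)
  expect_equal(po$p_open, mean(fit$path == "forward"))
  expect_equal(po$p_open, 1 - mean(fit$path == "backward"))
  # biased force moves the occupancy per the Boltzmann factor
  hb <- simulate_hopping(14.9, f_half = 14.7, delta_x = 14, duration = 300,
                         sampling_rate = 100, noise_sd = 2, seed = 6)
  pb <- open_probability(fit_two_state_hmm(hb, seed = 6))
  expect_equal(pb$p_open, 1 / (1 + exp(-0.2 * 14 / kbt_default)),
               tolerance = 0.08)
})

test_that("Boltzmann fits recover exact curves and their energetics", {
  f <- seq(13.8, 15.6, length.out = 7)
  p <- 1 / (1 + exp((14.7 - f) * 17 / kbt_default))
  bf <- fit_boltzmann(f, p)
  expect_equal(bf$f_half, 14.7, tolerance = 1e-6)
  expect_equal(bf$delta_x, 17, tolerance = 1e-6)
  expect_equal(bf$delta_g_kbt, 14.7 * 17 / kbt_default, tolerance = 1e-6)
  expect_equal(predict(bf, bf$f_half), 0.5)
  # two conditions with dG 61 and 50 kBT differ by 11 kBT
  p50 <- 1 / (1 + exp((14.7 - f) * (50 * kbt_default / 14.7) / kbt_default))
  bf50 <- fit_boltzmann(f, p50)
  expect_equal(bf$delta_g_kbt - bf50$delta_g_kbt,
               61.11 - 50, tolerance = 0.01)
  expect_error(fit_boltzmann(f[1:3], p[1:3]), "4 forces")
  expect_error(fit_boltzmann(f, p * 0.3 + 0.6), "one side")
})

test_that("dwell curves summarise fits across forces", {
  fits <- lapply(1:3, function(i) {
    h <- simulate_hopping(14.5 + 0.2 * i, f_half = 14.7, delta_x = 14,
                          attempt_rate = 2, duration = 120,
                          sampling_rate = 100, noise_sd = 2, seed = 30 + i)
    fit_two_state_hmm(h, seed = 30 + i)
  })
  tbl <- dwell_vs_force(fits)
  expect_equal(nrow(tbl), 6)
  expect_true(all(c("force", "state", "mean_dwell", "se") %in% names(tbl)))
  # at F_half the generator rates are symmetric
  at_half <- tbl[abs(tbl$force - 14.7) < 1e-9, ]
  expect_equal(at_half$mean_dwell[1], at_half$mean_dwell[2], tolerance = 0.3)
  # forward dwell grows with force in the generator model
  fwd <- tbl[tbl$state == "forward", ]
  expect_gt(stats::cor(fwd$force, fwd$mean_dwell), 0)
  d <- dwell_difference(tbl, tbl)
  expect_true(all(abs(d$difference) < 1e-12))
  expect_error(dwell_vs_force(fits[1:2]), "3 or more")
})

test_that("TRF1 shortening of the backward dwell is recovered at F_half", {
  # two fork conditions built so the backward dwell differs by 8.7 s at
  # the shared half-opening force
  hA <- simulate_hopping(14.7, delta_x = hopping_preset(FALSE)$delta_x,
                         attempt_rate = 1 / 9.5, duration = 3000,
                         sampling_rate = 100, noise_sd = 2, seed = 11)
  hB <- simulate_hopping(14.7, delta_x = hopping_preset(TRUE)$delta_x,
                         attempt_rate = 1 / 0.8, duration = 3000,
                         sampling_rate = 100, noise_sd = 2, seed = 12)
  fA <- fit_two_state_hmm(hA, seed = 11)
  fB <- fit_two_state_hmm(hB, seed = 12)
  diff_bw <- mean(fA$dwell_backward) - mean(fB$dwell_backward)
  expect_lt(abs(diff_bw - 8.7) / 8.7, 0.2)
})
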