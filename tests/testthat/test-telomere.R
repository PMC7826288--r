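test_that("telomere length round-trips through simulation and measurement", {
  for (tl in c(500, 2500, 7000)) {
    tr <- simulate_force_extension(tl, protocol = ramp_protocol(0.1, 17.5, 4),
                                   noise_sd = 0, seed = tl)
    m <- measure_tl(tr)
    expect_lt(abs(m$tl_bp - tl) / tl, 0.01)
    expect_false(m$qc$flag)
  }
})

test_that("measure_tl is robust to 2x subsampling", {
  tr <- simulate_force_extension(2500, protocol = ramp_protocol(0.1, 17.5, 4),
                                 noise_sd = 4, seed = 42)
  m <- measure_tl(tr)
  sub <- tr[seq(1, nrow(tr), by = 2), ]
  tr2 <- mt_trace(sub$time, sub$force, sub$extension,
                  sampling_rate = sampling_rate(tr) / 2)
  m2 <- measure_tl(tr2)
  expect_lt(abs(m2$tl_bp - m$tl_bp) / m$tl_bp, 0.01)
})

test_that("measure_tl flags and errors on pathological traces", {
  tr <- simulate_force_extension(2500, protocol = ramp_protocol(0.1, 10, 4),
                                 noise_sd = 0, seed = 1)
  expect_error(measure_tl(tr), "never reached")
  tr2 <- simulate_force_extension(2500, protocol = ramp_protocol(0.1, 17.5, 4),
                                  noise_sd = 0, seed = 2)
  tr2$extension[] <- 0
  m <- measure_tl(tr2)
  expect_true(m$qc$flag)
  expect_equal(m$tl_bp, 0)
  # an unruptured compaction leaves stretch and relax apart -> QC flag
  tr3 <- simulate_force_extension(2500, protocol = ramp_protocol(0.1, 17.5, 4),
                                  noise_sd = 0, seed = 3)
  imax <- which.max(tr3$force)
  tr3$extension[seq_len(imax)] <- tr3$extension[seq_len(imax)] * 0.9
  expect_true(measure_tl(tr3)$qc$flag)
})

test_that("population sampling and summaries match the preset distribution", {
  set.seed(11)
  tl <- sample_tl_population(2000)
  expect_gte(min(tl), 300)
  expect_lte(max(tl), 7400)
  # truncation pulls the mean slightly above 2500; compare against the
  # truncated-normal expectation rather than the untruncated centre
  a <- (300 - 2500) / 900; b <- (7400 - 2500) / 900
  m_th <- 2500 + 900 * (stats::dnorm(a) - stats::dnorm(b)) /
    (stats::pnorm(b) - stats::pnorm(a))
  expect_lt(abs(mean(tl) - m_th), 2 * 900 / sqrt(2000))
  d <- tl_distribution(tl)
  expect_equal(d$n, 2000)
  expect_equal(sum(d$histogram$count), 2000)
  expect_equal(d$frac_short, mean(tl < 1000))
  # short telomeres (<1 kb) are roughly an order of magnitude rarer than
  # the modal-bin mass in the preset population
  modal <- max(d$histogram$count) / d$n
  expect_lt(d$frac_short, modal)
  d1 <- tl_distribution(2500)
  expect_equal(d1$sd, 0)
  expect_true(d1$sd_undefined)
})
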