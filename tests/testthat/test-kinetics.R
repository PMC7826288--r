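test_that("Bell-Evans fits are exact on noiseless rate data", {
  f <- c(2, 4, 6, 8)
  md <- 1 / bell_evans_rate(f, k0 = 0.04, x_dagger = 0.7)
  be <- fit_bell_evans(f, md)
  expect_equal(be$k0, 0.04, tolerance = 1e-9)
  expect_equal(be$x_dagger, 0.7, tolerance = 1e-9)
  expect_equal(be$tau0, 25, tolerance = 1e-9)
  expect_equal(bell_evans_rate(0, be$k0, be$x_dagger), be$k0)
  expect_error(fit_bell_evans(4, 10), "3 or more")
  expect_error(fit_bell_evans(f, c(-1, 1, 1, 1)), "positive")
})

test_that("Bell-Evans recovery from simulated dwell ensembles", {
  set.seed(101)
  f <- c(2, 4, 6, 8)
  md <- vapply(f, function(ff) mean(draw_rupture_dwells(200, ff)), numeric(1))
  be <- fit_bell_evans(f, md)
  expect_lt(abs(be$x_dagger - 0.7), 0.15)
  expect_lt(max(be$k0 / 0.04, 0.04 / be$k0), 1.5)
})

test_that("exponential dwell fits are unbiased under truncation", {
  set.seed(5)
  d <- stats::rexp(4000, 1 / 0.36)
  d <- d[d > 0.02][1:1290]
  ef <- fit_exponential(d)
  expect_equal(ef$tau, 0.36, tolerance = 2 * ef$se / 0.36)
  expect_equal(ef$se, ef$tau / sqrt(1290), tolerance = 1e-9)
  expect_gt(ef$r_squared, 0.9)
  # scale equivariance: scaling dwells and floor by c scales tau by c
  ef2 <- fit_exponential(3 * d, min_dwell = 0.06)
  expect_equal(ef2$tau, 3 * ef$tau, tolerance = 1e-9)
  expect_error(fit_exponential(d[1:10]), "20 dwells")
  expect_warning(fit_exponential(rep(0.5, 30)), "degenerate")
})

test_that("Hill fits recover Kd and reject saturated tables", {
  conc <- c(2, 5, 10, 17.5, 30, 60, 120)
  f <- conc / (17.5 + conc)
  hf <- fit_hill(conc, f)
  expect_equal(hf$kd, 17.5, tolerance = 1e-6)
  expect_equal(hf$hill_n, 1, tolerance = 1e-6)
  expect_equal(unname(stats::predict(hf$fit,
                                     newdata = data.frame(conc = hf$kd))),
               0.5, tolerance = 1e-6)
  # noisy replicates still land near the true Kd
  set.seed(6)
  cc <- rep(conc, 3)
  ff <- pmin(pmax(cc / (17.5 + cc) + stats::rnorm(length(cc), 0, 0.05), 0), 1)
  hf2 <- fit_hill(cc, ff)
  expect_lt(abs(hf2$kd - 17.5), 2)
  hf3 <- fit_hill(conc, f, fix_n = 1)
  expect_equal(hf3$kd, 17.5, tolerance = 1e-6)
  expect_error(fit_hill(conc[1:3], f[1:3]), "4 concentrations")
  expect_error(fit_hill(conc, rep(1, 7)), "saturated")
})

test_that("Gaussian mixtures recover the loop-size presets", {
  set.seed(7)
  x <- c(stats::rnorm(250, 258, 117), stats::rnorm(250, 470, 120))
  g <- fit_gaussian_mixture(x, 2)
  expect_equal(g$n_components, 2)
  expect_lt(abs(g$components$mean[1] - 258), 40)
  expect_lt(abs(g$components$mean[2] - 470), 40)
  # a single tight component centres at the sample mean
  y <- stats::rnorm(200, 400, 20)
  g1 <- fit_gaussian_mixture(y, 1)
  expect_equal(g1$components$mean, mean(y), tolerance = 1e-6)
  # equal-mean components merge under BIC
  z <- c(stats::rnorm(300, 100, 10), stats::rnorm(300, 100, 10))
  expect_equal(fit_gaussian_mixture(z)$n_components, 1)
  expect_error(fit_gaussian_mixture(stats::rnorm(30), 2), "50 observations")
})

test_that("partial correlations match the residual-regression oracle", {
  set.seed(8)
  for (i in 1:5) {
    x <- stats::rnorm(60); y <- stats::rnorm(60)
    z <- data.frame(z1 = stats::rnorm(60), z2 = stats::rnorm(60))
    p2 <- partial_correlation(x, y, z)
    expect_equal(p2$r, residual_pcor_oracle(x, y, z), tolerance = 1e-10)
    expect_equal(p2$order, 2L)
    p1 <- partial_correlation(x, y, z["z1"])
    expect_equal(p1$r, residual_pcor_oracle(x, y, z["z1"]), tolerance = 1e-10)
  }
  # controls uncorrelated with x and y leave r essentially unchanged
  x <- stats::rnorm(2000); y <- x + stats::rnorm(2000)
  z <- data.frame(z = stats::rnorm(2000))
  expect_equal(partial_correlation(x, y, z)$r, stats::cor(x, y),
               tolerance = 0.01)
  # x = y gives r = 1 at every order
  expect_equal(partial_correlation(x, x)$r, 1)
  expect_equal(partial_correlation(x, x, z)$r, 1, tolerance = 1e-9)
  expect_error(partial_correlation(x, y, data.frame(a = x, b = x)),
               "collinear")
})

test_that("p-values use the order-adjusted degrees of freedom", {
  set.seed(9)
  x <- stats::rnorm(30); y <- stats::rnorm(30)
  p0 <- partial_correlation(x, y)
  r <- p0$r
  t0 <- r * sqrt((30 - 2) / (1 - r^2))
  expect_equal(p0$p, 2 * stats::pt(-abs(t0), 28), tolerance = 1e-12)
  expect_equal(p0$p, stats::cor.test(x, y)$p.value, tolerance = 1e-10)
})
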