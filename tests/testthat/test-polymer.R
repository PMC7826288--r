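test_that("dsDNA extensible WLC matches direct evaluation and the printed factor", {
  # frozen from direct evaluation of 1 - (1/2)sqrt(kBT/(F Lp)) + F/S
  expect_equal(ds_relative_extension(17), 0.9825947, tolerance = 1e-6)
  # S -> infinity and F = kBT/Lp makes the sqrt term exactly 1/2
  p_stiff <- ds_wlc_params(stretch_modulus = 1e12)
  expect_equal(ds_relative_extension(p_stiff$kbt / p_stiff$persistence_length,
                                     p_stiff), 0.5, tolerance = 1e-6)
  # the nm/bp ruler at 17 pN rounds to 0.33
  expect_equal(round(ds_nm_per_bp(17), 2), 0.33)
  expect_error(ds_relative_extension(0), "positive")
  expect_error(ds_relative_extension(-2), "positive")
})

test_that("ssDNA WLC force matches direct evaluation and is monotone", {
  expect_equal(ss_force(0), 0)
  expect_equal(ss_force(0.5), 5.875, tolerance = 1e-4)
  r <- seq(0, 0.99, by = 0.01)
  expect_true(all(diff(ss_force(r)) > 0))
  f <- seq(0.5, 25, by = 0.5)
  expect_true(all(diff(ds_relative_extension(f)) > 0))
  expect_error(ss_force(1), "\\[0, 1\\)")
})

test_that("ssDNA WLC inverse agrees with grid search and round-trips", {
  expect_equal(ss_relative_extension(0), 0)
  r17 <- ss_relative_extension(17)
  expect_equal(r17, 0.718, tolerance = 1e-3)
  expect_equal(ss_nm_per_nt(17), 0.496, tolerance = 1e-3)
  for (f in c(0.5, 1, 5, 17, 22, 25)) {
    expect_equal(ss_relative_extension(f), ss_inverse_grid_oracle(f),
                 tolerance = 1e-4)
    expect_equal(ss_force(ss_relative_extension(f)), f, tolerance = 1e-6)
  }
})

test_that("extension <-> bp conversion uses the force-dependent factor", {
  expect_equal(extension_to_bp(835, 17), 2500, tolerance = 1e-3)
  expect_equal(extension_to_bp(0, 17), 0)
  for (n in c(0, 100, 2500, 7400))
    expect_equal(extension_to_bp(bp_to_extension(n, 17), 17), n,
                 tolerance = 1e-6)
  # at a different test force the factor moves with the WLC
  expect_equal(bp_to_extension(1, 4) / 0.34, ds_relative_extension(4),
               tolerance = 1e-12)
  expect_error(extension_to_bp(-1, 17), "non-negative")
})

test_that("parameter bundles validate their invariants", {
  expect_error(ds_wlc_params(persistence_length = -1))
  expect_error(ds_wlc_params(kbt = 5), "3.8")
  expect_error(ss_wlc_params(contour_per_nt = 0))
  expect_equal(thermal_energy(23), 4.089, tolerance = 1e-3)
})

test_that("physiological dimer concentration follows from copy number and volume", {
  expect_equal(dimer_concentration(40000, 1540), 21.6, tolerance = 0.01)
  expect_equal(dimer_concentration(40000, 760), 43.7, tolerance = 0.01)
  expect_equal(dimer_concentration(40000, 2730), 12.2, tolerance = 0.01)
})
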