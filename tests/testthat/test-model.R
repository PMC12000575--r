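test_that("field-dependent force constant and its inverse agree with hand arithmetic", {
  cf <- coeffs_762()
  expect_equal(k_of_field(0, cf), 762.0)
  expect_equal(k_of_field(5.33e9, cf), 643.141, tolerance = 1e-6)
  expect_error(k_of_field(cf$k0 / cf$d2pdd2, cf), "unphysical")

  expect_equal(field_of_k(762.0, cf), 0)
  # C60-confined water band average
  expect_equal(field_of_k(725.2, cf), 1.7e9, tolerance = 0.2 / 1.7)
  # ice Ih
  expect_equal(field_of_k(596.3, cf), 7.430e9, tolerance = 1e-3)
  expect_error(field_of_k(770, cf), "blue-shift")
  expect_error(field_of_k(-1, cf), "positive")

  E <- seq(0, 7e9, length.out = 100)
  expect_equal(field_of_k(k_of_field(E, cf), cf), E, tolerance = 1e-12)
})

test_that("bond length grows with field from d0", {
  cf <- coeffs_762()
  expect_equal(bond_length(0, cf), cf$d0)
  E <- seq(0, 7.5e9, length.out = 50)
  expect_true(all(diff(bond_length(E, cf)) > 0))
})

test_that("Taylor bond dipole reproduces calibrated points", {
  cf <- coeffs_762()
  expect_equal(bond_dipole(cf$d0, cf) / debye, 1.514)
  expect_equal(bond_dipole(0.984e-10, cf) / debye, 2.17216, tolerance = 1e-4)
  expect_equal(bond_dipole(1.014e-10, cf) / debye, 2.96061, tolerance = 1e-4)
  expect_warning(bond_dipole(1.102e-10, cf), "0.12 Angstrom")
})

test_that("molecular dipole is the vector sum across the H-O-H angle", {
  p0 <- 1.514 * debye
  expect_equal(molecular_dipole(p0, p0, 104.48) / debye, 1.855,
               tolerance = 0.002 / 1.855)
  expect_equal(molecular_dipole(p0, p0, 180 - 1e-9) / debye, 0,
               tolerance = 1e-9)
  # gas-phase bond length through the Taylor dipole: free-molecule value
  pb <- bond_dipole(0.9578e-10, coeffs_762())
  expect_equal(molecular_dipole(pb, pb, 104.48) / debye, 1.88,
               tolerance = 0.04 / 1.88)
  expect_error(molecular_dipole(p0, p0, 200), "between 0 and 180")
})

test_that("hydrogen-bond energies land on the reference systems", {
  cf <- coeffs_762()
  expect_identical(hb_energy(1.5 * debye, 0), 0)
  # ice Ih: measured bond length 1.014 A with the 3279 cm-1 peak
  U_ice <- hb_energy(bond_dipole(1.014e-10, cf),
                     field_of_k(wavenumber_to_force_constant(3279), cf))
  expect_equal(convert_units(U_ice, "J", "meV"), 455, tolerance = 52 / 455)
  expect_equal(convert_units(U_ice, "J", "kcal/mol"), 10.5, tolerance = 1.2 / 10.5)
  # single water in C60: average of the two red-shifted stretching modes
  st <- hb_predict(coupled_mode_average(c(3573, 3659.6)), cf,
                   uncertainty = "none")
  expect_equal(convert_units(st$U_HB, "J", "meV"), 66, tolerance = 9 / 66)
  expect_equal(st$k, 725, tolerance = 1 / 725)
})

test_that("polarizability closed forms match in both parametrizations", {
  cf <- coeffs_762()
  expect_equal(polarizability_of_length(cf$d0, cf), cf$dpdd^2 / cf$k0,
               tolerance = 1e-14)
  expect_equal(polarizability_of_field(0, cf), cf$dpdd^2 / cf$k0,
               tolerance = 1e-14)
  expect_equal(polarizability_of_length(cf$d0, cf), 8.0458e-40,
               tolerance = 1e-4)
  expect_equal(polarizability_of_length(0.984e-10, cf), 1.00484e-39,
               tolerance = 1e-4)
  expect_equal(polarizability_of_field(5.33e9, cf), 1.33818e-39,
               tolerance = 1e-4)
  expect_equal(polarizability_of_field(3.82e9, cf), 1.14822e-39,
               tolerance = 1e-4)
  expect_error(polarizability_of_length(0.2e-10, cf), "bracket")
})

test_that("length-form and field-form polarizability are algebraically identical", {
  cf <- default_coefficients()
  E <- seq(0, 8e9, length.out = 200)
  expect_equal(polarizability_of_length(bond_length(E, cf), cf),
               polarizability_of_field(E, cf), tolerance = 1e-12)
})

test_that("increasing field softens k and grows d, p, U and alpha", {
  cf <- default_coefficients()
  E <- seq(0, 8e9, length.out = 60)
  k <- k_of_field(E, cf)
  d <- bond_length(E, cf)
  p <- bond_dipole(d, cf)
  U <- hb_energy(p, E)
  a <- polarizability_of_field(E, cf)
  expect_true(all(diff(k) < 0))
  expect_true(all(diff(d) > 0))
  expect_true(all(diff(p) > 0))
  expect_true(all(diff(U) > 0))
  expect_true(all(diff(a) > 0))
})

test_that("the free-molecule wavenumber is an exact fixed point", {
  st <- hb_predict(3706.491, uncertainty = "none")
  expect_identical(st$E_tot, 0)
  expect_identical(st$d, default_coefficients()$d0)
  expect_identical(st$U_HB, 0)
})

test_that("blue-shifted wavenumbers are rejected, not extrapolated", {
  expect_error(hb_predict(3750), "blue-shift")
  expect_error(hb_predict(3707.5), "blue-shift")  # just past the free bond
})

test_that("the prediction chain reproduces the water-graphene worked example", {
  st <- hb_predict(3616, hoh_angle = 104.48)
  expect_equal(st$k, 725.1, tolerance = 0.3 / 725)
  expect_equal(st$E_tot, 1.7e9, tolerance = 0.2 / 1.7)
  expect_equal(st$d / 1e-10, 0.975, tolerance = 0.004 / 0.975)
  expect_equal(convert_units(st$U_HB, "J", "kcal/mol"), 1.54,
               tolerance = 0.20 / 1.54)
  expect_equal(st$p_mol / debye, 2.37, tolerance = 0.14 / 2.37)
  # liquid water: field from the band midpoint, dipole at the measured
  # liquid bond length (the chain-predicted length is not used when a
  # diffraction length exists)
  cf <- default_coefficients()
  U_liq <- hb_energy(
    bond_dipole(0.984e-10, cf),
    field_of_k(wavenumber_to_force_constant(liquid_water_wavenumber()), cf))
  expect_equal(convert_units(U_liq, "J", "kcal/mol"), 5.1,
               tolerance = 0.5 / 5.1)
})

test_that("delta-method uncertainties agree with the Monte-Carlo oracle", {
  de <- hb_predict(3616, uncertainty = "delta")
  mc <- hb_predict(3616, uncertainty = "mc", seed = 42L, n_draws = 10000L)
  expect_equal(mc$sigma2_U_HB, de$sigma2_U_HB, tolerance = 0.15)
  expect_equal(mc$sigma2_d, de$sigma2_d, tolerance = 0.15)
  expect_true(all(de$sigma2_U_HB > 0))
  # the MC path restores the global RNG stream
  set.seed(123)
  before <- .Random.seed
  hb_predict(3616, uncertainty = "mc", seed = 7L, n_draws = 500L)
  expect_identical(.Random.seed, before)
})

test_that("hb_state JSON records carry units, provenance and all rows", {
  st <- hb_predict(c(3279, 3616), uncertainty = "none")
  js <- jsonlite::fromJSON(hb_state_json(st))
  expect_equal(nrow(js$records), 2L)
  expect_equal(js$coefficients$p0, default_coefficients()$p0)
  expect_equal(js$units$k, "N/m")
})
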