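test_that("polarizability projection onto the confining axis", {
  expect_equal(effective_polarizability(1e-39, 0), 1e-39)
  expect_equal(effective_polarizability(1e-39, 90), 0, tolerance = 1e-50)
  expect_equal(effective_polarizability(1, 9.37), 0.97350, tolerance = 1e-4)
  expect_error(effective_polarizability(1, 120), "90")
})

test_that("confined-water summation: vacuum limit and linearity", {
  empty <- data.frame(alpha_c = numeric(), number_density = numeric())
  expect_identical(epsilon_confined(empty), 1)
  comp <- data.frame(alpha_c = c(1e-40, 5e-40), number_density = 4e28)
  e1 <- epsilon_confined(comp)
  comp2 <- comp; comp2$number_density <- 2 * comp2$number_density
  expect_equal(epsilon_confined(comp2) - 1, 2 * (e1 - 1), tolerance = 1e-12)
})

test_that("gypsum confined water reaches the reference dielectric constant", {
  g <- epsilon_confined_water()   # main-text rounding by construction
  expect_equal(g$epsilon, 6.6, tolerance = 0.7 / 6.6)
  expect_equal(nrow(g$components), 2L)
  # the weakly bound interlayer dipole, nearly parallel to the axis,
  # dominates the response
  expect_gt(g$components$alpha_c[2], 5 * g$components$alpha_c[1])
})

test_that("series-capacitor decomposition inverts composition", {
  expect_equal(series_decompose(3.68, 0.40, 6.6), 2.8, tolerance = 0.5 / 2.8)
  expect_equal(series_compose(c(0.3, 0.7), c(4, 4)), 4, tolerance = 1e-12)
  eps_w <- 6.649
  eps_c <- series_decompose(3.68, 0.40, eps_w)
  expect_equal(series_compose(c(0.40, 0.60), c(eps_w, eps_c)), 3.68,
               tolerance = 1e-12)
  expect_error(series_decompose(10, 0.4, 2), "no physical solution")
})

test_that("Boltzmann cos^2 average: exact limits, closed form, Taylor band", {
  expect_identical(boltzmann_cos2_average(0, "quadrature"), 1 / 3)
  expect_identical(boltzmann_cos2_average(0, "taylor"), 1 / 3)
  # quadrature against the independent closed form 1 - 2coth(x)/x + 2/x^2
  xs <- c(0.05, 0.3, 1, 5, 50, 500)
  closed <- 1 - 2 / (xs * tanh(xs)) + 2 / xs^2
  expect_equal(boltzmann_cos2_average(xs), closed, tolerance = 1e-9)
  # small-field Taylor agreement: the truncation error is the quartic term
  # ~4x^4/945, i.e. 1e-4 holds up to x ~ 0.4 and 3e-4 across x <= 0.5
  xt3 <- seq(0.01, 0.3, by = 0.01)
  expect_lt(max(abs(boltzmann_cos2_average(xt3) -
                      boltzmann_cos2_average(xt3, "taylor"))), 1e-4)
  xt5 <- seq(0.01, 0.5, by = 0.01)
  expect_lt(max(abs(boltzmann_cos2_average(xt5) -
                      boltzmann_cos2_average(xt5, "taylor"))), 3e-4)
  # saturation: monotone approach to 1, reached only at very large x
  big <- boltzmann_cos2_average(c(50, 500, 5000))
  expect_true(all(diff(big) > 0))
  expect_lt(abs(big[3] - 1), 1e-3)
  expect_true(all(big < 1))
  expect_error(boltzmann_cos2_average(-1), "non-negative")
})

test_that("liquid water: epsilon ~27 uncorrelated, Kirkwood factor ~3.15 for 79", {
  lw <- liquid_water_params()
  expect_equal(lw$p / debye, 2.66, tolerance = 0.13 / 2.66)
  eps <- epsilon_liquid_water(lw$p, lw$alpha)
  expect_equal(eps, 27, tolerance = 2 / 27)
  G <- kirkwood_factor(79, lw$p, lw$alpha)
  expect_equal(G, 3.15, tolerance = 0.05)
  expect_equal(epsilon_liquid_water(lw$p, lw$alpha, G_k = G), 79,
               tolerance = 1e-10)
  # epsilon is monotone in the correlation factor
  eg <- vapply(seq(1, 4, by = 0.5), function(g)
    epsilon_liquid_water(lw$p, lw$alpha, G_k = g), numeric(1))
  expect_true(all(diff(eg) > 0))
  # without reorientation only the stretching term remains
  frozen <- epsilon_liquid_water(lw$p, lw$alpha, orientation_term = FALSE)
  expect_equal(frozen, 1 + 3.35e28 * 2 * lw$alpha /
                 (3 * hb_constants()$vacuum_permittivity), tolerance = 1e-12)
})

test_that("non-reorientation polarization stays below the confined-water cap", {
  # at the high confined-water density, frozen-rotation polarization alone
  # cannot push epsilon past ~13
  N_conf <- 3.39e6 / 18.01528 * hb_constants()$avogadro  # 3.39 g/cm3
  lw <- liquid_water_params()
  cap <- epsilon_liquid_water(lw$p, lw$alpha, N0 = N_conf,
                              orientation_term = FALSE)
  expect_lte(cap, 13.5)
  expect_gt(cap, 1)
})

test_that("ordered-ice dielectric needs geometry and scales linearly with density", {
  expect_error(epsilon_ordered_ice(NULL, d = 1.01e-10, density = 0.93),
               "geometry")
  geom <- data.frame(theta_deg = c(30, 75), multiplicity = c(2, 2))
  e1 <- epsilon_ordered_ice(geom, d = 1.01e-10, density = 0.93)
  expect_gt(e1$epsilon, 1)
  e2 <- epsilon_ordered_ice(geom, d = 1.01e-10, density = 1.86)
  expect_equal(e2$epsilon - 1, 2 * (e1$epsilon - 1), tolerance = 1e-12)
  # all dipoles perpendicular to the axis: vacuum response
  perp <- data.frame(theta_deg = 90, multiplicity = 4)
  expect_equal(epsilon_ordered_ice(perp, 1.01e-10, 0.93)$epsilon, 1,
               tolerance = 1e-12)
})

test_that("field modulation of the gypsum dielectric is tiny and even in field", {
  expect_equal(field_modulation_epsilon(0)$modulation, 0)
  fm <- field_modulation_epsilon(0.5e9)
  expect_lt(fm$modulation, 0.002)   # order 0.1%
  expect_equal(fm$epsilon0, 6.649, tolerance = 1e-3)
  sc <- fm$scan
  eps_plus <- sc$epsilon[sc$E_ext > 0]
  eps_minus <- rev(sc$epsilon[sc$E_ext < 0])
  expect_equal(eps_plus, eps_minus, tolerance = 1e-12)
})
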