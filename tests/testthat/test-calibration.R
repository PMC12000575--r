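test_that("noiseless synthetic sweeps are recovered exactly by the shared-slope fit", {
  sw <- gypsum_sweeps(sigma = 0)
  fit <- fit_shared_slope(sw)
  expect_equal(fit$d2pdd2, 2.23e-8, tolerance = 1e-10)
  expect_equal(unname(fit$E_HB[["O-H_A"]]), 5.33e9, tolerance = 1e-10)
  expect_equal(unname(fit$E_HB[["O-H_B"]]), 3.82e9, tolerance = 1e-10)
  expect_true(is.na(fit$reduced_chi2))  # unweighted: no error model
})

test_that("a single dataset reduces to an ordinary per-dataset regression", {
  sw <- gypsum_sweeps(sigma = 0)[[1]]
  fit <- fit_shared_slope(sw)
  k <- wavenumber_to_force_constant(sw$wavenumber)
  x <- sw$E_ext * cos(sw$theta_deg * pi / 180)
  ols <- stats::lm(k ~ x)
  expect_equal(fit$d2pdd2, -unname(coef(ols)[2L]), tolerance = 1e-12)
})

test_that("the orientation flip is automatic, involutive and |slope|-preserving", {
  fwd <- generate_field_sweep(5.33e9, 69.60, orientation_sign = 1,
                              sigma_wavenumber = 0, species = "A",
                              dataset = "fwd")
  rev <- generate_field_sweep(5.33e9, 69.60, orientation_sign = -1,
                              sigma_wavenumber = 0, species = "A",
                              dataset = "rev")
  f1 <- fit_shared_slope(fwd)
  f2 <- fit_shared_slope(rev)
  expect_equal(f1$d2pdd2, f2$d2pdd2, tolerance = 1e-12)
  expect_equal(unname(f1$E_HB), unname(f2$E_HB), tolerance = 1e-12)
  expect_equal(unname(f1$orientation), 1)
  expect_equal(unname(f2$orientation), -1)
  # flipping a flipped dataset restores it: negating E twice is the identity
  expect_equal(field_sweep("A", 69.60, -(-rev$E_ext), rev$wavenumber)$E_ext,
               rev$E_ext)
  # joint fit with one of each orientation still recovers the truth
  f3 <- fit_shared_slope(list(fwd, rev))
  expect_equal(f3$d2pdd2, 2.23e-8, tolerance = 1e-10)
})

test_that("flat sweeps raise an orientation-ambiguity error naming the dataset", {
  flat <- field_sweep("A", 0, E_ext = seq(-0.5e9, 0.5e9, length.out = 5),
                      wavenumber = rep(3405, 5), dataset = "flat0")
  expect_error(fit_shared_slope(flat), "flat0")
  noisy_flat <- generate_field_sweep(5.33e9, 89.9, sigma_wavenumber = 2,
                                     species = "A", dataset = "nf",
                                     seed = 4L)
  expect_error(fit_shared_slope(noisy_flat), "indeterminate|flat")
  # an explicit orientation sign overrides the inference
  attr(noisy_flat, "orientation_sign") <- 1
  expect_s3_class(fit_shared_slope(noisy_flat), "shared_slope_fit")
})

test_that("the generator is deterministic and unbiased", {
  a <- generate_field_sweep(5.33e9, 69.60, sigma_wavenumber = 1, seed = 11L)
  b <- generate_field_sweep(5.33e9, 69.60, sigma_wavenumber = 1, seed = 11L)
  expect_identical(a, b)
  c <- generate_field_sweep(5.33e9, 69.60, sigma_wavenumber = 1, seed = 12L)
  expect_false(identical(a$wavenumber, c$wavenumber))
  # noiseless points lie exactly on the model line
  clean <- generate_field_sweep(5.33e9, 69.60, sigma_wavenumber = 0)
  k <- wavenumber_to_force_constant(clean$wavenumber)
  k0 <- wavenumber_to_force_constant(3706.491)
  expect_equal(k, k0 - 2.23e-8 * (5.33e9 + clean$E_ext * cos(69.60 * pi / 180)),
               tolerance = 1e-12)
  # law of large numbers at one grid point
  grid <- c(0, 0.5e9)
  sims <- vapply(seq_len(2000L), function(i)
    generate_field_sweep(5.33e9, 69.60, E_ext = grid, sigma_wavenumber = 2,
                         seed = 100L + i)$wavenumber[1L], numeric(1))
  truth <- force_constant_to_wavenumber(k0 - 2.23e-8 * 5.33e9)
  expect_lt(abs(mean(sims) - truth), 3 * 2 / sqrt(2000))
})

test_that("York fit is exact on collinear points and matches OLS as sx -> 0", {
  x <- c(0, 1, 2, 3, 4)
  y <- 0.5 + 2 * x
  yk <- fit_york(x, y, sx = rep(0.1, 5), sy = rep(0.1, 5))
  expect_equal(yk$slope, 2, tolerance = 1e-12)
  expect_equal(yk$intercept, 0.5, tolerance = 1e-12)
  expect_equal(yk$reduced_chi2, 0, tolerance = 1e-20)

  set.seed(99)
  yn <- y + rnorm(5, 0, 0.2)
  yk0 <- fit_york(x, yn, sx = rep(1e-12, 5), sy = rep(0.2, 5))
  ols <- stats::lm(yn ~ x)
  expect_equal(yk0$slope, unname(coef(ols)[2L]), tolerance = 1e-8)
  expect_equal(yk0$intercept, unname(coef(ols)[1L]), tolerance = 1e-8)
  # sx exactly zero is handled, not a division error
  ykz <- fit_york(x, yn, sx = 0, sy = rep(0.2, 5))
  expect_equal(ykz$slope, yk0$slope, tolerance = 1e-10)
})

test_that("York fit diagnostics behave: convergence condition and covariance", {
  set.seed(7)
  x <- runif(20, 0, 10)
  y <- 1 + 0.7 * x + rnorm(20, 0, 0.3)
  xo <- x + rnorm(20, 0, 0.3)
  expect_error(fit_york(xo, y, sx = 0.3, sy = 0.3, max_iter = 1L),
               class = "york_convergence_error")
  yk <- fit_york(xo, y, sx = 0.3, sy = 0.3)
  expect_true(yk$iterations <= 100L)
  V <- yk$covariance
  expect_equal(V, t(V))
  expect_true(all(eigen(V, symmetric = TRUE, only.values = TRUE)$values >= 0))
  expect_equal(unname(coef(yk)), c(yk$intercept, yk$slope))
  expect_equal(predict(yk, 0), yk$intercept)
})

test_that("the bond-length table pins the free molecule at x = 0 and has one row per bond", {
  tab <- build_length_field_table()
  expect_equal(nrow(tab), 21L)
  free <- tab[tab$system == "free H2O", ]
  expect_identical(free$x, 0)
  ice <- tab[tab$system == "ice Ih", ]
  expect_equal(ice$x, 1.2455e7, tolerance = 1e-4)
  expect_equal(ice$E, 7.426e9, tolerance = 1e-3)
  # sigma_x is pure first-order propagation of the softening-slope error
  expect_equal(tab$sigma_x, abs(tab$x) * 0.26e-8 / 2.23e-8, tolerance = 1e-12)
})

test_that("missing bond-length errors need an explicit default", {
  tab <- load_reference_table()
  tab$sigma_d_A[3] <- NA
  expect_error(build_length_field_table(tab), "sigma_d")
  expect_warning(out <- build_length_field_table(tab, default_sigma_d = 0.01),
                 "default")
  expect_equal(out$sigma_d[3], 0.01e-10)
})

test_that("the packaged table yields the calibrated dipole derivative and free length", {
  tab <- build_length_field_table()
  yk <- fit_york(tab$x, tab$d, tab$sigma_x, tab$sigma_d)
  expect_equal(yk$slope, 7.83e-19, tolerance = 1.26e-19 / 7.83e-19)
  expect_equal(yk$intercept / 1e-10, 0.957, tolerance = 0.001 / 0.957)
})

test_that("end-to-end calibration assembles a usable coefficient set", {
  sw <- gypsum_sweeps(sigma = 1, seed = 21L)
  cal <- calibrate(sweeps = sw)
  expect_s3_class(cal$coefficients, "hb_coefficients")
  expect_lt(abs(cal$shared_slope$d2pdd2 - 2.23e-8),
            2 * cal$shared_slope$sigma2_d2pdd2)  # generous: 4 sigma
  expect_equal(cal$coefficients$dpdd, cal$york$slope)
  expect_equal(cal$coefficients$d0, cal$york$intercept)
  expect_false(is.null(cal$coefficients$covariance))
  # degraded mode: no sweeps, softening slope taken as given
  cal2 <- calibrate()
  expect_null(cal2$shared_slope)
  expect_equal(cal2$coefficients$d2pdd2, 2.23e-8)
})

test_that("field-sweep CSV round trip preserves the data", {
  sw <- gypsum_sweeps(sigma = 1, seed = 31L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_field_sweeps(sw, f)
  back <- read_field_sweeps(f)
  expect_equal(length(back), 2L)
  expect_equal(back[["A1"]]$wavenumber, sw[[1]]$wavenumber, tolerance = 1e-9)
  expect_equal(back[["A1"]]$E_ext, sw[[1]]$E_ext, tolerance = 1e-9)
})
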