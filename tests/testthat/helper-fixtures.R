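# shared fixtures built in code

# coefficient set pinned at the printed headline values (k0 exactly 762.0),
# used where a test checks arithmetic against hand-derived numbers
coeffs_762 <- function(rounding = "methods") {
  default_coefficients(rounding, k0 = 762.0)
}

# a pair of gypsum-like synthetic sweeps (species A and B) at the calibrated
# truth; noiseless unless sigma > 0
gypsum_sweeps <- function(sigma = 0, seed = NULL, c2 = 2.23e-8,
                          E_A = 5.33e9, E_B = 3.82e9) {
  list(
    generate_field_sweep(E_HB = E_A, theta_deg = 69.60, d2pdd2 = c2,
                         sigma_wavenumber = sigma, species = "O-H_A",
                         dataset = "A1", seed = seed),
    generate_field_sweep(E_HB = E_B, theta_deg = 9.37, d2pdd2 = c2,
                         sigma_wavenumber = sigma, species = "O-H_B",
                         dataset = "B1",
                         seed = if (is.null(seed)) NULL else seed + 1000L)
  )
}

debye <- hb_constants()$debye
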