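#' Field-dependent force constant
#'
#' The local field softens the O-H spring: \eqn{k(E) = k_0 -
#' (\partial^2 p/\partial d^2) E}.  The model is only defined while
#' \eqn{k(E) > 0}, i.e. for \eqn{E < k_0 / (\partial^2 p/\partial d^2)}.
#'
#' @param E Total electric field along the bond, V m\eqn{^{-1}}.
#' @param coeffs An [hb_coefficients()] object.
#' @return Force constant(s), N m\eqn{^{-1}}.
#' @export
k_of_field <- function(E, coeffs = default_coefficients()) {
  stopifnot(inherits(coeffs, "hb_coefficients"), is.numeric(E))
  if (any(E >= coeffs$k0 / coeffs$d2pdd2))
    stop(sprintf("unphysical field: E must be below k0/d2pdd2 = %.3g V/m",
                 coeffs$k0 / coeffs$d2pdd2))
  coeffs$k0 - coeffs$d2pdd2 * E
}

#' Local field from a measured force constant
#'
#' Inverts the linear spring-softening relation: \eqn{E = (k_0 - k) /
#' (\partial^2 p/\partial d^2)}.  A force constant above \eqn{k_0} would
#' imply a blue-shifted stretching mode, which lies outside the model (strong
#' blue-shifting hydrogen bonds are governed by different physics) and is
#' reported as an error rather than clamped.
#'
#' @param k Force constant(s), N m\eqn{^{-1}}; must satisfy
#'   \eqn{0 < k \le k_0}.
#' @inheritParams k_of_field
#' @return Field(s), V m\eqn{^{-1}} (non-negative).
#' @export
field_of_k <- function(k, coeffs = default_coefficients()) {
  stopifnot(inherits(coeffs, "hb_coefficients"), is.numeric(k))
  if (any(k <= 0)) stop("force constant must be positive")
  if (any(k > coeffs$k0))
    stop("blue-shifted input: k exceeds the free-bond k0; ",
         "blue-shifting strong HBs are outside the model domain")
  (coeffs$k0 - k) / coeffs$d2pdd2
}

#' Field-dependent equilibrium bond length
#'
#' \eqn{d(E) = d_0 + (E / k(E)) \, \partial p/\partial d}: the field
#' stretches the bond against the softened spring.
#'
#' @inheritParams k_of_field
#' @return Bond length(s), m.
#' @export
bond_length <- function(E, coeffs = default_coefficients()) {
  coeffs$d0 + (E / k_of_field(E, coeffs)) * coeffs$dpdd
}

#' Bond dipole moment from bond length
#'
#' Taylor expansion of the O-H bond dipole about the free bond length,
#' truncated at second order (the calibration determines exactly two
#' derivatives): \eqn{p(d) = p_0 + p'(d - d_0) + \tfrac12 p''(d - d_0)^2}.
#' Offsets beyond 0.12 Å — the largest calibrated offset — are extrapolation;
#' a warning is emitted but the value is still returned.
#'
#' @param d Bond length(s), m; must be positive.
#' @inheritParams k_of_field
#' @param warn_extrapolation Warn when `d - d0` exceeds the calibrated range.
#' @return Dipole moment(s), C m.
#' @export
bond_dipole <- function(d, coeffs = default_coefficients(),
                        warn_extrapolation = TRUE) {
  stopifnot(inherits(coeffs, "hb_coefficients"), is.numeric(d))
  if (any(d <= 0)) stop("bond length must be positive")
  dd <- d - coeffs$d0
  if (warn_extrapolation && any(dd > 0.12e-10))
    warning("bond length offset exceeds 0.12 Angstrom: ",
            "beyond the calibrated range of the Taylor expansion")
  coeffs$p0 + coeffs$dpdd * dd + 0.5 * coeffs$d2pdd2 * dd^2
}

#' Molecular dipole from two bond dipoles
#'
#' Vector sum of the two O-H bond dipoles of a water molecule across the
#' H-O-H angle.  For equal bond dipoles this reduces to
#' \eqn{2 p \cos(\theta_{HOH}/2)}.
#'
#' @param p1,p2 Bond dipole magnitudes, C m.
#' @param hoh_angle H-O-H angle in degrees, in (0, 180).
#' @return Molecular dipole magnitude, C m.
#' @examples
#' cst <- hb_constants()
#' molecular_dipole(1.514 * cst$debye, 1.514 * cst$debye, 104.48) / cst$debye
#' @export
molecular_dipole <- function(p1, p2, hoh_angle) {
  stopifnot(is.numeric(p1), is.numeric(p2), is.numeric(hoh_angle))
  if (any(hoh_angle <= 0 | hoh_angle >= 180))
    stop("hoh_angle must lie strictly between 0 and 180 degrees")
  th <- hoh_angle * pi / 180
  sqrt(pmax(p1^2 + p2^2 + 2 * p1 * p2 * cos(th), 0))
}

#' Hydrogen-bond energy
#'
#' \eqn{U_{HB} = p E} under the collinear convention: the dipole is aligned
#' with the local field and the magnitude is reported as a positive binding
#' energy (the defining minus sign lives in the potential, not the report).
#'
#' @param p Bond dipole(s), C m.
#' @param E Local field(s), V m\eqn{^{-1}}.
#' @return Energy per bond, J.  Use [convert_units()] for meV or kcal/mol.
#' @export
hb_energy <- function(p, E) {
  stopifnot(is.numeric(p), is.numeric(E))
  abs(p) * abs(E)
}

#' Bond polarizability as a function of bond length
#'
#' \eqn{\alpha(d) = [p' + p'' (d - d_0)]^3 / (p' k_0)}.  At \eqn{d = d_0}
#' this reduces exactly to \eqn{p'^2 / k_0}.  Along the field-length map
#' \eqn{d(E)} it is algebraically identical to [polarizability_of_field()]
#' because the bracket equals \eqn{p' k_0 / k(E)}.
#'
#' @inheritParams bond_dipole
#' @return Polarizability, C m\eqn{^2} V\eqn{^{-1}}.
#' @export
polarizability_of_length <- function(d, coeffs = default_coefficients()) {
  stopifnot(inherits(coeffs, "hb_coefficients"), is.numeric(d))
  br <- coeffs$dpdd + coeffs$d2pdd2 * (d - coeffs$d0)
  if (any(br <= 0))
    stop("non-positive bracket in polarizability: outside the model domain")
  br^3 / (coeffs$dpdd * coeffs$k0)
}

#' Bond polarizability as a function of local field
#'
#' \eqn{\alpha(E) = p'^2 k_0^2 / (k_0 - p'' E)^3}; strictly increasing in E
#' on the valid domain.
#'
#' @inheritParams k_of_field
#' @return Polarizability, C m\eqn{^2} V\eqn{^{-1}}.
#' @export
polarizability_of_field <- function(E, coeffs = default_coefficients()) {
  kE <- k_of_field(E, coeffs)
  coeffs$dpdd^2 * coeffs$k0^2 / kE^3
}

#' Representative liquid-water stretching wavenumber
#'
#' Liquid water shows a broad O-H stretching band from 3200 to 3650
#' cm\eqn{^{-1}} rather than a single peak.  The package represents the band
#' by its midpoint, 3425 cm\eqn{^{-1}}; both the band and the midpoint are
#' exposed so the convention is explicit and overridable.
#'
#' @param band Two-element band limits in cm\eqn{^{-1}}.
#' @return Midpoint wavenumber, cm\eqn{^{-1}}.
#' @export
liquid_water_wavenumber <- function(band = c(3200, 3650)) {
  stopifnot(is.numeric(band), length(band) == 2L)
  mean(band)
}

# deterministic prediction chain used for both the central value and the
# uncertainty propagation.  th = c(k0, d0, p0, dpdd, d2pdd2).  Negative E is
# tolerated here (it arises transiently when perturbing k0 for derivatives);
# the user-facing domain check happens in hb_predict().
.hb_chain <- function(nu, th, masses, hoh_angle = NULL) {
  k <- wavenumber_to_force_constant(nu, masses)
  E <- (th[["k0"]] - k) / th[["d2pdd2"]]
  d <- th[["d0"]] + (E / k) * th[["dpdd"]]
  dd <- d - th[["d0"]]
  p <- th[["p0"]] + th[["dpdd"]] * dd + 0.5 * th[["d2pdd2"]] * dd^2
  U <- p * E
  a <- (th[["dpdd"]] + th[["d2pdd2"]] * dd)^3 / (th[["dpdd"]] * th[["k0"]])
  out <- c(k = k, E_tot = E, d = d, p_bond = p, U_HB = U, alpha = a)
  if (!is.null(hoh_angle))
    out <- c(out, p_mol = molecular_dipole(p, p, hoh_angle))
  out
}

.coef_theta <- function(coeffs) {
  c(k0 = coeffs$k0, d0 = coeffs$d0, p0 = coeffs$p0,
    dpdd = coeffs$dpdd, d2pdd2 = coeffs$d2pdd2)
}

# 1-sigma covariance of the coefficient vector: diagonal from sigma2/2,
# overlaid with any fitted covariance entries.
.coef_cov <- function(coeffs) {
  th <- .coef_theta(coeffs)
  S <- diag((coeffs$sigma2[names(th)] / 2)^2, nrow = length(th))
  dimnames(S) <- list(names(th), names(th))
  cv <- coeffs$covariance
  if (!is.null(cv)) {
    nm <- intersect(rownames(cv), names(th))
    S[nm, nm] <- cv[nm, nm]
  }
  S
}

#' Predict hydrogen-bond properties from a stretching wavenumber
#'
#' Runs the full prediction chain
#' \eqn{\tilde\nu \to k \to E \to d \to p \to U_{HB}, \alpha}: force constant
#' from the harmonic relation, local field from the spring softening, bond
#' length from the field-stretch relation, bond dipole from the Taylor
#' expansion, energy as \eqn{pE} and polarizability from the cubic bracket.
#' With a geometry the molecular dipole (two equal bond dipoles summed over
#' the H-O-H angle) is added.
#'
#' Uncertainty propagation is first-order (delta method) by default: a
#' numerical Jacobian of the chain with respect to the five coefficients and
#' the wavenumber, contracted with the coefficient covariance.  A Monte-Carlo
#' mode (`uncertainty = "mc"`) re-runs the chain over Gaussian coefficient
#' draws and serves as a cross-check of the linearization.
#'
#' @param wavenumber Stretching wavenumber(s), cm\eqn{^{-1}}.  Must not be
#'   blue-shifted past the free-bond force constant.
#' @param coeffs An [hb_coefficients()] object.
#' @param masses An [oscillator_masses()] object.
#' @param hoh_angle Optional H-O-H angle (degrees) for the molecular dipole.
#' @param sigma_wavenumber 1-sigma measurement error(s) on the wavenumber,
#'   cm\eqn{^{-1}} (scalar or vector).
#' @param uncertainty `"delta"`, `"mc"` or `"none"`.
#' @param n_draws Number of Monte-Carlo draws.
#' @param seed Seed for the Monte-Carlo mode (required there; ignored
#'   otherwise).
#' @return An object of class `"hb_state"`: a data frame with one row per
#'   wavenumber, SI-unit columns `k`, `E_tot`, `d`, `p_bond`, `U_HB`,
#'   `alpha` (and `p_mol` when a geometry is given) plus `sigma2_*`
#'   companions holding propagated 2-sigma uncertainties.  The print method
#'   reports conventional units.
#' @examples
#' hb_predict(3616)                      # dangling O-H at a carbon surface
#' hb_predict(3279, hoh_angle = 109.21)  # ice Ih
#' @export
hb_predict <- function(wavenumber, coeffs = default_coefficients(),
                       masses = oscillator_masses(), hoh_angle = NULL,
                       sigma_wavenumber = 0,
                       uncertainty = c("delta", "mc", "none"),
                       n_draws = 10000L, seed = NULL) {
  uncertainty <- match.arg(uncertainty)
  stopifnot(is.numeric(wavenumber), all(wavenumber > 0))
  sigma_wavenumber <- rep_len(sigma_wavenumber, length(wavenumber))
  k_in <- wavenumber_to_force_constant(wavenumber, masses)
  if (any(k_in > coeffs$k0)) {
    bad <- wavenumber[k_in > coeffs$k0]
    stop("blue-shifted input (", paste(signif(bad, 7), collapse = ", "),
         " cm-1): force constant exceeds the free-bond k0; blue-shifting ",
         "strong HBs are outside the model domain")
  }
  th <- .coef_theta(coeffs)
  S <- .coef_cov(coeffs)

  rows <- lapply(seq_along(wavenumber), function(i) {
    nu <- wavenumber[i]
    val <- .hb_chain(nu, th, masses, hoh_angle)
    sig <- rep(NA_real_, length(val))
    if (uncertainty == "delta") {
      f <- function(par) .hb_chain(par[1L], par[-1L], masses, hoh_angle)
      par0 <- c(nu = nu, th)
      Sfull <- diag(0, length(par0))
      dimnames(Sfull) <- list(names(par0), names(par0))
      Sfull["nu", "nu"] <- sigma_wavenumber[i]^2
      Sfull[names(th), names(th)] <- S
      J <- .num_jacobian(f, par0)
      V <- J %*% Sfull %*% t(J)
      sig <- 2 * sqrt(pmax(diag(V), 0))
    } else if (uncertainty == "mc") {
      if (is.null(seed)) stop("Monte-Carlo propagation requires a seed")
      draws <- .with_seed(seed + i - 1L, {
        n <- as.integer(n_draws)
        thd <- matrix(stats::rnorm(n * length(th)), nrow = n) %*%
          chol(S + diag(1e-300, nrow(S))) # guard exact-zero variances
        thd <- sweep(thd, 2L, th, "+")
        colnames(thd) <- names(th)
        nud <- nu + stats::rnorm(n, 0, sigma_wavenumber[i])
        t(vapply(seq_len(n),
                 function(j) .hb_chain(nud[j], thd[j, ], masses, hoh_angle),
                 numeric(length(val))))
      })
      sig <- 2 * apply(draws, 2L, stats::sd)
    }
    names(sig) <- paste0("sigma2_", names(val))
    c(wavenumber = nu, val, sig)
  })
  out <- as.data.frame(do.call(rbind, rows))
  class(out) <- c("hb_state", "data.frame")
  attr(out, "coefficients") <- coeffs
  attr(out, "uncertainty") <- uncertainty
  out
}

# central-difference Jacobian with per-parameter relative steps
.num_jacobian <- function(f, par, rel = 1e-6) {
  f0 <- f(par)
  J <- matrix(0, nrow = length(f0), ncol = length(par),
              dimnames = list(names(f0), names(par)))
  for (j in seq_along(par)) {
    h <- rel * max(abs(par[j]), 1e-300)
    up <- par; up[j] <- up[j] + h
    dn <- par; dn[j] <- dn[j] - h
    J[, j] <- (f(up) - f(dn)) / (2 * h)
  }
  J
}

# evaluate expr under a temporary RNG state; global stream untouched
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.hb_state <- function(x, ...) {
  cst <- hb_constants()
  cat("Hydrogen-bond state predicted from O-H stretching wavenumber\n")
  df <- data.frame(
    nu_cm1    = x$wavenumber,
    k_N_m     = round(x$k, 1),
    E_V_nm    = signif(x$E_tot / 1e9, 4),
    d_A       = round(x$d / 1e-10, 4),
    p_D       = round(x$p_bond / cst$debye, 3),
    U_kcal_mol = signif(convert_units(x$U_HB, "J", "kcal/mol"), 4),
    U_meV     = signif(convert_units(x$U_HB, "J", "meV"), 4),
    alpha_Cm2_V = signif(x$alpha, 4)
  )
  if ("p_mol" %in% names(x)) df$p_mol_D <- round(x$p_mol / cst$debye, 3)
  if (!all(is.na(x$sigma2_U_HB)))
    df$U_2sigma_kcal <- signif(convert_units(x$sigma2_U_HB, "J", "kcal/mol"), 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.hb_state <- function(object, ...) {
  cat(sprintf("hb_state: %d bond(s); uncertainty mode '%s'; coefficients [%s]\n",
              nrow(object), attr(object, "uncertainty"),
              attr(object, "coefficients")$label))
  print(object)
  invisible(object)
}

#' Serialize an hb_state to JSON records
#'
#' Emits one JSON record per bond with SI field values and 2-sigma fields,
#' plus a provenance block carrying the coefficient set.
#'
#' @param state An `"hb_state"` object from [hb_predict()].
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when writing to file).
#' @export
hb_state_json <- function(state, path = NULL) {
  stopifnot(inherits(state, "hb_state"))
  cf <- attr(state, "coefficients")
  payload <- list(
    units = list(wavenumber = "cm-1", k = "N/m", E_tot = "V/m", d = "m",
                 p_bond = "C.m", U_HB = "J", alpha = "C.m2/V",
                 sigma = "2-sigma, same units"),
    coefficients = list(k0 = cf$k0, d0 = cf$d0, p0 = cf$p0,
                        dpdd = cf$dpdd, d2pdd2 = cf$d2pdd2,
                        label = cf$label),
    records = as.data.frame(unclass(state), check.names = FALSE)
  )
  js <- jsonlite::toJSON(payload, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
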