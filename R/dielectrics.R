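#' Effective polarizability along a confining axis
#'
#' Projects a bond polarizability onto the confining direction:
#' \eqn{\alpha_c = \alpha \cos^2\vartheta}, where \eqn{\vartheta} is the
#' angle between the O-H dipole and the axis.
#'
#' @param alpha Bond polarizability, C m\eqn{^2} V\eqn{^{-1}}.
#' @param theta_deg Angle to the confining axis, degrees in \[0, 90\].
#' @return Projected polarizability, same units.
#' @export
effective_polarizability <- function(alpha, theta_deg) {
  stopifnot(is.numeric(alpha), is.numeric(theta_deg))
  if (any(theta_deg < 0 | theta_deg > 90))
    stop("theta_deg must lie in [0, 90]")
  alpha * cos(theta_deg * pi / 180)^2
}

#' Dielectric constant of rotationally frozen (confined) water
#'
#' When dipole reorientation is blocked by confinement, only bond
#' stretching polarizes, and the per-dipole contributions simply add:
#' \eqn{\epsilon_r = 1 + (1/\epsilon_0) \sum_i \alpha_{c,i} N_i}.  An empty
#' system is vacuum (\eqn{\epsilon_r = 1}).
#'
#' @param components Data frame (or list coercible to one) with columns
#'   `alpha_c` (C m\eqn{^2} V\eqn{^{-1}}) and `number_density`
#'   (m\eqn{^{-3}}); may have zero rows.
#' @return Dimensionless \eqn{\epsilon_r \ge 1}.
#' @examples
#' epsilon_confined(data.frame(alpha_c = numeric(), number_density = numeric()))
#' @export
epsilon_confined <- function(components) {
  components <- as.data.frame(components)
  if (nrow(components) == 0L) return(1)
  stopifnot(all(c("alpha_c", "number_density") %in% names(components)))
  if (any(components$alpha_c < 0) || any(components$number_density < 0))
    stop("alpha_c and number_density must be non-negative")
  1 + sum(components$alpha_c * components$number_density) /
    hb_constants()$vacuum_permittivity
}

#' Gypsum-type confined-water dielectric constant
#'
#' Convenience wrapper: from per-species local fields and confining angles,
#' evaluates the field-form polarizability, projects with
#' \eqn{\cos^2\vartheta} and sums over the number density.  The defaults
#' are the gypsum geometry ([gypsum_geometry()]) with the main-text-rounded
#' coefficients, the combination at which the reference value 6.6 for the
#' confined 2D water layer was computed.
#'
#' @param E_HB Named/unnamed vector of local fields, V m\eqn{^{-1}}.
#' @param theta_deg Angles to the confining axis, degrees (same length).
#' @param number_density Number density per dipole species, m\eqn{^{-3}}
#'   (recycled).
#' @param coeffs [hb_coefficients()].
#' @return List with `epsilon` and the per-species `components` data frame.
#' @export
epsilon_confined_water <- function(E_HB = gypsum_geometry()$E_HB,
                                   theta_deg = gypsum_geometry()$theta_deg,
                                   number_density =
                                     gypsum_geometry()$number_density_confined,
                                   coeffs = default_coefficients("main_text")) {
  stopifnot(length(E_HB) == length(theta_deg))
  alpha <- polarizability_of_field(E_HB, coeffs)
  comp <- data.frame(
    species = if (is.null(names(E_HB))) seq_along(E_HB) else names(E_HB),
    alpha = alpha,
    alpha_c = effective_polarizability(alpha, theta_deg),
    number_density = rep_len(number_density, length(E_HB))
  )
  list(epsilon = epsilon_confined(comp), components = comp)
}

#' Series-capacitor decomposition of a layered dielectric
#'
#' A layered crystal behaves as capacitors in series:
#' \eqn{1/\epsilon_{tot} = f_1/\epsilon_1 + f_2/\epsilon_2} with thickness
#' fractions \eqn{f_i}.  `series_decompose` solves for the unknown layer
#' given the total and one known layer; `series_compose` is the forward
#' relation.
#'
#' @param total_epsilon Measured total \eqn{\epsilon_r}.
#' @param fraction_known Thickness fraction of the known layer, in (0, 1).
#' @param epsilon_known Its \eqn{\epsilon_r} (>= 1).
#' @return Dielectric constant of the other layer (>= 1), or an error when
#'   the inputs admit no physical solution.
#' @examples
#' series_decompose(3.68, 0.40, 6.6)  # ~2.8 for the bare CaSO4 sheets
#' @export
series_decompose <- function(total_epsilon, fraction_known, epsilon_known) {
  stopifnot(total_epsilon > 0, epsilon_known >= 1,
            fraction_known > 0, fraction_known < 1)
  f_u <- 1 - fraction_known
  inv <- 1 / total_epsilon - fraction_known / epsilon_known
  eps <- f_u / inv
  if (!is.finite(eps) || eps < 1)
    stop(sprintf(paste0("no physical solution: total epsilon %.3g with layer ",
                        "(f = %.3g, epsilon = %.3g) implies epsilon = %.3g ",
                        "for the remaining layer"),
                 total_epsilon, fraction_known, epsilon_known, eps))
  eps
}

#' @rdname series_decompose
#' @param fractions Thickness fractions summing to 1.
#' @param epsilons Layer dielectric constants (all >= 1).
#' @export
series_compose <- function(fractions, epsilons) {
  stopifnot(length(fractions) == length(epsilons),
            all(epsilons >= 1), all(fractions > 0))
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  1 / sum(fractions / epsilons)
}

#' Boltzmann orientation average of cos^2
#'
#' For dipoles with orientation energy \eqn{-pE\cos\theta} at reduced field
#' \eqn{x = pE/k_BT}, the thermal average
#' \eqn{\langle\cos^2\theta\rangle = \int_{-1}^{1} y^2 e^{xy} dy /
#' \int_{-1}^{1} e^{xy} dy}.  `"quadrature"` evaluates the ratio by
#' adaptive quadrature (integrands are rescaled by \eqn{e^{-x}} so large
#' \eqn{x} cannot overflow); `"taylor"` is the small-field expansion kept
#' to quadratic order, \eqn{1/3 + 2x^2/45} (the exact average is
#' \eqn{1 - 2\coth(x)/x + 2/x^2}, which saturates to 1 only as
#' \eqn{x \to \infty}, approximately like \eqn{1 - 2/x}).
#'
#' @param x Reduced field \eqn{pE/k_BT \ge 0} (vectorized).
#' @param method `"quadrature"` or `"taylor"`.
#' @param rel_tol Quadrature relative tolerance.
#' @return \eqn{\langle\cos^2\theta\rangle} in \[1/3, 1\) for quadrature.
#' @examples
#' boltzmann_cos2_average(0)        # exactly 1/3
#' boltzmann_cos2_average(60)       # saturates toward 1
#' @export
boltzmann_cos2_average <- function(x, method = c("quadrature", "taylor"),
                                   rel_tol = 1e-10) {
  method <- match.arg(method)
  stopifnot(is.numeric(x))
  if (any(x < 0)) stop("x = pE/kT must be non-negative")
  if (method == "taylor") return(1 / 3 + 2 * x^2 / 45)
  vapply(x, function(xi) {
    if (xi == 0) return(1 / 3)
    num <- tryCatch(
      stats::integrate(function(y) y^2 * exp(xi * (y - 1)), -1, 1,
                       rel.tol = rel_tol, abs.tol = 0)$value,
      error = function(e) stop("quadrature failed for x = ", xi, ": ",
                               conditionMessage(e)))
    den <- stats::integrate(function(y) exp(xi * (y - 1)), -1, 1,
                            rel.tol = rel_tol, abs.tol = 0)$value
    num / den
  }, numeric(1))
}

#' Static dielectric constant of bulk liquid water
#'
#' Langevin-Debye orientation polarization plus atomic/electronic (bond
#' stretching) polarization:
#' \deqn{\epsilon_r = 1 + \frac{N_0}{3\epsilon_0}\left[G_k\frac{p^2}{k_BT}
#'   + 2\alpha + \frac{2\alpha}{15}\left(\frac{pE}{k_BT}\right)^2\right]}
#' where \eqn{p} is the molecular dipole, \eqn{\alpha} the per-bond
#' polarizability (each molecule carries two O-H bonds, hence the factor
#' 2), \eqn{N_0} the molecular number density and \eqn{G_k} the Kirkwood
#' dipole correlation factor multiplying the orientation term only
#' (\eqn{G_k = 1}: uncorrelated rotations).
#'
#' @param p Molecular dipole moment, C m.
#' @param alpha Per-bond polarizability, C m\eqn{^2} V\eqn{^{-1}}.
#' @param N0 Molecular number density, m\eqn{^{-3}} (default 3.35e28,
#'   ambient liquid water).
#' @param temperature Temperature, K (default 298).
#' @param G_k Kirkwood correlation factor (>= 1).
#' @param E Probing field, V m\eqn{^{-1}} (default 0; enters only the
#'   small quadratic saturation term).
#' @param orientation_term Include the dipole-reorientation term; set
#'   `FALSE` for rotationally frozen water (then only the \eqn{2\alpha}
#'   and saturation terms remain).
#' @return Dimensionless \eqn{\epsilon_r}.
#' @examples
#' lw <- liquid_water_params()
#' epsilon_liquid_water(lw$p, lw$alpha)          # ~27 at G_k = 1
#' @export
epsilon_liquid_water <- function(p, alpha, N0 = 3.35e28, temperature = 298,
                                 G_k = 1, E = 0, orientation_term = TRUE) {
  stopifnot(temperature > 0, N0 > 0, G_k >= 1)
  cst <- hb_constants()
  kT <- cst$boltzmann * temperature
  term <- 2 * alpha + (2 * alpha / 15) * (p * E / kT)^2
  if (orientation_term) term <- term + G_k * p^2 / kT
  1 + N0 / (3 * cst$vacuum_permittivity) * term
}

#' Model inputs for bulk liquid water
#'
#' Evaluates the molecular dipole (bond dipole at the liquid-phase bond
#' length 0.984 Å, vector-summed over the liquid H-O-H angle 103.924°) and
#' the per-bond polarizability at that length.  The main-text-rounded
#' coefficients are the default because the reference liquid-water results
#' (2.66 D, \eqn{\epsilon_r} = 27) were computed at that rounding.
#'
#' @param coeffs [hb_coefficients()].
#' @param d Liquid O-H bond length, m.
#' @param hoh_angle Liquid H-O-H angle, degrees.
#' @return List with `p` (C m), `alpha` (C m\eqn{^2} V\eqn{^{-1}}), `d`,
#'   `hoh_angle`.
#' @export
liquid_water_params <- function(coeffs = default_coefficients("main_text"),
                                d = 0.984e-10, hoh_angle = 103.924) {
  pb <- bond_dipole(d, coeffs)
  list(p = molecular_dipole(pb, pb, hoh_angle),
       alpha = polarizability_of_length(d, coeffs),
       d = d, hoh_angle = hoh_angle)
}

#' Kirkwood factor required to reach a target dielectric constant
#'
#' Solves the liquid-water relation for \eqn{G_k} given a target
#' \eqn{\epsilon_r} (closed form, since \eqn{G_k} enters linearly).
#'
#' @inheritParams epsilon_liquid_water
#' @param target Target \eqn{\epsilon_r} (e.g. the experimental 79).
#' @return The required \eqn{G_k}.
#' @examples
#' lw <- liquid_water_params()
#' kirkwood_factor(79, lw$p, lw$alpha)  # ~3.15
#' @export
kirkwood_factor <- function(target, p, alpha, N0 = 3.35e28,
                            temperature = 298, E = 0) {
  cst <- hb_constants()
  kT <- cst$boltzmann * temperature
  pref <- N0 / (3 * cst$vacuum_permittivity)
  ((target - 1) / pref - 2 * alpha - (2 * alpha / 15) * (p * E / kT)^2) *
    kT / p^2
}

#' Dielectric constant of a proton-ordered ice from its geometry
#'
#' For proton-ordered phases (XI, II, IX) every O-H dipole has a fixed
#' orientation, so the static response is purely atomic/electronic and
#' follows the confined-water summation: number densities from the mass
#' density, per-dipole-type polarizability from the bond length, projection
#' by \eqn{\cos^2\vartheta} on the assessed axis.
#'
#' The crystallographic dipole orientations are not packaged — they must be
#' taken from published neutron structures of the respective phases — so
#' `geometry` is a required user input.
#'
#' @param geometry Data frame with `theta_deg` (angle of each non-equivalent
#'   O-H dipole type to the assessed axis) and `multiplicity` (its count in
#'   the cell); missing input is an explicit data-requirement error.
#' @param d Bond length, m (scalar, or one per dipole type).
#' @param density Mass density, g cm\eqn{^{-3}}.
#' @param coeffs [hb_coefficients()].
#' @param molar_mass Molar mass of the repeat unit, g mol\eqn{^{-1}}
#'   (default H\eqn{_2}O).
#' @return List with `epsilon` and the per-type `components`.
#' @export
epsilon_ordered_ice <- function(geometry, d, density,
                                coeffs = default_coefficients(),
                                molar_mass = 18.01528) {
  if (missing(geometry) || is.null(geometry))
    stop("proton-ordered ice geometry (theta_deg, multiplicity per ",
         "non-equivalent O-H dipole) is required input: take it from the ",
         "published neutron structure of the phase; it is not packaged")
  geometry <- as.data.frame(geometry)
  stopifnot(all(c("theta_deg", "multiplicity") %in% names(geometry)),
            density > 0)
  N_mol <- density * 1e6 / molar_mass * hb_constants()$avogadro  # molecules/m3
  w <- geometry$multiplicity / sum(geometry$multiplicity)
  N_i <- 2 * N_mol * w                     # two O-H dipoles per molecule
  alpha <- polarizability_of_length(rep_len(d, nrow(geometry)), coeffs)
  comp <- data.frame(
    theta_deg = geometry$theta_deg,
    alpha = alpha,
    alpha_c = effective_polarizability(alpha, geometry$theta_deg),
    number_density = N_i
  )
  list(epsilon = epsilon_confined(comp), components = comp)
}

#' Field modulation of a confined-water dielectric constant
#'
#' Under an external field along the confining axis the two antiparallel
#' members of each dipole species see \eqn{E_{HB} \pm E\cos\vartheta}: the
#' symmetry breaks, each species' polarizability splits into two branches,
#' and the dielectric constant acquires a weak, even-in-field modulation.
#' Returns the maximum relative change of \eqn{\epsilon_r} over the scanned
#' range, relative to the zero-field value.
#'
#' @param E_range Scan limit(s), V m\eqn{^{-1}}: a scalar (scan \eqn{\pm}
#'   that value) or a vector of fields to evaluate.
#' @param E_HB Per-species local fields, V m\eqn{^{-1}}.
#' @param theta_deg Per-species confining angles, degrees.
#' @param number_density Number density per species, m\eqn{^{-3}}.
#' @param coeffs [hb_coefficients()].
#' @param n_grid Grid points across the range.
#' @return List with `modulation` (max \eqn{|\Delta\epsilon|/\epsilon(0)}),
#'   `epsilon0`, and the scanned `epsilon` curve.
#' @export
field_modulation_epsilon <- function(E_range,
                                     E_HB = gypsum_geometry()$E_HB,
                                     theta_deg = gypsum_geometry()$theta_deg,
                                     number_density =
                                       gypsum_geometry()$number_density_confined,
                                     coeffs = default_coefficients("main_text"),
                                     n_grid = 41L) {
  stopifnot(length(E_HB) == length(theta_deg))
  grid <- if (length(E_range) == 1L)
    seq(-abs(E_range), abs(E_range), length.out = n_grid) else E_range
  number_density <- rep_len(number_density, length(E_HB))
  eps_at <- function(E_ext) {
    ct <- cos(theta_deg * pi / 180)
    a_plus <- polarizability_of_field(E_HB + E_ext * ct, coeffs)
    a_minus <- polarizability_of_field(E_HB - E_ext * ct, coeffs)
    comp <- data.frame(alpha_c = effective_polarizability(
                         c(a_plus, a_minus), rep(theta_deg, 2L)),
                       number_density = rep(number_density / 2, 2L))
    epsilon_confined(comp)
  }
  eps <- vapply(grid, eps_at, numeric(1))
  eps0 <- eps_at(0)
  list(modulation = max(abs(eps - eps0)) / eps0,
       epsilon0 = eps0,
       scan = data.frame(E_ext = grid, epsilon = eps))
}
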