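#' Oscillator masses for the D-H stretching mode
#'
#' Builds the mass pair whose reduced mass converts a stretching wavenumber
#' into a harmonic force constant, \eqn{k = \mu (2\pi c \tilde\nu)^2}.
#'
#' The default is the integer-mass convention (\eqn{m_O = 16}, \eqn{m_H = 1}
#' u).  This convention is deliberate: it reproduces the reference free O-H
#' force constant of 762.0 N m\eqn{^{-1}} at 3706.491 cm\eqn{^{-1}}, whereas
#' isotopic masses (15.994915, 1.0078250) give about 767.8 N m\eqn{^{-1}}.
#' The choice is exposed rather than hidden so users can audit it.
#'
#' @param donor_mass Donor (heavy-atom) mass in atomic mass units.
#' @param hydrogen_mass Hydrogen mass in atomic mass units.
#' @return An object of class `"oscillator_masses"`: a list with
#'   `donor_mass`, `hydrogen_mass` and derived `reduced_mass` (all in u).
#' @examples
#' oscillator_masses()            # integer-mass convention
#' oscillator_masses(15.994915, 1.00782503)  # isotopic, NOT the default
#' @export
oscillator_masses <- function(donor_mass = 16, hydrogen_mass = 1) {
  stopifnot(is.numeric(donor_mass), is.numeric(hydrogen_mass),
            length(donor_mass) == 1L, length(hydrogen_mass) == 1L)
  if (donor_mass <= 0 || hydrogen_mass <= 0)
    stop("oscillator masses must be positive")
  m <- list(
    donor_mass    = donor_mass,
    hydrogen_mass = hydrogen_mass,
    reduced_mass  = donor_mass * hydrogen_mass / (donor_mass + hydrogen_mass)
  )
  class(m) <- "oscillator_masses"
  m
}

#' @export
print.oscillator_masses <- function(x, ...) {
  cat(sprintf("O-H oscillator masses: donor %g u, hydrogen %g u, reduced %.7g u\n",
              x$donor_mass, x$hydrogen_mass, x$reduced_mass))
  invisible(x)
}

#' Convert a stretching wavenumber to a harmonic force constant
#'
#' \eqn{k = \mu (2 \pi c \tilde\nu)^2} with \eqn{\mu} the reduced mass of the
#' donor-hydrogen pair.
#'
#' @param wavenumber Stretching wavenumber(s) in cm\eqn{^{-1}}; must be
#'   non-negative.
#' @param masses An [oscillator_masses()] object.
#' @return Force constant(s) in N m\eqn{^{-1}}.
#' @examples
#' wavenumber_to_force_constant(3706.491)  # ~762 N/m, free O-H
#' @export
wavenumber_to_force_constant <- function(wavenumber, masses = oscillator_masses()) {
  stopifnot(is.numeric(wavenumber), inherits(masses, "oscillator_masses"))
  if (any(wavenumber < 0)) stop("wavenumber must be non-negative")
  cst <- hb_constants()
  mu <- masses$reduced_mass * cst$atomic_mass_unit
  omega <- 2 * pi * cst$speed_of_light_cm * wavenumber
  mu * omega^2
}

#' Convert a harmonic force constant back to a stretching wavenumber
#'
#' Exact inverse of [wavenumber_to_force_constant()].
#'
#' @param k Force constant(s) in N m\eqn{^{-1}}; must be non-negative.
#' @inheritParams wavenumber_to_force_constant
#' @return Wavenumber(s) in cm\eqn{^{-1}}.
#' @examples
#' force_constant_to_wavenumber(725)  # ~3616 cm^-1, water-carbon band
#' @export
force_constant_to_wavenumber <- function(k, masses = oscillator_masses()) {
  stopifnot(is.numeric(k), inherits(masses, "oscillator_masses"))
  if (any(k < 0)) stop("force constant must be non-negative")
  cst <- hb_constants()
  mu <- masses$reduced_mass * cst$atomic_mass_unit
  sqrt(k / mu) / (2 * pi * cst$speed_of_light_cm)
}

# unit table: per physical dimension, the factor taking one unit to the SI
# anchor of that dimension.  Energy units are per-particle joules; molar
# units fold in Avogadro's number.
.unit_table <- function() {
  cst <- hb_constants()
  list(
    length = c("m" = 1, "angstrom" = 1e-10, "A" = 1e-10),
    dipole = c("C.m" = 1, "D" = cst$debye),
    field  = c("V/m" = 1, "V/nm" = 1e9),
    energy = c("J" = 1,
               "eV" = cst$elementary_charge,
               "meV" = cst$elementary_charge * 1e-3,
               "kcal/mol" = 4184 / cst$avogadro,
               "kJ/mol" = 1000 / cst$avogadro),
    wavenumber = c("cm-1" = 1),
    force_constant = c("N/m" = 1)
  )
}

#' Linear unit conversion at the I/O boundary
#'
#' Internally the package is strictly SI; this helper converts between the
#' conventional spectroscopic units at input/output.  Supported:
#' length (`"m"`, `"angstrom"`), dipole moment (`"C.m"`, `"D"`; 1 D =
#' 3.33564e-30 C m), electric field (`"V/m"`, `"V/nm"`), energy (`"J"`,
#' `"eV"`, `"meV"`, `"kcal/mol"`, `"kJ/mol"`), plus the identity units
#' `"cm-1"` and `"N/m"`.  Cross-dimension conversions are refused.
#'
#' @param value Numeric vector.
#' @param from,to Unit names.
#' @return Converted numeric vector.
#' @examples
#' convert_units(1.514, "D", "C.m")
#' convert_units(455, "meV", "kcal/mol")  # ~10.5
#' @export
convert_units <- function(value, from, to) {
  stopifnot(is.numeric(value), is.character(from), is.character(to))
  tab <- .unit_table()
  dim_of <- function(u) {
    hit <- vapply(tab, function(d) u %in% names(d), logical(1))
    if (!any(hit)) stop(sprintf("unknown unit '%s'", u))
    names(tab)[which(hit)[1L]]
  }
  df <- dim_of(from); dt <- dim_of(to)
  if (df != dt)
    stop(sprintf("cannot convert between '%s' (%s) and '%s' (%s)",
                 from, df, to, dt))
  value * tab[[df]][[from]] / tab[[dt]][[to]]
}
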