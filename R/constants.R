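#' Physical constants used throughout the package
#'
#' Returns the pinned CODATA 2018 constants the package computes with.  The
#' set is created once at load time and is not user-configurable: every
#' downstream quantity (force constants, energies, dielectric constants) is
#' defined relative to these values, so changing them silently would make
#' results irreproducible.
#'
#' @return A named list with components
#'   \describe{
#'     \item{vacuum_permittivity}{\eqn{\epsilon_0} in F m\eqn{^{-1}}.}
#'     \item{boltzmann}{\eqn{k_B} in J K\eqn{^{-1}}.}
#'     \item{speed_of_light_cm}{c in cm s\eqn{^{-1}} (spectroscopic form, so
#'       that \eqn{\omega = 2\pi c \tilde\nu} takes wavenumbers in
#'       cm\eqn{^{-1}}).}
#'     \item{debye}{1 Debye in C m (3.33564e-30).}
#'     \item{avogadro}{mol\eqn{^{-1}}.}
#'     \item{atomic_mass_unit}{kg.}
#'     \item{elementary_charge}{C.}
#'   }
#' @examples
#' hb_constants()$debye
#' @export
hb_constants <- function() {
  list(
    vacuum_permittivity = 8.8541878128e-12,
    boltzmann           = 1.380649e-23,
    speed_of_light_cm   = 2.99792458e10,
    debye               = 3.33564e-30,
    avogadro            = 6.02214076e23,
    atomic_mass_unit    = 1.66053906660e-27,
    elementary_charge   = 1.602176634e-19
  )
}

#' Constants as machine-readable JSON
#'
#' Serializes [hb_constants()] for provenance blocks in reports.
#'
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when writing to a file).
#' @export
constants_json <- function(path = NULL) {
  js <- jsonlite::toJSON(hb_constants(), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
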