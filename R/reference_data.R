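#' Load the packaged reference-system table
#'
#' Curated table of solid-state water systems with assigned O-H stretching
#' wavenumbers and thermally corrected bond lengths: the free molecule, ices
#' Ih/II/VI/VIII/IX/XVII, gypsum, and the solid hydrates
#' Li\eqn{_2}SO\eqn{_4}·H\eqn{_2}O, CuSO\eqn{_4}·5H\eqn{_2}O
#' (non-coordinated water only), Ba(ClO\eqn{_3})\eqn{_2}·H\eqn{_2}O,
#' LiClO\eqn{_4}·3H\eqn{_2}O and BaCl\eqn{_2}·2H\eqn{_2}O.  One row per
#' usable bond; systems excluded from the calibration are listed separately
#' in [reference_exclusions()].
#'
#' Bond lengths measured on deuterated samples carry the pre-conversion
#' value in `d_preconversion_A`; `d_corrected_A` is the D-to-H upshifted
#' (+3%) value actually used downstream.  Thermal-correction formulas are
#' deliberately not implemented: corrected lengths are stored as data, with
#' the correction type noted in `provenance`.
#'
#' @param path Optional CSV path; defaults to the packaged table.
#' @return Data frame of class `"reference_table"` with columns `system`,
#'   `temperature_K`, `isotope`, `bond_label`, `wavenumber_cm1`,
#'   `d_corrected_A`, `sigma_d_A`, `d_preconversion_A`, `provenance`.
#' @export
load_reference_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "reference_systems.csv",
                        package = "hbdipole", mustWork = TRUE)
  schema_path <- system.file("extdata", "reference_systems_schema.json",
                             package = "hbdipole", mustWork = TRUE)
  schema <- jsonlite::read_json(schema_path, simplifyVector = TRUE)
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1L]]
  if (!identical(header, schema$columns))
    stop("reference table schema mismatch: expected columns (v",
         schema$schema_version, "): ",
         paste(schema$columns, collapse = ", "))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = unlist(schema$column_classes))
  class(df) <- c("reference_table", "data.frame")
  attr(df, "schema_version") <- schema$schema_version
  df
}

#' @rdname load_reference_table
#' @return `reference_exclusions`: data frame with `system` and `reason`.
#' @export
reference_exclusions <- function() {
  utils::read.csv(system.file("extdata", "reference_exclusions.csv",
                              package = "hbdipole", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

# canonical number formatting: plain decimal notation, no trailing zeros,
# so write -> read -> write is byte-stable
.fmt_num <- function(x) {
  ifelse(is.na(x), "",
         vapply(x, function(v) format(v, scientific = FALSE, trim = TRUE,
                                      digits = 15), character(1)))
}

#' Write a reference table in canonical form
#'
#' Fixed column order and plain-decimal number formatting so that a
#' write/read cycle is byte-identical (the packaged table was written with
#' this function).
#'
#' @param tab A `"reference_table"` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_reference_table <- function(tab, path) {
  cols <- c("system", "temperature_K", "isotope", "bond_label",
            "wavenumber_cm1", "d_corrected_A", "sigma_d_A",
            "d_preconversion_A", "provenance")
  stopifnot(all(cols %in% names(tab)))
  num <- c("temperature_K", "wavenumber_cm1", "d_corrected_A", "sigma_d_A",
           "d_preconversion_A")
  m <- vapply(cols, function(cn) {
    v <- tab[[cn]]
    if (cn %in% num) .fmt_num(v) else ifelse(is.na(v), "", as.character(v))
  }, character(nrow(tab)))
  if (nrow(tab) == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, cols))
  lines <- c(paste(cols, collapse = ","),
             apply(m, 1L, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Deuterated-to-protiated bond-length conversion
#'
#' O-H bonds are about 3% longer than the O-D bonds measured on deuterated
#' samples; lengths from D\eqn{_2}O neutron data are upshifted by exactly
#' that factor.
#'
#' @param d_deuterated Bond length(s), any length unit.
#' @return Length(s) scaled by 1.03.
#' @examples
#' dh_length_conversion(0.981)  # 1.010 (ice VIII)
#' @export
dh_length_conversion <- function(d_deuterated) {
  stopifnot(is.numeric(d_deuterated))
  if (any(d_deuterated <= 0)) stop("bond length must be positive")
  d_deuterated * 1.03
}

#' Average intramolecularly coupled stretching modes
#'
#' When a molecule's two O-H bonds are equivalent, the stretching vibration
#' couples into symmetric/antisymmetric normal modes; the uncoupled
#' bond-stretching frequency is represented by their arithmetic mean.
#'
#' @param wavenumbers Non-empty numeric vector, cm\eqn{^{-1}}.
#' @return Mean wavenumber, cm\eqn{^{-1}}.
#' @examples
#' coupled_mode_average(c(3477.4, 3447.6, 3358.8))  # ice VIII, 3427.9
#' @export
coupled_mode_average <- function(wavenumbers) {
  if (length(wavenumbers) == 0L) stop("no wavenumbers supplied")
  stopifnot(is.numeric(wavenumbers))
  mean(wavenumbers)
}

#' Pair bond lengths with stretching frequencies
#'
#' Assigns frequencies to bonds by the rule that a shorter bond vibrates at
#' a higher frequency (steeper potential): lengths sorted ascending are
#' paired with wavenumbers sorted descending.
#'
#' @param bond_lengths Numeric vector of lengths.
#' @param wavenumbers Numeric vector of the same length, cm\eqn{^{-1}}.
#' @return Data frame with `d` (ascending) and `wavenumber` (descending).
#' @export
assign_frequencies <- function(bond_lengths, wavenumbers) {
  if (length(bond_lengths) != length(wavenumbers))
    stop("bond_lengths and wavenumbers must have equal length")
  data.frame(d = sort(bond_lengths),
             wavenumber = sort(wavenumbers, decreasing = TRUE))
}

#' Check packaged assignments against the shorter-bond rule
#'
#' Re-derives every system's length-frequency pairing from
#' [assign_frequencies()] and reports rows where the packaged table
#' disagrees.  Conflicts are reported, never overridden: the packaged
#' pairing follows its sources.
#'
#' @param tab A reference table.
#' @return Data frame of conflicting rows (zero rows when fully monotone).
#' @export
verify_reference_assignments <- function(tab = load_reference_table()) {
  out <- lapply(split(seq_len(nrow(tab)), tab$system), function(ix) {
    sub <- tab[ix, ]
    if (nrow(sub) < 2L) return(NULL)
    rule <- assign_frequencies(sub$d_corrected_A, sub$wavenumber_cm1)
    sub <- sub[order(sub$d_corrected_A), ]
    bad <- sub$wavenumber_cm1 != rule$wavenumber
    if (!any(bad)) return(NULL)
    cbind(sub[bad, c("system", "bond_label", "d_corrected_A",
                     "wavenumber_cm1")],
          rule_wavenumber = rule$wavenumber[bad])
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(system = character(), bond_label = character(),
                      d_corrected_A = numeric(), wavenumber_cm1 = numeric(),
                      rule_wavenumber = numeric())
  rownames(out) <- NULL
  out
}

#' Water molecular geometries used in dipole reconstructions
#'
#' H-O-H angles and O-H bond lengths for the three standard reference
#' states of water, as used when combining two bond dipoles into a
#' molecular dipole: gas phase, ambient liquid, and a proton-ordered ice Ih
#' structure (thermally corrected bond length).
#'
#' @return Data frame with `state`, `hoh_angle_deg`, `d_A`.
#' @export
water_geometries <- function() {
  data.frame(
    state = c("gas", "liquid", "ice_Ih"),
    hoh_angle_deg = c(104.48, 103.924, 109.21),
    d_A = c(0.9578, 0.984, 1.0125)
  )
}

#' Gypsum confined-water geometry and reference quantities
#'
#' The two crystallographically distinct O-H dipoles of structural water in
#' gypsum (CaSO\eqn{_4}·2H\eqn{_2}O): intralayer O-H_A and interlayer
#' O-H_B, their angles to the out-of-plane (confining) b-axis from neutron
#' diffraction, their calibrated local fields, the water number density in
#' the confining space, the confined volume fraction, and the measured
#' dielectric constant of the whole crystal.
#'
#' @return A list with `theta_deg` (named, degrees), `E_HB` (named, V/m),
#'   `number_density_confined` (m\eqn{^{-3}}, per dipole type),
#'   `confined_fraction`, and `measured_epsilon`.
#' @export
gypsum_geometry <- function() {
  list(
    theta_deg = c(A = 69.60, B = 9.37),
    E_HB = c(A = 5.33e9, B = 3.82e9),
    number_density_confined = 4.06e28,
    confined_fraction = 0.40,
    measured_epsilon = 3.68
  )
}
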