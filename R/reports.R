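# report layer behind the command-line tool: pure functions of their inputs
# so repeated runs are byte-identical.

.provenance <- function(coeffs) {
  list(package = "hbdipole",
       version = as.character(utils::packageVersion("hbdipole")),
       coefficients = list(k0 = coeffs$k0, d0 = coeffs$d0, p0 = coeffs$p0,
                           dpdd = coeffs$dpdd, d2pdd2 = coeffs$d2pdd2,
                           label = coeffs$label))
}

#' Prediction report for a set of stretching wavenumbers
#'
#' Runs [hb_predict()] on each input wavenumber and renders the result as a
#' human-readable table (`"text"`), tab-separated values (`"tsv"`) or a JSON
#' document with a provenance block (`"json"`).  Blue-shifted inputs
#' propagate the model-domain error.
#'
#' @param wavenumber Wavenumbers, cm\eqn{^{-1}}.
#' @param coeffs [hb_coefficients()].
#' @param hoh_angle Optional H-O-H angle for molecular dipoles, degrees.
#' @param format Output format.
#' @return Character vector of report lines (a single JSON string for
#'   `"json"`).
#' @export
report_predict <- function(wavenumber, coeffs = default_coefficients(),
                           hoh_angle = NULL,
                           format = c("text", "json", "tsv")) {
  format <- match.arg(format)
  st <- hb_predict(wavenumber, coeffs = coeffs, hoh_angle = hoh_angle)
  if (format == "json") {
    payload <- list(provenance = .provenance(coeffs),
                    records = as.data.frame(unclass(st), check.names = FALSE))
    return(jsonlite::toJSON(payload, dataframe = "rows", auto_unbox = TRUE,
                            digits = NA, na = "null"))
  }
  cst <- hb_constants()
  df <- data.frame(
    nu_cm1 = st$wavenumber,
    k_N_m = sprintf("%.1f", st$k),
    E_V_nm = sprintf("%.3f", st$E_tot / 1e9),
    d_A = sprintf("%.4f", st$d / 1e-10),
    p_D = sprintf("%.3f", st$p_bond / cst$debye),
    U_kcal_mol = sprintf("%.3f", convert_units(st$U_HB, "J", "kcal/mol")),
    U_2s = sprintf("%.3f", convert_units(st$sigma2_U_HB, "J", "kcal/mol"))
  )
  if (format == "tsv")
    return(c(paste(names(df), collapse = "\t"),
             apply(df, 1L, paste, collapse = "\t")))
  c(sprintf("hbdipole %s prediction report [%s]",
            utils::packageVersion("hbdipole"), coeffs$label),
    utils::capture.output(print(df, row.names = FALSE)))
}

#' Calibration report
#'
#' Runs [calibrate()] (both stages, or the reference-table stage alone when
#' no sweeps are given) and serializes the resulting coefficient set,
#' covariances and goodness-of-fit as JSON.
#'
#' @param sweeps Optional list of [field_sweep()] datasets (or a CSV path
#'   readable by [read_field_sweeps()]).
#' @param reference Reference table (or CSV path).
#' @param ... Passed to [calibrate()].
#' @return JSON string.
#' @export
report_calibrate <- function(sweeps = NULL,
                             reference = load_reference_table(), ...) {
  if (is.character(sweeps)) sweeps <- read_field_sweeps(sweeps)
  if (is.character(reference)) reference <- load_reference_table(reference)
  cal <- calibrate(sweeps = sweeps, reference = reference, ...)
  cf <- cal$coefficients
  payload <- list(
    provenance = .provenance(cf),
    stage1_shared_slope = if (is.null(cal$shared_slope)) {
      "skipped: no field sweeps supplied; softening slope taken as given"
    } else list(
      d2pdd2 = cal$shared_slope$d2pdd2,
      sigma2_d2pdd2 = cal$shared_slope$sigma2_d2pdd2,
      E_HB = as.list(cal$shared_slope$E_HB),
      sigma2_E_HB = as.list(stats::setNames(cal$shared_slope$sigma2_E_HB,
                                            names(cal$shared_slope$E_HB))),
      reduced_chi2 = cal$shared_slope$reduced_chi2,
      covariance = cal$shared_slope$covariance
    ),
    stage2_york = list(
      slope = cal$york$slope, intercept = cal$york$intercept,
      sigma2_slope = cal$york$sigma2_slope,
      sigma2_intercept = cal$york$sigma2_intercept,
      reduced_chi2 = cal$york$reduced_chi2, n = cal$york$n
    ),
    coefficients = list(k0 = cf$k0, d0 = cf$d0, p0 = cf$p0, dpdd = cf$dpdd,
                        d2pdd2 = cf$d2pdd2, sigma2 = as.list(cf$sigma2))
  )
  jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, na = "null",
                   matrix = "rowmajor")
}

# read a dielectric system definition from JSON or YAML
.read_system_definition <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML definitions need the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Dielectric report for a system definition
#'
#' Evaluates a dielectric-system definition (a list, or path to a JSON/YAML
#' file).  Two definition types are understood:
#' \describe{
#'   \item{confined}{`dipoles`: records with `label`, `theta_deg`, one of
#'     `E_HB_V_per_nm` or `d_angstrom`, and `N_m3`; summed per the confined
#'     relation.  Optional `series`: `total_epsilon` and `fraction_water`
#'     to also decompose the remaining layer.}
#'   \item{liquid}{`G_k`, `temperature_K`, `N_m3`, optional `E_V_per_nm`;
#'     Langevin-Debye with the model dipole and polarizability.}
#' }
#' An empty `dipoles` list is vacuum and reports \eqn{\epsilon_r = 1}.
#'
#' @param definition List or file path.
#' @param coeffs [hb_coefficients()].
#' @return JSON string with \eqn{\epsilon_r}, per-component contributions
#'   and provenance.
#' @export
report_dielectric <- function(definition,
                              coeffs = default_coefficients("main_text")) {
  if (is.character(definition))
    definition <- .read_system_definition(definition)
  type <- definition$type %||% "confined"
  if (type == "liquid") {
    lw <- liquid_water_params(coeffs)
    G <- definition$G_k %||% 1
    Tk <- definition$temperature_K %||% 298
    N0 <- definition$N_m3 %||% 3.35e28
    E <- (definition$E_V_per_nm %||% 0) * 1e9
    eps <- epsilon_liquid_water(lw$p, lw$alpha, N0 = N0, temperature = Tk,
                                G_k = G, E = E)
    out <- list(provenance = .provenance(coeffs), type = "liquid",
                epsilon = eps, G_k = G, temperature_K = Tk,
                p_D = lw$p / hb_constants()$debye, alpha = lw$alpha)
    return(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA))
  }
  dp <- as.data.frame(definition$dipoles %||%
                        data.frame(theta_deg = numeric(), N_m3 = numeric()))
  if (nrow(dp) == 0L) {
    comp <- data.frame(alpha_c = numeric(), number_density = numeric())
  } else {
    alpha <- if (!is.null(dp$E_HB_V_per_nm))
      polarizability_of_field(dp$E_HB_V_per_nm * 1e9, coeffs)
    else if (!is.null(dp$d_angstrom))
      polarizability_of_length(dp$d_angstrom * 1e-10, coeffs)
    else stop("each dipole needs E_HB_V_per_nm or d_angstrom")
    comp <- data.frame(
      label = dp$label %||% as.character(seq_len(nrow(dp))),
      alpha = alpha,
      alpha_c = effective_polarizability(alpha, dp$theta_deg),
      number_density = dp$N_m3
    )
  }
  eps <- epsilon_confined(comp)
  out <- list(provenance = .provenance(coeffs), type = "confined",
              epsilon = eps, components = comp)
  if (!is.null(definition$series)) {
    out$series <- list(
      total_epsilon = definition$series$total_epsilon,
      fraction_water = definition$series$fraction_water,
      epsilon_other_layer = series_decompose(
        definition$series$total_epsilon,
        definition$series$fraction_water, eps))
  }
  jsonlite::toJSON(out, dataframe = "rows", auto_unbox = TRUE, digits = NA)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
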