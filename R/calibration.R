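#' Construct a field-sweep dataset
#'
#' One species' stretching peak position versus externally applied field, as
#' measured on a single sample: the raw material of the shared-slope
#' calibration.
#'
#' @param species Species label (e.g. `"O-H_A"`, `"O-H_B"`).
#' @param theta_deg Angle between the dipole and the field axis, degrees.
#' @param E_ext Applied fields, V m\eqn{^{-1}} (distinct values, >= 2).
#' @param wavenumber Peak positions, cm\eqn{^{-1}} (same length).
#' @param sigma_wavenumber 1-sigma peak-position errors, cm\eqn{^{-1}}
#'   (scalar or vector; 0 = noiseless).
#' @param temperature_K Acquisition temperature (metadata).
#' @param orientation_sign +1 or -1 when the dipole orientation relative to
#'   the field axis is known; `NA` (default) lets the fit decide from the
#'   sign of the raw slope.
#' @param dataset Dataset label (one label per sample/temperature).
#' @return A data frame of class `"field_sweep"` with metadata attributes.
#' @export
field_sweep <- function(species, theta_deg, E_ext, wavenumber,
                        sigma_wavenumber = 0, temperature_K = NA_real_,
                        orientation_sign = NA_real_, dataset = species) {
  stopifnot(length(E_ext) >= 2L, length(wavenumber) == length(E_ext))
  if (anyDuplicated(E_ext)) stop("E_ext values must be distinct")
  if (!is.na(orientation_sign) && !orientation_sign %in% c(-1, 1))
    stop("orientation_sign must be +1, -1 or NA")
  ds <- data.frame(
    species = species, theta_deg = theta_deg, temperature_K = temperature_K,
    E_ext = E_ext, wavenumber = wavenumber,
    sigma_wavenumber = rep_len(sigma_wavenumber, length(E_ext)),
    dataset = dataset
  )
  attr(ds, "orientation_sign") <- orientation_sign
  class(ds) <- c("field_sweep", "data.frame")
  ds
}

#' Generate a synthetic field sweep
#'
#' Draws peak positions from the spring-softening model
#' \eqn{k = k_0 - p''\,(E_{HB} + s\,E_{ext}\cos\vartheta)} (s = dipole
#' orientation sign), maps them to wavenumbers and adds Gaussian peak noise.
#' Deterministic for a fixed seed; the global RNG stream is untouched.
#'
#' The defaults emulate the calibration experiment: seven field points
#' across \eqn{\pm 0.5} V nm\eqn{^{-1}} and 1 cm\eqn{^{-1}} peak-position
#' noise at 80 K.
#'
#' @param E_HB True local field, V m\eqn{^{-1}}.
#' @param theta_deg Dipole angle to the field axis, degrees.
#' @param d2pdd2 True spring-softening slope \eqn{\partial^2 p/\partial
#'   d^2}, C m\eqn{^{-1}}.
#' @param E_ext Field grid, V m\eqn{^{-1}}.
#' @param sigma_wavenumber Gaussian 1-sigma peak noise, cm\eqn{^{-1}}.
#' @param k0 Free force constant; default derived from the free-molecule
#'   wavenumber.
#' @param masses [oscillator_masses()].
#' @param orientation_sign +1 or -1 true dipole orientation.
#' @param declare_orientation Record the true sign on the dataset (otherwise
#'   the fit must infer it from the slope).
#' @param seed Integer seed (required when `sigma_wavenumber > 0`).
#' @inheritParams field_sweep
#' @return A [field_sweep()] object.
#' @export
generate_field_sweep <- function(E_HB, theta_deg, d2pdd2 = 2.23e-8,
                                 E_ext = seq(-0.5e9, 0.5e9, length.out = 7),
                                 sigma_wavenumber = 1, k0 = NULL,
                                 masses = oscillator_masses(),
                                 orientation_sign = 1,
                                 declare_orientation = FALSE,
                                 species = "O-H", temperature_K = 80,
                                 dataset = species, seed = NULL) {
  if (is.null(k0)) k0 <- wavenumber_to_force_constant(3706.491, masses)
  ct <- cos(theta_deg * pi / 180)
  k <- k0 - d2pdd2 * (E_HB + orientation_sign * E_ext * ct)
  if (any(k <= 0)) stop("field grid leaves the valid domain (k <= 0)")
  nu <- force_constant_to_wavenumber(k, masses)
  if (sigma_wavenumber > 0) {
    if (is.null(seed)) stop("a seed is required for noisy sweeps")
    nu <- nu + .with_seed(seed, stats::rnorm(length(nu), 0, sigma_wavenumber))
  }
  field_sweep(species = species, theta_deg = theta_deg, E_ext = E_ext,
              wavenumber = nu, sigma_wavenumber = sigma_wavenumber,
              temperature_K = temperature_K,
              orientation_sign = if (declare_orientation) orientation_sign
                                 else NA_real_,
              dataset = dataset)
}

# per-dataset orientation: flip datasets whose raw k-vs-field slope is
# positive so every dataset red-shifts along its field axis.  The flip is an
# involution (negating the field axis twice restores the data) and leaves
# |slope| unchanged.
.sweep_orientation <- function(ds) {
  os <- attr(ds, "orientation_sign")
  if (!is.null(os) && !is.na(os)) return(os)
  k <- wavenumber_to_force_constant(ds$wavenumber)
  x <- ds$E_ext * cos(ds$theta_deg[1L] * pi / 180)
  # slope and its standard error by hand: avoids summary.lm chatter on
  # noiseless (perfect-fit) datasets
  sxx <- sum((x - mean(x))^2)
  sl <- sum((x - mean(x)) * (k - mean(k))) / sxx
  rss <- sum((k - mean(k) - sl * (x - mean(x)))^2)
  se <- if (length(x) > 2L) sqrt(rss / (length(x) - 2L) / sxx) else Inf
  if (se > 0 && abs(sl) / se < 2)
    stop("dataset '", ds$dataset[1L], "': slope sign indeterminate ",
         "(flat within noise); set orientation_sign explicitly")
  if (se == 0 && sl == 0)
    stop("dataset '", ds$dataset[1L], "': exactly flat sweep, ",
         "orientation cannot be inferred")
  if (sl > 0) -1 else 1
}

#' Global shared-slope fit of force constant versus field
#'
#' Fits all field-sweep datasets jointly to
#' \eqn{k = k_0 - p''\,(E_{HB}^{(s)} + E_{ext}\cos\vartheta)} with three free
#' parameters for a two-species experiment: one shared softening slope
#' \eqn{p'' = \partial^2 p/\partial d^2} and one local field
#' \eqn{E_{HB}} per species.  Wavenumbers are converted to force constants,
#' each dataset's field axis is projected by \eqn{\cos\vartheta}, and
#' datasets whose raw slope is positive (dipole anti-aligned with the field
#' axis) are flipped horizontally before the joint fit.
#'
#' The fit is a weighted linear least-squares problem (weights
#' \eqn{1/\sigma_k^2} when peak errors are supplied, unit weights
#' otherwise); uncertainties on the local fields follow from the coefficient
#' covariance by the delta method.  Quoted uncertainties are 2-sigma.
#'
#' @param datasets A [field_sweep()] or list of them.
#' @param k0 Free force constant pinned during the fit (not a free
#'   parameter); default from the free-molecule wavenumber.
#' @param masses [oscillator_masses()].
#' @return Object of class `"shared_slope_fit"`: list with elements
#'   `d2pdd2`, `sigma2_d2pdd2`, `E_HB` (named per species),
#'   `sigma2_E_HB`, `covariance` (1-sigma, slope + species fields),
#'   `reduced_chi2` (NA for unweighted fits), `orientation` (per dataset),
#'   `n_points`, and the underlying `lm` fit.
#' @export
fit_shared_slope <- function(datasets, k0 = NULL,
                             masses = oscillator_masses()) {
  if (inherits(datasets, "field_sweep")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1L,
            all(vapply(datasets, inherits, logical(1), "field_sweep")))
  if (is.null(k0)) k0 <- wavenumber_to_force_constant(3706.491, masses)

  orient <- vapply(datasets, .sweep_orientation, numeric(1))
  names(orient) <- vapply(datasets, function(d) d$dataset[1L], character(1))
  stk <- do.call(rbind, lapply(seq_along(datasets), function(i) {
    d <- datasets[[i]]
    k <- wavenumber_to_force_constant(d$wavenumber, masses)
    if (any(k > k0))
      stop("dataset '", d$dataset[1L], "' contains blue-shifted points")
    data.frame(
      species = d$species,
      x = orient[i] * d$E_ext * cos(d$theta_deg * pi / 180),
      k = k,
      sigma_k = ifelse(d$sigma_wavenumber > 0,
                       2 * k * d$sigma_wavenumber / d$wavenumber, 0)
    )
  }))
  weighted <- all(stk$sigma_k > 0)
  stk$species <- factor(stk$species)
  # explicit design matrix (per-species intercept + shared slope); built by
  # hand so a single-species fit works identically to the joint one
  lv <- levels(stk$species)
  xsc <- max(abs(stk$x))            # balance the design matrix columns
  if (xsc == 0) xsc <- 1
  X <- cbind(vapply(lv, function(s) as.numeric(stk$species == s),
                    numeric(nrow(stk))),
             x = stk$x / xsc)
  colnames(X) <- c(paste0("species", lv), "x")
  w <- if (weighted) 1 / stk$sigma_k^2 else rep(1, nrow(stk))
  fit <- stats::lm.wfit(X, stk$k, w)
  n <- nrow(X); npar <- ncol(X)
  if (n <= npar) stop("not enough points for ", npar, " parameters")
  s2 <- sum(w * fit$residuals^2) / (n - npar)
  Rm <- qr.R(qr(X * sqrt(w)))
  V <- s2 * chol2inv(Rm)
  dimnames(V) <- list(colnames(X), colnames(X))
  cf <- fit$coefficients
  # undo the column scaling so slope and covariance are in SI units
  cf[["x"]] <- cf[["x"]] / xsc
  V["x", ] <- V["x", ] / xsc
  V[, "x"] <- V[, "x"] / xsc
  slope <- cf[["x"]]
  if (slope >= 0)
    stop("joint slope is non-negative after orientation flips; ",
         "data do not red-shift with field")
  c2 <- -slope
  sp <- levels(stk$species)
  icpt <- cf[paste0("species", sp)]
  E <- (k0 - icpt) / c2
  names(E) <- sp

  # delta method on E_s = (k0 - a_s)/c2 with c2 = -slope
  var_E <- numeric(length(sp))
  cov_out <- matrix(0, length(sp) + 1L, length(sp) + 1L,
                    dimnames = list(c("d2pdd2", sp), c("d2pdd2", sp)))
  cov_out[1L, 1L] <- V["x", "x"]
  for (i in seq_along(sp)) {
    a <- paste0("species", sp[i])
    g <- c(-1 / c2, -E[i] / c2)           # d E / d(a_s, c2); c2 = -slope
    Vi <- matrix(c(V[a, a], -V[a, "x"], -V[a, "x"], V["x", "x"]), 2L)
    var_E[i] <- drop(t(g) %*% Vi %*% g)
    cov_out[1L, i + 1L] <- cov_out[i + 1L, 1L] <-
      g[1] * (-V[a, "x"]) + g[2] * V["x", "x"]    # cov(c2, E_s); c2=-slope
  }
  for (i in seq_along(sp)) cov_out[i + 1L, i + 1L] <- var_E[i]

  red_chi2 <- if (weighted) {
    sum((fit$residuals / stk$sigma_k)^2) / (n - npar)
  } else NA_real_

  out <- list(
    d2pdd2 = c2,
    sigma2_d2pdd2 = 2 * sqrt(V["x", "x"]),
    E_HB = E,
    sigma2_E_HB = 2 * sqrt(var_E),
    covariance = cov_out,
    reduced_chi2 = red_chi2,
    orientation = orient,
    n_points = nrow(stk),
    k0 = k0,
    fit = fit
  )
  class(out) <- "shared_slope_fit"
  out
}

#' @export
coef.shared_slope_fit <- function(object, ...) {
  c(d2pdd2 = object$d2pdd2,
    stats::setNames(object$E_HB, paste0("E_HB.", names(object$E_HB))))
}

#' @export
print.shared_slope_fit <- function(x, ...) {
  cat("Shared-slope calibration fit (k vs field)\n")
  cat(sprintf("  d2p/dd2 = %.4g +/- %.2g C/m (2s)\n",
              x$d2pdd2, x$sigma2_d2pdd2))
  for (i in seq_along(x$E_HB))
    cat(sprintf("  E_HB[%s] = %.4g +/- %.2g V/m (2s)\n",
                names(x$E_HB)[i], x$E_HB[i], x$sigma2_E_HB[i]))
  cat(sprintf("  n = %d points, %d dataset(s); reduced chi2 = %s\n",
              x$n_points, length(x$orientation),
              ifelse(is.na(x$reduced_chi2), "NA (unweighted)",
                     sprintf("%.3f", x$reduced_chi2))))
  invisible(x)
}

#' @export
summary.shared_slope_fit <- function(object, ...) {
  print(object)
  cat("  orientation signs:",
      paste(sprintf("%s:%+d", names(object$orientation),
                    as.integer(object$orientation)), collapse = ", "), "\n")
  invisible(object)
}

#' York errors-in-variables straight-line fit
#'
#' Iteratively reweighted least squares for a straight line when both axes
#' carry errors (York's unified equations, allowing per-point x-y error
#' correlation).  Each point gets weight
#' \eqn{W_i = (\sigma_{y,i}^2 + b^2\sigma_{x,i}^2 -
#' 2 b r_i \sigma_{x,i}\sigma_{y,i})^{-1}}; iteration stops when successive
#' slopes agree to `tol` (relative).  Points with \eqn{\sigma_x = 0} are
#' handled exactly (they reduce to y-weighted least squares), so the fit
#' degrades gracefully to ordinary least squares as x-errors vanish.
#'
#' When `scale_errors = TRUE` (default) the parameter standard errors are
#' multiplied by \eqn{\sqrt{\chi^2_\nu}}, the usual goodness-of-fit
#' inflation when the per-point errors are taken at face value; set `FALSE`
#' for the bare York errors.
#'
#' @param x,y Observed values.
#' @param sx,sy 1-sigma errors on x and y (non-negative; `sy` positive).
#' @param r Per-point x-y error correlation (default 0).
#' @param tol Relative slope convergence tolerance.
#' @param max_iter Maximum iterations; non-convergence raises a condition
#'   carrying the last iterate.
#' @param scale_errors Inflate standard errors by \eqn{\sqrt{\chi^2_\nu}}.
#' @return Object of class `"york_fit"`: `slope`, `intercept`, `se_slope`,
#'   `se_intercept` (1-sigma), `sigma2_slope`, `sigma2_intercept`
#'   (2-sigma), `covariance` (2x2, intercept first), `reduced_chi2`,
#'   `n`, `iterations`.
#' @references York, Evensen, Lopez Martinez & De Basabe Delgado (2004),
#'   Am. J. Phys. 72, 367: unified equations for the slope, intercept and
#'   standard errors of the best straight line.
#' @export
fit_york <- function(x, y, sx, sy, r = 0, tol = 1e-12, max_iter = 100L,
                     scale_errors = TRUE) {
  n <- length(x)
  stopifnot(n >= 3L, length(y) == n, length(sx) == n || length(sx) == 1L,
            length(sy) == n || length(sy) == 1L)
  sx <- rep_len(sx, n); sy <- rep_len(sy, n); r <- rep_len(r, n)
  if (any(sy <= 0)) stop("sy must be positive")
  if (any(sx < 0)) stop("sx must be non-negative")

  b <- stats::coef(stats::lm(y ~ x))[[2L]]
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    W <- 1 / (sy^2 + b^2 * sx^2 - 2 * b * r * sx * sy)
    Xb <- sum(W * x) / sum(W)
    Yb <- sum(W * y) / sum(W)
    U <- x - Xb; V <- y - Yb
    beta <- W * (U * sy^2 + b * V * sx^2 - (b * U + V) * r * sx * sy)
    b_new <- sum(W * beta * V) / sum(W * beta * U)
    if (abs(b_new - b) <= tol * abs(b_new)) {
      b <- b_new; converged <- TRUE; break
    }
    b <- b_new
  }
  if (!converged)
    stop(errorCondition(
      sprintf("York fit did not converge in %d iterations (last slope %.6g)",
              max_iter, b),
      last_slope = b, iterations = iter,
      class = "york_convergence_error"))

  W <- 1 / (sy^2 + b^2 * sx^2 - 2 * b * r * sx * sy)
  Xb <- sum(W * x) / sum(W); Yb <- sum(W * y) / sum(W)
  U <- x - Xb; V <- y - Yb
  beta <- W * (U * sy^2 + b * V * sx^2 - (b * U + V) * r * sx * sy)
  a <- Yb - b * Xb
  x_adj <- Xb + beta
  xbar <- sum(W * x_adj) / sum(W)
  u <- x_adj - xbar
  var_b <- 1 / sum(W * u^2)
  var_a <- 1 / sum(W) + xbar^2 * var_b
  cov_ab <- -xbar * var_b
  chi2 <- sum(W * (y - b * x - a)^2)
  red_chi2 <- if (n > 2L) chi2 / (n - 2L) else NA_real_
  scl <- if (scale_errors && is.finite(red_chi2)) red_chi2 else 1
  cv <- matrix(c(var_a, cov_ab, cov_ab, var_b) * scl, 2L,
               dimnames = list(c("intercept", "slope"),
                               c("intercept", "slope")))
  out <- list(
    slope = b, intercept = a,
    se_slope = sqrt(cv["slope", "slope"]),
    se_intercept = sqrt(cv["intercept", "intercept"]),
    sigma2_slope = 2 * sqrt(cv["slope", "slope"]),
    sigma2_intercept = 2 * sqrt(cv["intercept", "intercept"]),
    covariance = cv, reduced_chi2 = red_chi2, n = n,
    iterations = iter, scale_errors = scale_errors,
    data = data.frame(x = x, y = y, sx = sx, sy = sy)
  )
  class(out) <- "york_fit"
  out
}

#' @export
coef.york_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
print.york_fit <- function(x, ...) {
  cat("York errors-in-variables straight-line fit\n")
  cat(sprintf("  slope     = %.6g +/- %.3g (2s)\n", x$slope, x$sigma2_slope))
  cat(sprintf("  intercept = %.6g +/- %.3g (2s)\n",
              x$intercept, x$sigma2_intercept))
  cat(sprintf("  n = %d, reduced chi2 = %.3f, %d iteration(s)%s\n",
              x$n, x$reduced_chi2, x$iterations,
              if (x$scale_errors) ", errors chi2-scaled" else ""))
  invisible(x)
}

#' @export
summary.york_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
predict.york_fit <- function(object, newdata, ...) {
  xx <- if (missing(newdata)) object$data$x else newdata
  object$intercept + object$slope * xx
}

#' Build the bond-length versus field/force-constant table
#'
#' Converts each reference bond's stretching wavenumber into a force
#' constant, derives its local field \eqn{E = (k_0 - k)/p''} from the
#' spring-softening slope, and forms the regressor \eqn{x = E/k} whose
#' straight-line relation to the bond length carries
#' \eqn{\partial p/\partial d} (slope) and \eqn{d_0} (intercept).
#'
#' The x-error is first-order propagation of the softening-slope uncertainty
#' only, \eqn{\sigma_x = |x|\,\sigma_{p''}/p''}, matching how the error bars
#' of this relation are constructed; wavenumber-noise contributions can be
#' added via `sigma_wavenumber` but are off by default.  `k0` defaults to
#' the force constant of the free-molecule wavenumber so the free bond sits
#' exactly at \eqn{x = 0}.
#'
#' @param systems A reference table from [load_reference_table()] (or any
#'   data frame with `system`, `bond_label`, `wavenumber_cm1`,
#'   `d_corrected_A`, `sigma_d_A`).
#' @param d2pdd2 Spring-softening slope, C m\eqn{^{-1}}.
#' @param sigma_d2pdd2 Its uncertainty as quoted (propagated into
#'   \eqn{\sigma_x} at face value).
#' @param k0 Free force constant; default from the free-molecule wavenumber.
#' @param masses [oscillator_masses()].
#' @param default_sigma_d Fallback bond-length error (Angstrom) for rows
#'   with missing \eqn{\sigma_d}; used with a warning.
#' @param sigma_wavenumber Optional 1-sigma wavenumber noise (cm\eqn{^{-1}})
#'   folded into \eqn{\sigma_x}.
#' @return Data frame of class `"length_field_table"`: one row per bond with
#'   `k` (N/m), `E` (V/m), `x` (m V N\eqn{^{-1}}), `sigma_x`, `d`,
#'   `sigma_d` (m).
#' @export
build_length_field_table <- function(systems = load_reference_table(),
                                     d2pdd2 = 2.23e-8,
                                     sigma_d2pdd2 = 0.26e-8,
                                     k0 = NULL,
                                     masses = oscillator_masses(),
                                     default_sigma_d = NULL,
                                     sigma_wavenumber = NULL) {
  stopifnot(all(c("system", "bond_label", "wavenumber_cm1", "d_corrected_A",
                  "sigma_d_A") %in% names(systems)))
  if (is.null(k0)) k0 <- wavenumber_to_force_constant(3706.491, masses)
  sd_A <- systems$sigma_d_A
  if (anyNA(sd_A)) {
    if (is.null(default_sigma_d))
      stop("rows without sigma_d: ",
           paste(systems$system[is.na(sd_A)], collapse = ", "),
           "; supply default_sigma_d to proceed")
    warning(sum(is.na(sd_A)), " row(s) missing sigma_d; using default ",
            default_sigma_d, " Angstrom")
    sd_A[is.na(sd_A)] <- default_sigma_d
  }
  k <- wavenumber_to_force_constant(systems$wavenumber_cm1, masses)
  if (any(k > k0))
    stop("blue-shifted reference rows: ",
         paste(systems$system[k > k0], collapse = ", "))
  E <- (k0 - k) / d2pdd2
  x <- E / k
  sigma_x <- abs(x) * sigma_d2pdd2 / d2pdd2
  if (!is.null(sigma_wavenumber)) {
    sk <- 2 * k * sigma_wavenumber / systems$wavenumber_cm1
    sigma_x <- sqrt(sigma_x^2 + (k0 / (d2pdd2 * k^2) * sk)^2)
  }
  out <- data.frame(
    system = systems$system, bond_label = systems$bond_label,
    wavenumber_cm1 = systems$wavenumber_cm1,
    k = k, E = E, x = x, sigma_x = sigma_x,
    d = systems$d_corrected_A * 1e-10, sigma_d = sd_A * 1e-10
  )
  class(out) <- c("length_field_table", "data.frame")
  attr(out, "d2pdd2") <- d2pdd2
  attr(out, "k0") <- k0
  out
}

#' End-to-end calibration
#'
#' Orchestrates the two calibration stages: the shared-slope fit of field
#' sweeps (stage 1, yields \eqn{\partial^2 p/\partial d^2} and the local
#' fields) and the York errors-in-variables fit of the reference
#' bond-length table (stage 2, yields \eqn{\partial p/\partial d} and
#' \eqn{d_0}).  With no sweeps, stage 2 runs alone using the supplied
#' softening slope (degraded mode).
#'
#' @param sweeps Optional list of [field_sweep()] datasets.
#' @param reference Reference system table (see [load_reference_table()]).
#' @param d2pdd2,sigma_d2pdd2 Softening slope (and uncertainty) used for
#'   stage 2 when no sweeps are given; ignored when sweeps are fitted.
#' @param p0 Free bond dipole (C m) adopted into the coefficient set.
#' @param masses [oscillator_masses()].
#' @return List of class `"hb_calibration"` with elements `shared_slope`
#'   (NULL in degraded mode), `york`, `table` and `coefficients` (an
#'   [hb_coefficients()] object assembled from the fits, carrying the
#'   slope-intercept covariance of the York stage).
#' @export
calibrate <- function(sweeps = NULL, reference = load_reference_table(),
                      d2pdd2 = 2.23e-8, sigma_d2pdd2 = 0.26e-8,
                      p0 = 1.514 * hb_constants()$debye,
                      masses = oscillator_masses()) {
  ss <- NULL
  if (!is.null(sweeps)) {
    ss <- fit_shared_slope(sweeps, masses = masses)
    d2pdd2 <- ss$d2pdd2
    sigma_d2pdd2 <- ss$sigma2_d2pdd2
  }
  tab <- build_length_field_table(reference, d2pdd2 = d2pdd2,
                                  sigma_d2pdd2 = sigma_d2pdd2,
                                  masses = masses)
  yk <- fit_york(tab$x, tab$d, tab$sigma_x, tab$sigma_d)
  cv <- matrix(0, 2L, 2L, dimnames = list(c("d0", "dpdd"), c("d0", "dpdd")))
  cv["d0", "d0"] <- yk$covariance["intercept", "intercept"]
  cv["dpdd", "dpdd"] <- yk$covariance["slope", "slope"]
  cv["d0", "dpdd"] <- cv["dpdd", "d0"] <- yk$covariance["intercept", "slope"]
  coeffs <- hb_coefficients(
    k0 = attr(tab, "k0"), d0 = yk$intercept, p0 = p0,
    dpdd = yk$slope, d2pdd2 = d2pdd2,
    sigma2 = c(d0 = yk$sigma2_intercept, dpdd = yk$sigma2_slope,
               d2pdd2 = sigma_d2pdd2, k0 = 0.3,
               p0 = 0.0004 * hb_constants()$debye),
    covariance = cv,
    label = if (is.null(ss)) "calibrated (reference table only)"
            else "calibrated (sweeps + reference table)"
  )
  out <- list(shared_slope = ss, york = yk, table = tab,
              coefficients = coeffs)
  class(out) <- "hb_calibration"
  out
}

#' @export
print.hb_calibration <- function(x, ...) {
  cat("Two-stage hydrogen-bond model calibration\n")
  if (is.null(x$shared_slope)) {
    cat("  stage 1 (shared slope): skipped - softening slope supplied\n")
  } else {
    print(x$shared_slope)
  }
  print(x$york)
  print(x$coefficients)
  invisible(x)
}

#' Read / write field-sweep CSV files
#'
#' CSV layout: columns `species`, `theta_deg`, `temperature_K`,
#' `E_ext_V_per_nm`, `wavenumber_cm1`, `sigma_cm1` and optional `dataset`
#' (defaults to species x temperature).
#'
#' @param path CSV path.
#' @return `read_field_sweeps`: list of [field_sweep()] objects (one per
#'   dataset label).  `write_field_sweeps` returns `path` invisibly.
#' @export
read_field_sweeps <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "theta_deg", "temperature_K", "E_ext_V_per_nm",
            "wavenumber_cm1", "sigma_cm1")
  if (!all(need %in% names(df)))
    stop("field-sweep CSV must have columns: ", paste(need, collapse = ", "))
  if (is.null(df$dataset))
    df$dataset <- paste(df$species, df$temperature_K, sep = "@")
  lapply(split(df, df$dataset), function(d)
    field_sweep(species = d$species[1L], theta_deg = d$theta_deg[1L],
                E_ext = d$E_ext_V_per_nm * 1e9, wavenumber = d$wavenumber_cm1,
                sigma_wavenumber = d$sigma_cm1,
                temperature_K = d$temperature_K[1L],
                dataset = d$dataset[1L]))
}

#' @rdname read_field_sweeps
#' @param sweeps List of [field_sweep()] objects.
#' @export
write_field_sweeps <- function(sweeps, path) {
  if (inherits(sweeps, "field_sweep")) sweeps <- list(sweeps)
  df <- do.call(rbind, lapply(sweeps, function(d)
    data.frame(species = d$species, theta_deg = d$theta_deg,
               temperature_K = d$temperature_K,
               E_ext_V_per_nm = d$E_ext / 1e9,
               wavenumber_cm1 = d$wavenumber, sigma_cm1 = d$sigma_wavenumber,
               dataset = d$dataset)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
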