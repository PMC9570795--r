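# Energy-dependent interaction coefficients for the bundled materials and
# the exponential-fit extraction of tissue coefficients at the K-line
# energies.  All linear coefficients are per cm; energies in keV.

.kf_cache <- new.env(parent = emptyenv())

# densities (g/cm^3) of the bundled materials, matching data-raw generation
.kf_densities <- c(
  fat = 0.95, fibrous = 1.02, tumor = 1.044, iodine = 4.93,
  silicon = 2.33, aluminium = 2.699, gadolinium = 7.90, air = 1.20479e-3
)

#' Construct an attenuation curve
#'
#' An attenuation curve holds a material's linear attenuation coefficient on
#' an ascending energy grid, optionally with the photoelectric component and
#' (for air) the mass energy-absorption coefficient.  Interpolation between
#' grid nodes is log-linear in the coefficient (see [mu_at()]).
#'
#' @param material_name Label for the material.
#' @param energies Ascending energy grid, keV.
#' @param mu_total Linear attenuation coefficient, per cm, at each grid energy.
#' @param mu_pe Optional photoelectric linear coefficient, per cm.
#' @param mu_en_rho Optional mass energy-absorption coefficient, cm^2/g.
#' @param density Optional mass density, g/cm^3; required by callers that
#'   need mass coefficients (e.g. the contrast-agent loading of
#'   [iodine_equivalent_mu()]).
#' @return An object of class `attenuation_curve`.
#' @export
attenuation_curve <- function(material_name, energies, mu_total,
                              mu_pe = NULL, mu_en_rho = NULL, density = NULL) {
  stopifnot(is.character(material_name), length(material_name) == 1L)
  energies <- as.numeric(energies)
  mu_total <- as.numeric(mu_total)
  if (length(energies) < 2L || any(diff(energies) <= 0)) {
    stop("energies must be a strictly ascending grid of length >= 2")
  }
  if (length(mu_total) != length(energies) || any(!is.finite(mu_total)) ||
      any(mu_total <= 0)) {
    stop("mu_total must be strictly positive and match the energy grid")
  }
  if (!is.null(mu_pe)) {
    mu_pe <- as.numeric(mu_pe)
    if (length(mu_pe) != length(energies) || any(mu_pe <= 0)) {
      stop("mu_pe must be strictly positive and match the energy grid")
    }
    if (any(mu_pe > mu_total * (1 + 1e-9))) {
      stop("mu_pe must not exceed mu_total")
    }
  }
  if (!is.null(mu_en_rho)) {
    mu_en_rho <- as.numeric(mu_en_rho)
    if (length(mu_en_rho) != length(energies) || any(mu_en_rho <= 0)) {
      stop("mu_en_rho must be strictly positive and match the energy grid")
    }
  }
  structure(
    list(material_name = material_name, energies = energies,
         mu_total = mu_total, mu_pe = mu_pe, mu_en_rho = mu_en_rho,
         density = density),
    class = "attenuation_curve"
  )
}

#' @export
print.attenuation_curve <- function(x, ...) {
  cat(sprintf("<attenuation_curve> %s: %d nodes, %.3f-%.3f keV%s%s\n",
              x$material_name, length(x$energies),
              min(x$energies), max(x$energies),
              if (!is.null(x$mu_pe)) ", photoelectric" else "",
              if (!is.null(x$mu_en_rho)) ", mu_en/rho" else ""))
  invisible(x)
}

#' Read an attenuation table from CSV
#'
#' Expects the header `energy_keV,mu_total_per_cm[,mu_pe_per_cm][,mu_en_rho_cm2_g]`.
#'
#' @param path CSV file path.
#' @param material_name Material label; defaults to the file name.
#' @param density Optional density, g/cm^3.
#' @return An `attenuation_curve`.
#' @export
read_attenuation_csv <- function(path, material_name = NULL, density = NULL) {
  if (is.null(material_name)) {
    material_name <- sub("\\.csv$", "", basename(path))
  }
  d <- utils::read.csv(path)
  if (!all(c("energy_keV", "mu_total_per_cm") %in% names(d))) {
    stop("attenuation CSV needs columns energy_keV, mu_total_per_cm: ", path)
  }
  attenuation_curve(
    material_name, d$energy_keV, d$mu_total_per_cm,
    mu_pe = if ("mu_pe_per_cm" %in% names(d)) d$mu_pe_per_cm,
    mu_en_rho = if ("mu_en_rho_cm2_g" %in% names(d)) d$mu_en_rho_cm2_g,
    density = density
  )
}

#' Look up a bundled material
#'
#' Loads (and caches) one of the attenuation tables shipped with the package:
#' `fat`, `fibrous`, `tumor`, `iodine`, `silicon`, `aluminium`, `gadolinium`,
#' `air`.  Tissue tables carry total coefficients; iodine and silicon also
#' carry the photoelectric component; air carries the mass energy-absorption
#' coefficient used for air-kerma evaluation.
#'
#' @param name Material name.
#' @return An `attenuation_curve` with density attached.
#' @export
kf_material <- function(name) {
  name <- match.arg(name, names(.kf_densities))
  key <- paste0("material_", name)
  if (!is.null(.kf_cache[[key]])) {
    return(.kf_cache[[key]])
  }
  path <- system.file("extdata", "attenuation", paste0(name, ".csv"),
                      package = "kfluoro", mustWork = TRUE)
  curve <- read_attenuation_csv(path, name, density = .kf_densities[[name]])
  .kf_cache[[key]] <- curve
  curve
}

#' Linear attenuation coefficient at given energies
#'
#' Log-linear interpolation (linear in energy, linear in `log(mu)`) between
#' grid nodes; exact at the nodes.  Queries outside the tabulated range are
#' an error: extrapolation below a tissue grid is only supported through
#' [fit_exponential()].
#'
#' @param curve An `attenuation_curve`.
#' @param energy Energies, keV (vectorised).
#' @param component `"total"` (default) or `"photoelectric"`.
#' @return Linear attenuation coefficients, per cm.
#' @export
mu_at <- function(curve, energy, component = c("total", "photoelectric")) {
  stopifnot(inherits(curve, "attenuation_curve"))
  component <- match.arg(component)
  mu <- if (component == "total") curve$mu_total else curve$mu_pe
  if (is.null(mu)) {
    stop("material '", curve$material_name,
         "' has no tabulated photoelectric component")
  }
  e <- curve$energies
  bad <- !is.finite(energy) | energy < e[1L] | energy > e[length(e)]
  if (any(bad)) {
    stop(sprintf(
      "energy %.4g keV outside tabulated range [%.4g, %.4g] for material '%s'",
      energy[bad][1L], e[1L], e[length(e)], curve$material_name))
  }
  exp(stats::approx(e, log(mu), xout = energy, ties = "ordered")$y)
}

#' Mass attenuation coefficient at given energies
#'
#' @inheritParams mu_at
#' @return Mass attenuation coefficients, cm^2/g.
#' @export
mass_mu_at <- function(curve, energy, component = c("total", "photoelectric")) {
  if (is.null(curve$density)) {
    stop("material '", curve$material_name, "' has no density attached")
  }
  mu_at(curve, energy, component) / curve$density
}

#' Fit an exponential model to attenuation measurements
#'
#' Fits `mu(E) = amplitude * exp(-decay_rate * E)` by least squares in log
#' space, the standard way sparse measured tissue coefficients are carried
#' down to the fluorescence line energies that lie off the measured grid.
#'
#' @param energies Measurement energies, keV (>= 3 distinct values).
#' @param mu Measured linear attenuation coefficients, per cm (positive).
#' @return An object of class `exponential_fit` with fields `amplitude`
#'   (per cm), `decay_rate` (per keV), `fit_energy_range` and `residual`
#'   (residual standard deviation of `log(mu)`).
#' @export
fit_exponential <- function(energies, mu) {
  energies <- as.numeric(energies)
  mu <- as.numeric(mu)
  if (length(energies) < 3L || anyDuplicated(energies)) {
    stop("need at least 3 distinct energies to fit")
  }
  if (length(mu) != length(energies) || any(!is.finite(mu)) || any(mu <= 0)) {
    stop("mu must be positive and match energies")
  }
  fit <- stats::lm(log(mu) ~ energies)
  co <- stats::coef(fit)
  structure(
    list(amplitude = exp(unname(co[1L])), decay_rate = -unname(co[2L]),
         fit_energy_range = range(energies),
         residual = sqrt(mean(stats::residuals(fit)^2))),
    class = "exponential_fit"
  )
}

#' @export
print.exponential_fit <- function(x, ...) {
  cat(sprintf(
    "<exponential_fit> %.4g * exp(-%.4g E), fitted %.4g-%.4g keV, rms(log) %.3g\n",
    x$amplitude, x$decay_rate, x$fit_energy_range[1L], x$fit_energy_range[2L],
    x$residual))
  invisible(x)
}

#' Evaluate an exponential attenuation fit
#'
#' @param object An `exponential_fit`.
#' @param energy Energies, keV.
#' @param ... Unused.
#' @return Fitted linear attenuation coefficients, per cm.
#' @export
predict.exponential_fit <- function(object, energy, ...) {
  object$amplitude * exp(-object$decay_rate * as.numeric(energy))
}

#' Effective linear attenuation of the contrast-loaded layer
#'
#' The contrast layer is modelled through the iodine content alone: the
#' effective coefficient is the iodine mass attenuation times the nominal
#' agent concentration times the packing density (the fraction of the
#' nominal concentration actually present in the tissue).
#'
#' @param energy Energies, keV.
#' @param concentration Nominal contrast-agent concentration, g/cm^3
#'   (300 mg/mL = 0.300).
#' @param packing_density Fraction in (0, 1]; 0.14 for normal tissue, 0.56
#'   for tumor.
#' @param iodine Iodine `attenuation_curve` (bundled table by default).
#' @param component `"total"` or `"photoelectric"`.
#' @return Effective linear attenuation coefficients, per cm.
#' @export
iodine_equivalent_mu <- function(energy, concentration, packing_density,
                                 iodine = kf_material("iodine"),
                                 component = "total") {
  if (!is.numeric(concentration) || concentration <= 0) {
    stop("concentration must be positive")
  }
  if (!is.numeric(packing_density) || packing_density <= 0 ||
      packing_density > 1) {
    stop("packing_density must be in (0, 1]")
  }
  mass_mu_at(iodine, energy, component) * concentration * packing_density
}

#' Relative probability of photoelectric absorption
#'
#' Ratio of the photoelectric to the total linear attenuation coefficient,
#' the probability that an interaction is photoelectric rather than a
#' scattering (Rayleigh/Compton) event.
#'
#' @inheritParams mu_at
#' @return Probabilities in (0, 1].
#' @export
photoelectric_fraction <- function(curve, energy) {
  if (is.null(curve$mu_pe)) {
    stop("material '", curve$material_name,
         "' has no photoelectric component configured")
  }
  pmin(mu_at(curve, energy, "photoelectric") / mu_at(curve, energy, "total"), 1)
}

#' Iodine K-shell share of photoelectric absorption
#'
#' Probability that a photoelectric absorption in iodine creates a K-shell
#' (rather than L-shell) vacancy, from the bundled energy-indexed table.
#' Below the K-edge no K vacancy is possible and the value is 0 by contract.
#'
#' @param energy Energies, keV (vectorised).
#' @return Probabilities in \[0, 1).
#' @export
kshell_fraction <- function(energy) {
  key <- "kshell_table"
  tab <- .kf_cache[[key]]
  if (is.null(tab)) {
    path <- system.file("extdata", "attenuation", "iodine_kshell_fraction.csv",
                        package = "kfluoro", mustWork = TRUE)
    tab <- utils::read.csv(path)
    .kf_cache[[key]] <- tab
  }
  edge <- iodine_fluorescence()$k_edge
  out <- numeric(length(energy))
  above <- is.finite(energy) & energy >= edge
  if (any(above)) {
    e <- pmin(energy[above], max(tab$energy_keV))
    if (any(energy[above] > max(tab$energy_keV) + 1e-6)) {
      stop("energy above tabulated K-shell fraction range")
    }
    out[above] <- stats::approx(tab$energy_keV, tab$k_fraction, xout = e,
                                rule = 2, ties = "ordered")$y
  }
  out
}

#' Iodine fluorescence parameters
#'
#' K-edge and K-line energies, fluorescent yields and the KL relaxation
#' probability of iodine used throughout the simulation.
#'
#' @return A `fluorescence_params` list with fields `k_edge`, `e_kalpha`,
#'   `e_kbeta1` (keV), `omega_kalpha`, `omega_kbeta`, `xi_KL`.
#' @export
iodine_fluorescence <- function() {
  structure(
    list(k_edge = 33.18, e_kalpha = 28.46, e_kbeta1 = 33.29,
         omega_kalpha = 0.841, omega_kbeta = 0.900, xi_KL = 0.820),
    class = "fluorescence_params"
  )
}

#' @export
print.fluorescence_params <- function(x, ...) {
  cat(sprintf(
    "<fluorescence_params> K-edge %.2f keV; Kalpha %.2f, Kbeta1 %.2f keV; omega_Ka %.3f, omega_Kb %.3f, xi_KL %.3f\n",
    x$k_edge, x$e_kalpha, x$e_kbeta1, x$omega_kalpha, x$omega_kbeta, x$xi_KL))
  invisible(x)
}
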