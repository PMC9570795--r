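# Photon-counting detection in a silicon converter layer: an escaped
# K-photon is counted iff its sampled free path in silicon ends inside the
# converter AND the interaction is photoelectric.

#' Detector configuration
#'
#' @param thickness_um Converter thickness, micrometres (default 700).
#' @param material Converter `attenuation_curve`; bundled silicon by default.
#' @return An object of class `kf_detector`.
#' @export
detector_config <- function(thickness_um = 700,
                            material = kf_material("silicon")) {
  if (!is.numeric(thickness_um) || thickness_um <= 0) {
    stop("detector thickness must be positive")
  }
  if (is.null(material$mu_pe)) {
    stop("detector material needs a photoelectric component")
  }
  structure(
    list(thickness_cm = thickness_um * 1e-4, material = material),
    class = "kf_detector"
  )
}

#' @export
print.kf_detector <- function(x, ...) {
  cat(sprintf("<kf_detector> %s converter, %.0f um\n",
              x$material$material_name, x$thickness_cm * 1e4))
  invisible(x)
}

#' Monte Carlo photon-counting decision
#'
#' Samples the free path `-ln(R)/mu_total(E)` in the converter; the photon
#' interacts iff the path does not exceed the converter thickness, and is
#' counted iff the interaction is additionally photoelectric (probability
#' `mu_pe/mu_total`).  The sampled path is compared to the nominal
#' thickness regardless of incidence angle; `angled_paths = TRUE` compares
#' against `thickness / |cos(theta)|` instead (sensitivity analysis).
#'
#' @param energy Photon energies, keV (vectorised).
#' @param cfg A `kf_detector`.
#' @param cos_theta Optional cosine of the incidence angle per photon, used
#'   only when `angled_paths = TRUE`.
#' @param angled_paths Compare the sampled path to the slanted thickness.
#' @return Logical vector: counted or not.
#' @export
detect <- function(energy, cfg = detector_config(), cos_theta = NULL,
                   angled_paths = FALSE) {
  stopifnot(inherits(cfg, "kf_detector"))
  n <- length(energy)
  if (n == 0L) return(logical(0))
  th <- cfg$thickness_cm
  if (angled_paths) {
    if (is.null(cos_theta)) stop("angled_paths = TRUE needs cos_theta")
    th <- th / pmax(abs(cos_theta), 1e-12)
  }
  mu <- mu_at(cfg$material, energy)
  interacts <- -log(stats::runif(n)) / mu <= th
  interacts & stats::runif(n) <= photoelectric_fraction(cfg$material, energy)
}

#' Closed-form counting probability
#'
#' Companion to [detect()]: `(1 - exp(-mu_total(E) * Th)) * mu_pe(E)/mu_total(E)`.
#'
#' @param energy Photon energies, keV.
#' @param cfg A `kf_detector`.
#' @return Counting probabilities.
#' @export
detection_probability <- function(energy, cfg = detector_config()) {
  stopifnot(inherits(cfg, "kf_detector"))
  mu <- mu_at(cfg$material, energy)
  (1 - exp(-mu * cfg$thickness_cm)) * photoelectric_fraction(cfg$material, energy)
}
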