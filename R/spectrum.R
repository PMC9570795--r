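# Incident X-ray spectra: representation, generation, filtration, energy
# fluence, entrance-surface air kerma and photon-budget normalisation.

# uGy resulting from 1 photon/mm^2 of 1 keV with mu_en/rho = 1 cm^2/g:
# 100 (mm^-2 -> cm^-2) * 1.602176634e-16 (keV -> J) * 1e3 (g -> kg) * 1e6 (Gy -> uGy)
.kerma_const_uGy <- 1.602176634e-5

#' Construct a binned X-ray spectrum
#'
#' @param energies Bin-centre energies, keV, ascending with uniform width.
#' @param counts Photons per bin; interpreted as photons per mm^2 wherever
#'   air kerma is evaluated.
#' @param tube_kv Optional tube-voltage label, kV; counts must vanish above it.
#' @param filtration List of applied filters, each `list(material, thickness_cm)`.
#' @return An object of class `xray_spectrum`.
#' @export
spectrum <- function(energies, counts, tube_kv = NULL, filtration = list()) {
  energies <- as.numeric(energies)
  counts <- as.numeric(counts)
  if (length(energies) < 1L) stop("empty energy grid")
  if (length(energies) > 1L) {
    w <- diff(energies)
    if (any(w <= 0) || max(abs(w - w[1L])) > 1e-9 * w[1L]) {
      stop("energies must ascend with uniform bin width")
    }
    bin_width <- w[1L]
  } else {
    bin_width <- NA_real_
  }
  if (length(counts) != length(energies) || any(!is.finite(counts)) ||
      any(counts < 0)) {
    stop("counts must be nonnegative and match the energy grid")
  }
  if (!is.null(tube_kv) && any(counts[energies > tube_kv] > 0)) {
    stop("counts must be zero above the tube voltage")
  }
  structure(
    list(energies = energies, counts = counts, bin_width = bin_width,
         tube_kv = tube_kv, filtration = filtration),
    class = "xray_spectrum"
  )
}

#' @export
print.xray_spectrum <- function(x, ...) {
  filt <- if (length(x$filtration)) {
    paste(vapply(x$filtration, function(f) {
      sprintf("%s %.4g mm", f$material, f$thickness_cm * 10)
    }, character(1L)), collapse = " + ")
  } else "none"
  cat(sprintf(
    "<xray_spectrum> %s%d bins, %.4g-%.4g keV, total %.6g photons/mm^2, filtration: %s\n",
    if (!is.null(x$tube_kv)) sprintf("%g kV, ", x$tube_kv) else "",
    length(x$energies), min(x$energies), max(x$energies), sum(x$counts), filt))
  invisible(x)
}

#' Load a spectrum from a two-column CSV
#'
#' Expects header `energy_keV,photons_per_mm2` (any second column name is
#' accepted), energies ascending.
#'
#' @param path CSV file path.
#' @param tube_kv Optional tube-voltage label.
#' @return An `xray_spectrum`.
#' @export
load_spectrum <- function(path, tube_kv = NULL) {
  d <- utils::read.csv(path)
  if (ncol(d) < 2L) stop("spectrum CSV needs two columns: ", path)
  e <- as.numeric(d[[1L]])
  n <- as.numeric(d[[2L]])
  if (any(diff(e) <= 0)) {
    stop("non-ascending energies in ", path, " at line ",
         which(diff(e) <= 0)[1L] + 2L)
  }
  if (any(n < 0)) {
    stop("negative counts in ", path, " at line ", which(n < 0)[1L] + 1L)
  }
  spectrum(e, n, tube_kv = tube_kv)
}

#' Write a spectrum to CSV
#'
#' @param s An `xray_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "xray_spectrum"))
  utils::write.csv(
    data.frame(energy_keV = s$energies, photons_per_mm2 = s$counts),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate an unfiltered tungsten-anode spectrum
#'
#' Deterministic semi-empirical bremsstrahlung model (Kramers shape,
#' `N(E) ~ (kV - E)/E` at the exit window).  Tungsten characteristic K
#' lines require > 69.5 kV and the L lines (8.4-11.3 keV) are removed by
#' any clinically realistic filtration, so no line component is added in
#' the supported 20-60 kV range.
#'
#' @param kv Tube voltage, kV, in \[20, 60\].
#' @param bin_width Bin width, keV.
#' @param emin Lowest bin edge, keV.
#' @param exposure Total photons/mm^2 the unfiltered spectrum is scaled to.
#' @return An `xray_spectrum`.
#' @export
generate_w_spectrum <- function(kv, bin_width = 0.5, emin = 8, exposure = 1e6) {
  if (!is.numeric(kv) || length(kv) != 1L || kv < 20 || kv > 60) {
    stop("kv must be a single value in [20, 60]")
  }
  stopifnot(bin_width > 0, emin > 0, exposure >= 0)
  centers <- seq(emin + bin_width / 2, 60, by = bin_width)
  n <- pmax(kv - centers, 0) / centers
  if (sum(n) > 0) n <- n * (exposure / sum(n))
  spectrum(centers, n, tube_kv = kv)
}

#' Attenuate a spectrum by a filter
#'
#' Each bin is multiplied by `exp(-mu(E) * thickness)`; successive filters
#' commute.
#'
#' @param s An `xray_spectrum`.
#' @param material An `attenuation_curve` or the name of a bundled material.
#' @param thickness_cm Filter thickness, cm (>= 0).
#' @return The filtered `xray_spectrum`.
#' @export
apply_filtration <- function(s, material, thickness_cm) {
  stopifnot(inherits(s, "xray_spectrum"), thickness_cm >= 0)
  if (is.character(material)) material <- kf_material(material)
  live <- s$counts > 0
  counts <- s$counts
  counts[live] <- counts[live] *
    exp(-mu_at(material, s$energies[live]) * thickness_cm)
  spectrum(s$energies, counts, tube_kv = s$tube_kv,
           filtration = c(s$filtration,
                          list(list(material = material$material_name,
                                    thickness_cm = thickness_cm))))
}

#' Standard filtered tungsten spectrum
#'
#' The study beam: tungsten anode at `kv`, 1.6 mm aluminium intrinsic
#' filtration plus 0.3 mm gadolinium additional filtration.
#'
#' @inheritParams generate_w_spectrum
#' @return An `xray_spectrum`.
#' @export
standard_filtered_spectrum <- function(kv, bin_width = 0.5, emin = 8,
                                       exposure = 1e6) {
  s <- generate_w_spectrum(kv, bin_width = bin_width, emin = emin,
                           exposure = exposure)
  s <- apply_filtration(s, "aluminium", 0.16)
  apply_filtration(s, "gadolinium", 0.03)
}

#' Incident energy fluence
#'
#' Discretised integral of `N(E) * E` up to the spectrum endpoint.
#'
#' @param s An `xray_spectrum`.
#' @return Energy fluence, keV/mm^2.
#' @export
energy_fluence <- function(s) {
  stopifnot(inherits(s, "xray_spectrum"))
  sum(s$counts * s$energies)
}

#' Entrance surface air kerma
#'
#' `ESAK = c * sum N(Ei) Ei (mu_en(Ei)/rho)_air` with the fluence-to-kerma
#' constant `c = 1.602e-5` converting photons/mm^2 x keV x cm^2/g to uGy.
#'
#' @param s An `xray_spectrum` with counts in photons/mm^2.
#' @param air Air `attenuation_curve` carrying `mu_en_rho`.
#' @return Air kerma, uGy.
#' @export
esak <- function(s, air = kf_material("air")) {
  stopifnot(inherits(s, "xray_spectrum"))
  if (is.null(air$mu_en_rho)) {
    stop("air curve has no mass energy-absorption coefficient")
  }
  live <- s$counts > 0
  if (!any(live)) return(0)
  e <- s$energies[live]
  muen <- exp(stats::approx(air$energies, log(air$mu_en_rho), xout = e,
                            ties = "ordered")$y)
  if (any(is.na(muen))) {
    stop("mu_en/rho coverage does not span the spectrum energies")
  }
  .kerma_const_uGy * sum(s$counts[live] * e * muen)
}

#' Photon budget for a target air kerma
#'
#' Scales the spectrum so its entrance surface air kerma equals `target_uGy`
#' and reports the total photon count of the scaled spectrum.
#'
#' @param s An `xray_spectrum` with nonzero kerma.
#' @param target_uGy Target ESAK, uGy.
#' @param air Air `attenuation_curve`.
#' @return List with `n_photons` (integer total), `scale` and `spectrum`
#'   (the rescaled `xray_spectrum`).
#' @export
photons_for_esak <- function(s, target_uGy, air = kf_material("air")) {
  k <- esak(s, air)
  if (k <= 0) stop("spectrum has zero air kerma; cannot normalise")
  stopifnot(target_uGy >= 0)
  scale <- target_uGy / k
  scaled <- spectrum(s$energies, s$counts * scale, tube_kv = s$tube_kv,
                     filtration = s$filtration)
  list(n_photons = round(sum(scaled$counts)), scale = scale,
       spectrum = scaled)
}

#' Sample photon energies from a spectrum
#'
#' Inverse-CDF sampling over the bins (each draw lands on a bin-centre
#' energy).  Uses the current R random-number stream.
#'
#' @param s An `xray_spectrum` with nonzero total counts.
#' @param n Number of draws.
#' @return Numeric vector of `n` energies, keV.
#' @export
sample_energy <- function(s, n) {
  stopifnot(inherits(s, "xray_spectrum"), n >= 0)
  tot <- sum(s$counts)
  if (tot <= 0) stop("cannot sample from an all-zero spectrum")
  if (n == 0) return(numeric(0))
  cdf <- cumsum(s$counts) / tot
  idx <- findInterval(stats::runif(n), cdf) + 1L
  s$energies[idx]
}
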