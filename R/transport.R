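# The Monte Carlo core.  Incident photons travel along +z; free paths are
# sampled as -ln(R)/mu and re-scaled when a path crosses into a medium with
# a different attenuation coefficient.  All functions are vectorised over
# photons and consume the current R random-number stream, so a fixed
# `set.seed()` upstream makes every tally bit-reproducible.

#' Transport incident photons to the contrast layer
#'
#' Samples the free path in the upper fat layer; photons interacting there
#' are terminated (`"terminated_in_fat"`).  Survivors carry their residual
#' path into the contrast layer, re-scaled by the ratio of the fat
#' coefficient to the layer's effective iodine coefficient; a residual path
#' shorter than the layer thickness is an interaction (`"interacted"`) at
#' that depth, otherwise the photon exits the layer untracked
#' (`"passed_layer"`).
#'
#' @param energy Photon energies, keV (one per history).
#' @param phantom A `kf_phantom`.
#' @param fat,iodine Attenuation curves (bundled tables by default).
#' @return List with `status` (factor with the three levels above) and
#'   `depth` (interaction depth within the layer, cm; `NA` otherwise).
#' @export
advance_to_contrast_layer <- function(energy, phantom,
                                      fat = kf_material("fat"),
                                      iodine = kf_material("iodine")) {
  stopifnot(inherits(phantom, "kf_phantom"))
  n <- length(energy)
  status <- factor(rep("terminated_in_fat", n),
                   levels = c("terminated_in_fat", "passed_layer",
                              "interacted"))
  depth <- rep(NA_real_, n)
  if (n == 0L) return(list(status = status, depth = depth))

  mu_fat <- mu_at(fat, energy)
  s1 <- -log(stats::runif(n)) / mu_fat
  reach <- s1 > phantom$d1
  if (any(reach)) {
    mu_eff <- iodine_equivalent_mu(energy[reach], phantom$dCA, phantom$pdCA,
                                   iodine = iodine)
    s2p <- (s1[reach] - phantom$d1) * mu_fat[reach] / mu_eff
    hit <- s2p < phantom$d2
    idx <- which(reach)
    status[idx[hit]] <- "interacted"
    status[idx[!hit]] <- "passed_layer"
    depth[idx[hit]] <- s2p[hit]
  }
  list(status = status, depth = depth)
}

#' Sample the interaction channel in the contrast layer
#'
#' Given an interaction in the contrast layer, decides scattering versus
#' photoelectric absorption from the iodine coefficients, and for
#' photoelectric events above the K-edge splits K-shell from L-shell
#' vacancies.  Scattered and L-shell histories are terminal: only K-shell
#' vacancies can yield tracked fluorescence photons.
#'
#' @param energy Photon energies, keV (one per interacting history).
#' @param iodine Iodine `attenuation_curve` with photoelectric component.
#' @return Factor with levels `"scattered"`, `"photoelectric_L"`,
#'   `"photoelectric_K"`.
#' @export
sample_interaction_channel <- function(energy,
                                       iodine = kf_material("iodine")) {
  n <- length(energy)
  lev <- c("scattered", "photoelectric_L", "photoelectric_K")
  if (n == 0L) return(factor(character(0), levels = lev))
  p_pe <- photoelectric_fraction(iodine, energy)
  p_k <- kshell_fraction(energy)
  is_pe <- stats::runif(n) <= p_pe
  is_k <- is_pe & stats::runif(n) <= p_k
  out <- rep("scattered", n)
  out[is_pe] <- "photoelectric_L"
  out[is_k] <- "photoelectric_K"
  factor(out, levels = lev)
}

#' Sample K-fluorescence emission from K-shell vacancies
#'
#' A K vacancy yields a Kalpha photon with probability `xi_KL * omega_Kalpha`
#' (KL relaxation followed by radiative decay), a Kbeta1 photon with
#' probability `(1 - xi_KL) * omega_Kbeta`, and otherwise no tracked photon
#' (non-radiative relaxation).  Emitted photons receive the line energy and
#' an isotropic initial direction.
#'
#' @param n Number of K vacancies.
#' @param params `fluorescence_params` (iodine by default).
#' @return List with `line` (factor `"kalpha"`, `"kbeta1"`, `"none"`),
#'   `energy` (keV; `NA` for `"none"`) and direction cosines `a`, `b`, `c`.
#' @export
sample_k_emission <- function(n, params = iodine_fluorescence()) {
  lev <- c("kalpha", "kbeta1", "none")
  if (n == 0L) {
    return(list(line = factor(character(0), levels = lev),
                energy = numeric(0), a = numeric(0), b = numeric(0),
                c = numeric(0)))
  }
  r_branch <- stats::runif(n)
  r_yield <- stats::runif(n)
  ka <- r_branch <= params$xi_KL & r_yield <= params$omega_kalpha
  kb <- r_branch > params$xi_KL & r_yield <= params$omega_kbeta
  line <- rep("none", n)
  line[ka] <- "kalpha"
  line[kb] <- "kbeta1"
  energy <- rep(NA_real_, n)
  energy[ka] <- params$e_kalpha
  energy[kb] <- params$e_kbeta1
  # isotropic: cos(theta) uniform on [-1, 1], azimuth uniform on [0, 2*pi)
  cth <- 1 - 2 * stats::runif(n)
  phi <- 2 * pi * stats::runif(n)
  sth <- sqrt(pmax(1 - cth^2, 0))
  list(line = factor(line, levels = lev), energy = energy,
       a = sth * cos(phi), b = sth * sin(phi), c = cth)
}

#' Transport K-photons from their production site to escape
#'
#' From the production depth inside the contrast layer, a free path is
#' sampled with the internal tissue's attenuation coefficient (iodine is
#' excluded from the tissue attenuation seen by fluorescence photons) and
#' the photon advances the full sampled step.  If the step's z-extent
#' crosses the layer's lower boundary, the residual path beyond the
#' boundary (measured along the ray) is converted to the fat coefficient
#' and the photon advances that much further.  The photon escapes iff its
#' final position is beyond the exit plane and within the lateral bounds;
#' photons travelling upward or sideways out of bounds are absorbed.
#'
#' @param energy Photon energies, keV (per photon).
#' @param depth Production depth within the contrast layer, cm.
#' @param x,y Lateral production coordinates, cm.
#' @param direction List or data frame with direction cosines `a`, `b`, `c`.
#' @param phantom A `kf_phantom`.
#' @param tissue Attenuation curve of the internal tissue; defaults to the
#'   bundled table named by `phantom$internal_tissue`.
#' @param fat Fat attenuation curve.
#' @return List with `escaped` (logical) and final coordinates `x`, `y`, `z`.
#' @export
transport_k_photon <- function(energy, depth, x, y, direction, phantom,
                               tissue = kf_material(phantom$internal_tissue),
                               fat = kf_material("fat")) {
  stopifnot(inherits(phantom, "kf_phantom"))
  n <- length(energy)
  if (n == 0L) {
    return(list(escaped = logical(0), x = numeric(0), y = numeric(0),
                z = numeric(0)))
  }
  stopifnot(length(depth) == n, length(x) == n, length(y) == n)
  a <- direction$a; b <- direction$b; cc <- direction$c
  stopifnot(length(a) == n, length(b) == n, length(cc) == n)

  mu_t <- mu_at(tissue, energy)
  ks1 <- -log(stats::runif(n)) / mu_t
  x1 <- x + ks1 * a
  y1 <- y + ks1 * b
  z1 <- phantom$d1 + depth + ks1 * cc

  remain_z <- phantom$d2 - depth
  crossed <- (ks1 * cc) > remain_z          # only possible when cc > 0
  x2 <- x1; y2 <- y1; z2 <- z1
  if (any(crossed)) {
    ks2 <- ks1[crossed] - remain_z[crossed] / cc[crossed]
    ks2p <- ks2 * mu_t[crossed] / mu_at(fat, energy[crossed])
    x2[crossed] <- x1[crossed] + ks2p * a[crossed]
    y2[crossed] <- y1[crossed] + ks2p * b[crossed]
    z2[crossed] <- z1[crossed] + ks2p * cc[crossed]
  }
  escaped <- crossed & z2 > phantom$z_dimension &
    x2 > 0 & x2 <= phantom$x_dimension &
    y2 > 0 & y2 <= phantom$y_dimension
  list(escaped = escaped, x = x2, y = y2, z = z2)
}
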