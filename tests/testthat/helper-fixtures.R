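# Shared fixtures: synthetic curves and small spectra built in code.

# flat (energy-independent) curve, optionally with photoelectric component
flat_curve <- function(mu, mu_pe = NULL, name = "flat",
                       emin = 5, emax = 60, density = 1) {
  attenuation_curve(name, c(emin, emax), rep(mu, 2L),
                    mu_pe = if (!is.null(mu_pe)) rep(mu_pe, 2L),
                    density = density)
}

# single-bin spectrum at `energy` keV with `n` photons
mono_spectrum <- function(energy, n = 100) {
  spectrum(energy, n)
}

# path to a bundled attenuation CSV
extdata_csv <- function(name) {
  system.file("extdata", "attenuation", paste0(name, ".csv"),
              package = "kfluoro", mustWork = TRUE)
}

# binomial 3-sigma half-width for a frequency estimate
binom3 <- function(p, n) 3 * sqrt(p * (1 - p) / n)
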