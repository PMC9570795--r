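# kfluoro

Monte Carlo simulation of iodine K-fluorescence production, escape and
photon-counting detection in a layered breast phantom under filtered
tungsten X-ray spectra.

## The problem

In contrast-enhanced breast imaging, an iodinated agent accumulates more
densely in tumor tissue than in normal fibrous tissue.  Incident X-ray
photons above the iodine K-edge (33.18 keV) can photoionise the agent's
K shell; the vacancy relaxes by emitting characteristic fluorescence —
Kα at 28.46 keV or Kβ₁ at 33.29 keV — and a photon-counting detector
behind the breast can count those K-photons as a *functional* signal
alongside the conventional transmission image.  `kfluoro` is a compact
radiation-physics tool for exploring that idea quantitatively: it answers
how many K-photons are produced, escape, and are counted per exposure,
and how strongly the counted signal discriminates tumor from fibrous
tissue.

## The model

A three-slab phantom (fat *d₁* | contrast-loaded tissue *d₂* | fat *d₃*)
is irradiated along +z by a tungsten-anode spectrum filtered by 1.6 mm Al
and 0.3 mm Gd, normalised to an entrance-surface air kerma (ESAK) via

    K [µGy] = 1.602×10⁻⁵ Σᵢ N(Eᵢ) Eᵢ (μ_en(Eᵢ)/ρ)_air .

Transport chains exponential free paths: `S₁ = −ln(R)/μ_fat(E)` in fat,
re-scaled into the contrast layer by `μ_fat/μ_CA` where
`μ_CA = (μ/ρ)_I · d_CA · pd_CA` (concentration 300 mg/mL, packing density
0.14 fibrous / 0.56 tumor).  An interaction is photoelectric with
probability `μ_pe/μ` and K-shell with probability `σ_K/(σ_K+σ_L)`;
a K vacancy emits Kα with probability `ξ_KL·ω_Kα = 0.820×0.841` and Kβ₁
with `(1−ξ_KL)·ω_Kβ = 0.180×0.900`, isotropically.  The K-photon is
tracked through tissue and fat to the exit plane and counted iff a
sampled path in a 700 µm silicon converter ends inside it by
photoelectric absorption, `(1−e^{−μTh})·μ_pe/μ`.  Energy-dependent
attenuation tables for fat, fibrous, tumor, iodine, silicon, aluminium,
gadolinium and air are bundled as versioned CSV (see
`data-raw/make_attenuation_tables.py` for their provenance and
validation).

The headline observable is the tumor/fibrous ratio of counted Kα photons
— a packing-density contrast of 4 that self-absorption in the layer
erodes as the layer thickens, and the 40 kV → 50 kV increase in counted
photons at equal ESAK.

## Worked example

```r
library(kfluoro)
s40 <- standard_filtered_spectrum(40)          # W anode, 1.6 mm Al + 0.3 mm Gd
ph  <- make_study_phantom("tumor", d2_mm = 1.0, total_fat_cm = 4)
run_simulation(s40, ph, n_photons = 1e6, seed = 7)
#> <kf_tally> tumor, d2 1.00 mm, fat 4 cm, 40 kV, 1e+06 incident photons
#>   produced_kalpha        77,245 +/- 196
#>   emitted_kalpha          6,319 +/- 93
#>   counted_kalpha          1,218 +/- 46
#>   produced_kbeta1        17,952 +/- 104
#>   emitted_kbeta1          1,522 +/- 44
#>   counted_kbeta1            177 +/- 15
```

Of 10⁶ incident photons, ~7.7% of the above-edge survivors' K-shell
events yield ~77k Kα photons produced in the layer; most are reabsorbed
(isotropic emission under 2 cm of fat), ~6.3k escape through the exit
face and ~1.2k are counted by the converter.  Kα outnumbers Kβ₁ ~4.3:1
from the relaxation/yield products.  Uncertainties are batch standard
deviations (10 batches).  `ratio_study()` runs paired fibrous/tumor
sweeps over layer thicknesses and reports counted-photon ratios with
propagated errors; `write_report()` writes the CSV tables plus a JSON
manifest whose seed allows an exact re-run.

A thin CLI wraps the same functions:

```sh
inst/exec/kfluoro sweep --kv 40 --thicknesses 0.2,0.5,1.0,2.5 --fat 4 \
    --photons 2e6 --seed 1 --out out/
inst/exec/kfluoro run --config run.yaml --seed 1 --out out/
```

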