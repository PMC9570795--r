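Package: kfluoro
Title: Monte Carlo Model of Iodine K-Fluorescence Detection in Layered
    Breast Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the production, escape and photon-counting detection
    of iodine K-fluorescence X-rays in a three-layer breast phantom
    (fat / contrast-loaded fibrous or tumor tissue / fat) irradiated by
    filtered tungsten-anode spectra.  Incident photons are transported by
    analog Monte Carlo sampling of attenuation path lengths; K-shell
    photoelectric events in the iodine contrast agent generate Kalpha and
    Kbeta1 photons that are tracked to escape and counted by photoelectric
    absorption in a silicon converter layer.  Includes bundled
    energy-dependent attenuation tables, an X-ray tube spectrum model with
    beam filtration and entrance-surface air-kerma normalisation, and
    reporting of tally tables and tumor-to-fibrous counted-photon ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
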