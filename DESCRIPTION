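Package: photoscreen
Title: In Vitro Photoprotection Screening of Microbial Extracts
Version: 0.1.0
Authors@R:
    person("Photoscreen", "Developers", email = "photoscreen@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for screening natural extracts for
    photoprotection-related bioactivity. Computes spectrophotometric in vitro
    sun protection factor (Mansur erythemal-weighted sum), critical wavelength
    and UVA/UVB ratio with Boots star rating from 290-400 nm absorbance
    spectra; Trolox-equivalent antioxidant capacity (TEAC) and total
    phenolic/flavonoid equivalents from DPPH, ABTS, Folin-Ciocalteu and
    AlCl3 microplate assays; MTT cell-viability dose-response with
    four-parameter logistic IC50 and areal-dose conversion; a composite
    radar triangle-area photoprotection score with configurable selection
    filters; and LC-MS feature-table characterization (monoisotopic adduct
    m/z, ppm error, permeation-relevant mass fractions, cross-extract
    feature matching and ppm-window annotation). Includes seeded synthetic
    data generators for every input so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
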