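---
title: "Methods: in vitro photoprotection screening with photoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in vitro photoprotection screening with photoscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup}
library(photoscreen)
```

## Scope and model

`photoscreen` implements the desk side of a bioprospecting screen for
photoprotective natural extracts: given UV absorbance spectra, microplate
assay readouts and LC-MS feature tables, it computes the standard in
vitro sunscreen metrics, antioxidant capacities, viability dose-response
summaries, a composite ranking with selection filters, and feature-table
characterization. Everything upstream of these numbers — culture,
extraction, instrument acquisition, peak picking, sequence-based
identification — is out of scope.

## UV-absorbing metrics

The in vitro sun protection factor uses the Mansur spectrophotometric
form: absorbance is sampled at the seven 5 nm grid points of the UV-B
band (290–320 nm), weighted by the tabulated product of the erythemal
action spectrum and the solar intensity spectrum, summed, and multiplied
by the correction factor 10. The seven weights (shipped in
`erythemal_weights()`) sum to 1.0002; a flat unit-absorbance spectrum
therefore yields SPFi = 10.002, a useful closed-form check. Because the
weights are fixed, SPFi is linear in absorbance and hence proportional to
concentration in the Beer–Lambert regime.

The critical wavelength is the smallest λ at which the cumulative
integral of A from 290 nm reaches 90 % of the 290–400 nm total.
Integration is composite trapezoid on the spectrum's wavelength grid
(the sampling rule was not fixed by the assay description; trapezoid is
the conventional choice for smooth spectra). The 90 % crossing is located
by linear interpolation of the cumulative integral within the bracketing
segment and reported at 0.1 nm resolution, with a rounded-integer
convenience field matching how the metric is conventionally quoted.
Against a brute-force 0.01 nm cumulative-sum oracle this agrees within
0.05 nm on smooth band spectra (tested over 100 random band models).
λ_C is invariant under positive scaling of the spectrum.

The UVA/UVB ratio is the trapezoidal integral over 320–400 nm divided by
that over 290–320 nm. Star ratings follow the Boots band edges 0.6 / 0.8
/ 0.9 → 3 / 4 / 5 stars; the published assay description cites the star
system without printing the bands, so the edges are configurable, and the
lower bands of older Boots schemes are deliberately collapsed into
"0 = no claim". A broad-spectrum claim requires λ_C strictly above 370 nm
*and* ratio ≥ 0.7 (inclusive), both configurable in `run_config()`.

Negative absorbance values (baseline artifacts) are preserved in the
container and flagged, but clipped to zero with a warning before any
integral, since the metrics are only meaningful for nonnegative
absorbance. Spectra are resampled to the configured grid (default 1 nm;
the acquisition interval was unstated, so 1 nm is a recorded guess) by
linear interpolation; metrics on 1 nm and 0.5 nm grids agree within 0.2 %
(SPFi) and 0.5 nm (λ_C) on smooth spectra.

## Antioxidant capacity

Radical scavenging is `100·(mean A_C − mean A_S)/mean A_C`. Replicates
are averaged *before* the ratio (per-extract values with SD is how such
screens are reported); the SD shown is that of per-replicate RSC values
against the blank mean. Negative RSC (pro-oxidant behaviour or assay
interference) is retained with a flag — truncation would bias the
screen's selection step.

TEAC inverts the linear Trolox calibration analytically:
`T = (RSC − intercept)/slope` in µmol/L, divided by the extract
concentration in g/L. The shipped curves (`trolox_curve()`) are the
published DPPH and ABTS Trolox lines; at RSC = 50 % and 5 g/L they give
the selection cutoffs 4.66 and 3.35 µmol TE/g_DW, which also validates
reading the curve's X in µmol/L (the units were not stated explicitly).
Phenolic/flavonoid equivalents convert the fitted calibration
concentration (µg/mL) to mg equivalents per 100 g dry weight via
`C_eq/S × 100` with S in g/L — the "per 100 g" scaling convention was not
spelled out in the assay description and is documented here as the
package's choice. Responses below the lowest calibrated standard are
reported as "not detected" rather than extrapolated.

## Cytotoxicity

Viability is `100·mean(A_T)/mean(A_U)`; values above 100 % (apparent
proliferation) are allowed and flagged. Dose–response series are fitted
with a four-parameter logistic with free asymptotes — the published
curves show full sigmoid shapes without naming a model, and fixing
asymptotes would bias IC50 when the top plateau sits below 100 %.
Initialization: asymptotes at the min/max observed viability, midpoint at
the geometric mean of the doses, Hill slope 1. IC50 is read off the
fitted curve at absolute 50 % viability, not at the inflection — the
conventional cytotoxicity reading. If no mean viability reaches 50 %, the
result is right-censored ("IC50 > c_max"); if the optimizer fails on a
crossing series, a log-linear interpolation between the bracketing doses
is used and tagged in the output. The areal-dose conversion uses standard
96-well geometry (200 µL in 0.32 cm², both configurable), chosen because
it reproduces the benchmark filter's 75.93 µg/mL ↔ 47.46 µg/cm²
correspondence exactly (0.625 mL/cm² was the implied, unprinted
geometry).

## Selection and ranking

`select_candidates()` keeps isolates with RSC > cutoff in *both* radical
assays, SPFi > cutoff, λ_C > cutoff and ratio ≥ cutoff; records with any
missing metric are marked `incomplete` rather than silently dropped, and
every per-criterion decision is emitted in a machine-readable audit
trail. Selection is monotone: relaxing any threshold never removes a
selected record.

The composite score is the area of the radar triangle whose three axes
(120° apart) are SPFi as a percentage of the reference UV filter, DPPH
RSC and ABTS RSC: `(√3/4)(v₁v₂ + v₂v₃ + v₃v₁)`. With exactly three axes
the formula is symmetric in its arguments, so no axis-order convention is
needed; it is homogeneous of degree two. The SPFi normalization reference
is a config entry (`spfi_reference`), not a hard-coded benchmark value,
and normalization is applied after replicate averaging (the alternative
order was unstated; averaging first matches how the other axes are
built). Negative scavenging must be floored to zero (and is, in
`screen_panel()`, with the raw value retained in the record). Ties are
broken by SPFi % then lexicographic isolate id, making the ranking a
deterministic total order. Correlations between contents and activities
use the textbook Pearson t-test, unadjusted by default (screens report
raw p-values); a Bonferroni factor is available.

Two SPFi thresholds coexist in screening practice — a selection cutoff
(> 2) and a "most-active" tier (> 5). Both are exposed
(`spfi_cutoff`, `spfi_active_cutoff`); only the former gates selection.

## LC-MS feature characterization

Theoretical adduct m/z is the dot product of formula element counts with
fixed monoisotopic masses (C 12 exact, H 1.00782503, N 14.00307401,
O 15.99491462, P 30.97376151, S 31.97207069) plus the adduct shift; the
*proton* mass (1.00727646), not the hydrogen-atom mass, is added for +1
adducts. The canonical positive-mode set is [M+H]⁺, [M+ACN+H]⁺,
[M+2ACN+H]⁺ (acetonitrile 41.026549). This mass table reproduces a
published 17-row calculated-m/z column exactly at 4 decimals for 14 rows
and within 2×10⁻⁴ Th for the other three (whose source software
evidently used a slightly different mass table); the printed column is
treated as authoritative in tests. ppm error uses the calculated m/z as
denominator — the convention is documented because the function is then
only approximately symmetric.

Cross-extract matching is greedy nearest-neighbour: features are pooled,
scanned in ascending m/z, and each unassigned feature seeds a group that
absorbs at most one unassigned feature per other extract — the nearest in
m/z among those within the ppm and RT windows (defaults 10 ppm, 0.2 min).
No RT alignment is attempted (single instrument, single method). The
resulting partition is exhaustive and disjoint, so UpSet-style subset
counts sum to the number of groups. Annotation against a user-supplied
compound table assigns identification level 3 (putative candidate) when
exactly one structure matches within the window and level 4 (unequivocal
molecular formula) when several isomeric entries share the matching
formula, reporting the isomer count.

## Synthetic data: what it emulates, and what a green test shows

Generators emulate the screen's stated world: smooth multi-band Gaussian
absorbance spectra on 290–400 nm (closed-form integrals keep independent
oracles available); triplicate plates with blanks near 0.70 AU (the
adjusted radical working solution) and additive Gaussian absorbance noise
(default SD 0.005 AU, a typical plate-reader repeatability; sample
absorbances are back-computed from true RSC, so the pipeline is an exact
inverse at zero noise); 4PL viability curves with the 8-dose 3.13–400
µg/mL reference series and 2 % viability noise; and feature tables with
planted formulas/adducts, ±5 ppm uniform mass error and RT uniform on
2–26 min, with controlled overlap between extracts. The 35-isolate panel
default, with 10 designed passers, mirrors a realistic screen size.

What the generators do *not* emulate: heteroscedastic or drifting plate
noise, chromatographic peak shapes, isotope envelopes, co-elution, matrix
effects, or between-day variability. A green end-to-end test therefore
establishes that the *computational* pipeline is correct and stable under
realistic noise magnitudes — not that the assays themselves are robust.

All generators take explicit seeds, are byte-deterministic for a fixed
seed, and restore the caller's RNG state.

## Numerical choices and degenerate inputs

* All-zero spectra raise an undefined-metric error for λ_C and the ratio
  (rather than returning 400 or 0); a zero blank or untreated mean raises
  an assay error.
* λ_C ties at the 90 % target resolve to the *smallest* bracketing
  wavelength (`which(cum >= target)[1]`).
* Reported rounding: m/z half-up to 4 decimals; λ_C to 0.1 nm plus an
  integer convenience field. Internal computation is full precision.
* Ranking ties: score, then SPFi %, then isolate id.
* The rectangle spectrum edge case for λ_C is exact only when the input
  grid resolves the discontinuity; sampled at 0.01 nm the closed-form
  335.0 nm is recovered within 0.05 nm.

## Known limitations

In vivo SPF, photostability, transmittance-plate SPF methods, ORAC/FRAP,
kinetic DPPH, mechanistic toxicity, raw MS parsing, isotope-pattern
scoring and database content are all out of scope. The star-rating band
edges and the erythemal weight table are fixed constants of their
respective conventions; users with other conventions can pass their own
table/boundaries.
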