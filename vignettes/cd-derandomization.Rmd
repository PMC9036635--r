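---
title: "Secondary structure from CD spectra of partially unfolded proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Secondary structure from CD spectra of partially unfolded proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(cdsom)
```

## The problem

Far-UV circular dichroism (CD, 190–240 nm) reports protein secondary
structure: α-helix shows negative bands near 222 and 208 nm and a strong
positive band near 193 nm; β-sheet a negative band near 217 nm and a
positive one near 195 nm; disordered (random-coil) chain a strong negative
band near 198–200 nm. Standard deconvolution methods fit an experimental
spectrum against a reference set of spectra of proteins with known
(crystal-structure-derived) structure. They work poorly for proteins with
substantial unfolded domains or populations — e.g. a protein part-way
through a thermal melt — because fully folded and fully unfolded proteins
occupy different regions of spectral space and intermediate mixtures
resemble neither.

`cdsom` addresses this with a three-step procedure:

1. **Fit** spectra with a self-organising map (SOM) trained on
   structure-annotated reference spectra.
2. **Derandomize**: subtract trial fractions `f` of a random-coil (RC)
   reference spectrum and renormalise,
   `Δε_derand(λ) = (Δε_exp(λ) − f·Δε_RC(λ)) / (1 − f)`,
   sweeping `f` from 0 to 0.9 in steps of 0.1, and keep candidates whose
   SOM fit has NRMSD ≤ 0.03.
3. **Regenerate** the original protein's composition from the best core
   fit: helix and sheet scale by `(1 − f)` and the coil mass rejoins
   "other".

Because every spectrum is expressed as Δε per molar residue, the
derandomization formula is the exact algebraic inverse of the two-population
mixture `Δε_exp = (1 − f)·Δε_core + f·Δε_RC`; residue counts cancel.

The goodness-of-fit statistic is the normalised root-mean-square deviation

```
NRMSD = sqrt( Σ_λ (Δε_exp − Δε_calc)² / Σ_λ Δε_exp² )
```

computed over the shared wavelength grid. Other normalisations (e.g. by the
observed range) exist; this package fixes the sum-of-squares convention
above, under which fits of folded proteins typically score 0.005–0.03 and
the default acceptance gate is 0.03 (inclusive — a fit at exactly 0.03 is
kept, only strictly larger values are discounted).

## The self-organising map

Training uses classical online Kohonen updates. Each reference spectrum in
turn pulls its best matching node and a Gaussian neighbourhood
`h = exp(−d²_map / 2σ²)` toward itself; the learning rate and `σ` decay
exponentially from their initial to final values over the run. Defaults
(`som_config()`): a 50 × 50 map, 5 best matching units (BMUs) for
prediction, 100 epochs, learning rate 0.5 → 0.01, radius
`max(rows, cols)/2` → 1, and seeded weight initialisation uniform within
the per-wavelength envelope of the reference set. Everything is
deterministic given the seed; ties in all nearest-node searches break
lexicographically by (row, col).

Two design points were genuinely open and are fixed as follows:

* **Prediction weighting.** A query's structure and reconstructed spectrum
  are inverse-distance-weighted averages over its `k_bmu` BMUs
  (`w_i = (1/d_i)/Σ(1/d_j)`; a BMU at distance 0 takes all the weight).
  Inverse distance (rather than inverse squared) is the simplest choice
  that makes an exact-match query reproduce its node verbatim.
* **Node structures.** Each node's 5-class structure is the
  inverse-map-distance-weighted mean of the annotations of the
  `n_neighbours = 5` reference entries whose winning ("occupancy") nodes
  are nearest in map coordinates, with spectral distance breaking map-space
  ties; a node hosting a reference takes that reference's annotation
  exactly. Nearness is measured on the map, not in spectral space, because
  the map is what organises "similar spectral shape" into proximity.

For well-converged maps the package's own tests use a longer convergence
phase than the defaults (e.g. 300–400 epochs with final radius 0.25 and
final learning rate 0.002 on 15 × 15 to 20 × 20 maps); with tens of
reference spectra this trains in seconds and reproduces each training
spectrum essentially exactly. The 50 × 50 default mirrors the map sizes
used with full experimental reference sets (~180 spectra).

## Structure classes

Reference sets are annotated with five classes (α-helix, β-sheet, bonded
turn, bend, loop; any remainder is unannotated). A far-UV CD spectrum only
carries enough information for three, so all results are reported as
helix / sheet / other, with `collapse_structure()` pooling turn + bend +
loop + remainder into "other".

## Candidate selection and the β_II caveat

The sweep produces one candidate per fraction (the 0% candidate always
competes). After the NRMSD ≤ 0.03 filter, `rank_candidates()` sorts by
NRMSD with ties to the smaller fraction, and marks every candidate within
15% (relative) of the best as *co-optimal*. Near-ties are real: in
practice they are resolved by inspecting how experimental and predicted
spectra overlay between 190 and 210 nm (where the spectrum crosses zero,
where its extrema sit) and by looking at *which* reference proteins are
the BMUs. `inspect_candidate()` automates the evidence-gathering: it
reports zero crossings (linear interpolation) and extrema in 190–210 nm
for both spectra, lists the reference proteins occupying nodes within a
small map radius of each BMU, and raises `beta2_flag` when any of them is
in the β_II list (default: α-chymotrypsin, chymotrypsinogen, elastase).
β_II proteins' sheet CD resembles unfolded/polyproline-II spectra, so when
one is a BMU the sheet/coil split of the fit is genuinely ambiguous — the
report says so rather than deciding. The final choice between co-optimal
candidates is deliberately left to the user.

## The synthetic-data generator

`make_reference_set()`, `make_rc_spectrum()` and `make_melting_series()`
exist so the entire pipeline can be exercised with exactly known ground
truth. Spectra are built from four Gaussian-band basis shapes (see
`cd_basis()$bands` for the constants): helix (+21.5 at 193, −11 at 208,
−11.5 at 222 nm), sheet (+7.5 at 196, −4.8 at 218 nm), a weak turn-like
"folded other" shape, and coil (−12 at 198, +0.9 at 220 nm). Annotations
map to shapes as helix → helix, sheet → sheet, turn + bend → folded-other,
loop + unannotated → coil: folded turns and bends do *not* look like
random coil in far-UV CD, and keeping the coil shape for genuinely
disordered mass is what makes partially melted spectra hard to fit
directly — the phenomenon derandomization exploits. Folded entries draw
compositions from a Dirichlet favouring realistic mixtures with small loop
content; the set is augmented with a few near-fully-unfolded and
near-fully-helical entries, mirroring how experimental reference sets are
augmented for unfolded-domain work.

Melting series follow a two-state picture:
`spectrum(T) = (1 − f(T))·core + f(T)·RC + noise`, with the default
schedule (0, 0, 0, 0, 0.2, 0.3, 0.5, 0.5, 0.6) over 20–100 °C emulating a
serum-albumin-like gradual melt, a core of (0.70, 0.05, 0.25)
helix/sheet/other, and i.i.d. Gaussian noise at 2% of the clean spectrum's
maximum |Δε|. Known simplifications: real CD noise grows steeply below
200 nm rather than being wavelength-independent; real unfolding is rarely
strictly two-state; and Gaussian-band spectra are smoother than real
protein spectra. Passing tests therefore demonstrate the *method's*
internal consistency (the sweep finds the planted fraction, regeneration
recovers the planted composition), not instrument-level performance on
real proteins.

Under those conditions the test suite verifies, among other properties:
self-consistency (≥ 90% of a 40-entry noiseless reference set re-predicted
with NRMSD < 0.05 and 3-class structure within ±0.10), and parameter
recovery over 20 seeded noisy series (recovered fraction within ±0.1 of
the schedule at every temperature on average — one sweep step — and mean
absolute error of the regenerated helix fraction ≤ 0.05; in the shipped
runs the observed errors are roughly 0.02 and 0.02 respectively).

## Numerical and degenerate-input behaviour

* Wavelength grids are stored descending (240 → 190 nm, 1 nm, 51 points by
  default) to match the file layout; arithmetic is order-agnostic.
  Resampling is linear and refuses extrapolation.
* `nrmsd()` rejects an identically zero observed spectrum (undefined
  normalisation).
* Derandomized spectra at high `f` amplify noise by `1/(1 − f)` and may be
  non-physical; they are never clipped — the NRMSD filter is the guard.
* A `1 × 1` map degenerates gracefully (its single node converges to the
  reference mean); a single-spectrum reference set turns the map into one
  attractor.
* Structure fractions are validated to `[0, 1]` with a 1e−6 tolerance and
  clamped only for floating-point dust; 3-class outputs always sum to 1.

## Interfaces

Reference sets, test sets and the RC spectrum travel as column-oriented
CSV (spectra in columns, wavelengths descending in the first column,
five annotation rows appended per reference column; a trailing `"70C"` in
a test-column header is parsed as a temperature). Trained maps persist as
a single JSON document. The `exec/cdsom` script exposes `train`,
`predict`, `derand`, `melt` and `synth` subcommands over these files, with
YAML config files overridden by flags, logs on stderr, and exit codes
0 / 2 / 3 for success / input error / no-acceptable-fit.

## Limitations

The absolute recovered RC fractions depend on the intensity calibration of
the supplied RC spectrum; results are internally consistent but `f` should
be read relative to that choice. The package does not convert instrument
units, subtract baselines, or estimate an RC spectrum from data; and it
will not decide β_II versus coil versus polyproline II — no CD method can.
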