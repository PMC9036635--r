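# cdsom

Secondary-structure estimation from far-UV circular dichroism (CD) spectra
of proteins with unfolded domains or populations, using a self-organising
map (SOM) fit plus systematic random-coil **derandomization** and
**regeneration**.

## Who this is for

Protein scientists with Δε-per-molar-residue CD spectra (typically
240–190 nm, 1 nm steps) of samples suspected to contain disordered
content — thermal melting series, intrinsically disordered regions, fusion
constructs, or production batches that may be partially unfolded — and a
structure-annotated reference set of folded-protein spectra.

## The method

Standard CD deconvolution fits a spectrum against reference proteins of
known structure. It fails for partially unfolded samples because folded
and unfolded spectra occupy different regions of spectral space. `cdsom`:

1. **Trains a SOM** (default 50 × 50 nodes, online Kohonen updates,
   Gaussian neighbourhood, deterministic given a seed) on the reference
   spectra, then attaches 5-class structure fractions (α-helix, β-sheet,
   turn, bend, loop) to every node from its nearest reference occupants.
2. **Derandomizes** the experimental spectrum for each trial coil
   fraction *f* ∈ {0, 0.1, …, 0.9}:

   Δε_derand(λ) = (Δε_exp(λ) − f·Δε_RC(λ)) / (1 − f)

   where Δε_RC is a measured random-coil reference spectrum. This is the
   exact inverse of the two-population mixture
   Δε_exp = (1−f)·Δε_core + f·Δε_RC (per-residue units make residue
   counts cancel).
3. **Fits** each derandomized spectrum via its 5 best matching units
   (inverse-distance weighting), scoring fits with

   NRMSD = √( Σ_λ (Δε_exp − Δε_calc)² / Σ_λ Δε_exp² )

   and discarding candidates with NRMSD strictly above 0.03.
4. **Regenerates** the original protein's 3-class composition from the
   winning core fit: helix′ = (1−f)·helix, sheet′ = (1−f)·sheet,
   other′ = (1−f)·other + f.
5. **Inspects** the best matching units: if a β_II-class reference protein
   (α-chymotrypsin, chymotrypsinogen, elastase by default) neighbours a
   BMU, the sheet/coil split is flagged as ambiguous — β_II, random coil
   and polyproline II are spectroscopically indistinguishable. Near-tied
   candidates are marked co-optimal and reported with 190–210 nm shape
   diagnostics (zero crossings, extrema) for human review.

A synthetic-data module (`make_reference_set()`, `make_rc_spectrum()`,
`make_melting_series()`) generates Gaussian-band spectra with exactly
known ground truth, so the whole pipeline is testable offline.

## Worked example

A synthetic serum-albumin-like melt: core (0.70, 0.05, 0.25)
helix/sheet/other, coil fractions (0, 0, 0, 0, 0.2, 0.3, 0.5, 0.5, 0.6)
over 20–100 °C, noise added.

```r
library(cdsom)
refset <- make_reference_set(60, seed = 101)
map <- train_som(refset, som_config(rows = 20, cols = 20, epochs = 400,
                                    radius_final = 0.25, lr_final = 0.002,
                                    seed = 42))
rc <- make_rc_spectrum()
series <- make_melting_series(structure_fractions3(0.70, 0.05, 0.25),
                              f_schedule = c(0, 0, 0, 0, 0.2, 0.3, 0.5, 0.5, 0.6),
                              noise_sd = 0.1, seed = 20)
analyze_series(series, rc, map)
#> <melt_analysis> 9 temperatures, NRMSD threshold 0.03
#>   temperature_C best_nrmsd rc_added derand_helix ... regen_helix regen_other  note
#> 1            20     0.0178      0.0        0.681 ...       0.681       0.155
#> 4            50     0.0174      0.0        0.680 ...       0.680       0.156
#> 5            60     0.0220      0.2        0.681 ...       0.545       0.324  co-optimal candidates; inspect
#> 7            80     0.0292      0.4        0.559 ...       0.335       0.598  co-optimal candidates; inspect
#> 9           100     0.0320      0.5        0.533 ...       0.266       0.674  no acceptable fit
```

Reading the output: below 50 °C the best fit needs no coil subtraction and
the regenerated helix stays ≈ 0.68; from 60 °C the sweep removes growing
coil fractions (recovering the planted schedule to within one 0.1 step)
and the regenerated helix falls toward 0.27, tracking the planted truth
(0.28 at 100 °C). The 100 °C row is honestly marked `no acceptable fit`
because its best NRMSD (0.032) sits just above the 0.03 gate — the row
still reports the best candidate. Inspecting it:

```r
inspect_candidate(analyze_series(series, rc, map)$selected[[9]])
#> <inspection> 50% RC, NRMSD 0.0320
#>   BMU neighbours: ref08, ref58, ref60, ref18, ref14
#>   beta-II flag: FALSE
#>   experimental 190-210 nm: zeros at [200.7], max +9.17 at 192 nm, min -8.08 at 209 nm
#>   predicted   190-210 nm: zeros at [200.8], max +9.15 at 192 nm, min -8.3 at 210 nm
```

The regeneration arithmetic itself, e.g. a 100 °C fit whose best candidate
removed 60% coil and predicted a (0.61, 0.04, 0.35) core:

```r
regenerate(structure_fractions3(0.61, 0.04, 0.35), 0.60)
#> <structure3> helix 0.244 sheet 0.016 other 0.740
```

i.e. the original protein retains 24% helix.

A command-line front end (`exec/cdsom`) exposes the same workflow as
`train`, `predict`, `derand`, `melt` and `synth` subcommands over
column-CSV spectrum files and a JSON map file; see
`vignettes/cd-derandomization.Rmd` for the file dialects and the full
account of the method.

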