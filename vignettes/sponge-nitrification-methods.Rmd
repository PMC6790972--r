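---
title: "Models and methods: quantifying nitrification by a sponge's archaeal symbiont"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: quantifying nitrification by a sponge's archaeal symbiont}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitrosponge)
```

Marine sponges host dense communities of ammonia-oxidizing archaea (AOA)
that convert host-excreted ammonia into nitrite. `nitrosponge` implements
the quantitative chain needed to demonstrate and characterize such an
activity from incubation experiments and omics data: isotope-pool-dilution
rate estimation, net dissolved-inorganic-nitrogen (DIN) fluxes, tracer-based
carbon fixation, symbiont quantification, and comparative-genomic and
proteomic summaries. This vignette is the package's account of the models,
the parameters that matter, and the design choices behind them.

## Gross nitrification by isotope pool dilution

The product pool (NO~2~^-^+NO~3~^-^, measured jointly because both species
are recovered together by microdiffusion before isotope-ratio mass
spectrometry) is spiked with ^15^N-nitrate. Gross production $p$ adds
*unlabelled* product and therefore dilutes the pool's ^15^N enrichment,
while consumption $c$ removes labelled and unlabelled molecules in
proportion and leaves the enrichment unchanged. With $C(t)$ the pool and
$A(t)$ its atom% ^15^N excess,

$$\frac{dC}{dt} = p - c, \qquad \frac{dA}{dt} = -\,p\,\frac{A}{C}.$$

For constant rates this integrates to
$A(t) = A_0\,(C(t)/C_0)^{-p/(p-c)}$, and the two-point estimator used by
`gross_rates_ipd()` inverts it:

$$p = \frac{C_t - C_0}{\Delta t}\cdot
      \frac{\ln(A_0/A_t)}{\ln(C_t/C_0)},\qquad
  c = p - \frac{C_t - C_0}{\Delta t}.$$

Assumptions: rates constant over the window, a single well-mixed pool, and
no re-entry of consumed label. Only the *ratio* $A_0/A_t$ enters, so any
common calibration factor on the enrichment cancels.

Numerical choices:

* The formula has a removable singularity at $C_t = C_0$; within a relative
  tolerance of $10^{-9}$ the limiting form $p = (C_0/\Delta t)\ln(A_0/A_t)$
  is used instead.
* Measurement noise can push $p$ or $c$ slightly negative. Negatives within
  5% of the estimate magnitude are clamped to zero with a
  `clamped_negative` flag; anything larger keeps its value and is flagged
  `model_violation`, since a strongly negative rate means the model's
  assumptions failed, not that the rate is zero.
* An enrichment that *rose* over the window (`apet > ape0`) contradicts the
  tracer model outright; the estimate is withheld (NA) and flagged
  `enrichment_increased` rather than returned as a number.

The label addition is planned by `plan_label_addition()`, which keeps the
tracer at no more than 10% of the pool so the addition itself does not
stimulate turnover. The target fraction is interpreted against the
*post-addition* pool (the stricter reading; `fraction_basis = "pre"`
switches to the simpler convention), and the label mass is counted as part
of the pool at $t = 0$, the usual pool-dilution bookkeeping.

Net fluxes (`net_flux()`) are linear concentration changes over the 6-18 h
window, normalized by container volume over sponge wet weight; the window
skips the label-equilibration transient at the start of an incubation. A
window endpoint may be linearly interpolated when bracketing samples lie
within ±1 h; beyond that the window is reported uncovered rather than
silently extrapolated. Net nitrification is the sum of the NO~2~^-^ and
NO~3~^-^ fluxes, and the NO~2~^-^:NO~3~^-^ ratio is carried as a
diagnostic, since incomplete (nitrite-stopping) nitrification shows up as
nitrite accumulating faster than nitrate.

All rates are expressed per day internally (hours only at I/O) and in
µmol N g^-1^ wet weight d^-1^ after normalization.

One quantity seen in figure captions of this literature — "weighted" gross
rates with unspecified weights — is deliberately not implemented; without a
definition any weighting would be a guess.

## Ammonia speciation

NH~3~, not NH~4~^+^, is both the substrate of archaeal ammonia
monooxygenase and the species toxic to the host, so the NH~3~ fraction of
total ammonia frames both substrate supply and stress in amended
treatments. `ammonia_fraction()` uses Henderson-Hasselbalch with a
stoichiometric seawater dissociation exponent

$$\mathrm{p}K_a^* = 10.0423 - 0.0315536\,T + 0.003071\,S,$$

a published linear seawater formulation adequate near surface conditions.
No pH default is baked in — the experiment's measured pH must be supplied —
but the packaged examples use pH 8.05, a typical coastal value at which
about 4.5–4.7% of total ammonia is NH~3~ at 25 °C and salinity 35.
Carbonate-system speciation, pH-scale conversions and activity corrections
are out of scope; over the pH 8.0–8.1 band the fraction moves from ~4.2%
to ~5.2%, which bounds the uncertainty a user inherits from not knowing
the exact pH and pK formulation.

## Carbon fixation from tissue ^13^C

A ^13^C-bicarbonate spike enriches the DIC pool; `mix_dic_label()` computes
the mixed enrichment by concentration-weighted mass balance (e.g. 100 µM at
99 at% into a 1975 µM natural-abundance background gives 2075 µM at
5.83 at%, an excess of 4.72 at%). Tissue enrichment then maps to a fixation
rate by a two-pool mixing model in `fixation_rate()`:

$$\text{rate} = \frac{at\%_{final} - at\%_{initial}}{at\%^{excess}_{DIC}}
  \cdot \frac{C_{tissue}}{t},$$

with δ^13^C converted to atom% via $R = R_{VPDB}(1 + \delta/1000)$,
$at\% = 100R/(1+R)$, and $R_{VPDB} = 0.0112372$ (the Craig value; the
^15^N natural-abundance baseline is likewise fixed at 0.3663 at% — both
are ordinary configurable fields, chosen because they are the conventional
tracer-ecology constants). Background DIC is taken as 0 ‰ (1.1112 at%)
unless measured values are supplied, a good approximation for surface
seawater.

The DIC excess is treated as constant at its post-mixing value. In
intermittently opened incubations some label escapes, which biases the
fixation rate *down* and any N:C ratio built on it *up*; the
`label_retention` parameter (a fraction in (0, 1]) lets users discount the
excess when a loss estimate exists, but no correction is invented by
default. Tissue baselines default to unamended-control means with
per-sample overrides. Whether tissue carbon is on a dry- or wet-weight
basis is recorded by the caller; no hidden conversion factor is applied.

`nc_coupling()` regresses gross nitrification (response) on carbon
fixation (predictor), so the slope *is* the N:C ratio — moles of ammonia
oxidized per mole of carbon fixed; the reciprocal is reported alongside.
Free-living marine AOA sit around 7–29; substantially higher values
indicate label loss and/or mixotrophic growth.

## Symbiont quantification

qPCR standard curves regress Cq on log~10~ copies over a 10^6^–10^0^
copies µl^-1^ dilution series (`fit_standard_curve()`); the amplification
efficiency is $10^{-1/\text{slope}} - 1$, flagged outside [0.9, 1.1].
Unknowns are inverted through the curve after averaging duplicate wells on
the Cq scale (averaging copies instead would bias high under Cq noise,
since the inversion is convex), scaled from template to elution volume and
divided by tissue wet weight. Extrapolation beyond the calibrated Cq range
is flagged, not forbidden. Extraction-yield corrections are not modelled;
the elution/template scaling is the documented assumption.

Cell-specific rates divide a bulk rate by symbiont density
(`cell_specific_rate()`, µmol g^-1^ d^-1^ → fmol cell^-1^ d^-1^).
`copies_per_cell` defaults to 1 because marine Thaumarchaeota carry a
single rRNA operon, making the gene-copy and per-cell interpretations
coincide; both are reported when the default is overridden.

FISH counts give relative abundance as the per-image archaeal percentage,
summarised by mean ± SE across images; segmentation and counting are
upstream of this package.

## Comparative genomics

Alignment itself is external: hit tables (BLAST `-outfmt 6` plus `qlen`,
`slen`) are inputs, and the module owns only the selection and aggregation
mathematics, because identity values depend on the aligner version no
matter what.

* **AAI** (`aai()`): per direction, best hit per query by bitscore with
  ties broken by identity then lexicographic subject id (determinism);
  hits aligning over <70% of the *query* length are discarded in each
  direction, so a pair must pass the coverage filter both ways; AAI is the
  mean identity of reciprocal pairs weighted by gene length. "Gene length"
  is ambiguous between query, subject and alignment length; the
  forward-query weighting is the default and the unweighted,
  reverse-weighted and symmetrized means are emitted alongside.
* **ANI** (`ani_fragment()`): genomes are cut into non-overlapping
  1020 bp windows (`fragment_genome()`, 0-based half-open coordinates,
  terminal remainders discarded), fragments matched by reciprocal best
  hit, pairs under 70% identity dropped, ANI is the mean retained
  identity and the aligned fraction is retained length over the smaller
  genome.
* **Gene-family algebra** (`exclusive_shared_families()`,
  `family_category_fractions()`): set operations on a families × genomes
  count matrix — exclusively shared means present in every focal genome
  and absent everywhere else; core/unique/other fractions partition the
  focal genome's gene content. Ortholog inference (OrthoFinder and kin) is
  upstream.

`assembly_stats()` computes contig count, total length, GC over
unambiguous bases only, and cumulative-half N50.

## Proteomics

NSAF (`nsaf()`) is the per-protein spectral count over protein length,
normalized to sum to one per sample; `aggregate_nsaf()` sums within bins
or gene-family categories per sample and then averages shares across
samples (the alternative, pooling counts before normalizing, is available
as `combine = "summed"` because the averaging convention is often left
unstated in methods sections). Identification filtering keeps proteins
with ≥2 exclusively unique peptides; the FDR uses the concatenated
target-decoy convention $2D/(T+D)$, with the plain ratio $D/T$ as a
switch. Peptide-to-protein inference is search-engine territory and is
assumed resolved in the input.

## What the synthetic generators emulate — and what they do not

Every analysis stage has a seeded generator producing inputs with exactly
the statistical structure the stage assumes, plus a hidden truth record:

* `simulate_incubation()` integrates the pool-dilution kinetics above with
  classical fixed-step Runge-Kutta (step ≤ 0.01 d; the analytic solution
  is the cross-check in the tests) and adds Gaussian noise to sampled
  concentrations and enrichments. The combined NOx pool is split into
  NO~2~^-^/NO~3~^-^ at a fixed fraction (default 2.8:1), mirroring
  nitrite-dominated accumulation.
* `simulate_tissue_labeling()` inverts the fixation model; δ^13^C noise
  defaults to 0.2 ‰, a realistic IRMS repeatability.
* `simulate_qpcr()` draws Cq values around the log-linear curve
  (σ = 0.15 cycles as the realistic default in tests).
* `simulate_proteome()` draws multinomial spectral counts with
  probabilities proportional to share × length, so NSAF recovers the
  configured bin shares in expectation; lengths are log-normal.
* `simulate_genome_pair()` mutates a random genome site-wise at
  $1 - \text{identity}/100$ and emits hit tables containing the true
  pairing plus always-outscored decoys; `colinear_fragment_hits()`
  supplies positionally true fragment hits for the ANI path.

These generators deliberately omit real-data features: sponge pumping
behaviour and oxygen microgradients, diel rate variation, matrix effects
and inhibition in qPCR, shared-peptide ambiguity in proteomics, and
genome rearrangements or horizontal transfer. Passing tests therefore
demonstrate that the estimators are *correct inverses of their models* at
realistic noise, not that the models capture every property of a live
sponge incubation.

Default generator conditions follow the experimental design they emulate:
1.5 l containers, ~5 g sponge clones, a two-point 0/20 h isotope design
inside 24 h incubations repeated over 7 days, labels at ≤10% of the pool,
a 1975 µM DIC background with a 100 µM 99 at% spike, and symbiont
densities around 10^10^ copies g^-1^.

## Problem sizes and reproducibility

The packaged tests and the acceptance script run entirely on synthetic
data at deliberately modest sizes — rate grids of 16 (p, c) combinations,
50-replicate Monte-Carlo loops for tracer noise, 20-seed qPCR round
trips, 100 random instances for the brute-force AAI/family-algebra
cross-checks, 20-gene toy genomes — sizes at which the brute-force
oracles stay exact and a full run takes seconds. Every stochastic step
takes an explicit seed, and one root seed derives all substreams, so a
rerun with the same seed is byte-identical.

## Known limitations

* The two-point pool-dilution estimator cannot detect rate changes within
  the window; multi-point designs are accepted but only the first/last
  isotope samples are used.
* NO~2~^-^ and NO~3~^-^ are not resolved as separate ^15^N pools (the
  measurement is of their sum), so nitrite-oxidation rates are not
  separable from the combined gross signal.
* The N:C ratio inherits the label-loss bias of open incubations; treat
  absolute values as upper bounds unless `label_retention` is measured.
* AAI/ANI values are conditional on the external aligner's scoring; the
  module guarantees only the selection and averaging conventions.
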