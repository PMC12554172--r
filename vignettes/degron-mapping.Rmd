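---
title: "Mapping a degron: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a degron: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degronmap)
```

`degronmap` analyses the four kinds of evidence that together localize a
degradation motif within a substrate: positional substitution arrays,
molecular-dynamics trajectory ensembles of the docked complex, equilibrium
binding titrations, and cellular turnover assays. This vignette records
the models behind each module, the defaults and why they were chosen, the
numerical conventions, and what the synthetic-data generators do and do
not emulate. The running example is the RGS2 N-terminal degron
(Met5–Met16, `MFLAVQHDCRPM`) recognized by the FBA domain of the F-box
protein FBXO44, whose residue numbering (position 5 = first peptide
residue) is used throughout.

## The substitution array model

A positional substitution scan prints, for each of the 12 parent
positions, the parent peptide plus the 19 single-residue variants, and a
C-terminal truncation series. Fluorescence of bound probe is proportional
to binding, so the natural effect measure is multiplicative: the
`effect_profile` ground truth of the generator is a factor on the parent
signal per cell, with the parent residue pinned at exactly 1.

**Normalization.** The field's convention is percent of the parent
residue's signal at the same position. Two estimators are provided.
The default (`method = "replicate"`) divides each replicate by the
parent signal of the *same replicate* before averaging. This has two
properties we consider non-negotiable for array data: the parent cell is
exactly 100% with zero spread, and rescaling all signals of one replicate
by a constant (a scanner-gain or exposure difference) cancels exactly.
The alternative (`method = "pooled"`) is the ratio of cell mean to parent
mean; it keeps the parent cell's own replicate scatter visible in its sd
but loses scale invariance. The two agree exactly on noiseless data and
to first order otherwise; the choice matters only for heteroscedasticity
diagnostics.

**Significance.** `test_substitution_effects()` analyses the
parent-normalized replicate values in the two-way position × residue
cell-means layout and reports, per position, each substitution against
the parent residue with a Tukey studentized-range adjustment over the
full 20-mean family of that position, using the pooled within-cell mean
square of the whole array. This "simple effects within columns" reading
reproduces what a standard two-way ANOVA followed by Tukey's post hoc,
restricted to parent contrasts, would report; the implementation is
verified in the test suite against `emmeans` pairwise Tukey contrasts on
the identical `aov` model. Whether to analyse raw or normalized
fluorescence is genuinely open; we default to normalized because the
reported effect axis is percent of parent, and expose `on = "raw"`.
Replicates are pooled (flattened) by default; with a single replicate per
cell the function refuses to test and returns a descriptive table.

Two numerical conventions: a contrast with zero estimated difference has
adjusted p of 1 regardless of the residual variance (so exactly-null
noiseless arrays are never flagged), and a nonzero difference with zero
residual variance is reported as p = 0 (the noiseless planted-effect
limit).

**Classification.** `classify_positions()` encodes the field's reading of
a scan. *Essential* requires that at least 80% of the countable
substitutions (all non-parent residues except Arg and Lys) fall below 20%
of parent *and* be significant decreases. Arg/Lys are exempted from the
count because positive charge can rescue binding through generic
electrostatics without the position itself being dispensable — exactly
the behavior of the essential cysteine here, where only Arg substitution
survives. The 20%/0.8 defaults reproduce that call without per-dataset
tuning and are exposed as arguments. *Charge-enhanced* requires a
significant Arg or Lys increase with no significant decrease; remaining
positions with any flag are *mixed*, the rest *tolerant*. An
all-enhancing position (like the aspartate at 12, where every
substitution improves binding) is therefore charge-enhanced.

**Truncation boundary.** The scan runs from the full-length peptide down;
the boundary is `last_retained + 1` of the first truncation whose mean
signal drops below the loss threshold (default 20% of the full-length
reference, taken as the mean of the parent-residue cells). If no
truncation crosses the threshold the scan reports "no boundary in range"
(`NA`) rather than guessing.

## Trajectory stability and contacts

**RMSD.** `rmsd_series()` measures each frame against frame 1 of its
trial — the conformation at the start of the production run — after
least-squares superposition (Kabsch, proper rotation enforced). The
selection itself is superposed and scored: `"peptide"` fits and measures
the peptide Cα set; `"complex"` pools both chains. Fitting on the
selection mirrors common MD-toolchain defaults; which selection a given
analysis used is often left unstated, so this default is documented as the
package's own choice, and a fit-on-receptor variant can be composed from
`kabsch_superpose()` directly. No mass weighting is applied (Cα-only
selections make it nearly irrelevant). The RMSD fast path forms residuals
explicitly after rotation rather than using the singular-value identity,
which keeps rigid-motion invariance at the 1e-12 nm level even for widely
spread coordinates.

`aggregate_rmsd()` reports the pointwise mean and the *population*
variance across trials (divide by the number of trials): the variance
band is a descriptive spread of the trials actually run, not an estimate
for hypothetical further trials, and a single trial then has zero
variance by construction.

**Contacts.** Two residues are in contact when their Cα atoms are within
0.8 nm; the comparison is strict (`d < 0.8`, a pair at exactly the cutoff
is not in contact — a convention that must be fixed somewhere, is
documented here, and is pinned by a test). Frequencies are computed per
trial over retained frames and then averaged over trials; with equal
frame counts per trial this equals pooling all frames, and the suite
asserts both paths agree. Scores are normalized 0–1 by construction: 1
means continuous contact over all trials, 0 means never observed. The
default burn-in discards a fixed 500 frames, a conservative bound for
equilibrated production runs of this length; a rolling-mean plateau detector
(`detect_burn_in()`) is provided but off by default because a fixed
discard is reproducible across ensembles. All frames after burn-in are
used (stride 1). Only cross-chain (receptor × peptide) pairs are
reported.

**Pose ranking.** `rank_pose_stability()` orders poses by time-mean
peptide RMSD (drift), then across-trial variance, ascending — the reading
that "most stable" means smallest drift from the predicted structure with
the most reproducible trials — with exact ties broken by the largest
contact-map entry (descending) and finally pose label. Exact ties do not
arise in continuous data; the comparator is exposed as
`rank_pose_table()` so the tie-break semantics are testable.

**Static contacts.** For predicted static complexes,
`static_contacts()` reimplements the van der Waals overlap criterion:
atoms in different chains are in contact when
`r_i + r_j − d_ij ≥ −0.40 Å`, with Bondi-style radii bundled in
`vdw_radii()`. Pairs overlapping by 0.6 Å or more are additionally
flagged as clashes. Units follow each file family's native convention:
trajectory math in nm, static-structure math in Å.

## Equilibrium binding

SPR equilibrium responses from a two-flow-cell instrument decompose as
specific binding plus a nonspecific term common to the blank reference
channel. `reference_subtract()` takes measurement minus reference per
concentration; negative specific responses are flagged but retained,
because clipping would bias the fit near zero. `fit_saturation()` then
fits the one-site Langmuir isotherm `R(C) = Bmax·C/(K_D + C)` by
Levenberg–Marquardt least squares, unweighted by default (the instrument
noise model is unknown; inverse-variance weights can be supplied), with
Wald confidence intervals from the asymptotic covariance. Only the
equilibrium model is fitted — no association/dissociation kinetics — as
the quantity of interest is the dissociation constant at equilibrium.
A K_D estimate outside `[min(C)/10, max(C)·10]` triggers a
"poorly constrained" warning rather than an error: the fit is reported,
the user is told not to trust it.

The synthetic titration uses a two-fold series from 0.29 μM whose ninth
point lands at 74.24 ≈ 75 μM, matching the span this interaction was
titrated over; real input
files carry their own grid. `dose_response_check()` covers the simpler
dot-blot dilution series with a one-sided Spearman test; note that with
only three dose levels a perfect ranking cannot reach p < 0.05, so a
perfect rank correlation is accepted as dose-dependent directly (the
verdict rule is p < α *or* ρ = 1).

## Turnover kinetics

Chase courses are modeled as a single exponential,
`N(t) = 100·2^(−t/t½)`; one half-life per condition is the reported
quantity and nothing in the data here supports more structure. The
default fit is linear regression of log abundance on time through the
origin: the course is anchored at 100% at t = 0 by its own
normalization, the log transform linearizes the model, and multiplicative
densitometry error becomes approximately homoscedastic. A raw-scale
nonlinear fit (`method = "nls"`) and a plateau-offset variant
(`model = "plateau"`, reported with AIC next to the single exponential)
are options. Half-lives are fitted on pooled replicate points by default;
per-replicate fitting is a trivial `group_by` + `group_map` composition
left to the caller.

Densitometry normalization divides each band by its lane's loading
control and anchors the designated reference (t = 0, or the wild-type
untreated condition) at 100%, matched within replicate so global
per-replicate intensity scaling cancels. Co-IP association normalizes
immunoprecipitated signal to the input level of the same protein and
scales the wild-type mean to 100%, with negative-control lanes reported
but excluded from scaling. `compare_stabilization()` runs the genotype ×
treatment two-way ANOVA with Tukey (default) or Bonferroni post hoc —
both are standard in this literature, so the choice is a config switch — and
collapses to Student's unpaired t test when the design is two groups.
Pairwise reporting is restricted to contrasts sharing a factor level;
cross contrasts (different genotype *and* different treatment) answer no
question asked here.

## The synthetic-data generators

The generators exist so every analysis function can be exercised against
known ground truth. Their defaults encode the study conditions of the
motivating system: a 12-position × 20-residue array spanning residues
5–16 with the essential-cysteine/charge-enhancement pattern
(`rgs2_degron_profile()`), nine replicates (three experiments × three
technical replicates, flattened), a 0.29–75 μM two-fold SPR series at
K_D 2.1 μM, chase timepoints {0, 10, 20, 30, 45, 60} min at half-lives
19.5 and 33.5 min (the exact published timepoints are not printed; this
grid is a configurable stand-in), and 5 poses × 4 trials of trajectory
frames saved every 10 ps. Noise defaults are mean-one multiplicative
lognormal for fluorescence and densitometry (positive, right-skewed
signals) and additive Gaussian for SPR response units; fluorescence noise
of 15% CV and chase noise of 5% are realistic for quantified blots and
arrays. One integer seed fans out to per-generator substreams, so the
four assays are jointly reproducible but mutually independent, and the
caller's RNG state is restored afterwards.

Trajectories are kinematic toys, not physics: the receptor is rigid, each
prescribed contact pair toggles between placements at 0.5 and 1.5 nm from
its partner (inside/outside the 0.8 nm cutoff), unlisted cross-chain
pairs stay beyond 1.2 nm by construction, and with zero noise the first
`⌈f·n⌉` frames of a trial are in contact so the realized occupancy is
exact to 1/n (a random frame subset under noise). Planted conformational
"drift" is a radial dilation of the peptide about its centroid growing
linearly over frames — a *non-rigid* deformation, because any rigid
motion vanishes under superposition — calibrated so the final-frame
peptide RMSD equals the drift parameter in nm exactly. Contact guarantees
hold exactly only at zero drift, since dilation moves peptide residues.

What passing tests on these generators shows: the estimators recover
known effects, rates and constants at realistic noise, control their
type-I error on null arrays, and agree with independent brute-force
oracles. What it does not show: robustness to spatial artifacts on real
arrays (spot morphology, edge effects, carryover), SPR drift and
regeneration failures, partially folded trajectory starts, or saturated
blots. Those require instrument data and upstream QC that are out of
scope here.

## Degron spelling

Two spellings of the example degron circulate, `MFLAVQHDCRPM` and
`MFLAVQHDRCPM` (cysteine and arginine at positions 13/14 transposed).
The residue roles (Asp12, Cys13, Arg14) identify the former as canonical,
and `rgs2_degron_sequence()` returns it; the constructors accept the
transposed variant but warn, rather than silently correcting, since a
user may genuinely mean the swapped peptide.

## Problem sizes and determinism

The shipped tests and the acceptance script run entirely on synthetic
data at desk scale, chosen as the smallest sizes at which the statistical
claims are meaningful: 100 seeded repetitions for Monte-Carlo recovery of
K_D and half-lives, 200 null arrays for the type-I bound, 100 seeded
ensembles (5 poses × 4 trials × 40 frames) for ranking recovery, and
brute-force oracle comparisons on ensembles up to 20 residues × 50
frames. Identical seeds give bit-identical generator output; all
stochastic assertions in the suite are made under fixed seeds.

## Known limitations

* The array ANOVA treats normalized replicate values as exchangeable
  across experiments (flattened replicates); a nested
  experiment/technical error structure would need a mixed model, which
  the pooled data here cannot identify.
* Wald intervals for K_D and t½ are symmetric on the parameter scale and
  degrade for poorly constrained fits; profile likelihood would be
  preferable near the data's resolution limit.
* `static_contacts()` is all-pairs and intended for interfaces of
  hundreds to a few thousand atoms, not whole proteomes.
* The PDB trajectory writer emits Cα-only pseudo-residues (GLY records);
  it is an exchange format for these coarse ensembles, not a general
  structure writer.
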