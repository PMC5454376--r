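---
title: "Mapping GBA-motif binding on Gαi3 from NMR peak lists: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping GBA-motif binding on Gαi3 from NMR peak lists: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbamap)
```

## The problem

A GBA motif docks onto the SwII/α3 cleft of Gαi and acts as a
guanine-nucleotide exchange factor. Where exactly it binds, and how its
binding propagates to the nucleotide pocket, can be read out at residue
resolution from ¹H–¹⁵N TROSY spectra of isotope-labelled Gαi3: signals
of residues at or near the interface shift (chemical shift
perturbation, CSP) and broaden (intensity loss) when the ligand is
added. `gbamap` turns a published assignment table plus experimental
peak lists into per-residue perturbation classes, projects them onto
annotated sequence regions and a structure, and scores the downstream
mutant panel. This vignette explains the model assumptions, the
tunable parameters, the synthetic data that back the tests, and the
design decisions that were genuinely open.

## Metrics

All matching and perturbation metrics live in one scaled shift space,
`d = sqrt(dH^2 + (s*dN)^2)` with nitrogen weight `s = 0.2`, reflecting
the roughly five-fold larger dispersion of amide ¹⁵N shifts. The CSP of
a residue is the same distance between its free and bound positions
with an averaging divisor:

```{r}
compute_csp(8.10, 120.5, 8.00, 120.0)   # dH = 0.10, dN = 0.50 -> 0.1 ppm
```

The weighting constant and the divisor are conventions, not physics:
changing them (e.g. weight 0.14, no averaging) rescales every CSP by a
common factor, which the median-multiple classification below absorbs
almost entirely. Both are exposed (`n_weight`, `averaging`).

Intensity perturbation is the ratio `I_ratio = I_free / I_bound` after
dividing each spectrum's intensities by its reference signal — the
C-terminal Y354 amide, a narrow, isolated, binding-inert signal — so
that arbitrary spectrometer scaling cancels. Bound intensities below 1%
of the free intensity, including signals broadened beyond detection,
are treated as exactly 1%, capping `I_ratio` at 100 (`log10 = 2`). The
floor makes disappearance a first-class, bounded observation instead of
a division blow-up; it also gives `I_ratio` a bounded heavy tail, which
is why profile correlations default to `log10(I_ratio)`.

Significance is defined against each metric's own median M over
residues with data: strong above 10 M, medium above 5 M, weak above
3 M, below otherwise; residues without a reliable measurement are
no-data. The thresholds act on the linear metric scale — the
median-multiple wording reads most naturally on the metric itself, and
on the log scale the same rule would compress the classes into
near-indistinguishability. The composite class is the larger of the
CSP and I_ratio classes, with no-data acting as absence.

## Assignment transfer and offsets

Experimental spectra carry a systematic referencing offset relative to
published shifts. The estimator alternates mutual-nearest-neighbour
matching (gate 0.5 scaled ppm) with a median update of the offsets
until both change by less than 0.001 ppm (at most 20 iterations).
Medians, not means: binding-site peaks genuinely move and would bias a
mean. The iteration is initialized from the difference of the two point
sets' marginal medians rather than from zero; that initialization is
itself translation-equivariant, which makes the whole estimator exactly
equivariant — an invariant the test suite checks literally.

Transfer then assigns each reference entry to its nearest experimental
peak within `r_accept = 0.05` scaled ppm, one-to-one, greedily by
ascending distance. A match is committed only when it beats every
competitor for the same peak or the same reference by an ambiguity
margin (0.02 scaled ppm, about the peak-position noise between two
spectra); otherwise all parties are refused and reported. Refusal over
completeness: a swapped assignment is silent and poisons every
downstream number, a refused one is a grey residue. At margin zero the
rule degenerates to refusing exact ties (1e-9 ppm).

## Bound-form assignment and titration tracking

A single free→bound nearest-neighbour jump cannot assign peaks whose
CSP exceeds the peak spacing, so the bound form is assigned the way the
underlying experiment supports: by following each signal stepwise
through the titration (molar ratios 1:0, 1:0.2, 1:0.5, 1:1, 1:2, 1:5).
Under fast exchange the observed position is the population-weighted
average `δ_free + f_bound·Δδ`, so per-step movements are a fraction of
the full CSP and stay inside a gating radius (0.08 scaled ppm).

Position alone cannot distinguish two signals crossing each other, so
the per-step cost adds an intensity-continuity penalty of 0.03 scaled
ppm per natural-log-fold of intensity change: intensities evolve
smoothly along a titration while unrelated signals typically differ in
height. Three further safeguards deal with crowding:

- contests decided by less than the ambiguity margin are refused for
  that step; the contested peak stays unclaimed and the trajectories
  coast at their previous position and compete again next step;
- unassigned and unclaimed peaks are followed as anonymous
  trajectories, so a moving peak cannot silently adopt a stray signal
  whose owner simply was not tracked;
- every endpoint is re-tracked backwards through the series and must
  return to its own free-form position within 0.03 scaled ppm
  (forward–backward consistency).

A trajectory with no candidate in the gate is lost — interpreted
downstream as broadened beyond detection and floored at
`I_ratio = 100`. A trajectory that ends unresolved (still coasting) or
fails the round-trip check is something else entirely: an unreliable
measurement, reported as no-data. Free-form peaks closer than 0.03
scaled ppm to a neighbour are likewise excluded up front, because any
assignment between them is an arbitrary choice. These no-data outcomes
are the synthetic analogue of the grey "no reliable measurement"
residues every crowded spectrum produces.

## Region summaries and structure mapping

Per-segment summaries count residues per class; a segment is
"perturbed" when every residue with data exceeds `below`, "unperturbed"
when none does, "mixed" otherwise. Composite classes are written into
the B-factor column of a copy of the structure (−1 = no-data …
3 = strong): integer codes survive any viewer bit-exactly, unlike
viewer-specific colouring scripts. Sequence numbering follows UniProt
P08754 throughout; mapping to a differently numbered structure is a
single explicit offset.

## The mutant panel

Fluorescence-polarization curves (titrant 0–8 µM, probe 0.025 µM) are
fit to `R = R_min + (R_max − R_min)·[G]/(K_d + [G])` by
Levenberg–Marquardt least squares, multi-started from K_d at 0.1, 1 and
10 times the median concentration and bounded to [1e-4, 1e4] µM. The
free ≈ total approximation is adopted deliberately: the probe sits at
least four-fold below the smallest non-zero titrant concentration, so
ligand-depletion correction would change K_d by less than the fit
noise. A fit is saturating when the fitted fractional occupancy at the
top concentration reaches 90% (configurable); mutants that do not
saturate are refit with the plateau pinned to the wild-type's
normalized 100% value, since their own plateau is not identified by the
data. Both fixed and floating baselines are supported (`fix_rmin`).

Fold-change classes use strict inequalities — impaired above a K_d
ratio of 2, enhanced below 0.5, boundary values neutral — and the
cross-ligand Pearson correlation runs over mutants only (wild type is
identically zero in both columns and would inflate r). GEF activity is
expressed as percent of each variant's own basal activity; inhibition
is defined on activation deltas, not raw activities, because a mutant
with low basal activity but intact coupling should not score as
inhibited. Variants with non-positive basal activity are ND.

## Synthetic study conditions

The generators are pure functions of (parameters, seed) and every
injected quantity is recorded in a truth object, so each pipeline stage
can be scored without re-reading generator internals. The shipped
profiles fix the study conditions:

- amide shifts: ¹H ~ N(8.3, 0.5²) on [6.5, 10.5] ppm, ¹⁵N ~ N(119, 4²)
  on [103, 135] ppm; 250 of 354 residues observed; three Trp indoles;
  the reference Y354 redrawn until isolated by 0.1 scaled ppm (that
  isolation is what makes it usable as an intensity standard);
- referencing offsets +0.09 / −1.1 ppm; position noise σ_H = 0.01,
  σ_N = 0.05 ppm; intensity CV 5%, free intensities lognormal
  (sdlog 0.4);
- global attenuation lognormal with median 3.0 (`givct`) or 1/0.85
  (`givpept`, i.e. a median 15% intensity decrease) and shape 0.35;
  W211 and W258 broadened beyond detection;
- binding site: all of the P-loop, SwI and SwII segments plus a seeded
  sample from β1, α3 and the α3–β5 loop, sized so the expected shifted
  fraction is 15% of observed residues; site CSP magnitudes lognormal
  around a median of 0.15 ppm (sdlog 0.4), direction uniform in the
  scaled plane;
- titrations from the exact one-site equilibrium (quadratic solution
  with ligand depletion; protein 32 µM, K_d 10 µM by default);
- FP panel: 12 mutants × 2 ligands with bivariate-normal log₂ K_d
  effects (correlation 0.97, sd 2), responses 20–180 units with 2%
  multiplicative noise; activity deltas shrink with binding impairment.

These values were fixed once as plausible study conditions; the
region annotation (G-boxes, switches, helices in P08754 numbering) is a
shipped demonstration table. The problem sizes used throughout the
tests and the acceptance script — 250-residue tables, 150 residues for
offset recovery, 20 seeds, 50 noisy binding curves — are the package's
chosen simulation scale.

## What the synthetic data do and do not show

The generators emulate the statistical structure the analysis assumes:
Gaussian position noise, lognormal intensities and attenuation, fast
exchange, one-site binding, multiplicative assay noise. They do not
simulate lineshapes, relaxation, intermediate/slow exchange (split or
coalescing peaks), temperature or pH drifts between spectra, spectral
artifacts, or 3D experiments. Passing tests therefore demonstrate that
the pipeline recovers what it is designed to recover under its own
stated assumptions — not that those assumptions hold for any given real
spectrum. One consequence is visible in the end-to-end demo: with 250
peaks in a realistic shift window, coincidental overlaps are common
enough that the tracker must refuse or discard a fraction of residues,
and across random seeds the full pipeline reproduces the expected
G-box contrast (phosphate-side elements perturbed, guanine-side G-4 and
G-5 silent) in roughly three quarters of runs, with the failures being
honest no-data segments or near-threshold noise rather than wrong
positives. The shipped demonstration configuration (default seed) is
one of the reproducing runs; in the real experiment this residual
ambiguity was resolved with 3D spectra, which have no peak-list-level
counterpart and are out of scope here.

## Numerical and degenerate-input choices

- Missing intensity is `NA`, distinct from an observed zero; zero is
  routed to the detection floor.
- An all-zero CSP vector would make M = 0; classification then returns
  all `below` with a warning unless an explicit epsilon is supplied.
- Ties and near-ties in matching are refused, never broken arbitrarily;
  determinism and order-independence are tested properties.
- Peak lists are written with full double precision (`%.17g`) so
  read–write–read round trips are bit-identical.
- The provenance record contains the configuration echo, package
  version and seed but no timestamp, so identical runs are
  byte-identical.
- K_d fits hitting the box bounds are flagged unreliable and excluded
  from fold-change matrices (reported, not dropped silently).

## Known limitations

Tracking operates on 2D peak lists only; systems in slow exchange, or
titrations coarse enough that per-step movements exceed the gate,
produce losses that are indistinguishable from broadening at the
peak-list level. The overlap, contest-refusal and round-trip rules
trade completeness for reliability and can leave short segments without
data in crowded spectra. The one-site binding model ignores probe
depletion and cooperative effects; the activity model treats replicate
noise as multiplicative and reports no replicate-level inference.
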