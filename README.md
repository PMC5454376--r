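# gbamap

Residue-level NMR perturbation mapping of GBA-motif binding to Gα
subunits, with the downstream mutant binding/activity panel.

GBA motifs (Gα-binding-and-activating) are ~30-residue sequences in
non-receptor guanine-nucleotide exchange factors such as GIV and DAPLE
that bind the SwII/α3 cleft of Gαi and accelerate nucleotide exchange.
`gbamap` implements the peak-list-level analysis used to localize that
binding site on ²H,¹³C,¹⁵N-Gαi3 from ¹H–¹⁵N TROSY spectra, and the
biochemical panel used to validate it by mutagenesis. It is written for
structural biologists who have Sparky-style peak lists, a published
assignment table (BMRB-style TSV), and fluorescence-polarization /
GTPase activity tables — and for anyone who wants a fully synthetic,
ground-truthed testbed for this kind of analysis.

## What it computes

**Assignment transfer with referencing-offset correction.** Published
shifts rarely share the referencing of a new spectrum. The systematic
offset (ΔδH, ΔδN) is estimated by iterated mutual-nearest-neighbour
matching in the scaled shift space `d = √(ΔδH² + (0.2·ΔδN)²)`, updating
the offsets to the medians of the matched residuals (robust against the
minority of peaks that genuinely move). Assignments are then transferred
one-to-one, greedily by distance, refusing matches that a competitor
approaches within noise.

**Titration tracking.** Bound-form signals are assigned by following
each peak stepwise through a ligand titration (molar ratios
1:0 → 1:5) under fast exchange, with an intensity-continuity penalty,
contest refusal, and a forward–backward round-trip check; peaks that
vanish are treated as broadened beyond detection.

**Per-residue perturbation statistics.** For each residue,

- CSP = √((ΔδH² + (0.2·ΔδN)²)/2), the weighted average shift change;
- I_ratio = I_free/I_bound on intensities normalized to an unperturbed
  reference signal (Y354), with bound intensities below 1% of free
  floored so that I_ratio = 100 exactly;
- five-level classes against multiples of the median M of each metric:
  strong (>10 M), medium (>5 M), weak (>3 M), below, no-data; the
  composite class is the larger of the CSP and I_ratio classes.

Classes are summarized over annotated regions (G-1…G-5 boxes, switches,
secondary structure) and written into the B-factor column of a PDB copy
(no-data = −1 … strong = 3).

**Mutant panel.** Fluorescence-polarization curves are fit to the
one-site hyperbola `R = R_min + (R_max − R_min)·[G]/(K_d + [G])` with
WT-plateau normalization for non-saturating mutants; the variant ×
ligand matrix of log₂(K_d^mut/K_d^WT) carries fold-change classes
(impaired > 2-fold, enhanced < 0.5-fold) and cross-ligand Pearson
correlations. GEF activity is expressed as percent of basal, with
inhibition classes (moderate 30–50%, strong >50%, ND when basal
activity is compromised).

**Synthetic data.** Every stage has a seeded generator with recorded
ground truth: amide shift tables, free/bound pairs with lognormal
attenuation and binding-site CSPs, fast-exchange titrations from the
exact one-site equilibrium, FP curves, and activity tables. Two shipped
profiles mirror the study conditions: `givct` (median 3-fold intensity
attenuation, W211/W258 broadened out, ~15% of residues shifted) and
`givpept` (median 15% intensity decrease, same site).

## Worked example

```r
library(gbamap)
cfg <- pipeline_config(out_dir = "results/perturbation_run", seed = 1,
                       profile = "givct", n_residues = 250)
res <- run_pipeline(cfg)
print(res$offsets)
res$regions[res$regions$name %in% c("G-1/P-loop", "G-2/SwI", "SwII", "G-4", "G-5"),
            c("name", "n_data", "top_class", "status")]
```

prints

```
offset estimate: dH = +0.0908 ppm, dN = -1.1058 ppm (n = 253)
       name n_data top_class      status
 G-1/P-loop      3    strong   perturbed
    G-2/SwI      2    strong   perturbed
       SwII     12    strong   perturbed
        G-4      3     below unperturbed
        G-5      4     below unperturbed
```

The injected referencing offsets (+0.09, −1.1 ppm) are recovered from
the peak positions alone, and the region summary shows the GBA
signature: the phosphate-side nucleotide elements (G-1/P-loop, G-2/SwI)
and the SwII cleft are perturbed while the guanine-side G-4 and G-5
boxes are untouched. `results/perturbation_run/` holds the assigned
peak lists, trajectories, the per-residue table, the region summary,
the class-coded PDB, and a provenance record; running the same
configuration twice produces byte-identical outputs.

The numbered drivers under `analysis/` run the full study:
`01_simulate.R` (fixtures), `02_perturbation_mapping.R` (the run
above), `03_profile_correlation.R` (construct vs peptide profiles,
median I_ratio ≈ 3 vs 15% decrease, Pearson r ≈ 0.99 on log₁₀ I_ratio),
`04_binding_panel.R` (K_d matrix, cross-ligand r ≈ 0.98, inhibition
classes).

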