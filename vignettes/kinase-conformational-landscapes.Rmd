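---
title: "Classifying and comparing kinase conformational landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying and comparing kinase conformational landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinconform)
library(dplyr)
```

## The problem

Protein kinases switch between active and inactive conformations of their
catalytic domain, and the switch is read off two structural elements: the
DFG motif (Asp-Phe-Gly) at the start of the activation loop, whose Phe can
sit under the αC helix ("DFG-in") or flip into the ATP pocket ("DFG-out"),
and the αC helix itself, whose conserved Glu either forms the catalytic salt
bridge with the β3 Lys ("αC-in") or swings away ("αC-out"). Crossing the two
axes gives four named states — CIDI, CIDO, CODI, CODO — plus an intermediate
DFG placement (DFGinter) and an Unassigned sink, the six-way vocabulary this
package uses throughout. The DFG-out states matter practically: they open
the back pocket targeted by type-II inhibitors. A second, softer axis is the
activation loop itself, which is "extended" in active structures and
"folded" in many inactive ones.

The package provides a self-contained pipeline over this vocabulary:
structure parsing (PDB/mmCIF), motif anchoring, geometric classification,
distribution statistics across structure sources and MSA depths,
novel-conformation accounting at pLDDT confidence thresholds, TM-score
similarity with the model as reference, and virtual-screening enrichment
AUCs — together with a synthetic-data generator that makes every stage
testable without downloading a single structure.

## The geometric classifier

Published conformational assignments of this kind are usually delegated to
external classifiers trained on the PDB. This package instead defines an
explicit, self-contained geometric contract. For a structure with anchored
motifs it computes:

* `dihedral_x`: the Cα pseudo-dihedral over DFG-Asp, DFG-Phe, DFG-Gly,
  DFG+1 — the torsion that tracks the DFG flip;
* `dihedral_y`: the Cα pseudo-dihedral over DFG−2, DFG−1, DFG-Asp, DFG-Phe;
* `d1`: distance from the Cα four residues after the αC Glu to the tip of
  the DFG Phe (short when the Phe packs under the helix, i.e. DFG-in);
* `d2`: distance from the β3 Lys amine to the Phe tip (short when the Phe
  occupies the ATP pocket, i.e. DFG-out);
* `salt_bridge`: minimum distance from the αC-Glu carboxyl oxygens to the
  Lys NZ;
* `loop_dist`: Cα distance between the HRD−2 and DFG+2 residues.

The decision rules, all exposed in `conformation_config()`:

| state | rule (defaults) |
|---|---|
| DFG-in | `d1 <= 11` Å and `d2 > 11` Å |
| DFG-out | `d1 > 11` Å and `d2 <= 11` Å |
| DFGinter | both `<= 11` Å |
| unassigned | both `> 11` Å, or a metric unavailable |
| αC-in | `salt_bridge <= 4.5` Å (Cα fallback `<= 12` Å, flagged) |
| extended loop | `loop_dist <= 10` Å (boundary inclusive) |

The 11 Å anchor-distance cuts sit between the short (~5–9 Å) and long
(~13–18 Å) regimes the two DFG placements produce for these particular
anchor atoms; 4.5 Å is the conventional outer limit for a formed salt
bridge between charged side-chain atoms; and 10 Å splits the ≈7 Å extended
activation-loop regime from folded loops. DFGinter outranks the αC state
because the six-label vocabulary does not split the intermediate placement;
a DFG call with an undetermined αC state falls to Unassigned with a cause
flag rather than guessing. Degenerate dihedral geometry (zero-length
virtual bonds, collinear triples) raises an error rather than silently
returning 0, and classification then falls to the sink state.

The pseudo-dihedral uses the IUPAC sign convention (cis = 0°, trans = 180°,
right-handed positive) on the range (−180°, 180°], and the suite checks it
against an independently derived frame-projection oracle to 10⁻⁹ degrees.

## Motif anchoring

All metrics hang off four anchors: the DFG Asp, the HRD His, the αC Glu and
the β3 Lys. Annotation (author residue numbers in a per-kinase table) always
overrides detection; detection scans the one-letter sequence for an HRD-like
3-mer (`[HY]R[DN]`) followed 10–40 residues later by a DFG-like 3-mer
(`D[FYWL]G` — substitution-tolerant, so DYG kinases such as NEK9 still
anchor), preferring the pairing whose gap is closest to 20 residues, then
takes the last Lys in a window upstream of HRD and the first Glu in a window
downstream of that Lys. The β3 Lys is anchored explicitly even though the
αC state is conventionally described through the Glu alone: the in/out call
needs the Glu–Lys pair, and that pair is the standard geometric
operationalisation. All windows and patterns are configuration, not code.
Internally residues are indexed 0-based and contiguously, so motif
arithmetic (HRD−2, DFG+2) survives author-numbering gaps and insertion
codes. Structures that fail anchoring are excluded and counted — never
silently dropped — mirroring how kinome-wide studies report the kinases
their classifier cannot anchor.

## A worked pass through the pipeline

```{r pipeline}
ens <- make_ensemble(
  c(CIDI = 0.5, CODI = 0.2, CIDO = 0.15, CODO = 0.05,
    DFGinter = 0.05, Unassigned = 0.05),
  n = 120, noise_sigma = 0.2, seed = 42
)
calls <- classify_structures(ens$structures)
conformation_distribution(calls) |> filter(count > 0)
mean(calls$label == ens$truth$label)
```

```{r stats}
dist_shallow <- c(CIDI = 250, CODI = 120, CIDO = 80, CODO = 30, DFGinter = 20)
dist_deep <- c(CIDI = 420, CODI = 40, CIDO = 25, CODO = 10, DFGinter = 5)
tidy(bootstrap_fraction_compare(dist_deep, dist_shallow, "CIDI",
                                alternative = "greater", seed = 1))
bonferroni_threshold(0.05, choose(7, 2))
```

## Statistical conventions

* **Bootstrap fraction comparison** draws multinomial resamples from each
  distribution's fractions — each side at its own dataset size, the standard
  nonparametric choice; whether a fixed common size was ever intended is
  undocumented in the procedures this mirrors, so the package declares its
  own convention — and compares the focal label's resampled counts with a
  one-sided Wilcoxon rank-sum test (midranks, normal approximation with
  continuity correction at `n_boot >= 50`). The suite checks null
  calibration: self-comparisons reject at 5% within [1%, 15%] over 200 runs.
* **Fisher's exact test** is exact for 2×2 (verified against full
  hypergeometric enumeration to 10⁻¹⁰) and fixed-seed Monte-Carlo with
  100,000 tables beyond 2×2, declared and reproducible.
* **Chi-squared** is the plain Pearson statistic with (r−1)(c−1) degrees of
  freedom; zero-total label columns are dropped, no continuity correction.
* **Paired and one-sample t-tests** handle the degenerate zero-variance
  cases explicitly (p = 1 for no difference, p = 0 flagged `degenerate` for
  a constant nonzero difference, p = 0.5 for a constant AUC of exactly 50),
  since `t.test()` refuses constant data.
* **Multi-model averaging**: kinases with several deposited models
  contribute fractionally via 1,000 random one-model-per-kinase samples,
  repeated 10 times and averaged; single-model kinases contribute
  deterministically.
* **Novelty accounting** filters models at a strict mean-pLDDT threshold
  (`> 70` for confident, `> 90` for high-accuracy) and counts a model as
  novel when its label is absent from its kinase's experimentally observed
  label set; kinases with no experimental structure contribute all their
  confident models. Counts are monotone in the threshold by construction.
* **Unique conformations per kinase** count distinct labels among the five
  named states only: Unassigned is a sink, not a conformation.

All randomised routines take explicit seeds and are bit-reproducible; no
hidden RNG state is used.

## TM-score conventions

`tm_score(model, other)` normalises by the length of its *first* argument
and takes `d0 = 1.24 (L−15)^{1/3} − 1.8` Å floored at 0.5 Å — so using the
predicted model as reference excludes flexible insertions unresolved in
experimental partners from inflating the score. Correspondence is by author
numbering over an identical construct rather than sequence alignment, which
is the regime these comparisons target (same kinase, same expression
construct; unmatched residues are dropped from the pairing but still count
in the reference length). The reported score is the maximum over a
superposition search: the one-shot global Kabsch fit plus fits seeded on
contiguous fragments of full, half and quarter length, each refined by
re-superposing on pairs within a distance cutoff schedule `d0, 2d0, 4d0`
until the retained set stabilises. This replicates the spirit of
TM-align's superposition search with a fixed alignment, and by construction
the result can never fall below the one-shot global fit — a property the
suite asserts on 50 hinge-perturbed synthetic pairs. Comparisons are gated
on an identical DFG-position 3-mer, and equal best scores break toward the
earliest target identifier.

## Enrichment conventions

Docking scores are lower-better by default; each compound keeps only its
best pose; tied scores share the midpoint position (realised by linear
interpolation of the trapezoid across the tied block — unbiased for the
rank-AUC identity); and the AUC is the trapezoidal area under the full
retrieval curve, scaled to 0–100 so that 50 is random. With 50 actives
ranked strictly above 2,500 decoys the analytic area is 99.02, and the
integration/tie policy can shift an AUC by under one unit at these dataset
sizes. For Normal active/decoy scores the closed form
`100 Φ((μ_D − μ_A)/(σ√2))` gives the expected AUC, which estimated AUCs
match within ±1.5 over 100 seeded tables. Stratified summaries report mean,
sample standard deviation (n−1; a single model reports 0 with a flag) and
maximum per kinase, conformation, or mean-pLDDT tier (`100 > x ≥ 90`,
`90 > x ≥ 80`, `80 > x ≥ 70`, boundaries upward).

## What the synthetic generator does and does not emulate

`make_structure()` inverts the classifier's geometry: the metric-defining
atoms are placed analytically (torsion-chain construction for the two
dihedral windows; exact distance placement for the Phe tip, Lys NZ, Glu
OE1/OE2 and the two loop Cαs) so the requested metrics are realised exactly
at zero noise, and the remaining Cα trace is threaded smoothly through the
anchors with the planted K/E/HRD/DFG sequence. Label-conditioned sampling
draws geometry from the label's interior region, at least 1 Å / 10° from
every decision boundary, which makes round-trip tests sharp; boundary
behaviour is tested separately with explicit geometries. Virtual bond
lengths are near 3.8 Å along constructed segments but only approximate
between distant anchors at extreme geometries; no Ramachandran or packing
realism is claimed, and predictor error modes (e.g. the correlation of
pLDDT with accuracy) are not simulated. Passing round-trip tests therefore
demonstrates the internal consistency of generator and classifier and the
correctness of the geometry code — not classifier accuracy on real kinases,
which depends on thresholds calibrated against experimentally classified
structures.

`make_model_manifest()` emulates the bookkeeping shape of a kinome-scale
prediction campaign: 497 kinases, up to 5 models each at MSA depths
{2, 4, 8, 16, 32, 128, 512}, a 12/497 anchoring-failure fraction excluded
everywhere, optional per-depth dropouts (so a depth can classify 2,420
rather than 2,425 models), conformational diversity decreasing and model
confidence increasing with depth, and a configurable fraction of kinases
with no experimental reference. The per-depth label probabilities and
pLDDT means are this package's realistic defaults, documented in
`default_depth_probs()`, not fitted to any dataset.

## Problem sizes and numerical choices

The test suite generates everything it consumes: 600-structure ensembles
for classifier round-trips (noiseless and σ = 0.2 Å), 50 structure pairs
for TM dominance, 100 random 2×2 tables for the Fisher oracle, 200
bootstrap self-comparisons for null calibration, and 1,000 score tables of
50 actives / 2,500 decoys for the random-enrichment baseline — sizes chosen
to make the Monte-Carlo bands tight while a full check runs in minutes on
one CPU. Coordinates are written in PDB fixed precision (10⁻³ Å), which
bounds file round-trip error; all internal geometry is double precision.

## Known limitations

* The classifier thresholds are a declared geometric contract, not a
  re-derivation of any published classifier's decision boundaries;
  agreement with reference assignments on real PDB entries is a calibration
  exercise requiring downloads and is intentionally out of scope here.
* Residue correspondence for TM-scoring assumes an identical underlying
  construct; no sequence alignment is performed.
* Multi-model files (NMR-style) use the first model only; multi-copy
  entries reduce to one chain (the requested chain, else the first with a
  Cα).
* The enrichment module consumes score tables; docking, ligand preparation
  and decoy generation live upstream.
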