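---
title: "Disorder and conditional folding from predicted structures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disorder and conditional folding from predicted structures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afdisorder)
```

## The model

`afdisorder` derives intrinsic-disorder and conditional-folding predictions
from a single predicted structure model per protein. It assumes the input is
an AlphaFoldDB-style single-chain model: heavy atoms only, per-residue pLDDT
confidence (0–100) written identically to every atom of a residue in the
B-factor column. Three per-residue scores in [0, 1] are computed.

**pLDDT score.** `1 − pLDDT/100`. Low confidence correlates with disorder;
the default decision threshold 0.312 corresponds exactly to calling residues
with pLDDT below 68.8% disordered.

**RSA score.** Predicted models render disordered segments as extended
"ribbons" around the folded core, so high solvent accessibility is a
geometric disorder proxy. Per-atom solvent accessible surface area (SASA) is
computed by Shrake–Rupley sphere sampling, summed per residue, normalised by
the maximum accessibility of the residue type in an extended Gly-X-Gly
tripeptide (clamped to [0, 1]), and averaged over a 25-residue window
centred on the residue, mirroring the profile at the termini.

**Bind score.** Disordered binding regions (conditional folding) are
exposed yet confidently modelled — accessibility says "no stable tertiary
structure" while pLDDT says "reproducible local structure". With windowed
RSA score $s$, pivot $T$ and $p = \text{pLDDT}/100$:

$$
\mathrm{Bind}(s, p) =
\begin{cases}
s, & s \le T \\
T + p\,(1 - T), & s > T
\end{cases}
$$

The $1 - T$ rescaling keeps the score in [0, 1]. The function is
discontinuous at $s = T$ unless $p = 0$; this is preserved as defined — no
smoothing of the combined score is applied, and the boundary $s = T$ takes
the accessibility branch. The pLDDT operand is the raw per-residue value:
only the RSA ingredient is window-smoothed.

Binary calls use `score >= threshold` everywhere, so a score exactly at a
threshold is a positive call.

## Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `window` | 25 | residues | RSA smoothing window (±12 around the centre); must be odd |
| `thr_plddt` | 0.312 | score | pLDDT-score decision threshold (pLDDT < 68.8%) |
| `thr_rsa` | 0.581 | score | RSA-score decision threshold |
| `thr_bind` | 0.773 | score | Bind-score decision threshold |
| `T` | `thr_rsa` | score | pivot of the Bind piecewise formula |
| `probe_radius` | 1.4 | Å | solvent probe radius |
| `n_points` | 960 | points/atom | Shrake–Rupley sample density |
| `max_asa_dialect` | `"sander"` | — | Gly-X-Gly normalisation table |
| `mirror` | `"reflect"` | — | terminus handling of the window |

The three thresholds and the window are the method's published operating
point, originally selected by F1 maximisation on curated disorder
benchmarks; `optimize_threshold()` and `window_grid_search()` re-run that
procedure on any labelled dataset. Deriving the exact numerical thresholds
requires those curated benchmark sets and the full model database, which the
package deliberately does not ship; the procedure, not the constants, is in
scope.

## Solvent accessibility: engine and dialects

SASA is computed in-package by Shrake–Rupley sampling: each atom's
solvent-expanded sphere (van der Waals radius + probe) is covered with a
golden-spiral lattice of `n_points` quasi-uniform points; a point is exposed
when outside every other atom's expanded sphere; SASA is the exposed
fraction times the sphere area. Neighbour search is restricted to atoms
within $r_i + r_j + 2\,r_\text{probe}$. An isolated sphere is exact for any
`n_points`; for occluded geometry the orientation-averaged quadrature error
decreases with each doubling of `n_points` and is below 1% of the
closed-form two-sphere value at the default 960 points.

Design choices, each switchable:

* **Radii** — a compact protein set (C 1.70, N 1.55, O 1.52, S 1.80 Å),
  unknown elements 1.8 Å. Absolute ASA therefore differs slightly from
  DSSP's values; this only matters through the RSA threshold, and
  `read_dssp_acc()` can substitute externally computed DSSP accessibilities
  for exact parity studies.
* **Normalisation table** — Sander–Rost empirical Gly-X-Gly maxima by
  default; the theoretical (Tien) table via `max_asa_dialect = "tien"`.
  Which table a given external pipeline used is rarely documented, hence
  both dialects.
* **Clamp** — RSA is clamped at 1 so the Bind formula stays within [0, 1];
  extended conformations can exceed the tabulated maxima.
* **Hydrogens** are excluded (predicted models are heavy-atom only; the rule
  exists for completeness). Unknown residues map to `X` and normalise by the
  glycine maximum.

## Window mirroring

Positions within half a window of a terminus lack neighbours on one side.
The window is completed by reflecting the profile about the terminal
residue *without duplicating it*: 0-based index $-k$ maps to $+k$ and
$N-1+k$ to $N-1-k$, applied recursively for windows wider than the
sequence. The alternative edge-duplicating convention is available as
`mirror = "duplicate"` because external implementations differ and the
choice is otherwise invisible in the output. The closed form used is
index reflection modulo $2(N-1)$ (or $2N$ when duplicating); a brute-force
reflection oracle in the test suite checks both on random sequences.

## Evaluation conventions

Evaluation follows the CAID benchmark conventions. Residues from all matched
targets are pooled into a single confusion matrix; Fmax is the maximum F1
over every distinct score cut (ties broken toward the smaller threshold);
AUC uses the rank formulation with ties counting one half. Residues with
unknown reference labels are excluded from pooling; reference targets with
no predictions affect only the coverage ratio
$|\text{predicted} \cap \text{reference}| / |\text{reference}|$ (reported to
2 decimals). Degenerate conventions: precision 0 when nothing is called,
recall 0 when there are no positives, F1 0 when both are 0; an evaluation
with no positive labels or no matched targets is an error rather than a
silent 0. A protein is "fully disordered" when at least 95% of its residues
are called positive — the fraction is a configurable dialect, since
published usage does not pin the criterion. Reference set size is treated as
data-driven throughout.

## Calibration

`optimize_threshold()` sweeps every distinct observed score (plus 0 and 1),
which contains the exact pooled-F1 optimum; a fixed-step grid is available
for parity with assessments that discretise. Ties break toward the smallest
threshold — deterministic and sensitivity-favouring. `window_grid_search()`
re-smooths the raw RSA profiles at each candidate odd width (even widths
are skipped with a warning, since a centred ±h window is odd by
construction), records pooled Fmax and F1 at a fixed threshold per window —
both are recorded because either could be the selection metric — and
returns the smallest window attaining the maximal Fmax. The expected shape
of this search on block-structured disorder is a broad plateau rather than
a sharp peak.

## Synthetic data: what it emulates and what it does not

`benchmark_suite()` generates single-chain backbone models (N, CA, C, O;
all-glycine) mixing four archetypes: fully ordered compact cores; cores
with low-confidence extended tails; two cores joined by a disordered
linker; and targets with an exposed *high*-confidence segment — the
conditional-folding signature. Core segments pack residues on a 3.8 Å
serpentine lattice so interior residues are occluded; extended segments use
3.5 Å per-residue spacing; helices use ideal geometry (1.5 Å rise,
100°/residue). B-factors carry the segment pLDDT. Coordinates get ±0.1 Å
seeded jitter; backbone offsets are staggered so no two atoms approach the
1 Å contact floor, and generation retries with fresh jitter if they do.
Two CAID-format references are written: disorder (disorder + binding
segments positive) and binding (binding segments only).

`simulate_rsa_profiles()` is a score-level generator for the window search:
targets alternate ordered blocks (~45 residues) with disordered blocks
(~20 residues); per-residue RSA is the block base level (0.40 ordered, 0.55
disordered) plus Gaussian noise (σ = 0.15), clamped to [0, 1]. The base
levels are the typical per-residue accessibility contrast between ordered
regions — a mix of buried and surface residues, hence well above zero — and
exposed linkers; with noise of comparable size, single-residue
classification is genuinely poor and window averaging is required, which is
the regime the window search is meant to probe. The domains-and-linkers
architecture mirrors how short disordered linkers sit between longer folded
domains in real proteins.

What passing synthetic tests does **not** show: real models have side
chains, heterogeneous sequences, continuous pLDDT variation and annotation
noise; real disorder references are incomplete (hence the unknown-label
machinery). The synthetic suite demonstrates that the pipeline's machinery
— parsing, SASA, smoothing, scoring, pooling, calibration — behaves
correctly and that the scores order as expected when ground truth is known
(accessibility separates disorder from order; the combined score, not raw
confidence, identifies exposed-but-confident segments). It says nothing
quantitative about benchmark performance on curated datasets.

Problem sizes used by the tests and the acceptance script — 20 synthetic
targets (~1,400 residues) for end-to-end evaluation, 20 profile targets
(~6,500 residues) for the window search, 960 sample points per atom —
are the package's chosen defaults for a desk-scale, fully reproducible
analysis.

## Numerical choices and degenerate inputs

* Score rendering in all written formats is 3 decimals, round-half-even.
* pLDDT per residue is read from the CA atom's B-factor, falling back to
  the residue's atom mean; the two agree on real model files, which write
  identical values per residue, so the rule only disambiguates hand-made
  inputs.
* Alternate locations resolve to the highest-occupancy conformer (ties by
  altloc identifier); predicted models have none, so this is defensive.
* A model without B-factors is a hard error: pLDDT is mandatory input, and
  silently treating missing confidence as 0 or 100 would corrupt two of the
  three scores.
* Window width 1 is the identity; a length-1 sequence is returned unchanged
  for any window.
* The structure parser excludes hetero/water records; a file with no
  protein atoms is an "empty model" error, and a requested absent chain is
  a lookup error.

## Known limitations

* The Shrake–Rupley engine is quadrature-based: SASA is exactly
  translation-invariant but rotation-invariant only to quadrature accuracy
  (well below 1% at the default density).
* Absolute ASA is radii-set dependent; parity with DSSP-based pipelines
  requires the DSSP adapter.
* No multi-model ensembles, no secondary-structure assignment, no
  downloading: files in, tables out.
* The Bind score's discontinuity at the pivot is intentional and inherited
  from its definition; smoothing it would change the published operating
  point.
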