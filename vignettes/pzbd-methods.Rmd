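---
title: "Methods: pZBD classification, geometry and kinetics in pzbd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pZBD classification, geometry and kinetics in pzbd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pzbd)
```

# The scientific problem

Bacterial glutamyl-tRNA synthetase (GluRS) carries, inside its N-terminal
catalytic domain, a putative zinc-binding domain (pZBD): two helices (H4,
H5) capped by two short beta-strands (E3, E4). In *E. coli* the pZBD
chelates a Zn²⁺ ion through a gapped cysteine/tyrosine motif (a "ZB-motif"
such as `CxCx20Yx3C`), positions the tRNA^Glu acceptor arm, and couples to
the amino-acid site. Yet across bacteria the picture is heterogeneous: many
GluRS have no recognisable ZB-motif, a few have a shortened pZBD, and a
handful have lost the domain entirely — while remaining functional enzymes.
This package implements the computational side of that analysis as a
reusable, fully tested pipeline:

1. **Motif scanning** — parse ZB-motif notation into executable gapped
   patterns and scan protein sequences for exact and near-miss
   ("disrupted") matches.
2. **Domain classification** — extract the pZBD from anchor-annotated
   alignments, measure its length, and assign each sequence to one of five
   groups (canonical motif, modified motif, motif-free long, motif-free
   short, deleted).
3. **Structural geometry** — detect, from 3D coordinates, the features that
   substitute for zinc in zinc-free pZBDs: long-range side-chain H-bonds,
   the Tyr–(i+4) backbone H-bond, Arg–aromatic cation–π contacts, plus zinc
   coordination spheres and anchored rigid superposition.
4. **Genomic context** — test whether pZBD deletion co-occurs with
   redundancy or disruption of the indirect glutaminylation pathway
   (GlnRS/GluRS2 presence, gatCAB, tRNA^Gln 1/72 identity).
5. **Kinetics and thermodynamics** — fit depletion-aware 1:1 binding
   isotherms and Michaelis–Menten kinetics, and derive catalytic
   efficiencies, fold changes, ΔΔG values and zinc stoichiometries.
6. **Synthetic data** — generate every input class with known ground truth
   so each stage is testable offline.

# Motif model

A ZB-motif is an ordered list of anchored residue sets separated by bounded
wildcard gaps. In the notation (`parse_pattern()`), `x` is exactly one
arbitrary residue, `xN` exactly `N`, and `xA-B` any count in `[A, B]`. Gap
subscripts are positional: a gap of 20 means exactly twenty residues of any
identity, a reading consistent with the fixed spacings seen in
structure-based alignments of the motif-bearing domains.

Decisions worth knowing:

* An `X` (unknown residue) in a sequence never satisfies an anchored
  position — anchors must be observed — but wildcard gaps may span `X`,
  because gaps only consume positions.
* All overlapping matches are reported; classification uses only the
  existence of a match, with catalog order (canonical before modified)
  as the priority rule.
* The shipped catalogs are: bacterial GluRS `CxCx20-21Yx3C` (group I) and
  `CxCx20Yx3H` (group II); bacterial Glu-Q-RS `CxCx11-28Yx3C`; archaeal
  GluRS `CxCx14CxC` and `CxCx14CxH`; eukaryal GluRS `CxCx20Yx3C` and
  `CxCx20Cx3C`. User catalogs load from YAML (`read_catalog_yaml()`).
* The *E. coli* motif is sometimes written in an alternative long form
  ending `...CxH` (the histidine after the fourth cysteine). The catalog
  keeps the four-anchor form; the trailing histidine is outside the
  pattern. `find_disrupted()` reports near-misses (≥ 2 matching anchors)
  such as the `CxMx20Yx3W` disruption, for description only — never for
  group assignment.

The scanner is an anchored candidate-position join; the test suite holds it
against an independent naive enumerator over every start position and gap
combination (exhaustively for all 4-letter-alphabet strings up to length 8
with compact test patterns, and on 10,000 random sequences up to length 40
with the real catalogs — sizes chosen to keep the default suite fast while
still covering every code path).

# Domain extraction and the five groups

The pZBD window is the ungapped residue stretch *strictly between* the last
column of strand E3 and the first column of strand E4; the anchors are
user-supplied alignment columns (`anchor_spec()`, YAML-loadable). The
strands themselves are excluded because deleted-pZBD sequences retain E3
and E4 — counting them would make "deleted" lengths nonzero. Secondary
structure is never inferred; the anchors come from a structure-based
alignment.

Group assignment (`assign_group()`) is motif-first: group I or II when the
taxon's pattern matched inside the pZBD window (scanned with a 3-residue
margin on each side, so an anchored residue on a strand edge still counts).
Motif-free sequences are split by length: 0–17 is group V ("deleted"),
31–36 group IV ("short"), and ≥ 37 group III ("long"). Observed length
distributions are bimodal with motif-free populations near 10–17, 31–36 and
above ~46; the 18–30 zone has no observed members, so rather than silently
misfiling a novel length the classifier flags it `"unassigned"`. Motif-free
lengths 37–45 go to group III, whose distribution extends below the
46-residue mode.

# Geometric detectors

Thresholds are standard structural-biology practice, not fitted values, and
all are exposed as arguments:

| quantity | default | unit |
|---|---|---|
| Zn–ligand distance (`detect_zn_site`) | 2.8 | Å |
| heavy-atom H-bond distance (`detect_hbonds`) | 3.5 | Å |
| long-range separation (|i−j|) | ≥ 5 | residues |
| cation–π centroid distance (`detect_cation_pi`) | 6.0 | Å |
| cation–π normal angle | ≤ 45 | degrees |

Residue separation uses ordinal indices within a chain rather than author
numbering, so numbering gaps and insertion codes cannot corrupt the
long-range flag ("more than four residues apart" is implemented as
|i−j| ≥ 5). Hydrogens are ignored; donor/acceptor chemistry is simplified
to heavy N/O atoms with at least one side-chain partner. Zinc coordination
spheres are summarised by ligand element counts (e.g. `S3N1` for three
sulfurs and one nitrogen, `S3O1` for the Cys₃/Tyr sphere). Cation–π pairs
require a face-on geometry: the centroid-to-guanidinium vector within 45°
of the aromatic ring normal (computed by SVD of the centred ring atoms).
PDB input is parsed with `bio3d`; only the first MODEL is used and
alternate locations collapse to the highest-occupancy atom (ties towards
altloc A).

`superpose()` is the closed-form least-squares rigid superposition
(Kabsch, via SVD of the cross-covariance, with the determinant correction
that forbids reflections). Degenerate inputs — fewer than three points or
collinear sets — are errors, not warnings, because the rotation is then
not identifiable.

# Genomic co-occurrence model

A genome's verdict is *consistent* unless its GluRS pZBD is deleted while
no direct glutaminylation route exists (neither GlnRS nor GluRS2) *and*
the indirect route is intact (gatCAB present and a compatible tRNA^Gln
1/72 pair). The 1/72 signature appears in the literature in both
orientations (U1-A72 as the requirement, A1-U72 described for one genome
as satisfying recognition), so matching is orientation-insensitive by
default; `orientation = "exact"` gives the strict reading, and the
required pair itself is a parameter. Unknown signatures (`"?"`) propagate
conservatively: the indirect route is assumed intact and the verdict is
annotated.

The association between deletion and a direct route is tested with the
two-sided exact hypergeometric (Fisher) test via `stats::fisher.test`; the
test suite validates the p-values against a from-scratch enumeration of
all margin-preserving tables to 1e-12, and checks the test's type-I rate
under an independence generator (it is conservative, as exact tests are).

# Binding and kinetic fits

`fit_binding()` fits `signal = baseline + amplitude · f(L)` where `f` is
the exact depletion-aware bound fraction

$$ f = \frac{(E + L + K_d) - \sqrt{(E + L + K_d)^2 - 4EL}}{2E}, $$

appropriate because the titrations of interest run the enzyme (0.5 µM)
well above the dissociation constants being measured (tens to hundreds of
nM); the Langmuir hyperbola `f = L/(Kd + L)` is available as
`model = "hyperbolic"` and agrees with the quadratic in the excess-ligand
limit. Which form the original titration analyses used is not documented
("standard equations, 1:1 stoichiometry"); the depletion-aware form is the
safe default at these concentrations. Starting values come from a coarse
logarithmic grid over Kd with baseline/amplitude profiled linearly, and
the final fit is bounded Levenberg–Marquardt (`minpack.lm::nlsLM`,
`Kd ≥ 0`) — deterministic, no random restarts. `fit_mm()` fits
`v = kcat·E·[S]/(Km + [S])` the same way. Both return classed model
objects with `coef`, `predict`, `summary`, `residuals` and `fitted`
methods, and asymptotic standard errors from the local quadratic
approximation.

Derived quantities: `efficiency()` is kcat/Km;
`delta_g(kd_ref, kd_variant, T) = RT·ln(kd_variant/kd_ref)` with
R = 1.987×10⁻³ kcal mol⁻¹ K⁻¹ at 298.15 K by default (the titration
temperature, 25 °C — this convention reproduces the reported ΔΔG values
even though activity assays ran at 37 °C); `fold_change()` rounds to two
significant figures by default, three where ratios are conventionally
reported so; `zinc_ratio()` inverse-predicts released Zn²⁺ from an
ordinary-least-squares standard curve of zinc-bound chromophore absorbance
at 500 nm, warning when the sample falls outside the standard range.
Recomputation from raw printed parameters occasionally differs from a
reported derived value in the last digit (e.g. 1.077 → printed 1.07;
623.5 → printed 623), consistent with truncation rather than rounding in
the source; all comparisons in `paper_numbers()` therefore use one unit in
the last printed digit.

# What the synthetic generators emulate — and what they do not

`gen_sequence_cohort()` builds ungapped sequences (flank + E3 strand +
pZBD + E4 strand + flank), plants the taxon motif for groups I/II with
uniformly sampled gap lengths, and guarantees motif-free members by
rejection sampling against the scanner. Group length ranges default to the
observed ones (46–54 for I/II/III, 31–36 for IV, 10–17 for V). Background
residues around planted motifs are drawn from an alphabet excluding C, H
and Y so a planted instance cannot be extended or duplicated by chance;
motif-free pZBDs use the full 20-letter alphabet with rejection. The
alignment is produced by right-padding pZBDs to the cohort maximum — a
crude but exactly invertible stand-in for a real multiple alignment.

What this does *not* emulate: phylogenetic covariance between cohort
members (sequences are independent), realistic amino-acid composition,
alignment uncertainty, or anchor-column error. Passing the round-trip
tests therefore shows the classifier is exact *given correct anchors*, not
that anchors are easy to obtain for real alignments; reproducing the
published group counts from the real supplementary alignments would
require those files and the authors' anchor columns, and is out of scope.

`gen_structure()` plants exact geometry (zinc spheres at chosen distances
on a tetrahedral frame, cation–π pairs at a chosen centroid distance and
normal angle) on a straight poly-alanine backbone. Coordinates are
quantized to the three decimals PDB text carries *before* the truth is
recorded, so round-trips are exact to 1e-6. The backbone is not
stereochemically realistic and detectors are validated on geometry, not
chemistry.

`gen_titration()` / `gen_mm()` / `gen_zinc()` forward-simulate the exact
fitting models with multiplicative Gaussian noise; defaults are the
wild-type study conditions (Kd 62.5 nM at E = 0.5 µM; kcat 5.3 s⁻¹,
Km 65.4 µM over 50–300 µM substrate; 0.93 Zn per protein at 10 µM). The
default titration design is a 38-point single-point-titration grid — 25 nM
steps through the sub-stoichiometric transition plus sparser plateau
points — because with the enzyme ~8-fold above Kd, depletion dominates and
only the transition region identifies Kd; with 1% multiplicative noise the
median Kd recovery error over 20 replicates is ~3%.

`gen_genome_table()` samples deletion and the direct route from a 2×2
model with a requested odds ratio (baseline route probability 0.5), then
fills gatCAB and signature fields consistently with the pathway model.
It emulates marginal association only, not phylogenetic structure among
genomes.

# Problem sizes and numerical choices

The default test suite uses: full scanner/oracle enumeration over the
4-letter alphabet to length 8 plus 10⁴ random length ≤ 40 cases; 100
random rigid transforms at tolerance 1e-6; a 212-sequence round-trip
cohort at the published composition (88/5/105/7/7); 20-replicate noise
recovery for both fits; and 1000 (tests) / 200 (report script) simulated
200-genome tables for null calibration. These sizes were chosen as the
smallest that exercise every property convincingly. Seeds are explicit
everywhere; every generator restores the caller's RNG state.

# Known limitations

* Group assignment for motif-free lengths 18–30 is deliberately
  `"unassigned"`; downstream code must handle that level.
* Only single-chain analyses are supported by the H-bond detector
  (inter-chain H-bonds are not reported); π–π and hydrophobic stacking are
  not detected at all, since no published criteria exist for them in this
  context.
* The binding fit's standard errors are asymptotic; for strongly
  depleted titrations a profile or bootstrap interval would be wider.
* Gene presence/absence flags are inputs — the package does not detect
  GlnRS/GluRS2/gatCAB genes in raw genomes, nor does it predict tRNA
  identity elements.
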