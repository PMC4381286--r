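# pzbd

Analysis toolkit for the **putative zinc-binding domain (pZBD)** of
glutamyl-tRNA synthetase (GluRS) and its relatives (Glu-Q-RS, archaeal and
eukaryal GluRS).

The pZBD — two helices capped by the β-strands E3 and E4 inside the GluRS
N-terminal catalytic domain — chelates Zn²⁺ in some bacteria through a
gapped cysteine/tyrosine **ZB-motif** such as `CxCx20-21Yx3C`, but many
bacterial GluRS carry no motif, a shortened domain, or no pZBD at all while
remaining functional. This package implements the computational analyses
behind that observation as a tested, reusable pipeline, for sequence
analysts and structural biologists studying aminoacyl-tRNA synthetase
evolution:

* **Motif scanning** (`parse_pattern`, `scan_sequence`, `classify_motif`,
  `find_disrupted`): executable gapped patterns from compact notation —
  `x` = exactly one arbitrary residue, `xN` exactly N, `xA-B` any count in
  [A, B] — with all overlapping matches reported and near-miss "disrupted"
  motifs (e.g. `CxMx20Yx3W`) listed descriptively.
* **Domain classification** (`extract_pzbd`, `assign_group`,
  `classify_pzbd`, `length_histogram`): the pZBD is the ungapped stretch
  strictly between user-supplied E3/E4 anchor columns; sequences fall into
  groups **I** (canonical motif), **II** (modified motif), **III**
  (motif-free, length ≥ 37), **IV** (motif-free, 31–36) and **V**
  ("deleted", ≤ 17).
* **Structure geometry** (`read_structure`, `detect_zn_site`,
  `detect_hbonds`, `detect_tyr_i4_hbond`, `detect_cation_pi`,
  `superpose`): zinc coordination spheres summarised by element (`S3N1`,
  `S3O1`), long-range side-chain H-bonds (|i−j| ≥ 5), the conserved
  Tyr–(i+4) backbone H-bond, face-on Arg–aromatic cation–π contacts
  (≤ 6 Å, ≤ 45°), and Kabsch least-squares superposition.
* **Genomic context** (`evaluate_pathway`, `contingency_test`): a
  pZBD-deleted GluRS is expected only where the indirect glutaminylation
  route (GluRS → GatCAB transamidation, requiring gatCAB and the tRNA^Gln
  U1-A72 identity pair) is redundant (GlnRS or GluRS2 present) or
  disrupted; association is tested with the two-sided exact
  hypergeometric test.
* **Kinetics & thermodynamics** (`fit_binding`, `fit_mm`, `efficiency`,
  `fold_change`, `delta_g`, `zinc_ratio`): depletion-aware 1:1 binding
  isotherm

  `f = ((E + L + Kd) − sqrt((E + L + Kd)² − 4EL)) / (2E)`,

  Michaelis–Menten fits `v = kcat·E·[S]/(Km+[S])`, catalytic efficiency
  kcat/Km, fold changes, `ΔΔG = RT·ln(Kd₍variant₎/Kd₍ref₎)` in kcal/mol,
  and PAR/MMTS zinc:protein stoichiometry from a standard curve.
* **Synthetic data** (`gen_sequence_cohort`, `gen_structure`,
  `gen_genome_table`, `gen_titration`, `gen_mm`, `gen_zinc`): every input
  class with machine-readable ground truth, deterministic per seed.

## Worked example

```r
library(pzbd)

## a synthetic cohort with planted groups, classified back exactly
cohort <- gen_sequence_cohort(c(I = 5, III = 4, V = 3), seed = 42)
ann <- classify_pzbd(cohort$alignment, cohort$anchors, "bacteria-GluRS")
table(ann$group)
#>   I III   V
#>   5   4   3

## a noisy fluorescence titration, fitted with the depletion-aware model
ti <- gen_titration(kd = 62.5e-9, noise = 0.01, seed = 7)
fit_binding(ti$series$ligand_conc, ti$series$signal, enzyme_conc = 0.5e-6)
#> 1:1 binding fit (quadratic model)
#>   kd = 6.731e-08 +/- 4.16e-09
#>   amplitude = -0.6057 +/- 0.005588
#>   baseline = 1.002 +/- 0.00333
```

The fitted Kd (67.3 ± 4.2 nM) recovers the planted 62.5 nM within its
standard error at 1% noise. Derived quantities follow the field's
conventions:

```r
signif(efficiency(5.3, 65.4e-6), 2)   # kcat/Km, M^-1 s^-1
#> [1] 81000
delta_g(62.5e-9, 499e-9)              # kcal/mol, +ve = unfavourable
#> [1] 1.230725
```

The packaged seven pZBD-deleted genomes illustrate the co-occurrence
logic — six are consistent with the redundancy model and exactly one
(*M. infernorum*, no GlnRS/GluRS2 yet an intact indirect route) is the
flagged exception:

```r
evaluate_pathways(pzbd_deleted_genomes())[, c(1, 2, 3, 4)]
#>   genome_id direct_gln_route indirect_route_intact consistent
#> 1       acl             TRUE                 FALSE       TRUE
#> ...
#> 7       min            FALSE                  TRUE      FALSE
```

`run_pipeline()` orchestrates classify → histogram → context end to end
with TSV outputs and a provenance log, and `paper_numbers()` tabulates
every derived study quantity recomputed from the packaged raw values with
a pass/fail column.

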