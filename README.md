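# cyclopep

Computational scaffolding for the design of head-to-tail macrocyclic
peptide binders (7–24 residues) against protein targets. Deep-learning
design pipelines for macrocycles hinge on a small set of deterministic
components around the neural networks: a cyclic relative positional
encoding that tells a structure network the chain is a ring, backbone
geometry and ring-closure validation, cyclic-aware structure comparison
and clustering to count unique shapes, coordinate-derived interface and
developability metrics, and a multi-stage selection funnel that turns
tens of thousands of design models into a dozen candidates for
synthesis. `cyclopep` implements exactly that scaffolding — the parts
that need no trained weights — for structural bioinformaticians who
build, audit or reanalyze such pipelines.

## What it computes

**Cyclic relative positional encoding.** For residues `i, j` on a ring
of length `L`, the signed offset is the shortest signed path around the
ring:

    d = (j − i) mod L;   offset = d − L  if d > L/2,  else d

so `|offset| ≤ ⌊L/2⌋` and the termini are nearest neighbours
(`offset(0, L−1) = −1`), matching a head-to-tail peptide bond. In
binder–target complexes the macrocycle block is cyclized while target
and interchain blocks keep the standard linear encoding (interchain
entries are masked sentinels).

**Backbone geometry.** `build_from_torsions()` places N/CA/C/O with
ideal bond lengths and angles from φ/ψ/ω; `ccd_close()` closes the ring
by cyclic coordinate descent; `closure_check()` validates the closing
C(L)–N(1) peptide bond (1.329 ± 0.2 Å, angles ± 15°, trans ω ± 30° by
default); `measure_torsions()` wraps φ(1) and ψ(L) across the closing
bond so a cyclic chain has all `L` torsion pairs defined;
`ramachandran_counts()` bins them.

**Comparison and clustering.** Kabsch superposition; the two Cα
r.m.s.d. conventions used for design-versus-crystal comparison
(target-aligned with minimum over binder copies, and
macrocycle-aligned); TM-score

    TM = max over correspondences of (1/L) Σ 1 / (1 + (d_i/d0)²),
    d0 = max(0.5, 1.24 (L − 15)^⅓ − 1.8)

with a search over all `L` cyclic register shifts (and optionally the
reversed ring orientation); all-by-all matrices and greedy threshold
clustering at TM 0.5 for uniqueness counting.

**Interface metrics.** Shrake–Rupley SASA on a deterministic spherical
lattice; contact molecular surface as the buried-SASA proxy
`(SASA_binder + SASA_target − SASA_complex)/2`; spatial aggregation
propensity (SAP) with Black–Mould hydrophobicity zeroed at glycine;
hotspot contact coverage at a 5 Å heavy-atom cutoff.

**Selection funnel.** Strict-threshold filtering with per-metric
failure attribution, the self-consistency criterion (some repredicted
sequence with pLDDT > 0.8 and backbone r.m.s.d. < 2.0 Å), ddG ranking,
cluster-representative selection, and named campaign presets
(`mdm2`: iPAE < 0.3, ddG < −50, SAP < 35, CMS > 300; `gabarap`:
iPAE < 0.13, ddG < −30, SAP < 35, CMS > 300; `rbta`: iPAE < 0.4,
ddG < −30, r.m.s.d. < 1.5, CMS > 300; `mcl1`: metric set only,
thresholds user-configured).

**Synthetic fixtures.** Seeded generators for closed backbones with
controlled helix/strand/loop content, perturbed structure pairs,
planted cluster ensembles and metric tables with an exact planted
survivor count — every consumer of the package is testable offline.

## Worked example

```r
library(cyclopep)

# a seeded ensemble of closed 12-residue macrocycle backbones
ens <- generate_ensemble(generator_config(length = 12, seed = 7, n = 50))
ens$manifest$convergence_rate
#> [1] 1
closure_check(ens$structures[[1]])
#> closure_report: bond 1.277 A, angle dev 3.2/6.7 deg, omega -178.0 deg -> PASS

# uniqueness counting at TM-score 0.5
M <- pairwise_tm_matrix(ens$structures[1:12])
greedy_cluster(M, 0.5)
#> cluster_assignment: 12 structures in 11 clusters (threshold 0.50)

# the selection funnel on a synthetic metric table
preset <- campaign_preset("mdm2")
tab <- synth_metric_table(100, preset, planted_pass_count = 17, seed = 3)
res <- apply_preset(tab, preset)
res$report
#> funnel_report (preset mdm2): 100 -> 17 designs
#>   ipae         100 ->    48  (failed here: 52)
#>   ddg           48 ->    31  (failed here: 17)
#>   sap           31 ->    22  (failed here: 9)
#>   cms           22 ->    17  (failed here: 5)
rank_select(res$survivors, "ddg", 3)$design_id
#> [1] "d0011" "d0006" "d0003"
```

The funnel report reads: of 100 designs, 52 fail the normalized
interface-PAE cut first, 17 of the remainder fail the binding-energy
cut, and so on, leaving exactly the 17 planted survivors.

A thin command-line wrapper over the same functions ships in
`inst/cli/cyclopep`:

```sh
cyclopep encode --lengths 12:cyclic,150:linear --bmax 32 --out offsets.tsv
cyclopep synth ensemble --n 50 --length 12 --seed 7 --out designs/
cyclopep cluster --pdb-dir designs/ --tm-threshold 0.5 --out clusters.tsv
cyclopep funnel --metrics m.csv --preset mdm2 --rank ddg --top 11 --report report.json
```

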