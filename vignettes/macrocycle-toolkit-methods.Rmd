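---
title: "Methods: cyclic encodings, ring geometry, comparison and the selection funnel"
author: "cyclopep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cyclic encodings, ring geometry, comparison and the selection funnel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclopep)
```

`cyclopep` implements the deterministic, weights-free scaffolding of a
macrocyclic peptide binder-design pipeline. This vignette records the
models, the numerical choices, and the design decisions that were
genuinely open, so a maintainer can see why the code is the way it is.

## Cyclic relative positional encoding

A structure network perceives chain topology only through the relative
positional encoding, a matrix of signed residue-index offsets. For a
head-to-tail macrocycle the encoding must wrap: the offset from residue
`i` to residue `j` on a ring of length `L` is

\[ d = (j - i) \bmod L, \qquad
   \mathrm{offset} = \begin{cases} d - L & d > L/2 \\ d & \text{else,} \end{cases} \]

the shortest signed walk around the ring, positive rightward. The last
and first residues become nearest neighbours (`offset = -1`), which is
exactly what a closing peptide bond implies. Two choices were open:

* **Even-`L` antipode.** At `j` exactly halfway around, both walks have
  length `L/2`. We return the positive branch `+L/2`, making the map
  single-valued; a consumer preferring the negative branch can negate
  antipodal entries, which the bound invariant makes easy to find.
* **Interchain sentinel.** In complexes only the macrocycle block is
  cyclized; target and interchain blocks keep the linear encoding.
  Interchain cells hold a dedicated sentinel far outside any clamp
  bound, and a boolean mask is authoritative — inspecting the matrix
  never confuses a sentinel with a real offset. The clamp bound `bmax`
  applied before binning is a configuration value: no canonical value
  exists for it here, so none is asserted.

Indexing is 0-based internally; PDB residue numbering (1-based,
possibly with gaps and insertion codes) is mapped at I/O only.

## Backbone geometry and ring closure

`build_from_torsions()` extends a chain atom-by-atom (natural extension
reference frame) with fixed ideal geometry (N–CA 1.458 Å, CA–C 1.525 Å,
C–N 1.329 Å, C=O 1.231 Å, standard angles; see `backbone_geometry()`).
Torsions live on `(-180, 180]` degrees; the builder leaves the chain
open, and `ccd_close()` closes it.

Closure uses cyclic coordinate descent: a virtual copy of residue 1 is
built beyond residue L with ideal peptide geometry and trans omega, and
one torsion at a time (psi 1..L, phi 2..L, and the virtual phi) is
rotated by the closed-form angle that best superposes the virtual atoms
onto the real residue 1. Each update minimizes the anchor error
directly, so the closure gap is non-increasing by construction — a
property the tests assert on the per-sweep trace. When the virtual copy
lands on residue 1, the closing C(L)–N(1) bond has ideal geometry *by
construction*; there is no separate bond-building step that could
disagree with the validator. CCD was chosen over generalized kinematic
closure because it is derivative-free, simple to audit, and adequate
for fixtures; it makes no claim to reproduce the backbone distribution
of any generative model. The converged virtual-frame torsions are
stored with the structure so that re-closing a closed ring rebuilds the
same anchors and is an exact fixed point.

`closure_check()` accepts a ring when the closing bond is within
1.329 ± 0.2 Å, both flanking angles within 15° of ideal and |omega|
within 30° of 180° (cis accepted only on request). No published
acceptance window exists for "the termini are joined by a peptide
bond", so these defaults are the package's own, deliberately generous
enough to accept CCD output at its 0.08 Å gap tolerance and tight
enough to reject any open or broken ring; all four are arguments.

Torsion measurement wraps around the ring: phi(1) uses C of residue L,
psi(L) and omega(L) use residue 1, so a cyclic chain has all `L`
(phi, psi) pairs defined — the Ramachandran histogram of a macrocycle
ensemble therefore counts every residue, including the closing one.
Whether to include the wrapped torsions is exposed simply by marking
the structure cyclic or linear. D-amino acids are not modeled;
chirality shows up only as the sign structure of phi.

## Structure comparison

Compared macrocycles within a campaign length class have equal length,
so comparison uses a fixed index correspondence — never a structural
alignment of unequal chains. That substitution (relative to
TM-align-style tools) is deliberate: it makes the TM-score exactly
reproducible and lets the ring topology enter as a *register search*:
on a ring the starting index is arbitrary, so all `L` cyclic shifts
(and optionally the reversed orientation) are scored and the best kept.
Each correspondence is scored with the standard TM formula,
`d0 = max(0.5, 1.24 (L-15)^{1/3} - 1.8)`; the cube-root term is
negative at these lengths, so the 0.5 Å floor (common practice for
short chains) is what is actually in force for `L < 24`. The
per-correspondence score is maximized by fragment-seeded iterative
refinement (seeds: full chain, both halves, middle window; refit on
residues within the distance cutoff until the subset stabilizes) in
compiled code. Normalization is by the common length `L`; with equal
lengths the score is direction-symmetric by construction, and the
all-by-all matrix is built once per pair.

Superposition is closed-form Kabsch via SVD with the reflection
guarded; collinear point sets are rejected rather than silently
resolved. The r.m.s.d. reported for exact-recovery cases is computed
from residuals, not from the singular-value identity, to avoid
catastrophic cancellation near zero. Two r.m.s.d. conventions mirror
design-versus-crystal practice: *target-aligned* (fit on shared target
Cα, score the binder unfitted; minimum over binder copies when the
crystal holds several) and *macrocycle-aligned* (fit and score the
binder Cα). The target-aligned value is never below the
macrocycle-aligned value for the same pair, a relation the tests check.

Greedy threshold clustering picks the unassigned structure with the
most unassigned neighbours at TM ≥ threshold (ties to the lowest input
index), assigns that neighbourhood, and repeats. The order and
tie-break are fixed to make assignments deterministic; the exact
internal ordering of the clustering tools used in large published
campaigns is not public, so no claim is made to reproduce their counts,
only the thresholded-uniqueness semantics.

## Surface and interface metrics

SASA is Shrake–Rupley on a deterministic golden-spiral lattice
(960 points per atom by default, probe 1.4 Å, Bondi heavy-atom radii,
hydrogens ignored). Coordinates are first moved to a canonical frame
(principal axes, signs fixed by the third moment of the projections) so
that the fixed lattice yields rigid-motion-invariant areas — a plain
fixed lattice would leak ~0.1% orientation dependence into every
downstream metric. Isolated-sphere and two-sphere configurations have
closed forms, which the acceptance checks compare against at the 0.5%
and ~2% (discretization) level; doubling the point count moves a
100-atom total by well under 1%.

The contact molecular surface (CMS) is implemented as the buried-SASA
proxy `(SASA(binder) + SASA(target) - SASA(complex)) / 2`. The Rosetta
calculation that usually carries this name is not specified in the
literature this package draws on, so the proxy is adopted and
*documented as such*: threshold presets (e.g. CMS > 300 Å²) apply to
the proxy, and absolute comparability with Rosetta values is not
claimed.

SAP follows the published spatial-aggregation-propensity definition:
for each atom, sum over residues of (side-chain SASA within 5 Å,
relative to the fully exposed reference) × residue hydrophobicity
(Black–Mould, normalized so glycine is zero). The reference exposure is
the residue's side-chain SASA computed on its own atoms in isolation —
side-chain *building* is out of scope, so the extended
Gly-X-Gly-context reference cannot be constructed from backbone-only
inputs; the isolated-residue reference is self-consistent with the
structures the package actually handles and equals 1.0 exactly for a
fully exposed residue. The design score is the sum of positive per-atom
values. Backbone-only non-glycine input is rejected with a pointer to
supply full-atom models rather than silently scored as zero.

Hotspot coverage is the fraction of a supplied target-residue list with
any heavy atom within 5 Å (configurable) of any binder heavy atom —
the quantity used to verify that generated binders actually engage the
epitope their generation was steered toward.

## The selection funnel

All threshold comparisons are strict (`<`, `>`): published campaign
filters are written as strict inequalities, so boundary values fail,
including the self-consistency boundary (pLDDT exactly 0.8, r.m.s.d.
exactly 2.0 both fail). Failure attribution evaluates metrics in the
fixed order iPAE, ddG, SAP, CMS, r.m.s.d.-to-prediction and charges
each failing design to its first failing metric, so input = survivors +
tally sum — an identity the tests assert. ddG is an *ingested* column
(an external energy calculation), never computed here. The iPAE
normalization constant is not fixed by any source available to this
package; ingestion therefore accepts pre-normalized values or an
explicit divisor, and no default divisor is asserted. The `mcl1` preset
ships with its metric set but no numbers (its cutoffs are not in the
material this package is built from) and refuses to filter until
configured — a loud error was judged safer than invented defaults.

## Synthetic fixtures

The generators exist so every consumer is testable with no downloads.
Torsion sampling draws each residue's basin from configurable
helix/strand/loop weights (centers (−57, −47) and (−120, 120); the loop
basin is a 50/50 mixture of (−80, 150) and (60, 40) with a 25° spread —
a pragmatic stand-in for irregular loops, not a claim about loop
statistics). Defaults: 10° jitter, trans omega. Planted-cluster
ensembles draw `k` templates (rejecting any with TM ≥ 0.45 to an
accepted template, so planted clusters are separated at the 0.5
threshold), then emit perturbed copies; planted metric tables sample
passing rows strictly inside the preset's pass region and failing rows
with at least one strict violation, so the planted survivor count is
exact by construction and the funnel must recover it exactly.

Perturbation adds independent Gaussian noise per coordinate; at
amplitude `a` the macrocycle-aligned Cα r.m.s.d. concentrates near
`a√3` times the Kabsch shrinkage, which is why amplitude 0.5 Å lands in
(0.3, 1.2) Å and amplitude 0.3 Å keeps within-cluster TM above 0.5 at
ring length 24 while distinct templates stay far below it.

## Problem sizes and what the tests show

The verification suite uses: exhaustive offset checks to `L = 24`;
50-member ensembles for closure statistics; 50 random 5–12-point sets
against a staged 100,000-rotation Monte-Carlo search; planted-cluster
recovery at `k ∈ {2, 5, 10}` × 10 copies × 20 seeded runs at ring
length 24; and 100–1000-row metric tables. These sizes give stable
pass/fail behaviour at interactive runtimes on one CPU.

Passing tests show the components are *internally* correct (oracle
agreement, round trips, closed forms, planted recovery). They do not
show that synthetic backbones reproduce any generative model's
distribution, that the CMS proxy numerically matches Rosetta's surface,
or that funnel thresholds transfer to new targets — the published
campaigns themselves adjusted thresholds per target, and in-silico rank
does not perfectly order experimental affinities. Those caveats are
inherent to the weights-free scope, not defects of the tests.

## Known limitations

* No side-chain building, packing, or hydrogens; SASA/SAP on
  backbone-only models is either glycine-trivial or refused.
* No structural alignment of unequal-length macrocycles; cross-length
  comparisons are out of scope by design.
* No d-amino acids, noncanonical residues or crosslink chemistries.
* ddG, pLDDT, iPAE and r.m.s.d.-to-prediction are ingested, not
  computed; the package audits and filters on them.
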