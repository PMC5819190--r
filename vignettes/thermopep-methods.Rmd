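---
title: "Methods: comparative peptidase profiling and thermostability signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative peptidase profiling and thermostability signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermopep)
```

# Scope and scientific question

Thermophilic fungi grow at temperatures where most mesophilic proteins
unfold, and their enzymes — peptidases in particular — are of both applied
and evolutionary interest. `thermopep` implements a comparative genome-mining
workflow that asks, for a panel of thermophilic, thermotolerant and
mesophilic fungal species, three questions at three levels of organization:

1. **Repertoire** — do peptidase gene complements (counted per MEROPS
   catalytic type or family) differ between growth-temperature groups?
2. **Primary structure** — do proteome-wide amino-acid compositions shift in
   the directions associated with thermal adaptation?
3. **Tertiary structure** — do pepsin-like (A1A) aspartic peptidases from
   thermophiles have fewer solvent-inaccessible interior cavities?

Each stage is usable on its own; `run_study()` chains them. A synthetic-data
generator produces inputs with recorded ground truth for every stage, so the
whole pipeline is testable without any external database or download.

# Peptidase mining

## Model

A query protein is assigned to the peptidase family of its best-scoring
reference hit, if that hit is convincing. The reference is an annotated
library whose FASTA headers carry MEROPS-style family codes
(`id|FAM=A01|TYPE=A`; genuine pepunit-style headers are accepted through a
pluggable parser, `parse_reference_headers()`). The classifier has two
stages:

* **Prescreen.** A k-mer index (`build_kmer_index()`, default `k = 4`) ranks
  reference entries by the number of *distinct* shared k-mers with the
  query. Entries sharing at least `min_shared_kmers` (default 8) k-mers are
  candidates; the top `max_candidates` (default 50) proceed.
* **Rescoring.** Candidates are realigned with exact local Smith-Waterman
  (BLOSUM62; affine gaps costing `11 + L` for a gap of length `L`). The best
  hit is emitted iff raw score ≥ 60, percent identity over aligned columns
  ≥ 30, and query coverage (aligned query span / query length) ≥ 0.5.
  Score ties break by higher identity, then lexicographic reference id, so
  classification is a deterministic function of (query, reference,
  parameters).

Thresholds are deliberate package defaults — the upstream practice this
emulates (a BLAST search against a curated peptidase database) rarely states
its acceptance criteria, so all five are exposed in `mining_params()` and
recorded in run manifests. Non-standard letters (B, J, O, U, X, Z) score
zero in alignments: they can be spanned but never add signal.

One annotation per query is emitted (best hit only); the "Mixed" catalytic
category arises from reference families whose code starts with `P`, not from
multi-hit logic. `profile_species()` tabulates annotations into a
species-by-category `count_matrix`; row sums at family level equal row sums
at catalytic-type level by construction.

## What is not attempted

No E-value statistics, no profile HMMs, and no active-site residue mapping.
Consequently the package does not claim to reproduce any published
repertoire table from raw genomes: the bundled 23-species count matrix
enters the statistics as a fixed input, and the mining stage is validated
against synthetic truth tables instead (recovery ≥ 95% at 10% mutation
load, no background false calls at default thresholds in the test suite).

# Profile statistics

All four statistics are own implementations (the test suite cross-checks
them against independent oracles and, where available, `vegan`):

* **Bray-Curtis**: `BC(x, y) = Σ|x−y| / Σ(x+y)`, on raw counts by default.
  Undefined (error) for two all-zero profiles.
* **ANOSIM**: all pairwise distances are ranked with mid-ranks on ties;
  `R = (mean between-group rank − mean within-group rank) / (M/2)`,
  `M = n(n−1)/2`. P by label permutation with the `+1` convention
  (`n_perm` default 9999), so P is never exactly zero and its floor is
  `1/(n_perm+1)`.
* **SIMPER**: for each cross-group pair the per-category contribution is
  `|x_ij − x_ik| / Σ_v(x_vj + x_vk)`; averaging over pairs gives
  contributions that sum *exactly* to the overall average between-group
  dissimilarity (a conservation law asserted on 1000 fuzzed matrices in the
  tests). Ties in the descending ranking break lexicographically.
* **Kruskal-Wallis**: mid-rank H with tie correction
  `C = 1 − Σ(t³−t)/(N³−N)`; chi-square P from the survival function with
  `k−1` df, and an optional Monte-Carlo permutation P (same `+1`
  convention). All observations identical yields `H = 0, P = 1` rather than
  an error.

Because the upstream convention for distance input (raw counts vs row
percentages; 9 vs 7 categories) is typically unstated, `simper()` and
`anosim()` expose `relativize` and accept arbitrary column subsets; the
acceptance suite runs this 2×2 sensitivity grid. On the bundled survey
matrix the raw-count configurations give 26.12% (nine categories) and
26.00% (seven), bracketing the published headline of 26.08%, while the
row-percentage configurations give ≈ 12.9% — i.e. the survey statistic was
computed on raw counts. ANOSIM on raw counts gives R = 0.753 against the
published 0.7516.

For the cavity-count comparison (4 non-thermophilic vs 8 thermophilic
models) the exact permutation distribution is enumerable: over all
`C(12,4) = 495` splits, exactly 7 reach the observed tie-corrected
`H = 5.967`, so the exact permutation P is `7/495 = 0.0141` and the
chi-square approximation gives 0.0146. The published value for this
comparison, 0.0185, is close to but not exactly reproducible from the
printed cavity vectors under any permutation convention we examined; the
package reports both of its own P values and treats the difference as a
property of the upstream software's P variant.

Two-group comparisons exclude thermotolerant species by convention
(`subset_groups()`), mirroring standard practice for this panel.

# Composition statistics

`aa_composition()` computes residue percentages over standard residues only
(non-standard letters excluded from numerator *and* denominator), plus the
EMBOSS PEPSTATS class percentages: charged {D,E,H,K,R}, polar
{D,E,H,K,N,Q,R,S,T}, hydrophobic {A,C,F,G,I,L,M,P,V,W,Y}. Charged is a
subset of polar; the classes overlap by design and are reported
independently.

`compare_groups()` runs one test per variable (20 residues + 3 classes).
The default is **Welch's two-sample t-test on per-species means**. A paired
test is sometimes quoted for this kind of contrast, but with two groups of
~10^5 proteins there is no defensible protein-level pairing; we therefore
default to the unpaired species-level test and keep `student` and `paired`
modes available rather than hiding the ambiguity. Species means are
unweighted averages of per-protein percentages (each protein counts
equally); a length-weighted mode (pooled residue counts) is a flag. Raw P
values are primary — multiple-testing correction is typically not applied
in this analysis tradition — with Benjamini-Hochberg values reported
alongside. Whether the original analysis tested per-protein or per-species
units is unknowable from its description; both units are implemented and
neither is asserted as canonical.

# Hallmark filtering

Functional pepsin-like (A1A) aspartic peptidases are identified by five
ordered motifs: `D[TS]G`, `Y`, `XXG`, `D[TS]G`, `XXG` with
X ∈ {A,F,I,L,M,V}. `scan_hallmarks()` searches greedily left to right,
each motif strictly after the previous match, non-overlapping. Two
interpretation choices were genuinely open and are resolved as follows:

* the `Y` hallmark is a single tyrosine anywhere after the first catalytic
  motif (no context window is specified anywhere we know of); and
* no minimum spacing between the two catalytic lobes is imposed beyond
  strict ordering.

Greedy earliest matching could in principle miss orderings that a
backtracking search would find; for this motif set it does not — the test
suite asserts exact pass/fail agreement with an exhaustive ordered search
on 1000+ random sequences rather than assuming the property.

# Structure metrics

`count_cavities()` voxelizes the padded bounding box (default grid 0.8 Å),
marks voxels within `atom radius + probe` (probe 1.4 Å, water) of any atom
center as occupied, flood-fills the exterior from the box boundary
(6-connectivity), and counts remaining empty components of at least
`min_voxels` (default 5) voxels as interior cavities. Volumes are voxel
counts × res³. Absolute cavity counts are parameter-dependent — a coarser
grid or larger probe closes small voids — so cross-group comparisons must
hold (grid, probe, min_voxels) fixed; the package therefore validates the
counter on constructed fixtures with known void counts and uses the
*statistical comparison* of published per-model counts, not re-derivation
of those counts from coordinates. Surface-area and volume columns of the
bundled structure table are carried as data but never recomputed: their
units in the source material are not interpretable as molecular surfaces.

Sequence-level metrics: `molecular_weight()` sums average residue masses
plus one water (18.0153 Da); `isoelectric_point()` solves
Henderson-Hasselbalch net charge = 0 with the EMBOSS pKa set (N-term 8.6,
C-term 3.6, C 8.5, D 3.9, E 4.1, H 6.5, K 10.8, R 12.5, Y 10.1) by
bisection on pH ∈ [0, 14] to |charge| < 1e-4 (≤ 60 iterations; the charge
function is monotone so bisection is safe). Secondary-structure counts come
from HELIX/SHEET records only — no DSSP-style assignment from coordinates.

# The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated:

* **Proteomes** (`make_proteome()`): background proteins are i.i.d. residue
  draws — *no positional structure* — from a database-average amino-acid
  law (`aa_background_freqs()`), optionally shifted by
  `thermophilic_shift()`: +0.005 on {A,E,G,P,R,V}, −0.003 on
  {C,H,I,K,M,N,Q,S,T,W}, zero on {D,F,L,Y}, balanced to sum to zero. The
  *directions* follow the compositional contrasts reported for thermophilic
  fungi (including the implied class directions: charged and hydrophobic
  up, polar down); the *magnitudes* are free generator parameters chosen
  once to be of the order seen in proteome-scale box plots (a few tenths of
  a percentage point) — they are not calibrated to any published effect
  size, which is unavailable. Lengths are log-normal, median 400 residues,
  sigma 0.45. A `peptidase_fraction` of each proteome consists of reference
  members mutated by uniform substitution (no indels by default), which
  keeps identity/coverage semantics simple.
* **Count matrices** (`make_count_matrix()`): gamma-Poisson draws;
  negative-binomial dispersion 0.2 by default because family counts across
  species are overdispersed; dispersion 0 is exactly Poisson.
* **Structures** (`make_structure()`): hollow atom shells (Fibonacci-sphere
  point clouds at exactly the shell radius) embedded in a jittered cubic
  carbon slab. Because the nearest atom to a cavity center lies at exactly
  the shell radius, the interior free radius is analytically
  `radius − (1.70 + 1.4)` Å and the analytic interior volume is recorded as
  truth (observed voxel volumes land within a few percent).
* **Hallmark sets** (`make_hallmark_set()`): positives embed the five
  motifs in order in glycine-free random backgrounds (glycine only occurs
  inside injected motifs, so no accidental extra motifs can arise);
  negatives are provably negative by construction (either no glycine at
  all, or motifs 1-3 followed by a glycine-free tail).

What the generator does **not** emulate: phylogenetic correlation among
species, codon/GC structure, domain architecture, indels, or real secondary
structure. Passing tests therefore demonstrate correctness of the
statistics and algorithms under these stated laws — not that real proteomes
satisfy those laws.

All generators are bit-reproducible given (parameters, seed), and every
generated record appears exactly once in its truth table.

# Numerical and reproducibility choices

* Permutation P values always use the `+1`-in-numerator-and-denominator
  convention; comparisons of permuted statistics to the observed one use a
  `≥` with a 1e-12 slack so exact ties count.
* All RNG use goes through an internal scoped-seed helper, so package
  functions never disturb the caller's RNG stream; permutation results are
  reproducible given `seed` and invariant to input row order.
* `count_cavities()` guards against runaway grids with a voxel budget
  (default 3×10^7) and suggests a coarser resolution instead of exhausting
  memory.
* Problem sizes in the test suite are scaled to the laptop class: the
  compositional direction-recovery study uses 100 replicates of 10 + 10
  species at 150 proteins each (median length 400); ANOSIM calibration uses
  500 null matrices at 199 permutations; the cavity permutation test uses
  2×10^5 draws. These sizes were chosen once, from power considerations
  (the binding constraint is the +0.4 percentage-point charged-class shift,
  detected with power > 0.99 at these sizes), and the suite runs in a few
  minutes on one CPU.

# Known limitations

* Best-hit classification with fixed thresholds is a coarse stand-in for
  curated database assignment; borderline homologs near the thresholds are
  sensitive to parameter choice, and no significance statistics are
  attached to hits.
* Cavity counts on real structures depend on grid, probe and size
  threshold; only comparisons at fixed parameters are meaningful.
* The composition test treats species as exchangeable units and ignores
  phylogenetic non-independence — as does the analysis tradition it
  implements.
* The bundled survey tables are transcriptions; two of their printed row
  totals disagree with their own per-category entries (by 1 and 9 genes)
  and the per-category entries, which are what the statistics consume, were
  kept.
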