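# thermopep

Comparative genome mining of peptidases (EC 3.4) in thermophilic,
thermotolerant and mesophilic fungi, with tests for sequence- and
structure-level signatures of thermostability.

Thermophilic fungi are a prime source of industrially robust hydrolases,
and their peptidases carry putative thermal adaptations at three levels:
fewer peptidase-encoding genes overall, shifted amino-acid composition, and
more compact folds with fewer interior cavities. `thermopep` packages that
comparative analysis for R users — bioinformaticians profiling fungal
proteomes and anyone who needs reference implementations of the underlying
community-profile statistics.

## What it computes

* **Peptidase mining** — assignment of proteome sequences to MEROPS-style
  families and catalytic types by best hit against an annotated reference
  library: k-mer prescreen (default k = 4) plus exact Smith-Waterman
  rescoring (BLOSUM62, affine gap cost 11 + L), with score / identity /
  coverage thresholds. `profile_species()` tabulates the hits into a
  species × category count matrix.
* **Profile statistics** (from scratch, oracle-tested) — Bray-Curtis
  dissimilarity `BC(x,y) = Σ|x−y| / Σ(x+y)`; ANOSIM
  `R = (r̄_between − r̄_within) / (M/2)` with permutation P; SIMPER
  decomposition of the average between-group dissimilarity into
  per-category contributions (which sum exactly to the overall);
  tie-corrected Kruskal-Wallis `H` with chi-square and Monte-Carlo
  permutation P.
* **Composition statistics** — per-protein and per-species percentages of
  the 20 residues and of the charged / polar / hydrophobic classes
  (EMBOSS PEPSTATS definitions), with Welch / Student / paired t-tests per
  variable and direction calls.
* **Hallmark filtering** — functional pepsin-like (A1A) aspartic peptidases
  identified by five ordered motifs `D[TS]G, Y, XXG, D[TS]G, XXG`
  (X ∈ {A,F,I,L,M,V}).
* **Structure metrics** — interior cavity counting by probe-augmented voxel
  grid flood fill (grid 0.8 Å, probe 1.4 Å); molecular weight from average
  residue masses; pI by bisection of the Henderson-Hasselbalch net charge
  (EMBOSS pKa set).
* **Synthetic data with ground truth** — proteomes with known compositional
  shifts and peptidase content, overdispersed count matrices, structures
  with a known number of cavities, and labelled hallmark sets, so every
  stage is testable offline.

Two survey tables ship with the package: `fungal_peptidase_counts()`
(23 species × 9 catalytic types, with growth-temperature groups) and
`aspartic_peptidase_structures()` (12 A1A models with cavity counts).

## Worked example

```r
library(thermopep)

counts <- fungal_peptidase_counts()                      # 23 x 9 survey
two <- subset_groups(counts, c("mesophilic", "thermophilic"))

anosim(two, n_perm = 9999, seed = 42)
#> ANOSIM (braycurtis): R = 0.7531, P = 0.0001 (9999 permutations)

s <- simper(two, pair = c("mesophilic", "thermophilic"))
attr(s, "overall_pct")                                   # 26.12
head(as.data.frame(s), 4)
#>   variable contribution_pct contribution_rel cumulative_pct
#> 1   Serine            10.58             40.5           40.5
#> 2  Metallo             6.34             24.3           64.8
#> 3 Aspartic             3.84             14.7           79.5
#> 4 Cysteine             3.17             12.1           91.6

tab <- aspartic_peptidase_structures()
kruskal_wallis(tab$n_cavities, tab$group, n_perm = 2e5, seed = 42)
#> Kruskal-Wallis: H = 5.9668, df = 1, P(chi2) = 0.01458,
#>                 P(perm, 200000 draws) = 0.01404
```

Reading: mesophilic and thermophilic peptidase repertoires are strongly
separated (ANOSIM R = 0.75, permutation P at its floor of 1e-4), their
profiles differ by 26.1% on average, and serine peptidases alone account
for 40% of that difference. Thermophilic A1A models have significantly
fewer interior cavities (permutation P ≈ 0.014).

A full synthetic study with injected effects, mined and tested end to end:

```r
res <- run_study(study_config("synthetic", seed = 1,
                              n_species = c(mesophilic = 4, thermophilic = 4),
                              n_proteins = 60,
                              peptidase_fraction = c(mesophilic = 0.2,
                                                     thermophilic = 0.1)))
res$anosim; attr(res$simper, "overall_pct")
```

A thin CLI over the same functions is installed at
`system.file("cli", "thermopep.R", package = "thermopep")` with subcommands
`anosim`, `simper`, `kw`, `hallmark`, `mine`, `struct`, `simulate`, `run`.

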