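---
title: "Functional-group analysis of fish gut metagenomes: methods"
author: "gutFG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional-group analysis of fish gut metagenomes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the models
behind each stage, the parameters that matter, what the synthetic
generator does and does not emulate, and the numerical decisions taken
where the design was genuinely open.

## The scientific setting

Fish gut communities are typically dominated by Proteobacteria, with
Fusobacteria, Firmicutes and Bacteroidetes forming a second block of
comparable joint abundance. Co-occurrence analysis shows the two blocks
co-exclude each other, and their associations with host gene expression
run in opposite directions, motivating their treatment as two
*functional groups*: FG1 (Proteobacteria, enriched in virulence-factor
and antibiotic-resistance genes, starch-related CAZy families) and FG2
(Fusobacteria/Firmicutes/Bacteroidetes, enriched in fibre-degrading
CAZy families and SCFA production genes). The per-sample biomarker

$$\mathrm{ratio} = \frac{p_{\mathrm{Fuso}} + p_{\mathrm{Firm}} +
p_{\mathrm{Bact}}}{p_{\mathrm{Proteo}}}$$

(relative phylum abundances $p$) summarizes which block holds the
community. Because numerator and denominator come from the same sample,
the ratio is invariant to any positive rescaling of that sample's raw
abundances and to the choice of relative-abundance denominator, as long
as all four phyla are inside it.

## Data model

All tables travel as UTF-8 TSV with headers. `GeneAnnotationTable`
(an S4 wrapper around an `S4Vectors::DataFrame`) carries, per
non-redundant gene: a seven-rank lineage (ranks that upstream taxonomy
could not resolve hold the sentinel `"unknown"`), an optional KO, a
possibly-empty CAZy family set (`IRanges::CharacterList`; serialized
comma-joined), and optional VF/ARG class labels. Missing functional
annotation is *absence* (`NA`), never an empty-string category, so
category sums cannot silently absorb unannotated genes.
`FeatureProfile` extends `SummarizedExperiment` and tags its matrix
with a feature level and a normalization state (`raw`, `relative`,
`per_100k`); validity enforces non-negativity and, for `relative`, unit
sample sums to 1e-9.

## Aggregation and the ratio

Category abundance is the plain sum of member-gene abundances. Genes
without a label at the requested level are excluded from every category
but their mass is tracked (`unassignedMass()`), so mass conservation is
checkable: categories + unassigned = total, with CAZy multi-membership
inflating the left side by exactly $\sum (|\mathrm{families}| - 1)
\cdot \mathrm{abundance}$. A zero Proteobacteria abundance makes the
ratio an error, not infinity; an optional pseudocount (added to both
terms, default 0) supports sparse synthetic data. Sample labels:
`high_FG2` iff ratio strictly exceeds the threshold (default 1.0 — FG2
mass exceeds FG1 mass), ties to `high_FG1`. The threshold is a package
decision: the source analyses mark "high FG2" samples without stating a
numeric rule, and 1.0 is the only scale-free choice.

## Ecology

* Shannon uses the natural log; Simpson is reported as the
  Gini–Simpson index $1 - \sum p_i^2$ (no variant is standard enough to
  assume otherwise).
* Chao1 uses the bias-corrected form $S_{obs} + F_1(F_1-1)/(2(F_2+1))$,
  defined also when $F_2 = 0$. ACE uses the abundance-based coverage
  estimator with rare cutoff 10; when every rare species is a singleton
  the coverage estimate is zero and ACE is reported as `NA` (the
  reference implementation yields NaN there).
* Rarefaction is the analytic hypergeometric expectation
  $E[S(d)] = \sum_i (1 - \binom{N-n_i}{d}/\binom{N}{d})$, computed with
  log-binomials.
* PCoA Gower-centres $-d^2/2$; negative eigenvalues are reported but
  excluded from the proportion-explained denominator.
* PERMANOVA and ANOSIM permute labels freely (no strata) and report
  $p = (b+1)/(B+1)$ with $b$ counting permuted statistics $\ge$ the
  observed one. Note a consequence: with two widely separated groups,
  any permutation that reproduces the observed bipartition duplicates
  the observed statistic exactly, so the lattice minimum $1/(B+1)$ is
  attained only when no such permutation is drawn (probability
  $\approx 2B/\binom{n}{n_1}$ of at least one at equal group sizes).

## Co-occurrence networks and the partition

Edges are Spearman correlations (midranks on ties) kept at
$|\rho| > r_{\min}$ (default 0.5) and $p < 0.05$; p-values use the
t approximation (adequate for $n \ge 10$), with exact permutation
enumeration available for smaller n. No multiple-testing correction is
applied by default (Benjamini–Hochberg sits behind a flag), matching
common practice for these descriptive networks. Constant taxa are
dropped with a warning.

The random-matrix-theory threshold is exposed as an alternative to the
fixed 0.5 rule: for each candidate threshold the correlation matrix is
hard-thresholded, its eigenvalue spectrum unfolded with a smoothing
spline, and the nearest-neighbour spacing distribution tested
(chi-square on bins of width 0.5 up to 3) against Poisson (modular,
uncorrelated blocks) versus Wigner–Dyson (GOE) laws; the smallest
threshold where Poisson fits better wins, with a warned fallback to the
fixed rule. The procedure is a package decision — the source names the
idea without an algorithm — and the fixed rule is the default path.

The two-group partition maximizes $\sum_{\mathrm{edges}} \pm |\rho|$
(+ for a positive edge within a group or a negative edge across, −
otherwise). Up to 15 nodes the maximum is exact (all $2^{n-1}$
bipartitions); beyond that, a sign-guided agglomerative seed plus
single-node moves from 20 seeded random restarts. Ties break to the
lexicographically smallest membership of the group containing the first
node, making results deterministic.

## Host modules

Expression is standardized per gene; the dissimilarity is
$1 - |\mathrm{Pearson}\ r|$, clustered with average linkage and cut at
a static height (default **0.30**); clusters under `minSize` (default
30) become `grey`, and grey genes whose module-membership correlation
with an eigengene reaches 0.7 are rescued into that module (the usual
kME reassignment). The cut default is 0.30 rather than 0.25 because at
the stated simulation world the *sample* within-module dissimilarity
averages ~0.24–0.26 (sampling attenuation of the population 0.19),
which makes a 0.25 cut knife-edge, while cross-module dissimilarity
sits near 0.5; 0.30 separates the two bands with margin. This
deliberately minimal variant (no soft-thresholding or topological
overlap) is deterministic and oracle-testable while reproducing the
association logic.

Eigengenes are first principal components of the standardized module
expression, scaled to unit variance and sign-oriented to correlate
positively with the module mean — removing the PCA sign ambiguity that
would otherwise make association signs arbitrary. Associations are
plain Pearson correlations with two-sided t p-values, annotated with
the heatmap tiers (`$` p<0.1, `*` p<0.05, `**` p<0.01, `***` p<0.001).

The "consistently opposite" claim is operationalized as a permutation
test: the statistic is the correlation, across modules, between the
Proteobacteria association vector and each FG2 phylum's vector
(averaged over the three phyla), with a one-sided lower-tail p-value
from permuting the module rows of the Proteobacteria vector (default
999 permutations). Opposite association is declared at a negative
statistic with p < 0.05. Module–group association is computed both per
phylum and for summed FG1/FG2 abundance, since either convention is
defensible.

## Functional profiles

CAZy substrate lists (arabinoxylan, pectin, mucin, inulin, cellulose,
starch) are honoured exactly as published, including families listed
under several substrates (GH1, GH3, GH5): a gene contributes its full
abundance to every substrate it matches, with no deduplication.
Substrate values are normalized to the group's total CAZy-gene
abundance per sample and scaled to 100,000, making them invariant to
per-sample rescaling. SCFA key enzymes ship as an editable map
(`defaultScfaEnzymes()`: FTHFS→K01938, PcoAt→K01026, Buk→K00929,
AtoA→K01035, AtoD→K01034) because the enzymes, not KO numbers, are the
primary identifiers. VF/ARG profiling counts genes (per 100,000
annotated genes in the group) rather than weighting by abundance,
matching the "number of related genes" convention; an
abundance-weighted variant sits behind the `weights` argument. The
exclusion filter drops a feature only when it is below 1 per 100,000 in
*every* sample; the boundary value is retained.

Mann–Whitney comparisons enumerate the exact null when both samples
have at most 8 untied observations (two-sided tail of
$|U - nm/2|$), otherwise a normal approximation with tie and
continuity corrections.

## Virome coupling

Alpha-diversity coupling is the same Spearman routine used by the
network stage (one shared implementation). Beta-diversity coupling is a
Mantel test on Bray–Curtis matrices — Spearman by default so the result
is invariant to monotone transformations of either matrix, Pearson
optional — with a one-sided (greater) permutation p-value. The source
does not name its beta-correlation procedure; Mantel is the stated
package choice (Procrustes on PCoA coordinates would be the main
alternative and is noted, not implemented). The taxon–phage grid is
uncorrected pairwise Spearman by default, with BH behind a flag;
constant features yield `NA` cells rather than errors.

## The synthetic world

`simulateDataset()` emulates the feeding-trial design: 3 diets
(CD/OD/HD) × 2 weeks × 6 replicates = 36 samples. Its statistical
structure, with defaults chosen once:

* **Community.** Two latent factors with correlation
  `-groupAnticorr` (default 0.9, matching the strong co-exclusion the
  analysis assumes) drive the log abundances of FG1 and FG2 taxa
  (8 Proteobacteria, 6 Bacteroidetes, 6 Firmicutes, 4 Fusobacteria
  genera, plus 2 Actinobacteria as an unmapped "other" phylum).
  Per-phylum base abundances make Proteobacteria the dominant phylum at
  the carnivorous baseline. Exponentiation and downstream closure give
  logistic-normal compositions.
* **Scales.** The latent factors have log-scale SD 0.3 and per-taxon
  noise SD 0.5 (`noiseSd`). These two constants were fixed by a
  pre-registered power analysis, not tuned afterwards: the latent SD
  must be large enough that summed FG1 and FG2 raw abundances
  anti-correlate strongly (Spearman below −0.5 at `groupAnticorr` 0.9)
  yet small enough that a diet effect of 0.5 log units remains
  detectable by Mann–Whitney at 6 replicates per cell.
* **Diet.** OD/HD samples shift FG2 taxa by `+dietEffect` and FG1 taxa
  by `-dietEffect` log units (default 1.0). The reciprocal form mirrors
  the reported pattern — Proteobacteria falling while
  Firmicutes/Bacteroidetes/Fusobacteria rise under plant-based diets —
  and makes the log-ratio displacement equal to `2 * dietEffect`.
* **Genes.** Each taxon's abundance is split over `genesPerTaxon`
  (default 40) genes by a fixed Dirichlet(1) draw. Functional labels
  are planted with the directionality the analysis should detect: FG2
  genes carry arabinoxylan/pectin/cellulose CAZy families and SCFA KOs
  preferentially; FG1 genes carry starch families and a 3× higher
  VF/ARG Bernoulli rate (9% vs 3%) — directionality, not effect
  magnitude, is the claim.
* **Host modules.** `nModules` (default 5) modules, alternating signs,
  each with latent profile $t_m = \sqrt{0.6}\, z_{\mathrm{group}} +
  \sqrt{0.4}\, u_m$ and gene loadings `moduleCoupling` (default 0.9) on
  unit-variance noise. The 0.6 group share is the load-bearing
  constant: if modules were almost pure group factor, same-sign modules
  would be statistically identical and *no* clustering method
  (including the reference tool's own module-merging defaults) could
  separate them; at 0.6 modules separate cleanly while every eigengene
  still carries a clear signed group signature. Accordingly the truth
  object records each module's own latent profile (the recovery target
  for eigengenes) alongside the two community factors.
* **Virome.** Each of `nViralTaxa` (default 12) phages tracks one
  planted bacterial host: standardized log host abundance times
  `viromeCoupling` (default 0.9) plus noise.

What the generator does **not** emulate: realistic taxon inventories or
abundance distributions of any particular fish, sequencing depth and
count noise (abundances are continuous), compositional artefacts of
library size, gene length bias in abundance estimation, phylogenetic
correlation among taxa, or week-by-diet interactions. A green test
therefore establishes that the *machinery* recovers planted structure
of the assumed form at realistic effect sizes — not that real data have
that structure.

## Numerical choices and degenerate inputs

* Exact text round trip: numeric tables are written at 15 significant
  digits.
* All permutation p-values live on the $(b+1)/(B+1)$ lattice; observed
  statistics are compared with a $10^{-12}$ tie tolerance.
* Every randomized stage derives its seed from the pipeline master seed
  and a stage name (`deriveSeed`), so reruns are byte-identical and
  stage order is irrelevant.
* Degenerate inputs error early and specifically: all-zero samples in
  relative normalization, zero FG1 with zero pseudocount, all-zero
  sample pairs in Bray–Curtis, edgeless networks in the partition,
  single groups in PERMANOVA/ANOSIM. Constant taxa/genes are excluded
  with a warning or message, not an error, since they carry no
  correlation information.

## Known limitations

* The module machinery is a minimal WGCNA-style variant; real
  transcriptome analyses may prefer soft-thresholding and topological
  overlap, which trade determinism for robustness on noisy data.
* The RMT threshold scan is a reasonable operationalization of an
  under-specified idea; its chi-square spacing test is coarse for small
  networks, and the fixed 0.5 rule remains the default.
* ANOSIM/PERMANOVA assume exchangeable samples; the tank/replicate
  structure of a real feeding trial would call for restricted
  permutations, which are not implemented.
* Gene abundance estimation (read mapping, length normalization) is
  upstream of this package and treated as given input.
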