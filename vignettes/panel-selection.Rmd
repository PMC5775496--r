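---
title: "Methods: SNP panel selection and leave-one-out assignment evaluation"
author: "finepanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP panel selection and leave-one-out assignment evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its science: the models it
implements, the parameters that matter, the decisions taken where the design
was genuinely open, and what the synthetic experiments do and do not
demonstrate.

## The problem

Genetic stock identification assigns an individual to its source population
from a panel of bi-allelic SNPs and per-population baseline allele
frequencies. For weakly differentiated populations — river-scale salmonid
stocks with per-locus global $F_{ST}$ mostly under 0.1 — genome-wide data
easily support accurate assignment, but routine monitoring needs panels of
tens to hundreds of SNPs. The scientific question the workflow addresses:
given a genotype matrix with population labels, which small subset of loci
should the panel contain, and how should competing selection strategies be
compared without flattering any of them?

Genotypes are dosage-coded throughout: 0 for a homozygote of the globally
minor allele, 0.5 for a heterozygote, 1 for a major-allele homozygote, `NA`
for a missing call. The minor allele is defined over all populations pooled;
exact 50/50 ties break to the lexicographically smaller allele code so file
parsing is deterministic.

## Locus quality control

Four stages, in order:

1. **MAF filter** (`maf_min = 0.05`): loci with pooled minor-allele frequency
   *below* 5% are removed; a locus at exactly 0.05 is kept. Rare variants
   carry little assignment information and destabilise forest splits.
2. **Missingness filter** (`missing_max = 0.05`): loci missing in *more than*
   5% of individuals are removed (strict reading of "more than"; the boundary
   locus survives).
3. **Imputation**: the surviving sparse gaps (the generator's default is
   0.08% of cells) are filled by a proximity-based forest imputer. Missing
   cells start at the within-population per-locus mode (ties to the lower
   dosage code; the global mode if the population has no observed call);
   then for `impute_iters = 5` rounds a forest of `impute_trees = 5000`
   trees predicting the population labels is grown on the current matrix and
   each missing cell is replaced by the proximity-weighted mean of the
   locus's observed dosages, with proximity = share of trees in which two
   individuals land in the same leaf. Final values snap to the nearest of
   {0, 0.5, 1}. Observed cells are never modified, and a checksum test
   enforces that. The iteration count is a pragmatic default: the update is
   a smoothing operation and successive rounds change little on matrices
   this sparse.
4. **Redundancy ("top loci") pruning**: scan loci by descending global θ
   (ties by locus id, undefined θ last) and keep a locus iff θ ≥
   `fst_min = 0.05` and its squared Pearson correlation of dosages with every
   already-kept locus is ≤ `r2_max = 0.2`. Correlation uses
   pairwise-complete individuals; pairs sharing fewer than 10 complete
   individuals are treated as uncorrelated (and counted in a message),
   because a correlation estimated from a handful of points would prune on
   noise. Greedy keep-best-first was chosen over any graph-optimal subset:
   it is deterministic, order-independent (the scan order is a function of
   the statistics, not the column order), and matches how practitioners'
   pruning tools behave.

## Weir–Cockerham $F_{ST}$

Per-locus global θ uses the 1984 variance-components estimator:
$\theta = a/(a+b+c)$ with the among-population ($a$), among-individual ($b$)
and within-individual ($c$) components computed from per-population sample
sizes, allele frequencies and observed heterozygote proportions, including
the unequal-sample-size correction $n_c$. Missing genotypes are handled by
per-locus complete-case sample sizes. Three deliberate conventions:

* **Monomorphic loci are undefined**, not zero: $0/0$ is reported `NA` and
  such loci rank last. Treating them as 0 would silently let them pass a
  "θ below floor" check in the wrong direction.
* **Negative θ is reported as computed** — the estimator is negatively
  biased around zero differentiation and clamping would hide exactly the
  signal the low end of the ranking carries.
* **Multi-locus θ is the ratio of summed components**, never a mean of
  per-locus ratios; this is scale-invariant under duplicating loci and is
  what the pairwise population matrix uses.

The test suite checks the implementation against an independently coded
oracle built from the *other* formulation of the same estimator — the nested
ANOVA on allele indicators (MSP/MSI/MSG mean squares) — with agreement
required to $10^{-12}$, plus the analytic anchor points (fixed difference
⇒ θ = 1 exactly; duplicated populations ⇒ θ < 0).

## The forest family

The classification forest is purpose-built (Rcpp) rather than wrapped from a
general-purpose library, because the regularized variants need control of
the node-level gain comparison and a shared state across trees:

* Trees grow on bootstrap samples (n draws with replacement); each node
  samples `mtry` loci without replacement and takes the best Gini-gain
  split, testing only the dosage midpoints **0.25 and 0.75** — with ordered
  codes {0, 0.5, 1} these two thresholds exhaust the split space, which is
  why the node search is cheap. Recursion stops at purity or
  `min_node = 5`; leaves vote their in-bag majority; forest prediction is
  plurality with ties to the lowest class label. Gain ties break to the
  lowest locus index; all randomness comes from a pinned 64-bit splitmix
  generator, so one seed gives a bit-identical forest on any platform.
* Defaults: `ntree = 2000` (out-of-bag error on cohorts like these
  stabilises by two thousand trees), `mtry = 2⌈√p⌉` (twice the
  classification default, the setting with the lowest OOB error on
  low-differentiation SNP data), `min_node = 5` (larger trees than the
  default of 1 would allow noise splits to dominate importance).
* **MDA importance**: per tree with at least one OOB case, OOB accuracy
  minus OOB accuracy after permuting one locus among those cases, averaged
  over such trees. Loci a tree never uses contribute an exact zero, so a
  constant locus has importance exactly 0 — a useful sanity anchor. The
  value is reported raw, not divided by its standard error: the scaled
  variant is a tool-specific option, and the raw mean is what the
  regularized guidance consumes.
* **RRF/GRRF**: trees grow *sequentially* and share a selected-feature set
  F. At each node the candidates are the `mtry` sampled loci plus every
  member of F; a locus outside F competes with gain × λ_i, members with raw
  gain, and the winner joins F. The per-locus penalty is
  λ_i = (1−γ)·λ + γ·imp_i with the base penalty fixed at 1, so plain RRF is
  γ = 0 (uniform λ) and GRRF is parameterized by γ alone, guided by a
  normalized (clipped at zero, scaled by the maximum) MDA vector from one
  plain forest run. Ties prefer F members: with λ = 1 this is the "minimum
  regularization" in which a new locus must *beat*, not merely match, the
  selected set — which is what suppresses exact duplicates. The selected
  panel is F in order of first selection; "features used in splits" is the
  algorithm's native output, chosen over any post-hoc importance cut.

Smaller λ (harsher penalty) gives smaller selected sets; larger γ likewise.
These monotonicities are asserted on seeded fixtures, as is planted-signal
recovery: with 100 loci at $F_{ST}$ 0.2 planted among 1,900 near-neutral
ones, at least 70 of the top-100 MDA loci must be planted ones in every one
of three seeds.

## Panel construction

* A stratified random **third of each population** (rounded half-up, at
  least 1) forms the training set; every selection method sees only those
  individuals. Scrambling the holdout genotypes provably cannot change any
  panel — a property test enforces it.
* **FST-rank panels** take the top k of the training-set θ ranking.
* **RF consensus panels** intersect the top-k loci of five MDA rankings from
  forests differing only by seed (the runs in the design differ only by
  forest stochasticity), each ranking truncated to positive-MDA loci;
  the panel is ordered by mean rank. Because the intersection size at rank k
  is data-dependent, target sizes are hit by bisection over k, to within
  10%.
* **RRF/GRRF panels** are whatever F the regularized forest emits for each
  λ/γ on the grid; exact target sizes cannot be requested, so cross-method
  comparisons pair panels by nearest size and report both.

## Assignment model

Baseline = integer minor-allele counts and called-allele totals per
population × panel locus, accumulated over **all** individuals. For an
individual in population k, its own alleles are first subtracted from k's
counts (leave-one-out); frequencies are Dirichlet(½, ½)-smoothed,
$q = (count + \tfrac12)/(total + 1)$; per-locus genotype likelihoods are the
Hardy–Weinberg proportions $q^2$, $2q(1-q)$, $(1-q)^2$; log-likelihoods are
accumulated in log space (mandatory at hundreds of loci) and normalized
under a uniform prior. Missing loci are skipped symmetrically, so an
individual missing everywhere gets the uniform posterior; an empty panel
yields uniform posteriors and chance-level accuracy by construction.
Accuracy is reported on holdout individuals only; the all-individual figure
is available as a diagnostic flag, and the anti-bias property (holdout
accuracy must not exceed training accuracy by more than noise) is asserted
in the acceptance suite. Bootstrap simulation of genotypes from the smoothed
baseline is provided for power checks but never feeds the headline accuracy.

The smoothing-and-HWE likelihood is the model family underlying the standard
assignment engines in this field; the uniform prior and
lowest-label tie-break are explicit so that results are reproducible to the
bit.

## The synthetic cohort

The generator is Balding–Nichols: per locus an ancestral frequency
$p \sim U(0.05, 0.5)$ and a differentiation level F from a two-component
mixture; each population's frequency is Beta-distributed with mean $p$ and
variance $p(1-p)F$; genotypes are binomial; cells go missing independently
at 0.0008. Defaults emulate the study design this pipeline targets: 11
populations of 17–22 individuals (231 total), 3,000 loci, mixture 90% at
F = 0.04 and 10% at F = 0.23, calibrated so realized per-locus θ has mean
≈ 0.059 with range ≈ 0–0.6 at 5,000 loci. An optional two-level mode
composes two Beta draws (ancestral → region → population) for hierarchical
structure. After simulation each locus is re-oriented so dosage 0 is the
globally rarer allele, the same convention the file readers enforce —
otherwise a silent sign flip could cancel between simulator and estimator.
Balding–Nichols was preferred to a coalescent simulator because it is
parameterized directly by the quantity every downstream claim is about,
and it is fast and dependency-free.

**What the simulator does not emulate** — and therefore what passing tests
do *not* show about real data: linkage between loci (each locus is drawn
independently), family structure among sampled juveniles, genotyping error,
Hardy–Weinberg departures, and uneven pairwise differentiation (without the
hierarchical mode all population pairs are statistically exchangeable).
Two consequences are worth stating plainly. First, panels of ~60+
independent loci that all cleared an $F_{ST} \ge 0.05$ floor saturate
holdout accuracy at 100% on this cohort; the informative region of the
accuracy–size curve sits below ~40 loci, and the analysis scripts score
truncated sub-panels to chart it. Second, the forest methods' practical
advantage on real data comes from exploiting multivariate structure that
independent-locus simulations do not contain — so here the four methods are
expected to tie within noise, and the end-to-end checks assert exactly that
form of parity (forest-selected panels within 2 points of FST-rank panels of
matched size) rather than any superiority margin.

## Evaluation conventions

The accuracy-versus-size table carries one row per (method, parameter);
the method effect is tested by comparing nested least-squares fits of
accuracy on (size, size²) with and without method indicators, reporting the
F ratio with its own degrees of freedom. The F statistic is computed
directly from the residual sums of squares so that an exactly null effect
returns F = 0 rather than an NA from floating-point cancellation. Confusion
matrices are row-normalized percentages over holdout individuals; pairwise
mismatch deltas divide cross-assignments between a population pair by the
pair's holdout total, and are reported against the pair's multi-locus θ.
All comparison outputs are numeric tables; plots are left to the analyst.

## Problem sizes and determinism

The shipped tests and the acceptance script run the full pipeline at
5 populations × 30 individuals × 2,000 loci (three seeds), the scale at
which the estimator-closure, enrichment and parity properties are stable;
the analysis scripts use the full default cohort (231 × 3,000). These sizes
were chosen as the smallest at which the statistical properties under test
are comfortably away from their thresholds. Every stochastic step takes an
explicit integer seed; forests and the C++ RNG are bit-reproducible across
platforms, and R-side draws use R's default generator under local
`set.seed` scoping that restores the caller's RNG state.

## Known limitations

* Genepop population labels are recovered by the common `POP_ID` prefix
  convention; arbitrary labels cannot round-trip through plain Genepop.
* The dosage convention assumes the matrix is minor-oriented; matrices
  constructed by subsetting individuals may locally violate "minor is
  rarer" without invalidating any computation (θ is orientation-invariant),
  but re-exported Genepop files re-derive the orientation.
* `prune_top_loci` is O(p × kept × n); fine at tens of thousands of loci,
  not designed for millions.
* The likelihood model assumes HWE within populations and independent loci;
  both assumptions are inherited from the standard assignment engines, and
  panels pruned at r² ≤ 0.2 keep the independence approximation reasonable.
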