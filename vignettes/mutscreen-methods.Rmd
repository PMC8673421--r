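---
title: "Methods: integrated mutation-association and CRISPR-screen analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated mutation-association and CRISPR-screen analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutscreen)
```

## Overview

`mutscreen` nominates chemoresistance genes by combining two independent
lines of evidence: case-control somatic-mutation association in a cohort of
treatment responders and non-responders, and gene-level positive selection
in genome-scale CRISPR knockout drug screens. This vignette documents the
statistical model behind each stage, the parameters that matter, the
numerical conventions, and what the synthetic-data validation does and does
not establish.

## Clinical association model

Each gene (or CNV event) is reduced to per-patient binary status: a patient
either carries at least one qualifying somatic mutation in the gene or does
not. All clinical statistics consume this binary status; site-level detail
(protein positions) is carried only as decoration in the MAF-like output.
This is appropriate because the downstream decision — is the gene mutated
more often among resistant patients? — is a property of the 2×2 table

|              | mutated | unmutated |
|--------------|---------|-----------|
| resistant    | a       | b         |
| sensitive    | c       | d         |

The odds ratio is oriented as `OR = (a·d)/(b·c)`, so OR > 1 always means
*resistant-enriched*. Structural zeros are flagged (`inf` when `c = 0` with
`a > 0`, `zero` for the mirror case, `undefined` when the table is
degenerate) rather than silently propagated, and a Haldane–Anscombe
continuity-corrected OR (0.5 added to every cell) is always reported
alongside as a finite point estimate.

The Fisher exact test is two-sided by the point-probability method: the
p-value sums hypergeometric probabilities of all tables with the observed
margins whose point probability does not exceed the observed one. Because
two-sided conventions differ between implementations, this one is stated
explicitly and verified against brute-force enumeration over every table
with total count ≤ 24 in the test suite. Comparisons of point
probabilities use the standard relative guard (1 + 1e-7) so that
symmetric tables that tie in exact arithmetic are not split by
floating-point rounding.

The clinical candidate set follows a two-component rule: genes mutated
*only* in the resistant group are included directly (no numeric OR exists
for them), and genes mutated in both groups are included when the raw
OR exceeds 1. The "significant" subset applies a raw `p < α` cut
(default α = 0.05) within the candidate set. Benjamini–Hochberg q-values
are always computed and reported, but do not gate membership: the package
reproduces the common reporting convention of raw per-gene p-values while
keeping the FDR-controlled quantity visible for any user who prefers it.

CNV events are tested by exactly the same machinery on a sample × event
matrix, typically restricted to a high-tumour-purity subset of samples.

## Screen model

### Normalization

Per-sample size factors are median-of-ratios: the median, over sgRNAs with
all-positive counts, of the sample's counts divided by the per-sgRNA
geometric-mean reference. When fewer than 100 sgRNAs have all-positive
counts the estimator is noisy, and a matrix with no all-positive row falls
back to total-count scaling. Factors are rescaled to geometric mean 1; this
convention makes normalization idempotent (re-normalizing returns factors
of 1 to within 1e-9) and absorbs the common multiplicative bias that the
median-of-ratios estimator has under strong overdispersion.

### Per-sgRNA statistics

For one condition (cell line × drug × timepoint) with treated and control
arms, replicate arms are averaged after normalization and each sgRNA gets
`lfc = log2((mean treated + ½)/(mean control + ½))`. The pseudocount 0.5 is
symmetric and keeps the statistic finite at zero counts. sgRNAs are ranked
by a variance-stabilized score: the lfc standardized by a lowess
mean–variance trend fit across sgRNAs (counts at low abundance have noisier
ratios, and without stabilization they dominate the top ranks). Inputs with
fewer than 50 sgRNAs use a pooled scale instead, and an exactly degenerate
input (all arms identical) returns the raw lfc so that the all-zero case is
well defined. Replicates are not given a per-replicate variance model: the
reporting unit is a single p/lfc per condition, so the arms are averaged.

### Gene-level positive selection

Gene scores use α-truncated robust rank aggregation. With a gene's `n`
sgRNA rank percentiles `u₍₁₎ ≤ … ≤ u₍ₙ₎` (u = rank / N over all N sgRNAs
in the condition),

ρ = min over { k : u₍ₖ₎ ≤ α_frac } of P[Beta(k, n−k+1) ≤ u₍ₖ₎],

i.e. the most surprising order statistic among the gene's sgRNAs that land
in the top `α_frac` fraction (default 0.25). If no sgRNA lands there,
ρ = 1. Truncation makes the score robust to inert guides: a gene with
three strongly enriched and three dead sgRNAs still scores well.

Significance is a permutation p-value: null rank sets of the same size are
drawn uniformly without replacement, and
`p = (1 + #{ρ_null ≤ ρ_obs}) / (1 + n_perm)` (add-one correction, so
p ∈ [1/(n_perm+1), 1]). Whenever the number of possible rank sets
`choose(N, s)` does not exceed `n_perm`, the null is enumerated
exhaustively and `p = #{ρ_null ≤ ρ_obs} / choose(N, s)` is exact — the
test suite verifies this equals independent enumeration for all gene sizes
up to 10 over N ≤ 12 ranks. Null distributions are cached per sgRNA-set
size, and a fixed seed makes every p-value bitwise reproducible.

A deliberate consequence of truncation: ρ (and therefore p) has an atom at
1 with mass `(1 − α_frac)^n` (≈ 0.18 for six sgRNAs at α_frac = 0.25), so
truncated p-values are *conservative*, never anticonservative — their null
distribution is uniform below the atom and deficient near 1. The null
calibration checks therefore test the permutation machinery for exact
KS-uniformity with truncation disabled (α_frac = 1), and separately verify
that the truncated default holds its nominal level at the operating
threshold (the fraction of null genes with p < 0.05 stays near, and not
meaningfully above, 0.05).

A gene is *selected* in a condition when `p < 0.05` and `lfc > 0`, where
the reported gene lfc averages the truncation-kept sgRNAs (all sgRNAs when
none are kept). The screen resistance set is the union of selected genes
across conditions, with a per-gene support vector. The consensus set ranks
union genes by their best (minimum) ρ across conditions, keeps the top
quartile (ties broken by smaller best p, then gene symbol), and requires
selection in at least one condition of *every* screened cell line. The
quartile is taken over the union resistance set — the natural universe when
the consensus is described as a fraction "of all resistance genes"; the
alternative (per-condition quartiles) would make the cut depend on how many
timepoints were screened.

### Control-arm convention

Control samples carry the same (cell line, drug, timepoint) labels as their
treated counterparts with `arm = "control"`, i.e. condition-matched
untreated controls. Designs with a shared day-0 or plasmid baseline can be
encoded by replicating the baseline columns into each condition's control
arm.

## Integration

The integrated set is the plain intersection of the clinical candidate set
and the screen union, after uppercasing and whitespace-stripping gene
symbols on both sides; symbols present on only one side are retained in a
reconciliation log rather than silently dropped. Because the clinical side
only admits resistant-only and shared-OR>1 genes, no sensitive-only gene
can enter. The resistance matrix (clinically significant ∩ screen-supported
genes × conditions) orders rows by ascending clinical p; any visual
ordering beyond that carries no meaning.

## Over-representation analysis

Query sets are tested against GMT annotation collections with the
hypergeometric upper tail `P[X ≥ k]`, `X ~ Hypergeom(N, K, n)`. The
universe defaults to the full cohort gene namespace and must be explicit:
gene ratios (`k/n`, with n the annotated query size) are meaningless
without a stated universe and annotation release, which is why enrichment
statistics computed on different annotation versions are not comparable.
Terms are restricted to the universe and size-filtered (default 5–2000)
before testing; terms with `k = 0` are reported with p = 1 so the caller
can filter rather than lose them. Exactness is verified against direct
combinatorial summation up to N = 60.

## Synthetic-data generator

The generator emulates the study design the package targets:

* **Cohort**: 135 patients, 48 resistant / 87 sensitive, per-gene
  Bernoulli mutation status. Planted genes specify a sensitive-group
  probability and a target odds ratio; the resistant-group probability
  follows the odds transform `p_r = OR·o_s / (1 + OR·o_s)`,
  `o_s = p_s/(1−p_s)`. The background per-gene probability defaults to
  0.03 — a mid-frequency somatic rate (about four mutated patients per
  gene) typical of non-hypermutated exomes once ultra-rare genes are set
  aside.
* **CNV events**: same generative scheme over events, on a seeded random
  two-thirds sample subset, mirroring the exclusion of low-purity samples
  before CNV calling.
* **Screen**: negative-binomial counts with variance `μ + φμ²`
  (baseline mean 300 reads/sgRNA, dispersion φ = 0.2 — values typical of
  well-covered knockout screens), 6 sgRNAs per gene as in common
  genome-scale libraries, two cell lines × two drugs × two timepoints, two
  replicates per arm. Planted genes multiply the treated-arm mean by an
  enrichment fold (default 8) in their matching conditions. Library-size
  factors are drawn log-uniform in [0.7, 1.3] and rescaled to geometric
  mean 1 — the rescaling keeps the marginal control-count mean at the
  nominal baseline while still exercising normalization.

Every generator is a pure function of its parameter object, including the
seed; no global RNG state is touched.

What the generator does **not** emulate: mutational signatures and
per-site hotspots, copy-number segmentation noise, clonal structure, sgRNA
efficiency differences, bottleneck-induced count dropout, and
between-replicate batch effects. Passing recovery tests therefore
demonstrate that the estimators are correct and well calibrated under the
stated generative model — not that real cohorts of this size would yield
any particular number of candidates.

## Numerical choices and degenerate inputs

* Fisher point-probability comparisons and the enumeration oracle both use
  the relative guard (1 + 1e-7) against floating-point ties.
* Unmutated genes carry p = 1, category `unmutated`, and are excluded from
  BH adjustment.
* An all-zero screen sample is an error naming the sample; an event present
  in every sample is flagged `undefined` with p = 1.
* Empty mutation input yields an all-zero cohort matrix with a warning;
  zero CNV events yield an empty matrix without error.
* Gene symbols are matched after uppercasing and whitespace-stripping.
* All file writes are atomic (write-then-rename), and every output table
  round-trips through its reader bit-identically.

## Validation problem sizes

The test suite and `scripts/acceptance.R` validate calibration and recovery
at sizes chosen to make the binomial error of the measured rates small
relative to the margins being asserted: null calibration over 20 cohorts of
2000 genes and an 800-gene screen; clinical recovery over 200 seeds; screen
recovery over 100 seeds; end-to-end integration over 20 seeds of an
800-gene dual-modality simulation; permutation loops at n_perm = 1000–2000
(the package default is 10000, appropriate for production runs where the
smallest resolvable p matters).

## Known limitations

* The clinical test is marginal per gene: no covariates, no mutual
  adjustment, no driver-vs-passenger modelling.
* Truncated-RRA p-values are conservative near 1 (see above); do not
  interpret the shape of their upper tail.
* The two-component candidate rule admits every resistant-only gene
  regardless of frequency; with small cohorts this component is large and
  individually weak — the significant subset and the screen intersection
  are the interpretable outputs.
* OR estimates from structural-zero tables are reported only via the
  continuity-corrected estimator and should be read as order-of-magnitude.
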