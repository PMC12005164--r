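---
title: "Calling imprinting dynamics from reciprocal crosses: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling imprinting dynamics from reciprocal crosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imprintr)
library(dplyr)
```

# The problem

Triploid endosperm carries two copies of the maternal genome and one of the
paternal genome. Because of this asymmetry — and of maternal-specific
demethylation before fertilization — endosperm is the main site of genomic
imprinting in flowering plants: genes whose expression depends on the parent
of origin of the allele. `imprintr` implements a complete analysis chain for
detecting and characterizing imprinting from allele-resolved RNA-seq of
*reciprocal crosses* (A×B and B×A, so each genome is observed both as mother
and as father), across developmental time points and across genotype panels.

The pipeline assumes reads have already been mapped to the concatenated
parental genome assemblies and counted per parental gene model; the unit of
analysis throughout is therefore the **gene-allele**, a gene model of one
parental genome, identified as `"<genome>:<gene>"`.

# The reciprocal expression ratio and its dosage null

For a gene-allele, let $m$ be its mean RPM over the samples in which its
source genome was inherited maternally, and $p$ the mean RPM over the
reciprocal direction. The reciprocal expression ratio is

$$\mathrm{RER} = \frac{m}{m + p} \in [0, 1].$$

Under biparental expression proportional to genome dosage, the maternal
alleles produce $2/3$ of transcripts, so the null value is
$\mathrm{RER} = 2/3 \approx 0.66$ — not $1/2$. `compute_rer()` is
scale-invariant and undefined (NA) only when $m = p = 0$.

```{r}
compute_rer(2, 1)
```

Status calls combine RER cutoffs with a statistical gate:

* **MEG** (maternally expressed gene): RER $\ge$ 0.9 *and* adjusted
  $p < 0.05$ in the fold-change-threshold test below;
* **PEG**: RER $\le$ 0.3 and adjusted $p < 0.05$;
* **maternal / paternal bias**: RER $> 0.8$ / $< 0.4$, no significance
  required — a deliberately lenient tier that captures allelic preference
  where counts are too low for significance;
* **biparental** otherwise; **not expressed** below 1 RPM.

Boundary conventions: the imprinting cutoffs are closed ($\ge 0.9$,
$\le 0.3$), the bias cutoffs strict ($> 0.8$, $< 0.4$). Boundary values are
rare in practice; the convention is fixed here so the rule table is total.
The paternal-bias cutoff is a field of `imprint_thresholds()` because both
0.4 and a stricter 0.3 variant are in circulation; the default is 0.4.

# The fold-change-threshold test

Significance comes from a negative-binomial Wald test of the *composite*
null $|\log_2 FC| \le \theta$ (default $\theta = 1$) between the two
inheritance directions — i.e. a gene must be significantly **more** than
2-fold different when inherited maternally vs paternally, which absorbs the
2:1 dosage contribution. The construction is the standard one for
threshold tests: two one-sided Wald tests at $+\theta$ and $-\theta$,
$p = \min(1,\, 2\min(p^+, p^-))$.

Design notes, in decreasing order of consequence:

* **Size factors** are library totals divided by $10^6$, consistent with
  the RPM normalization used everywhere else (a config switch away from
  median-of-ratios scaling was considered and rejected for coherence:
  group means then come out directly in RPM units).
* **Dispersion** is estimated per gene by the method of moments on
  normalized counts (`dispersion_mom()`), pooled across the two groups,
  then shrunk toward a fitted $\alpha(q) = a_0 + a_1/q$ mean-dispersion
  trend with weight $d/(d + d_0)$, where $d$ is the residual degrees of
  freedom and $d_0 = 4$ the prior weight, floored at $10^{-8}$. With 3+3
  replicates this gives the trend half the weight. This is intentionally a
  re-implementation of the *contract* (NB Wald test, threshold composite
  null, BH FDR) rather than of any particular package's internals: no
  empirical-Bayes shrinkage of fold changes, no outlier replacement, no
  independent filtering.
* **Zero groups**: a group with zero total counts contributes half a read
  for estimation so the statistic stays finite; genes with zero counts in
  *both* groups are flagged untestable, get no p-value, and are excluded
  from the Benjamini–Hochberg denominator. BH adjustment is applied within
  each time point.
* The time-course contrast (`de_vs_baseline()`, each later time point vs
  11 DAP within one cross direction) instead uses the plain two-sided test
  plus the $|\log_2 FC| > 1$ point filter — the conventional "log2FC > 1,
  FDR < 0.05" DE rule — because the threshold null is specific to the
  imprinting question.
* Tests are run **per time point**; the alternative (one model with time
  as covariate) answers a different question and would entangle the
  per-time-point status calls that the temporal grouping consumes.

Calibration rather than bit-parity is what the test suite checks: on 5,000
simulated dosage-null genes (NB dispersion 0.05, 3+3 replicates, mean 500
counts — a regime where the true $|\log_2 FC|$ sits exactly on the
threshold), the fraction of MEG/PEG calls stays below $\alpha$ plus three
binomial standard errors.

# Temporal-consistency groups

Genes imprinted at $\ge 1$ time point are classified hierarchically
(first match wins, which makes the groups disjoint):

| rule | condition |
|------|-----------|
| filtered | mean RPM across time points $< 1$ |
| Group 1 | expressed ($\ge 1$ RPM) at every time point and imprinted in the same direction at every time point |
| Group 2 | imprinted in the same direction at every time point at which it is expressed |
| Group 3 | same-direction parental bias at every non-imprinted time point |
| Group 4 | $\ge 5$ RPM at every time point and $\ge 1$ time point neither imprinted nor same-direction biased |
| unassigned | otherwise |

"Expressed at a time point" means replicate-mean RPM $\ge 1$ there; the
global filter uses the mean across time points. Group 3 is applied
strictly (bias required at *every* non-imprinted time point); a
most-instead-of-every variant was considered and rejected because it blurs
the boundary with Group 4, which exists precisely to hold genes that
genuinely gain or lose imprinting. A gene called MEG at one time point and
PEG at another (never observed in practice; direction `"mixed"`) skips
Groups 1–3, and the Group 4 "same-direction bias" clause never matches for
it. The rule engine is a pure function of the status and RPM vectors; the
test suite proves it equivalent to an independently coded brute-force
evaluator over the full enumeration of $6^4$ status vectors crossed with
all $3^4$ RPM regimes $\{<1, [1,5), \ge 5\}$.

The two reciprocally mapped alleles of a gene are classified
independently and merged only in reporting, matching how per-genome
imprinting counts are usually presented.

# Cross-genotype conservation

For a panel of genotypes reciprocally crossed with the reference, each
gene's **percent same imprint** is the number of genotypes in which it is
parentally biased in its reference direction (lenient thresholds, no
significance gate — panel libraries are typically shallower than the time
series) divided by the number of genotypes with an expressed syntelog.
Choices made where the procedure is underdetermined:

* the per-genotype RER/status is read off the reference-mapped allele,
  since the reference is the common parent of every cross;
* a syntelog is "expressed" when maternal + paternal mean RPM $\ge 1$,
  reusing the grouping filter value;
* genes enter a genotype's tally only through a **single-copy** pan-gene
  row in both genomes — multi-copy rows and genes without informative
  variants never enter the denominator;
* the reference direction comes from the time-series calls, not from a
  panel consensus;
* group-level summaries drop genes with fewer than 4 expressed genotypes.

On constructed panels the score is exact ($k$ of $n$ biased genotypes
gives $k/n$), and planted group-wise conservation gradients are recovered
in order — the stepwise pattern by which conservation across genotypes
tracks consistency across development.

# Developmental clustering

Trajectories are replicate-mean RPM per time point within one cross
direction (allele rows summed per gene, the single-reference view),
divided by the per-gene maximum so every retained gene spans $[0,1]$ with
maximum exactly 1; all-zero genes are dropped and counted. Ties at the
maximum all take value 1 and `max_dap` reports the earliest — a
deterministic, documented convention. No expression floor is applied
before clustering (any nonzero gene enters); a floor is a caller-side
filter if wanted.

Clustering is `stats::kmeans` (Hartigan–Wong, Euclidean distance on the
normalized 4-vectors, `nstart = 25` restarts keeping the best objective)
under a fixed seed, with `k = 9` by default. `stats::kmeans` is used
deliberately rather than a bespoke Lloyd/k-means++ implementation: the
clustering is descriptive, exact algorithm identity carries no scientific
content, and determinism — which the seed plus restart-minimum provide —
is what matters. Because k-means labels are arbitrary, labels are
canonicalized by centroid peak time, then peak sharpness, which makes
assignments stable under permutations of gene order. Cluster labels fitted
on one direction are transferred to the reciprocal direction by gene
identity (`transfer_clusters()`); `transfer_consistency()` then correlates
each centroid with the mean reciprocal trajectory of its transferred
genes — near-1 correlations are the expected signature of shared dynamics
across the reciprocals.

# Tissue preference and the mutant cross-tabulation

Against a 10-tissue RPM atlas, a gene is **endosperm preferred** when
strictly more than 65% of its summed atlas RPM comes from the endosperm
replicate columns ("more than 65%" read literally, so exactly 65% is
multitissue). Fractions are computed on RPM, matching how such atlases
are distributed. The mutant-vs-WT DE list (the glycosylase-mutant
comparison used to annotate maternally activated genes) is an *input* —
a published result, not recomputed here — and genes outside that study's
detected universe land in an explicit `not_detected` bin rather than
being conflated with "not DE".

# The synthetic data generator

Every stage is exercised end-to-end on `simulate_experiment()`, which
draws experiments with known truth:

* counts per gene and library are negative binomial with mean
  `base_rpm(dap) × library_size / 1e6` and a shared dispersion
  (default 0.05, a typical bulk RNA-seq value; the study's real libraries
  provide no desk-scale dispersion estimate, so the default is chosen for
  testability, not fidelity);
* the maternal-allele count is binomial conditional on the gene total,
  with probability equal to the class's maternal transcript fraction —
  this keeps total-expression trajectories independent of imprinting
  class;
* the same gene appears as two allele rows, one per genome; genes subject
  to presence/absence variation lack the row (and lose the reads) of the
  missing genome.

Default study conditions: 2 directions × 4 time points (11/14/17/21 DAP)
× 3 replicates, 5e6-read libraries (15% CV), ~3,300 genes: 400
constitutive MEGs (maternal fraction 0.97) and 100 constitutive PEGs
(0.03); 200 transients (imprinted at 1–3 time points, biparental 2/3
elsewhere — the Group 4 archetype); 400 bias-class genes (imprinted at
exactly one time point, fractions 0.85 / 0.35 elsewhere, occupying the
lenient bands — the Group 3 archetype); 1,800 biparental genes with a
deliberate low-expression tail straddling the 1 RPM filter; 50 silent
genes; and 10 "zein-like" genes at 100–1,000× median expression peaking
at 17 DAP, which stress RPM normalization exactly the way storage-protein
transcripts do (they compress every other gene's RPM at their peak).

What the generator does **not** emulate: mapping/reference bias between
parental assemblies, read-level error, correlated library artifacts,
per-gene dispersion heterogeneity (configurable but constant by default),
and cis-regulatory structure. Passing tests therefore demonstrate that
the statistical machinery recovers known truth under its own model
assumptions — not that those assumptions hold for any particular real
library.

Recovery under the default conditions (checked in the test suite): ≥90%
of constitutive MEG alleles in Group 1, ≥80% of transients in Group 4,
≤5% of biparental genes in any group. The bias classes sit intentionally
close to their thresholds (0.85 against 0.8, 0.35 against 0.4), so their
Group 3 recovery is high only when dispersion is tight; that sensitivity
is a property of lenient thresholds near the sampling noise floor, and is
itself worth knowing when interpreting real bias calls.

# Reproducibility and problem sizes

Seeds are mandatory for every stochastic entry point; `run_pipeline()`
derives stage seeds from its master seed and writes byte-identical
outputs on rerun. The test suite runs the full default synthetic
experiment (~3,300 genes, 24 libraries) for class recovery, 5,000 genes
for test calibration, the complete 104,976-case rule enumeration, 1,000
random vectors against the brute-force FDR oracle, and 200-gene planted
clustering problems — sizes chosen so the whole suite completes in well
under a minute per file on a laptop while keeping every estimate's Monte
Carlo error far from the asserted margins.

# Known limitations

* The Wald test with moment dispersion is slightly anticonservative at
  very low counts; the RER gate in the status rule makes false MEG/PEG
  calls doubly unlikely, but raw `test_fold_change()` p-values near the
  expression floor deserve caution.
* RER is computed from replicate-mean RPM per direction, not per
  replicate; with very unequal replicate depths a weighted mean would
  differ. The group-level reading matches how the ratio is defined in
  the field.
* At 21 DAP real designs are sometimes unbalanced (lost libraries);
  the tests require ≥2 replicates per direction per time point and error
  otherwise rather than silently degrading.
* Syntelog identification is consumed, not performed: the package trusts
  the single-copy pan-gene resource it is given.
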