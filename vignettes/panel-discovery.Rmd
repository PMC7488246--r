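---
title: "Discovering pigmentation SNP panels: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering pigmentation SNP panels: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pigsnp)
```

`pigsnp` turns a regional association-discovery workflow for ordinal
pigmentation traits into a single fitted-model interface. This vignette is
the package's own account of the science inside it: the statistical models
and their assumptions, the parameters that matter, what the synthetic cohort
generator does and does not emulate, and the places where the design was
genuinely open and a choice had to be made.

## The trait model

Field phenotyping assigns each individual an ordinal darkness grade 0–4 per
trait. The pipeline treats these grades as a *continuous* target: the grades
quantify the concentration of dark pigment, so adjacent classes are not
independent categories but points on one axis. This single assumption drives
most downstream machinery — correlation/F screening, lasso regression and
the least-squares classifier are all linear models of grade on
alternate-allele counts (0/1/2). Red hair is the exception: it is a separate
phenotype axis (a recessive loss-of-function phenotype, not a point on the
darkness scale), and the package keeps it as its own class throughout.

Classification uses coarser forensic scales. The mapping from 5 grades to
the eye 3-class scale is not canonical; the package defaults to the
symmetric split {0,1} → blue, {2} → intermediate, {3,4} → brown, and exposes
the mapping in `class_scale()` because other splits are defensible. For hair
the anchors 0 → red, 1 → blond, 4 → dark are fixed and the unpinned middle
grades {2,3} default to brown.

## Feature selection: three scorers, one training split

Every dataset (each region, plus the pooled cohort) is split 60:40 into
training and test, stratified by class × region, and *all* selection,
scoring and model fitting consume the training split only. The test split is
touched exactly once, by the final per-class evaluation; the test suite
verifies this by mutating held-out labels and asserting bit-identical
selection output.

**Univariate F test.** For SNP j, `r_j = cor(x_j, y)` on the training
samples, `F_j = r_j² / (1 − r_j²) · (n − 2)`, with the upper-tail p-value on
(1, n − 2) degrees of freedom — identical to the squared t statistic of the
univariate regression slope. A `p < 0.01` gate precedes the descending-F
ranking. Monomorphic SNPs have undefined correlation and are excluded from
the ranking rather than given a pseudo-score.

**Mutual information.** MI between a genotype and the grade target is
estimated nonparametrically from k-nearest-neighbour distances (k = 3).
Genotype regressors are discrete, so the mixed discrete/continuous estimator
variant is used: within-class kNN radii in the (jittered, standardised)
target define per-point neighbourhood counts whose digamma averages combine
into the MI estimate; estimates are clipped at zero. For continuous pairs the
package provides the classic joint-space kNN estimator (`knn_mi()`), which the
test suite calibrates against the Gaussian closed form
`MI = −½ ln(1 − ρ²)` at n = 2000 within ±0.1 nats. A jitter of relative
magnitude 1e−10 breaks the heavy ties in ordinal targets; it is drawn from
the seeded RNG, so pipeline results are reproducible, and its influence on
the estimate is orders of magnitude below the reporting precision.

**Lasso path.** Coordinate descent minimises
`(1/2n)‖Xw − y‖² + α‖w‖₁` with an unpenalised intercept (handled by
centring), cyclic updates, active-set sweeps, a tolerance of 1e−6 on the
largest coefficient update and a budget of 10⁴ sweeps. Two numerical
choices matter:

- **No standardisation.** The downstream scoring rules threshold raw
  absolute coefficients (≥ 0.1, > 0.05). Those cutoffs are only meaningful
  on the natural 0/1/2 genotype scale, so regressors are deliberately not
  rescaled. A consequence worth knowing: low-frequency SNPs have small
  variance and therefore systematically larger coefficients, and the
  absolute-coefficient rules are mildly biased toward them.
- **"Nonzero" means |coef| > 1e−8**, absorbing solver noise well below the
  decision thresholds.

At the smallest grid penalties (α ≤ 0.005) with many more SNPs than training
samples the problem enters the interpolation regime: the fit is exact, the
solution is weakly determined, and convergence can be slow (the solver
flags non-convergence rather than hiding it). The selection rules only
consume coefficients at α ≥ 0.005, where the test suite verifies agreement
with an independent solver (glmnet) and with closed-form oracles
(soft-thresholding on orthonormal designs, brute-force grid search on
2-parameter problems, KKT conditions).

The path is fitted from the largest α downward with warm starts; nonzero
counts are non-increasing in α (checked as a property), and the per-α
training r² documents how much of the grade variance each sparsity level
captures.

## Scoring rules and SNP-set selection

The three scorers are condensed into an integer score 0–3 per SNP and
dataset by *declarative* rule sets (`scoring_rules()`): each rule is a score
plus a list of clauses over provenance flags (rank cutoffs, nonzero sets,
absolute-coefficient thresholds, best-list membership), a SNP receives the
maximum score among matching rules, and score 3 is reserved for the pooled
dataset, whose sample size makes its evidence the most robust. Keeping the
rules as data rather than code lets the eye/hair and pooled/regional
variants — including their threshold inconsistencies (≥ 0.1 for eye at
α = 0.005 and 0.2, strictly > 0.05 for hair at α = 0.2) — coexist verbatim,
and lets a user audit or modify them without touching the engine. An
independent brute-force transcription of the rules in the test suite guards
the engine against drift.

Two wording ambiguities in the regional rules had to be resolved:

- *"top 5 with highest F and MI scores"* is read as a conjunction (the SNP
  must sit in both top lists), the literal reading and the stricter one; the
  disjunctive reading is available via `regional_rank_combine = "or"`.
- The regional score-1 clause "nonzero at α = 0.7 and 0.5" overlaps the
  score-2 clause "nonzero at α = 0.7"; max-rule semantics resolves the
  overlap harmlessly.

Per-dataset scores are summed into the **total score** (a missing dataset
contributes 0), SNPs are ranked by descending total with ties broken by the
number of supporting datasets and then SNP id, and all-zero SNPs drop out.
The *optimal* set is every SNP with a nonzero pooled score; the *minimal*
set is the top tier — for eye colour, total ≥ 3 with support from more than
one dataset; for hair colour, the pooled score-3 SNPs. Both tier rules are
configurable because the ranking, not the cutoff, is the method's substance.

## Classification and evaluation

The classifier is ordinary least squares of grade on the selected codes —
deliberately simple, since the discovery claim is about the SNP set, not
the model class. Rank-deficient designs (selected SNPs in perfect LD) fall
back to a minimally regularised ridge solve (1e−6) with a warning.
Continuous predictions are cut at grade midpoints (exact midpoints resolve
to the darker grade) and mapped through the class scale.

Evaluation is per class: one-vs-rest AUC from the continuous score,
precision and recall from the hard classes, overall accuracy, and r² of the
continuous prediction against the ordinal grade. Conventions:

- For the extreme classes the continuous score itself (sign-oriented) is
  the ROC score, making the AUC invariant under monotone transforms.
- For middle classes no orientation of a one-dimensional score is canonical;
  the package uses the negative absolute distance to the class's
  representative grade. This is a documented convention — it is *not*
  invariant under monotone score transforms, and middle-class AUCs should be
  read accordingly.
- Classes with fewer than `min_class_n = 10` test samples are reported `NA`:
  metrics on a handful of samples mislead more than they inform, and
  ordinal cohorts structurally under-populate the intermediate classes.

Externally produced panel predictions (a CSV of per-sample classes and
optional per-class probabilities) run through the *same* evaluation code
(`evaluate_external()`), so comparisons between the discovered panel and a
reference panel are paired: one seeded split, one metric path, identical
N/A conventions.

## The synthetic cohort generator

The generator exists so the pipeline can be tested against known truth; its
defaults describe the study conditions the package is built for, not knobs
to be tuned per run.

- **Population structure.** Per-region allele frequencies follow the
  Balding–Nichols model: Beta-distributed around the ancestral frequency
  with variance `p(1−p)·F`, the standard drift parameterisation for
  structured populations (default divergence 0.1, three regions of 100
  samples). Frequencies are clipped to [1e−4, 1 − 1e−4] so no region fixes
  an allele.
- **LD.** SNPs come in blocks (default 5 SNPs) copying two shared latent
  haplotype alleles with flip probability 0.1, giving within-block genotype
  correlation ≈ 0.6 — enough to exercise the proxy-vs-causal ambiguity that
  total-score ranking has to survive, without the cost of coalescent
  simulation.
- **Causal architecture.** Each trait has 5 causal SNPs in disjoint blocks
  with liability effects (1.6, 1.0, 0.9, 0.8, 0.7) and Gaussian noise
  sd = 0.5, i.e. heritability ≈ 0.9 with one dominant lead locus about twice
  the effect of the rest. This mirrors the near-Mendelian genetics of human
  eye colour, where a single HERC2-region variant dominates and a handful of
  loci carry the remainder.
- **Phenotypes.** Liability is cut at ordered thresholds into grades; by
  default thresholds sit at the empirical liability quantiles implied by the
  target class proportions (eye 16/16/2/33/33 %, matching a cohort that is
  about one-third light-eyed with a thin intermediate class; hair darkness
  15/13/13/59 % among non-red). Red hair is a dedicated recessive locus
  (ancestral frequency 0.25): homozygous carriers get grade 0 regardless of
  darkness liability.
- **Data artefacts.** Genotype calls go missing uniformly at 2 %; written
  VCFs carry synthetic QUAL ~ U(20, 100) and DP ~ Poisson(30) so the QC
  filters have real work to do. All randomness flows from one seed; a fixed
  seed reproduces the dataset byte-for-byte on disk.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: realistic human LD maps and allele-frequency
spectra (blocks are independent and uniform-frequency), phenotyping
disagreement between observers, genotyping error beyond missingness,
cryptic relatedness or admixture gradients within regions, and any
environmental covariance. A pipeline that recovers planted causal SNPs here
has demonstrated its logic, not the field validity of any particular panel.

## Problem sizes used by the tests and the acceptance study

The synthetic recovery study runs 20 cohorts of 3 regions × 100 samples ×
5000 SNPs (5 causal) plus 5 null cohorts with all effects zero, checking
that every causal block reaches the optimal set in ≥ 90 % of seeds, that
held-out blue/brown AUC averages ≥ 0.9, and that null cohorts sit at
chance. The unit suite uses 2-region, 300-SNP cohorts; these sizes keep the
full suite comfortably fast while leaving every stage statistically
identifiable.

## Known limitations

- The discovery and evaluation samples come from one cohort; as in any
  single-cohort workflow, reported performance is an upper estimate, and
  region-specific SNPs in particular need replication.
- The intermediate classes are evaluated only when they reach the minimum
  class size, and their AUC orientation is a convention (above).
- The 5 → 3 eye-grade mapping and the minimal-set tier cutoffs are
  configurable defaults, not identified quantities.
- The absolute-coefficient rules inherit a mild low-frequency bias from the
  unstandardised lasso (discussed above); this is faithful to the method,
  not an accident of the implementation.
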