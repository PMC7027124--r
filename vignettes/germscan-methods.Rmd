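---
title: "Methods: discovering and evaluating prognostic germline variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering and evaluating prognostic germline variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germscan)
```

## The problem

Inherited (germline) variants can shift a cancer patient's prognosis, yet
most survival modelling in oncology uses clinical covariates alone.
`germscan` implements a complete discovery pipeline for prognostic germline
variants in multi-cancer cohorts: genotype calls from three sequencing
sources per patient are merged and quality-controlled, each variant is
tested for association with outcome by Cox proportional-hazards regression
within cancers and in pooled cancer groups, and the resulting hits are
characterized statistically, evaluated for added predictive value, and
triaged for a plausible *cis*-regulatory mechanism.

Real cohorts of this kind are access-controlled, so the package ships a
synthetic-cohort generator that reproduces the statistical structure the
analysis assumes — Hardy-Weinberg genotypes, three corruptible call sets
with read depths, proportional-hazards outcomes with planted effects,
planted eQTLs and planted variant–driver associations — with the planted
truth serialized next to every output. Every claim in this vignette is a
property the test suite actually computes on such cohorts.

## Call merging and quality control

Each patient contributes up to three call sets: normal exome, tumor exome,
and tumor RNA. Calls covered by fewer than `min_depth` reads (default 10)
are masked unknown. The merged genotype is the first known call in the
fixed precedence normal exome → tumor exome → tumor RNA, with the source
recorded as provenance.

A patient is *concordant* for a variant when all three sources give the
exact same genotype class. The per-variant concordance percentage divides
concordant patients by **all** patients of the cancer; a patient with any
unknown source call counts as not concordant. This is the conservative
reading of a denominator defined as "the total number of patients": the
alternative (dropping unknown-containing patients from the denominator)
would inflate concordance for poorly covered variants exactly where the
filter matters. The choice is configurable in spirit — concordance is a
plain function of the three call sets, so other summaries are easy to
derive — but the strict rule is what `qc_filter()` consumes.

Three filters gate discovery, evaluated per (variant, cancer):

* population allele frequency strictly greater than 5% (an input column;
  there is no population-database lookup);
* at least 15 carriers — "found in" a patient is read as carrying ≥ 1
  alternate allele in the merged calls;
* three-way concordance strictly greater than 90%.

Boundary semantics are strict on purpose: AF = 0.05 and concordance = 90.0
fail, 15 carriers pass. The filter fixture in the tests pins one excluded
variant per filter.

## The survival kernel

Cox models are fitted by partial-likelihood maximization (Efron tie
handling by default, Breslow available) and reported with Wald p-values,
the convention of the mainstream survival software this field uses.
Fits showing monotone-likelihood behaviour (runaway coefficients or
exploding standard errors, the signature of separation) are flagged
non-converged; scans exclude them from the multiple-testing family rather
than assigning p = 1, which would distort calibration. Non-converged fits
remain in the output tables for audit.

Clinical covariates are selected per cancer by L1-penalized Cox regression
with 10-fold cross-validation. The penalty is the largest within one
standard error of the minimum mean partial-likelihood deviance. The bare
minimum-deviance penalty was tried first and rejected: with one strong
planted covariate and nine pure-noise candidates it retained a median of
five noise covariates, which is useless as a *selection* rule; the 1-SE
rule retains the signal and drops almost all noise in the same benchmark.

Genotype coding for the tested variant is additive dosage (0/1/2) by
default — homozygous carriers of a risk allele show stronger effects than
heterozygotes in this setting — with a dominant (carrier) option. Patients
with unknown genotype at the tested variant are dropped from that variant's
fit only.

Power for a two-sided test of a binary exposure uses the Schoenfeld
formula with variance inflation,

$$\mathrm{power} = \Phi\!\left(|\ln \mathrm{HR}|\sqrt{D\,p(1-p)(1-R^2)} - z_{1-\alpha/2}\right),$$

with $D$ the expected number of events, $p$ the exposed fraction, and
$R^2$ the squared multiple correlation of the exposure with the other
covariates. The scan-wide significance level is $0.10/m$ for $m$ variants
tested in the cancer. The formula is validated against the empirical
rejection rate of 1,000 simulated Cox fits rather than against any
particular software implementation, since published analyses differ in
which variant of the formula they use. One caveat the tests pin down: when
events are scarce and the hazard ratio is large the approximation is
mildly *conservative* (it understates power by a few percent, because the
exposed fraction among events drifts above the sample exposed fraction);
it agrees with simulation closely at the event rates of the default study
conditions and never overstates power in either regime.

## The six discovery analyses

1. **Per-cancer scan** — one Cox fit per (variant, cancer) controlling the
   cancer's selected covariates; Benjamini-Hochberg within cancer; hits at
   FDR < 0.10.
2. **Recurrence** — variants with unadjusted p < 0.05 *and a single shared
   hazard-ratio direction* in ≥ 7 cancers.
3. **Pooled groups** — cancers pooled by clinical/molecular similarity.
   The design contains cancer-membership dummies (the last member in sorted
   order is the reference, so a group {X, Y} carries the column `X_status`)
   plus one interaction column per (cancer, selected covariate): the
   covariate inside that cancer, zero outside. A covariate selected in two
   member cancers contributes two separate columns, never a pooled one.
   Only variants with ≥ 15 pooled carriers are tested; BH within group.
4.–6. repeat 1–3 restricted to variants with CADD score > 25 (the
   recurrence threshold drops to 5 cancers), with the BH family equal to
   the restricted set.

Direction is labelled from the hazard ratio: HR > 1 is *poor*, HR < 1
*favorable*, applied uniformly in every module. Variants hit in several
overlapping groups are reported by the largest group. A sensitivity mode
reruns any scan with an extra covariate block and reports the Spearman
correlation of the log hazard ratios, the generic form of the
race-composition re-test.

## Characterization

* **Direction concordance.** For variants significant (p < 0.05) in ≥ 3
  cancers, the index is $\max(n_\mathrm{poor}, n_\mathrm{fav}) /
  (n_\mathrm{poor}+n_\mathrm{fav})$, so 1 means perfect concordance and
  the floor is 0.5. Because discovery conditions on significance, the
  expected index under no per-variant concordance is *not* 0.5; it is
  estimated empirically as the same ratio over the totals, and the
  observed indices are compared to it by a one-sample Wilcoxon test.
  Under random 50/50 directions with three qualifying cancers the mean
  index is exactly 0.75 (binomial enumeration), which the tests verify by
  simulation.
* **Hazard-ratio correlation.** All within-variant pairs of hazard ratios
  (favorable and poor sets separately), Spearman correlation; a partial
  Spearman (first-order partial correlation of rank-transformed vectors)
  controls for allele frequency, since effect size and frequency are
  themselves correlated.
* **Minor-allele enrichment.** Each linkage-pruned hit is classified by
  minor-allele status (alternate allele minor iff AF < 0.5; population AF
  preferred, cohort AF as fallback) and direction; a one-sided Fisher test
  asks whether minor alleles are enriched among poor-outcome associations.
* **Linkage pruning** removes variants whose genotype $r^2$ exceeds 0.8
  (no published threshold exists for "highly linked"; 0.8 is the GWAS
  convention) keeping the first variant by genomic position,
  order-independently.
* **Region classification** assigns upstream / 5′ UTR / exonic / intronic /
  3′ UTR / downstream / intergenic labels against a transcript table
  (1 kb flank windows by default), letting one variant count once per
  region across transcripts.
* **Pair independence.** For pairs of poor-direction hits within a cancer,
  homozygous carriers of either variant are excluded (they are rare and
  their stronger effect would confound the contrast), and three groups are
  formed: reference/reference, heterozygous for exactly one, heterozygous
  for both. One Cox fit per pair yields HR(one vs none) and HR(both vs
  none); a paired one-sided signed-rank test across pairs asks whether
  carrying both variants is worse than carrying one.
* **Driver association.** Per (hit, driver gene) with ≥ 5 mutated
  patients: one-sided Fisher test of risk-allele carriage against somatic
  mutation, BH within the variant's scan; then a global one-sided Fisher
  test of prognostic-versus-other variants against associated-versus-not.

## Added predictive value

For each hit, two Cox models are fitted on the cancer's patients — clinical
covariates only (C) and clinical plus variant (C + GV) — and each model's
linear predictor is scored by the cumulative/dynamic time-dependent AUC
with inverse-probability-of-censoring weights from the Kaplan-Meier
estimate of the censoring distribution: cases are patients with an event by
time t (weight $1/\hat G(T_i^-)$), controls are patients at risk beyond t
(weight $1/\hat G(t)$), and ties count one half. Without censoring this
reduces exactly to the fraction of concordant case–control pairs, which is
how the tests pin it.

The evaluation grid is every unique event time between the 10th and 90th
percentiles of the observed event times (the windowing is specified; the
grid inside it is not, and event times are where the estimand changes).
The improvement test is a one-sided Wilcoxon *rank-sum* comparison of the
C + GV AUCs against the C AUCs across the grid. The series are paired by
time, and a signed-rank test would be more powerful; the rank-sum form is
kept deliberately as the faithful reproduction of the published procedure,
and is conservative. Evaluation is in-sample (models fitted and scored on
the same cohort), again matching the procedure being reproduced; expect a
small optimistic bias on the null — the tests allow for it by checking the
null ΔAUC is centered near zero, not exactly zero.

## eQTL triage

A hit with an annotated gene is a candidate *cis*-eQTL mechanism when
three signs chain consistently: the variant's outcome direction, the
carrier expression shift (Wilcoxon rank-sum on carriers vs non-carriers),
and the hazard direction of the gene's expression itself (Cox on the
per-gene z-score, controlling clinical covariates; per-SD scale, since the
published scale is unstated). Both component p-values use a relaxed 0.10
cut — the concordance requirement multiplies the two error rates, so the
triage is hypothesis-generating by construction. Flipping the expression
shift sign alone flips the concordance verdict (antisymmetry), which the
tests assert.

## The synthetic generator

Defaults are chosen to resemble a mid-sized per-cancer cohort: ~300
patients per cancer, population allele frequencies uniform on
[0.05, 0.5], Weibull baseline with shape 1 (exponential; shape is
configurable but the proportional-hazards structure is exact for any
shape), 30% censoring, Poisson read depths with mean 30, 1% per-source
call discordance. Genotypes are Hardy-Weinberg at the annotated frequency.
Censoring is uniform administrative censoring whose upper bound is
calibrated by bisection so the realized censoring fraction matches the
target in expectation — reproducible target rates without a closed form.
Corruption flips a call to a uniformly chosen wrong class independently
per source, which is all the concordance filter can see; depths and flips
are independent. All randomness derives from one master seed through named
child streams, so adding a generator never perturbs existing draws.

What the generator does **not** emulate: linkage-disequilibrium haplotype
structure (only optional duplicated variants, enough to exercise pruning),
correlation between clinical covariates and genotypes (independence is
assumed; the real joint distribution is unknown), tumor purity, read-level
error processes, and non-proportional hazards. Passing tests therefore
demonstrate correctness of the statistical machinery under the stated
model, not robustness to real-data pathologies outside it.

## Numerical choices and problem sizes

Tie handling is Efron; BH is the standard step-up; Fisher tests are exact.
Separation is detected heuristically (|β| > 15 or SE > 50) — Cox partial
likelihoods have no finite maximizer under separation, so any cut is a
convention; these are far beyond biologically plausible hazard ratios.
The AUC estimator treats markers closer than 1e−12 as tied. The test suite
runs its simulation-based checks at deliberately modest sizes (hundreds of
patients, tens to hundreds of variants, 50–100 replicates), chosen so the
whole suite completes in minutes while keeping every binomial comparison
inside 3–4 standard errors of its target; the same machinery scales to
cohort sizes in the tens of thousands.

## Known limitations

No treatment covariates, no time-varying effects, no stratified baselines
or frailty terms, no trans-ancestry modelling, no cross-validated ΔAUC by
default (a mode exists in spirit via refitting, but the in-sample variant
is what the headline procedure defines). The concordance denominator and
the carrier reading of "found in N patients" are documented interpretations
of ambiguous prose; both are localized in `qc_filter()` and
`concordance_percent()` if a different reading is wanted.
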