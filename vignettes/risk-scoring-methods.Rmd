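---
title: "Log-odds-ratio risk scoring for coded EHR data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Log-odds-ratio risk scoring for coded EHR data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehrisk)
library(dplyr)
```

## The problem and the model

Clinical risk models built from electronic health records (EHR) try to flag,
years ahead of time, patients at elevated risk of a rare adverse outcome —
here, suicidal behavior identified from coded diagnoses. `ehrisk` implements
a Naive-Bayes-style scorer over longitudinal coded records, together with
the cohort construction, validation, and subpopulation-comparison machinery
around it.

Each binary feature $i$ — a diagnosis, medication, lab flag (low/normal/high),
or demographic category, coded *ever/never* per patient — receives a
**partial risk score**, the natural-log odds ratio of carrying it among
cases versus controls in the training arm:

$$
\mathrm{PRS}_i \;=\; \log\!\left[
\frac{\text{cases}_{w/i}/\text{cases}_{w/o\,i}}
     {\text{controls}_{w/i}/\text{controls}_{w/o\,i}}
\right].
$$

Negative scores are protective, positive scores adverse. A patient's
cumulative risk at time $t$ sums the scores of all distinct features first
observed on or before $t$,
$\mathrm{Risk}_t = \mathrm{PRS}_i + \mathrm{PRS}_j + \cdots$, and the
**overall risk score** is the running maximum
$\mathrm{ORS} = \max_t \mathrm{Risk}_t$. Classification compares the ORS to
cutoffs calibrated on the training controls' score distribution at benchmark
specificities (90% and 95% by default). This is a conditional-independence
model: it deliberately ignores feature interactions in exchange for
transparency and scalability, and every coefficient is directly
interpretable as an odds ratio.

Under conditional independence the exact Naive Bayes log-posterior-odds
would add, for each *absent* feature, a term
$\log[(1-p_{i|case})/(1-p_{i|ctrl})]$, and a class-prior intercept. Both are
omitted: absent-feature terms are negligible for the rare codes that
dominate EHR vocabularies, and the intercept shifts all scores equally, so
threshold-based classification, ROC curves and quantile cutoffs are
invariant to it.

## Cohort construction

* **Case definition.** A patient is a case if any diagnosis code matches a
  configurable prefix list (default `E95`, `965`, `967`, `969`, `881`,
  matching intentional self-harm, poisonings and forearm/wrist wounds),
  after stripping dots and upper-casing both codes and prefixes — EHR
  extracts disagree on whether codes carry dots, and normalization makes
  `965.0` and `9650x` behave identically. An optional external flag table
  (a death-certificate-linkage analog) adds cases and participates in the
  first-event minimum.
* **Inclusion.** Three or more visits (a visit is a distinct patient-date
  with at least one event — the most conservative reconstruction available
  from a coded-event table), at least 30 days between first and last visit
  (inclusive), and at least one event at age 10–90, with age computed as
  event year minus birth year (a missing birth year fails closed).
* **Case exclusions.** Cases with no event strictly before the first
  case-defining event carry no usable history and are dropped; cases whose
  event precedes the first subpopulation-marker diagnosis are dropped; cases
  with marker and event on the same date are retained. In a marker-defined
  cohort a case with no observed marker at all is classed event-before-marker:
  the record is censored at the event, so the cohort-defining marker can only
  postdate it. Exclusion reasons are mutually exclusive and the accounting
  identity (identified = included + per-reason exclusions) always balances.
* **Censoring.** All case records on or after the first case-defining event
  are removed before any feature is built, so neither the model nor the
  trajectories ever see the event or anything after it. Censoring is
  idempotent.
* **Split.** Included patients are partitioned uniformly at random into
  equal training and testing arms (sizes differ by at most one),
  deterministically given a seed. The split is not stratified by case
  status by default; a flag enables stratification for small synthetic
  experiments.

## Feature extraction and leakage control

The vocabulary — the set of scoreable feature keys — is built from the
training arm only, and features seen in fewer than `min_count` training
patients (default 5) are dropped; the floor stabilizes rare-feature odds
ratios before any smoothing is needed. Lab codes contribute up to three
keys (`L`/`N`/`H`). Demographic categories (sex, race, marital status, and
age bucketed per decade) become features dated at the patient's first
visit, since the prospective replay needs a date for every scored variable.
Features are ever-coded: a repeat coding never re-adds its score (a
`count_repeats` sensitivity analysis was considered and rejected because
the cumulative-sum reading of the score treats the index set of features as
a set). Out-of-vocabulary features in a test record are logged in
trajectories at score 0 and never affect classification.

## Numerical choices

* **Zero-cell smoothing.** The Haldane–Anscombe correction (+0.5 on all
  four cells) is applied only when a 2×2 table contains a zero, keeping all
  scores finite while leaving fully populated tables — including every
  published table this package reproduces — exactly untouched. Smoothed
  features are flagged.
* **Log base.** Natural log. The base rescales all scores and cutoffs
  jointly, leaving classification, ROC and quantiles invariant.
* **Threshold rule.** The cutoff at specificity target $s$ is the smallest
  observed control score $c$ with $\Pr(\text{control} > c) \le 1-s$;
  classification is *strictly greater than* the cutoff. On the training
  controls this guarantees achieved specificity $\ge s$ even under ties,
  and within $1/n$ of $s$ when scores are distinct.
* **AUC.** Mann–Whitney form with midranks,
  $P(\text{case} > \text{control}) + \tfrac12 P(\text{tie})$, which agrees
  exactly with brute-force pairwise enumeration (tested on random
  instances, and cross-checked against pROC).
* **Rounded-percent metrics.** Printed clinical tables compute likelihood
  ratios from integer-percent sensitivity/specificity; the metric panel
  therefore reports both exact and rounded-percent variants (at 90%
  specificity and 37% sensitivity the rounded LR+ is 0.37/0.10 = 3.70 while
  the exact value is 3.65).
* **Degenerate inputs.** Empty records score ORS 0 and are flagged;
  constant OR vectors cannot be Z-scaled (error); thresholds require at
  least 20 control scores; AUC requires both classes.
* **Lead-time CI.** Normal approximation, mean ± 1.96·SE over detected
  cases, in years of 365.25 days.
* **Z-scaled OR tables.** Z-scaling uses the sample SD over exactly the
  feature set supplied by the caller, because the displayed set (all
  features? grouped? top-k?) is an analysis choice, not a model property.

## The synthetic cohort generator

Real registry EHR data of this kind are not publicly deposited, so the
package ships a generator whose output exercises every pipeline stage with
known ground truth. Its defaults emulate a single-marker clinical cohort:
15,000 patients, 1.3% outcome prevalence, mean follow-up 8.4 years (gamma,
shape 2), roughly five coded events per patient-year, planted shared-risk
odds ratios spanning 0.7–13 (including one protective code), five
subpopulation-specific codes near OR 3–4.5, and 40 inert noise codes across
DX/RX/LAB sources.

The generative mechanism is the Naive Bayes factorization matched to the
scorer: case status is Bernoulli at the target prevalence, and each code is
then carried independently given class, with case exposure odds equal to
control odds times $e^{\beta_i}$. By Bayes' rule this is exactly a logistic
model for case status given codes whose coefficients are the planted
$\beta_i$ (the intercept exists in closed form), with two practical
advantages over drawing case status from the logistic directly: the
marginal prevalence is the target by construction, and every planted effect
equals the population 2×2 log odds ratio, so parameter recovery is not
attenuated by odds-ratio non-collapsibility across the other planted
covariates. Subpopulation-specific effects apply only to marker patients,
so those codes are exactly null outside the subpopulation.

Event dating: each carried code occurs one or more times (repeat counts
tuned to the target event density) at days uniform over the observed
record; cases' records are truncated at the case-defining event, which is
placed uniformly in the second half of follow-up so pre-event history
almost always exists (a `no_prior_fraction` toggle forces history-free
cases to exercise the exclusion filter). The marker diagnosis is dated
uniformly over the *untruncated* follow-up, so a realistic minority of
cases (~25–30%) have their event precede any observed marker, exercising
the temporal-order exclusions. The observed case/control follow-up-length
correlation reported in registry data is not planted by default; a
`case_followup_multiplier` makes it available.

What the generator does **not** emulate: real ICD-9 ontology structure,
visit/encounter bundling, code co-occurrence correlations (codes are
independent given class — exactly the scorer's assumption, so synthetic
results cannot reveal how violated conditional independence degrades the
model on real data), informative observation density, or temporal trends in
coding practice. Passing tests on synthetic cohorts therefore demonstrate
correctness of the pipeline and recoverability of planted structure, not
real-data performance; published real-data AUCs and lead times are not
reproducible without the original registry.

## The three-arm subpopulation experiment

`run_three_arm_comparison()` reproduces the design that motivates
subpopulation-specific modelling: with one validation half of the marked
subpopulation held fixed, it trains (a) on the subpopulation's other half,
(b) on a size-matched uniform sample of the general cohort, and (c) on the
full general cohort, always excluding validation patients from training.
The size-matched sample may include subpopulation training patients at
their natural population rate (a flag excludes them entirely); at realistic
subpopulation fractions the contamination is marginal. When
subpopulation-specific effects are planted, the subpopulation-trained model
dominates the size-matched general model (checked over 20 simulation
seeds at n = 20,000, subpopulation fraction 0.15, ten subpopulation-specific
codes at log-OR 1.5: median validation AUC 0.73 vs 0.57); with shared
effects only, the two are statistically indistinguishable and the
full-cohort model benefits from its sample size. These problem sizes keep
the full experiment to a few minutes on one CPU while leaving wide margins
between the compared medians.

## Known limitations

* No feature interactions or regularization; correlated features
  double-count risk by construction.
* Demographic features are treated as known from the first visit, not from
  birth.
* Age uses year arithmetic (birth dates beyond year are not modelled).
* The temporal-order statistics of marker vs event depend on the marker
  being coded in the censored record; cohorts defined by registry metadata
  rather than a coded marker need the `marker_required = FALSE` path.
* The rounded-percent likelihood-ratio variant is reported for
  comparability with printed tables; analyses should use the exact
  variant.
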