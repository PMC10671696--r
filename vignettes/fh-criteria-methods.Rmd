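---
title: "Methods: FH diagnostic criteria, treatment-intensity correction and evaluation"
author: "fhdx"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its models and the choices behind
them: what each component computes, which parameters matter, what the
synthetic data do and do not emulate, and where the design was genuinely
open.

# The diagnostic problem

Familial hypercholesterolemia (FH) produces lifelong elevated LDL
cholesterol and premature cardiovascular disease. Genetic testing (LDLR,
APOB, PCSK9) is the reference standard, but most diagnosis is clinical, via
point scores and threshold rules. Two practical complications shape
everything in this package:

1. **Most patients are already treated** when FH is suspected, so the
   untreated LDL-C the criteria refer to must be estimated from the
   on-treatment value and the regimen.
2. **Published benchmark tables print rounded percentages, not counts**, so
   checking or extending them needs the underlying integer confusion
   matrices back.

# Criterion engines

All six instruments read their thresholds and point tables from one YAML
config (`fh_default_config()`), so every number is inspectable and
overridable. Conventions adopted throughout:

* **All LDL-C / total-cholesterol comparisons are strict (`>`)**, mirroring
  how the instruments print their cutoffs. A subject at exactly 4.9 mmol/L
  is Simon Broome negative.
* **Within a DLCNC item group only the highest applicable item counts**
  (e.g. tendon xanthomata 6 supersedes arcus 4).
* The DLCNC instrument is published as a full point table; the comparison
  summaries that circulate print only its LDL-C bands. The non-LDL items
  shipped here are the standard published ones (family history 1–2,
  clinical history 1–2, signs 6/4, DNA 8) and live in the config, so an
  auditor can see — and change — exactly what the engine awards.
* **MEDPED thresholds** are the published total-cholesterol table (age
  bands <20 / 20–29 / 30–39 / ≥40 crossed with degree of relatedness,
  mmol/L). With only a yes/no "relative diagnosed with FH" flag in the
  cohort schema, the first-degree column is used when the flag is set and
  the general-population column otherwise.
* **Pediatric subjects**: Simon Broome, JFHMC and the Hong Kong panel have
  explicit pediatric cutoffs. The DLCNC score is not validated under 18;
  it is computed but flagged (`pediatric_not_validated`), and
  `dlcnc$pediatric_policy: suppress` blanks the categorical and binary
  calls while keeping the score visible.
* **Genetic items and circularity.** DLCNC and Simon Broome include a
  DNA-variant item. When the criteria are *assessed against* the genetic
  result, including that item would be circular, so
  `evaluate_criteria_on_cohort()` masks it (`use_genetic = FALSE`); the
  plain scoring functions include it by default, which is how the
  instruments are used clinically once a result is back.
* The Hong Kong panel marks family history "optional": a subject with
  unknown family history takes the same arm as one with documented absence.
  Simon Broome's definite-via-relative's-xanthomata route is in the
  published instrument though often omitted from summaries; it is included
  and can be disabled (`simon_broome$relative_xanthoma_counts`).
* An optional flag (`dlcnc$family_pcvd_separately`, off by default) scores
  a family history of premature CVD separately from hyperlipidemia instead
  of as one shared item — family pCVD history can be near-perfectly
  specific for genotype-positive FH, so up-weighting it is a plausible
  refinement worth experimenting with, but it is not part of any published
  instrument.

**LDL-C selection.** Criteria are scored on, in order of preference: the
measured pretreatment LDL-C; else the corrected on-treatment value
(below); and under the explicit `policy = "peak"`, the highest LDL-C ever
recorded. Peak values matter because the pretreatment measurement may not
be the lifetime maximum — scoring on peaks is a sensitivity analysis, not
the default. Provenance (`measured` / `corrected` / `peak`) is attached to
every scored value. A subject with no source at all is a scoring error
naming the subject, never a silent negative.

# Treatment intensity and LDL-C correction

A regimen is translated to a multiplier: if a drug/dose is expected to cut
LDL-C by fraction $r$, its intensity is $1/(1-r)$, and the untreated level
is estimated as on-treatment LDL-C × intensity. The shipped factor table is
anchored to three calibration points — Simvastatin 40–80 mg/day spanning
1.7–1.9, Atorvastatin 20 mg and Rosuvastatin 5 mg near 1.8 — and filled in
with literature-standard dose–response reductions for the other doses of
seven statins plus ezetimibe (10 mg → 1.2). Every number sits in the config
file; the model is the multiplier, not any particular table.

Choices that were genuinely open:

* **Statin × ezetimibe combination is multiplicative** (the only
  combination rule currently implemented). Treating the factors as
  independent proportional reductions is the standard first-order model.
* **Untreated subjects are intensity 1.0** — the identity multiplier, so
  `estimate_untreated_ldl()` is a no-op on them and the algebraic inverse
  property (estimate × (1 − implied reduction) = input, checked to 1e-12)
  holds uniformly. Analyses that code untreated as 0 exist (a group mean
  below 1 is the tell-tale); `treatment_intensity(untreated_as_zero =
  TRUE)` emulates that coding, but it breaks the multiplier semantics and
  is not the default.
* **The "around 50% drop" qualifier** of the intensity rule is a
  configurable band, default [0.40, 0.70]. The band brackets a ~50%
  reduction generously on purpose: its role is to confirm that the
  intensity actually produced the expected response, not to measure it
  precisely.
* **Exclusion, not negative calls**: a subject missing the regimen, the
  pretreatment or the on-treatment LDL-C cannot be assessed by the
  intensity rule and is excluded (`NA`), shrinking the row's effective n.
  Calling them negative would deflate sensitivity with no evidence.
* An intensity of 1.8 implies an expected reduction of 44.4% — inside the
  30–<50% "moderate" band, which is why a moderate-intensity regimen
  achieving a ~50% real-world drop is diagnostically informative.

The Friedewald estimate (TC − HDL − TG/2.2, mmol/L) is provided with its
reporting rule: suppressed (`NA`, never 0) when TG > 4.5 mmol/L strictly,
or when the arithmetic goes negative.

# Evaluation statistics

* **Rounding**: percentages are rendered half-up to one decimal
  (`percent_half_up()`), matching how performance tables are printed; base
  `round()`'s half-to-even would disagree on exact ties, and the
  reconstruction below must use the same rule as the tables it inverts.
* **Undefined metrics** (zero denominator) are `NA`, never 0.
* **Fisher exact**: two-sided p by the sum-of-probabilities-≤-observed
  convention, via `stats::fisher.test()`; the test suite cross-checks it
  against a direct hypergeometric enumeration.
* **ROC**: thresholds at midpoints between distinct observed scores plus
  sentinels; calls are `score ≥ t`; AUC by trapezoid, which the tests prove
  equal (to 1e-12) to the brute-force pairwise statistic
  P(score⁺ > score⁻) + ½P(tie), and which is invariant under strictly
  monotone transforms. Youden's J = se + sp − 1 is maximised over observed
  thresholds with **ties broken toward the lower threshold** (the more
  sensitive operating point — the cheaper error in a screening context).
  `pROC` serves as an independent cross-check in the tests, not as the
  implementation.
* **Integer reconstruction** (`reconstruct_confusion()`): enumerate all
  integer (tp, fp, fn, tn) with n ≤ n_max (default 60; ~6×10⁵ matrices,
  fully vectorised), keep those whose metrics round half-up to every
  supplied target, order by n. With four independent targets the smallest
  solution is unique in practice; the round-trip property (the generating
  matrix is always among the solutions) is tested on random matrices. This
  is how the package recovers unprinted metrics of published rows — e.g. a
  row printing se 84.6 / sp 40.0 / PPV 88.0 / NPV 33.3 forces (22, 3, 4, 2)
  and hence accuracy 77.4%.
* **Missing data**: per-criterion exclusion with the effective n and the
  prevalence actually used printed on every row — evaluation subsets
  differ across rows whenever a criterion needs inputs others do not, and
  a report that hides that is misleading.

# Variant spectrum

The cDNA parser covers the notations that occur in LDLR spectrum tables:
substitutions, duplications, deletions, intronic offsets
(`c.1060+2 T>C`). Parsing is whitespace-tolerant; `format_cdna()` renders a
canonical form and parse→format round-trips on every packaged entry.
Consequence classification is rule-ordered: `fs` → frameshift; `Ter`/`*`
without `fs` → nonsense; intronic within the near-splice window (default
±5 — wide enough to catch annotated non-canonical sites like +5, and
configurable) or an annotated new/disrupted splice site → splice
(synonymous protein + splice annotation → `synonymous_splice`); remaining
substitutions → missense. Receptor classes follow the standard expectation
— truncating/splice-disrupting → receptor-negative, missense →
receptor-defective — as a configurable map, since individual missense
variants can in fact be receptor-negative; the package predicts the class,
it does not assert function.

`spectrum_summary()` reports detection fractions (cases with a variant /
probands tested, per stratum) and the local-spectrum expansion
`n_new / (prior_total − n_new)`. Published spectrum tables are not always
internally consistent (distinct-variant counts vs listed rows, proband
observations vs single/compound case arithmetic); the summary carries such
discrepancies as notes rather than silently reconciling them.

# Synthetic cohorts

`generate_cohort()` draws a proband + cascade-screening study:

* **Strata**: adult/pediatric probands and cascade relatives, each with its
  own genotype prevalence (defaults 16/19, 6/12, 10/12) and zero-truncated
  normal pretreatment LDL-C (defaults: positive probands mean 8.77,
  negative probands 6.53, positive cascade relatives 6.60 mmol/L — so the
  positive-adult mixture mean lands at 7.94 by construction). **SDs default
  to 1.5 mmol/L**: group means are published without dispersion, so the SD
  is a modelling assumption, chosen as a typical clinical-cohort spread and
  documented as such. Pediatric stratum means (8.2 / 5.5) were set once so
  the 50/50 mixture matches the published overall pediatric mean (~6.9).
* **Lipid panel**: HDL and triglycerides are drawn independently and TC is
  assembled as LDL + HDL + TG/2.2, so panels are Friedewald-consistent.
* **Treatment**: regimens are sampled per genotype (intensive regimens for
  positives), and on-treatment LDL-C is the pretreatment value divided by
  the regimen's intensity with multiplicative log-normal noise — the
  generator and the correction model share the factor table, which is what
  makes parameter-recovery tests meaningful. Pretreatment records are
  available for a configurable fraction (default 0.74); unavailable ones
  exercise the corrected-LDL fallback.
* **Reproducibility**: generation is a pure function of (config, seed).
  Each subject draws from a counter-based substream keyed by stratum and
  index, so enlarging one stratum never perturbs subjects already drawn —
  a property the tests assert directly.

What the generator deliberately does **not** emulate: pedigree structure
(cascade relatives are sampled marginally at the cascade prevalence, not
via transmitted alleles); correlation between family-history flags beyond
genotype (they are conditionally independent given genotype); secular
treatment changes; assay error beyond rounding to 0.01 mmol/L. Passing
tests on synthetic cohorts therefore demonstrate the pipeline's arithmetic
and its statistical conventions, not clinical validity on real
populations.

**Parameter recovery as a test.** Because the strata are truncated
normals, the sensitivity/specificity of simple LDL rules have closed forms
(e.g. P(L ≥ 5.5 | stratum)), and the family-history arm of the Hong Kong
rule factorises under conditional independence. The suite generates 10,000
adult probands and requires empirical stratum means and rule operating
points to sit within 3 Monte-Carlo standard errors of theory. Problem
sizes (10,000 for recovery, 2,000 per point for the AUC-separation grid)
were chosen to make 3-SE bands tight enough to catch sign and scale errors
while keeping the default suite fast.

# The packaged adult cohort

`fh_adult_cohort()` is a 31-subject synthetic reconstruction, built (in
`data-raw/adult_cohort.R`) so that the packaged criteria reproduce, on it,
a published benchmark's per-criterion confusion matrices *exactly* —
(22, 3, 4, 2) for the Simon Broome / MEDPED / JFHMC rows, (23, 4, 3, 1)
for the expert-panel row, (21, 2, 5, 3) for the LDL ≥ 5.5 row,
(23, 1, 1, 4) and (20, 0, 4, 5) for the intensity-based rows with two
untreated subjects excluded — while matching the published stratum means
(LDL-C, TC, peak LDL-C, family-pCVD rates). It is an integration fixture
and a worked example, not patient data, and per-subject fields beyond
those constraints (ages, sexes, exact regimens) are arbitrary. Quantities
the constraints do not pin down — ROC shapes and AUCs above all — are
cohort-specific and should not be read as estimates of the published ones.

# Known limitations

* Criterion items not representable in the cohort schema (e.g. DLCNC's
  LDL > 95th percentile family item) are approximated by the nearest flag
  (first-degree hyperlipidemia).
* The factor table is dose-discrete: unlisted doses are an error rather
  than an interpolation, by design — silent interpolation would hide data
  entry problems.
* No PCSK9-inhibitor modelling, no adherence/intolerance modelling; the
  intensity rule assumes the prescribed regimen was taken.
* Fisher p-values on criterion × genotype tables treat margins as fixed;
  no multiplicity correction is applied across criterion rows.
* No confidence intervals on AUC and no formal AUC-difference test are
  provided.
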