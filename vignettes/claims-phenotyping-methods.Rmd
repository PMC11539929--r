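---
title: "Methods: claims-based phenotyping and burden analysis of agitation in Alzheimer dementia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: claims-based phenotyping and burden analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agitAD)
```

## The problem and the model

There is no single ICD diagnosis code for agitation occurring in Alzheimer
dementia, so observational studies identify affected patients with a
computable phenotype: deterministic rules over coded administrative claims.
`agitAD` implements a temporal-confirmation phenotype of the kind built on
the International Psychogeriatric Association (IPA) consensus definition of
agitation in cognitive disorders, together with the descriptive
burden analysis that typically follows it. The IPA definition's requirement
that behaviors persist or recur over at least two weeks is what the 14-day
claim-spacing rule operationalizes; the 30-day spacing rules for AD,
dementia and severe mental illness are the usual guard against rule-out or
miscoded single claims. The IPA criterion that behaviors cause *excess
disability* is deliberately not implemented: that information is largely
absent from claims, and conditioning on it would discard most cases.

The pipeline is purely rule-based and descriptive. There is no statistical
model in the identification step, and the outcome summaries are means, SDs,
frequencies and percentages — no inference, risk adjustment or censoring
model. The key behavioral assumptions are:

* **Dates, not times.** All intervals are inclusive calendar-day intervals;
  claims carry service dates only.
* **Inclusive gaps.** "k or more days apart" admits a gap of exactly k days.
  With more than two matching claims, a beneficiary qualifies when the span
  from the earliest to the latest matching date reaches the gap —
  equivalently, when *some* pair qualifies. The stricter consecutive-pair
  reading was rejected as stronger than the stated rule. Multiple claims on
  one date count once (distinct dates drive all gap logic).
* **System-aware code matching.** ICD-9 and ICD-10 lists coexist in one code
  set; an ICD-9 value never matches an ICD-10 entry. Entries match exactly
  or by prefix. No crosswalking is attempted.
* **Configuration over constants.** Code sets, the Charlson mapping and
  every threshold are inputs. The YAML files under `inst/extdata/` are
  illustrative templates only.

## Identification parameters

All knobs live in `identification_params()`:

| parameter | default | units | rationale |
|---|---|---|---|
| `ad_dementia_gap_days` | 30 | days | two-claim confirmation rule for AD and for dementia |
| `agitation_gap_days` | 14 | days | persistence/recurrence over ≥2 weeks |
| `smi_gap_days` | 30 | days | per-illness severe-mental-illness exclusion |
| `pre_window_days` | 183 | days | "6 months before": months are undefined in claims rules, so the contract is fixed in days |
| `post_window_days` | 365 | days | "12 months after", same reasoning |
| `dx_position_limit_confirmation` | 2 | positions | AD/dementia must appear in the primary or secondary field |
| `dx_position_limit_agitation_smi` | `Inf` | positions | agitation/SMI rules are not restricted by position in the source definition; configurable |
| `agitation_search_window` | full study period | — | agitation evidence may predate the index; a `followup_only` mode supports sensitivity analysis |
| `enrollment_gap_tolerance_days` | 0 | days | "continuously enrolled" is stated without tolerance |
| `stay_merge_gap_days` | 1 | days | claims ≤1 day apart merge into one stay, so transfers and interim bills do not inflate counts |
| `ed_conversion` | `TRUE` | — | an ED claim dated inside an acute stay is part of the hospitalization |
| `hospice_as_pac` | `TRUE` | — | hospice is grouped into the post-acute cost category so the seven categories partition all claims; configurable because reporting conventions differ |

The selection steps run in the order confirmation → index → enrollment →
SMI exclusion → agitation split. The ordering is the one consistent with
the attrition arithmetic of published selection flowcharts; it is also the
order in which the attrition report telescopes. A beneficiary meeting both
the agitation and SMI rules is excluded (exclusion precedes the split).
Whether the second confirming claim must precede the index date is not
specified in the source definition; the implementation does not require it.
The SMI exclusion is evaluated over the whole study period, not anchored to
the index.

## Outcome measures

* **Annualized rates.** Per beneficiary, `count × 365 / followup_days`,
  reported as mean (SD) × 100 — "per 100 members per year". Under the fixed
  365-day follow-up this is exactly 100 × the mean per-patient count.
* **Stays and LOS.** Stays are maximal merged runs of same-setting claims.
  LOS is the inclusive day count `discharge − admit + 1`, so a same-day stay
  has LOS 1 and merging abutting claims adds no phantom days. Stays are
  attributed to the follow-up window by their admission date and LOS is not
  truncated at the window edge (the simplest attributable rule; truncation
  would break the per-patient/per-stay accounting identity used as an
  invariant: total stay-days = Σ per-patient LOS = Σ per-stay LOS).
* **AD-specific hospitalizations** are acute stays whose *principal*
  diagnosis (position 1 of the earliest constituent claim) falls in the
  combined AD + dementia set — the standard claims convention, chosen
  because the source reporting never defines the term.
* **30-day readmission.** Pooled rate: denominator = acute discharges with
  ≥30 observable days before follow-up end; numerator = discharges followed
  by another acute admission 1–30 days later (inclusive). Same-day
  transfers have already merged into one stay, so they cannot count.
* **Per-patient LOS and costs include zeros.** Members with no stay (or no
  spend in a category) contribute 0 to per-patient means; per-stay
  statistics average over stays only. This makes per-stay ≥ per-patient for
  rates below one stay per patient, the pattern seen in published tables.
* **Costs.** Paid amounts are used as given (no payer/beneficiary split, no
  inflation adjustment), summed per category over `(index, index + 365]`;
  the per-beneficiary total is exactly the category sum, so cohort total
  PPPY equals the sum of category means by construction.

## The synthetic-data generator

`generate_population()` emulates the structure a researcher would receive
under a Medicare FFS data-use agreement: a beneficiary file (demographics,
dual eligibility, entitlement, a *precomputed* CMS-HCC score — the package
never computes HCC), enrollment spells with medical/pharmacy flags, dated
diagnosis claims, and paid amounts, over a July 2009 – December 2016 study
window with ICD-9 coding before October 2015 and ICD-10 after.

Each beneficiary draws one **planted pattern** that pins the identification
branch it must exit through: agitation case; non-agitation control;
AD- or dementia-confirmation failure (a single claim or a 29-day pair);
enrollment failure (a 1–30-day coverage gap inside the required window);
SMI exclusion (a per-illness 30+-day pair, half the time with agitation
claims too, so exclusion precedence is exercised); and two one-day
near-misses (SMI claims 29 days apart or split across illnesses; agitation
claims exactly 13 days apart). The near-misses make the inclusive-boundary
semantics a tested contract rather than a convention. The default pattern
mix mirrors the attrition structure of the study the conditions come from:
55.3% of confirmed beneficiaries fail enrollment, 35.8% of the enrolled are
excluded for SMI, and 36.5% of the final population are agitation cases;
confirmation failures (6%) and the near-misses (2% of included, each) have
no published analogue and were fixed once at small realistic values.

Included beneficiaries receive 12 months of utilization drawn from
per-cohort intensities (`default_cohort_params()`) taken from the published
tables: Poisson event counts (hospitalizations 0.89/0.81 per patient-year,
ED 1.15/0.96, outpatient 15.99/14.76), shifted-geometric lengths of stay
(support ≥1 day; acute means 8.96/8.69 days), Bernoulli post-acute use per
setting and lognormal claim costs. Distribution families are the simplest
ones consistent with non-negativity and the large SDs relative to means in
such tables; the source states no distributions. Three calibration details
matter:

* **Costs are planted per claim** with per-claim mean = category PPPY
  target / expected claim count, making the cohort per-category PPPY mean
  unbiased for the target (defaults sum to $32,322 vs $30,121). Diagnostic
  and baseline-comorbidity claims carry zero paid amounts so identification
  claims never leak into the cost calibration. Categories are carried by
  their event claims; a category whose event rate is zero cannot carry a
  positive cost target and the configuration is rejected up front.
* **Readmissions are placements, not extra stays.** A drawn stay is placed
  2–30 days after the previous discharge with probability
  `readmit_prob × r/(r − (1 − e^{−r}))` (r = hospitalization rate), which
  makes the pooled readmission rate target `readmit_prob` while the total
  stay count stays Poisson(r). Gaps below 2 days are avoided because such
  stays would merge as transfers.
* **Event dates are uniform over the follow-up**, re-drawn when an ED visit
  would land inside an acute stay (so the ED-conversion rule does not bias
  the planted ED rate). Other point events are not constrained.

Each beneficiary has its own RNG substream derived from `(seed, position)`,
so output is reproducible and one beneficiary's draws do not perturb
another's. Demography (70% female, dual eligibility 45.2%, age ≈
Normal(83, 8) truncated at 45, race/region/entitlement mixes, lognormal
CMS-HCC) matches the published baseline profile; entitlement categories are
generated as mutually exclusive even though the source table's percentages
suggest overlapping categories — the profile reports exclusive counts.

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real data: mortality and disenrollment censoring,
temporal clustering of events, seasonal coding drift, miscoding and
under-coding of dementia (real claims identify only ~85% of clinically
diagnosed patients), correlated comorbidity structure, realistic Medicare
payment schedules, and procedure/revenue-center detail. Tests on synthetic
data establish the *algorithmic* correctness of the pipeline (branch
recovery, boundary behavior, accounting identities, statistical
calibration), not the clinical validity of any particular code list.

## Numerical and degenerate-input choices

* Interval unions, not day loops, implement coverage and stay merging; a
  day-by-day scan is kept as the test oracle.
* Empty inputs are well-defined: no matching claims → not confirmed; zero
  beneficiaries → empty assignments and all-zero attrition; a cohort with
  no stays reports per-stay statistics as absent (`NA`) and per-patient LOS
  0; a readmission denominator of 0 reports an absent rate.
* Ties: claims on the same date count once; when AD and dementia first
  appear on the same date, that date is the index; the principal diagnosis
  of a merged stay comes from the earliest claim, with claim id as the
  deterministic tie-break.
* Percentages are reported to 1 decimal with cohort n as denominator;
  "Unknown" levels are reported, never dropped.
* The CMS-HCC score is reported only from the input field, over
  beneficiaries with a non-missing value.
* One claim suffices to flag a Charlson condition (two-claim rules apply to
  the phenotype, not to comorbidity profiling), over the 183-day baseline
  window `[index − 183, index)`.

## Problem sizes used in testing

The acceptance suite enumerates every 2-claim date configuration on a
0–60-day grid (both gap rules), all 3-claim combinations on a 4-day grid
and 10,000 randomized 1–4-claim configurations against a brute-force
all-pairs oracle; branch recovery, prevalence calibration (exact binomial
99% interval around 36.5%), parameter recovery (3 standard errors) and the
accounting identities run on one seeded synthetic study of 20,000
beneficiaries; end-to-end byte determinism is checked at n = 800 and the
packaged acceptance script regenerates the n = 20,000 study from scratch.
These sizes were chosen so the statistical checks have useful power while
the suite stays comfortably interactive.

## Known limitations

Only the provisional (2015-style) agitation definition is implemented, not
the 2023 revision; no death or disenrollment handling beyond the enrollment
filter; no procedure codes or provider structure; the shipped code sets and
Charlson mapping are illustrative; and the study-window end is a
configuration value rather than a constant because published uses of this
design are internally inconsistent about it (identification through 2016
with exclusion windows quoted through 2017).
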