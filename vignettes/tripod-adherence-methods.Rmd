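---
title: "Scoring reporting completeness against the TRIPOD checklist: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring reporting completeness against the TRIPOD checklist: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tripodscore)
```

## The problem

Multivariable prediction models — diagnostic or prognostic — are only usable
by others when their publications report enough detail to judge validity,
reproduce the model, and apply it to new individuals. The TRIPOD statement
defines 22 reporting items (37 scored subitems once compound items are
split) considered essential for that purpose. `tripodscore` implements the
assessment machinery for auditing a cohort of prediction-model publications
against that checklist at the *element* level: each item is decomposed into
the individual pieces of information it requests, a human (or the bundled
synthetic generator) records a judgement per element, and the package turns
those judgements into adherence scores at four levels — item, model,
publication, and per-item across a cohort.

## The scoring model

Let a model extraction carry a study type
$t \in \{\mathrm{D}, \mathrm{EV}, \mathrm{IV}, \mathrm{D{+}V}\}$
(development, external validation, incremental value, combined) and a
judgement $j_e \in \{\text{reported}, \text{not reported},
\text{not applicable}, \text{reported by reference}\}$ for every element
$e$ of every applicable item.

**Item completeness.** Item $i$ is complete for a model iff every element
of $i$ is covered:

$$C_i = \bigwedge_{e \in i} \big[ j_e = \text{reported} \;\lor\;
j_e = \text{not applicable} \;\lor\;
(j_e = \text{reported by reference} \land i \in R) \big]$$

where $R = \{4b, 5a, 6a, 7a\}$ is the set of items for which a citation to
another article is acceptable. A not-applicable element (say, end of
follow-up in a diagnostic study, or outcome blinding when the outcome is
all-cause mortality) counts as covered.

**Applicability algebra.** Six items apply only to development
(10a, 10b, 14a, 14b, 15a, 15b) and six only to validation
(10c, 10e, 12, 13c, 17, 19a), so the study types see 31 (D), 31 (EV),
37 (D+V) and 36 (IV) items. Five "if done" items (5c, 10e, 11, 14b, 17)
are scored only when the record flags the corresponding activity as
performed, and item 21 (availability of supplementary material) is
excluded from every score. The *scored item set* of a model is therefore

$$S(m) = A(t_m) \setminus \big(\{21\} \cup F_m\big)$$

with $A(t)$ the study type's applicable set and $F_m$ the items flagged
not applicable for that model.

**Model and publication adherence.** Model adherence is the exact ratio
$|\{i \in S(m) : C_i\}| / |S(m)|$, kept as an integer
numerator/denominator pair; percentages are produced only at rendering,
rounding half away from zero (so 8/170 renders as 5, 3/170 as 2). For a
publication containing several study types, the item universe is the union
of the member models' scored sets; an item counts complete only if complete
in every member where it is scored, except the either-type items
(3a, 18, 19a, 19b, 20), for which one complete member suffices. For
per-item tallies across a cohort, the denominator is the number of models
in which the item was scored; item 21 is special-cased to the total model
count, since which models it truly applied to cannot be known from reports.

## Decisions made where the design was open

Several choices had to be fixed where the assessment procedure the package
implements leaves room:

* **Incremental-value exclusion.** The incremental-value set has 36 items;
  the one structurally excluded item is taken to be 17 (model updating),
  the only validation item with no incremental-value applicability in
  published per-type counts. It is a field in the checklist definition
  (`incremental_value_excluded`), not code, so a different reading needs no
  code change.
* **Partial applicability.** Besides the five "if done" items, items 10c,
  12 and 19a are only sometimes applicable to incremental-value models, and
  19a only sometimes to combined models; these are driven by explicit
  per-record flags (`partial_applicability` in the definition file) because
  no inference rule from the judgements themselves exists.
* **Combined development+validation merge.** When one publication develops
  and validates the *same* model, the two parts are extracted separately
  and merged per element. The default takes the more favourable judgement
  (information reported anywhere in the publication counts), which matches
  the completeness question being asked; a `strict` mode (both parts must
  report) is available in `merge_model_parts()`.
* **Publication-level universe.** For multi-type publications the
  denominator is the union of the member models' scored sets, and an item
  scored in only one member is judged on that member alone.
* **Element decomposition.** The checklist file decomposes every item into
  elements. Items 1, 2 and 4b use the canonical published decompositions
  (4, 12 and 3 elements); the remaining items are decomposed one element
  per reporting requirement in the item's own phrasing (e.g. item 12 into
  setting, eligibility, outcome and predictor differences). Because the
  checklist is data, element lists can be refined against the published
  extraction form without touching code, subject to the structural
  validator.
* **Regression covariates for multi-model publications.** The adherence
  regression uses the publication's impact factor and design flag plus the
  sample size and predictor count of the member model with the largest
  sample.

## The synthetic cohort generator

No element-level extraction dataset is publicly deposited for the cohort
the defaults emulate, so the generator is the package's test bed: it
produces fully valid record sets whose *statistics* match the published
cohort description, which is what makes every pipeline stage testable
end to end.

The defaults encode the study conditions: 146 publications; a second,
different-type model in a publication with probability 24/146 (giving ~170
models); model-level study-type mix 0.43/0.25/0.19/0.12; 84% prognostic;
journal impact factor lognormal with median 5.3 and IQR 4.0–7.1; sample
size lognormal with median 450 and IQR 200–2005; predictor count a rounded
lognormal with median 5 and IQR 3–8 (all three fitted by matching the
printed median and quartiles on the log scale, a standard choice for
right-skewed positives). Conditional-item applicability is drawn per study
type with the published frequencies (e.g. item 11 "risk groups, if done"
applicable in 22/73 development models, item 17 in 4/43 external
validations).

**Item probabilities.** Each item has a target completeness probability.
24 of the 37 targets are published cohort percentages; the other 13 (4b,
5a, 5c, 6a, 8, 10c, 10e, 13a, 13c, 14a, 14b, 15b, 19a) have no printed
overall value and default to mid-range values in the 25–75% band (the
published extreme tables exhaust the items outside that band). These were
chosen once as plausible field values and are ordinary configuration, not
fitted quantities. Targets are constant across study types; genuinely
type-specific reporting rates (model-building procedures are reported far
less often in incremental-value studies, for instance) are not modelled.

**From item targets to element draws.** With $k$ independent elements, each
element is reported with probability $p_i^{1/k}$, so the product recovers
the item-level target exactly. Two elements additionally carry a
not-applicable channel: end of follow-up (`4b.3`) and outcome blinding
(`6b.1`), each drawn not-applicable with probability 0.16 — the share of
diagnostic publications and of all-cause-mortality outcomes respectively.
For those elements the reporting probability of the remaining channel is
solved from $r + (1-r)q = p_i^{1/k}$ so the item target is preserved.
Predictor blinding (7b) deliberately has no explicit NA channel: its
printed 6% completeness is *below* a 16% NA floor, so the target is read
as already absorbing non-issue judgements. Reference-acceptable items
record a reported element as `reported_by_reference` with probability 0.1,
which exercises that code path without affecting completeness.

**Planted effects.** `planted_effect_cohort()` shifts a publication's
expected adherence linearly in its covariates (slopes in percentage points
per covariate unit). The shift $\delta$ is realised by tilting item
probabilities proportionally to their headroom
($p_i' = p_i + \delta\,(1-p_i)/\overline{(1-p)}$ for positive $\delta$,
symmetrically via $p_i$ for negative), which keeps every probability in
$[0,1]$ and makes the mean shift exactly $\delta$; a shift beyond the
available headroom raises a range error. With zero slopes the generator is
byte-identical to `generate_cohort()`.

**What the generator does not emulate.** Judgements are independent across
elements, items and models: no within-publication correlation, no
journal/domain clustering, no correlation between covariates and reporting
quality (unless planted). Passing tests on synthetic cohorts therefore
demonstrate that the *scoring machinery* is correct under the published
marginal structure — not that the package would reproduce any particular
real cohort's joint behaviour.

## Numerical choices

* Scores are exact integer ratios; no floating rounding enters
  comparisons. Rendered percentages round half away from zero.
* Percentile summaries default to linear interpolation between order
  statistics (`stats::quantile` type 7); the mode is configurable because
  quartiles of ~150 observations are interpolation-sensitive at the
  ±1-point level and the convention used for the published figures is
  unknown.
* The adherence regression is an ordinary least-squares fit
  (`stats::lm`) on complete cases with two-sided Wald p-values; sample
  size enters untransformed by default with a log switch. Collinear
  covariates raise an error naming the aliased terms rather than silently
  dropping them.
* Querying an item outside a model's applicable set raises an error
  instead of returning `FALSE`, so extraction mistakes surface at the
  point of the query.
* Degenerate inputs: an empty scored set (every conditional flagged off in
  a reduced checklist) is an error; items never applicable in a cohort get
  `NA` percent and a warning rather than a division by zero.

## Problem sizes used by the test suite

Exhaustive oracle-equivalence runs enumerate every judgement assignment and
flag combination on a 3-item miniature checklist (a few hundred cases,
well under a second). Calibration-recovery tests use a ~2000-model cohort
(about one second to generate); the planted-effect recovery uses 500
publications; distributional checks on the published medians use replicates
of the default 146-publication cohort. The full suite runs in about half a
minute on one CPU.

## Known limitations

* Element decompositions beyond items 1, 2 and 4b follow the item phrasing
  rather than the published extraction form, which is not reproduced in the
  sources the package is built from; users auditing real publications
  should review (and can edit) the definition file.
* Only the TRIPOD checklist ships with the package; the definition format
  is deliberately narrow (no guideline-specific prose beyond element
  descriptions).
* Completeness of reporting is not quality of conduct: a model can be
  fully reported and methodologically weak. The package makes no
  risk-of-bias judgement.
* The per-item tallies treat models from the same publication as
  independent observations, mirroring the descriptive convention of the
  assessment design it implements.
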