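---
title: "Methods: referral rules, accuracy inference, and the synthetic population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: referral rules, accuracy inference, and the synthetic population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eyescreen)
```

## The screening problem

A community volunteer (CV) with brief training interviews a participant,
measures distance visual acuity with a smartphone test, checks near
vision with a reading card for older adults, and must decide: refer to
primary eye care, or not. The reference standard is an ophthalmic
clinical officer (OCO) examining the same person with standard outreach
equipment. `eyescreen` encodes the referral rule set this package is
built around (all seven of its development iterations), the
diagnostic-accuracy statistics used to validate such rules, and a
generative model of a screening population so the pipeline can be
exercised and stress-tested end to end.

## Acuity representation

Distance acuity is carried as metric Snellen text (`"6/12"`) at the
interface and as logMAR internally: logMAR = log10(denominator /
numerator), so 6/6 = 0.0, 6/60 = 1.0, and larger is worse. Thresholding
and ordering are done by exact cross-multiplication of the Snellen
ratios, so two notations of the same line can never differ by
floating-point noise, and the referral comparison is *strict*: "worse
than 6/12" excludes 6/12 itself, taking the rule's wording literally.

Two conventions the data format cannot express are fixed by assumption
and documented here: all acuities are treated as *presenting* (habitual
correction, if any), and reporting bands (`6/6–6/12`, `6/18–6/60`,
`<6/60`) are conventionally taken over the better eye, as in population
survey practice. Band boundaries are inclusive as printed: 6/12 belongs
to the first band, 6/18 and 6/60 to the second. Children under 6 are not
acuity-tested and map to a `not_assessed` band.

## The seven rule iterations

`algorithm_catalog()` is the authoritative encoding. Iterations 1–2 ask
a single "any eye problem (no time limit)" question with acuity testing
optional (consulted only when measured, never an error or a trigger when
absent); iteration 3 makes distance acuity mandatory from age 6;
iteration 4 narrows the question to "today"; iteration 5 replaces it
with eye *pain* plus difficulty seeing far/near; iteration 6 broadens
pain to *pain or discomfort*; iteration 7 adds a mandatory N8 near-vision
check at 33 cm for ages 40+. The guardian-reported problem rule for
children under 6 is applied uniformly across all iterations: the
published description attaches it to the final algorithm, and the
earlier "any problem" question subsumes it, so a uniform rule is the
conservative reading.

Age boundaries follow the wording literally: child rule strictly below
6, acuity from 6, near vision from 40. Ages are whole years, rounded up.

Because different iterations ask differently-scoped questions, the
participant record keeps them as distinct tri-state fields
(`problem_any`, `problem_today`, `eye_pain`, `pain_discomfort`,
`vision_difficulty`; `yes`/`no`/`NA`), rather than collapsing them into
booleans. `NA` means "not asked / not applicable"; a field an iteration
*requires* that is `NA` raises an error naming the field and iteration —
decisions are never silently defaulted. Reason codes are emitted in a
fixed canonical order (`child_problem`, `low_distance_va`,
`pain_or_discomfort`, `vision_difficulty`, `near_vision_fail`,
`any_eye_problem`) so output is deterministic, and `refer` is true
exactly when at least one reason fired.

## Accuracy inference

All accuracy metrics are exact binomial proportions of a 2×2 table with
fixed orientation (rows: reference refer / not; columns: index refer /
not). Confidence intervals are Clopper–Pearson, computed from the
beta-quantile identity `qbeta(α/2, k, n−k+1)` / `qbeta(1−α/2, k+1, n−k)`
with the degenerate endpoints pinned at k = 0 and k = n. The method
choice matters: the published interval for 344/378 (87.7–93.7%) is
reproduced by the exact interval but not by the large-sample Wilson
interval (upper bound 93.5%), so the exact method is used and pinned by
test. Coverage is verified by full binomial enumeration for all n ≤ 25
over a 1% grid of p.

A metric whose denominator is empty (e.g. specificity in an
all-referable cohort) is reported as *undefined* with a flag, never as a
number. Estimates are displayed at one decimal of a percent, kappa and
odds ratios at two decimals, matching the conventional display
precision; rounding is R's default, which reproduces every published
display used in the tests.

Cohen's kappa uses the marginal-product chance correction; a table whose
expected agreement is 1 (degenerate marginals) leaves kappa undefined
and flagged. Agreement bands follow the published reporting scheme
verbatim — 0.41–0.60 "moderate", 0.61–0.80 "fair", ≥ 0.81 "good" — even
though it is nonstandard (it swaps the usual moderate/fair order);
values below 0.41 are labelled "poor", a label the scheme does not
define. `reconstruct_2x2()` inverts published summaries (total, each
rater's positives, percent agreement) into the unique integer table,
erroring on parity or negativity violations rather than rounding them
away; reconstruction followed by `percent_agreement()` and marginal
extraction reproduces its inputs exactly.

Sample size uses Buderer's precision formula. With the published design
inputs (sensitivity 0.90, half-width 5%, prevalence 30%) it yields 139
cases and a total of 464, whereas the published design states 517; the
published derivation is not given, so the function reports the formula's
own answer together with the achieved half-width for any case count
(155 cases achieve ±4.7%), and the discrepancy is left visible rather
than reverse-engineered.

Logistic regression is a maximum-likelihood binomial GLM (IRLS, tight
tolerance, 50-iteration cap). Non-convergence and numerically degenerate
fitted probabilities (complete or quasi-complete separation) are raised
as errors, because Wald odds ratios are meaningless there. The 2×2
cross-product odds ratio with a log-scale Wald interval is kept as an
independent route and must agree with the single-covariate GLM to 1e-6
(a property the tests enforce); the Haldane–Anscombe 0.5 correction is
applied to odds ratios only when a zero cell exists, never to
sensitivity or specificity.

## The synthetic population

`default_population_model()` emulates the *statistical shape* of a
community screening cohort:

* age-group weights and the female share equal the published cohort
  margins (n = 574; 43.9% under 15, 62.9% female);
* the diagnosis mix equals the published reference-referred diagnosis
  distribution, scaled to a referable prevalence of 378/574 = 65.9%,
  with the remainder `normal`;
* the reference referral is generated per diagnosis
  (`referable = 1` for every disease group, `0` for normal), so the
  expected prevalence is 65.9% *by construction* and the Monte-Carlo
  recovery test is a genuine check of the sampling machinery;
* symptoms, per-eye acuity bands (then a uniform draw over the band's
  discrete chart lines), and near-vision failure are drawn conditionally
  on diagnosis: conjunctivitis is symptom-driven with normal acuity,
  cataract/refractive error are acuity-driven, presbyopia dominates
  near-vision failure — which makes symptom-flip noise concentrate false
  negatives in conjunctivitis, the pattern the validation cohort showed;
* screener measurement error (`cv_noise`): each elicited tri-state
  answer flips independently with probability 0.03, and measured logMAR
  is jittered with SD 0.05 (about half a chart line, consistent with
  acuity test–retest repeatability) and snapped to the nearest line.

The noise and normal-group symptom rates (0.06 pain/discomfort, 0.06
vision difficulty, 0.02 near-vision failure) were chosen once so that
the simulated final-iteration operating point lands near the validated
one (sensitivity ≈ 0.91, specificity ≈ 0.79 at n = 20,000) while keeping
each component individually plausible; they are calibration targets, not
epidemiological estimates.

Age, sex and diagnosis are drawn *independently* from their margins: the
joint distribution is unpublished, and independence keeps every margin
exactly calibrated and goodness-of-fit-testable. The cost is occasional
age-incongruous labels (a child with a presbyopia label); age-dependent
structure still enters through the rules themselves (children are not
acuity-tested, near vision only from 40). What the generator therefore
does *not* emulate: age–diagnosis correlation, disease severity within a
diagnosis, correlated eyes, symptom wording effects, household or site
clustering, and participation bias. Tests passing on synthetic cohorts
demonstrate the *machinery* (rule logic, exclusion accounting, interval
computation, reproducibility), not field performance of the rule on any
real population.

`reference_from_rule = TRUE` switches to a decision-consistent reference
(the iteration-7 rule applied to the latent noise-free fields), which
makes zero-noise sensitivity and specificity exactly 1 — the
self-consistency contract the tests pin.

Reproducibility contract: one integer seed, one R random stream
(`withr::with_seed`); identical seed, identical byte-level output.
`n = 0` is a valid request and yields an empty, schema-complete tibble.

## Problem sizes and runtimes

The suite sizes simulations to what the checks need: margin
goodness-of-fit and prevalence calibration at n = 50,000 (α = 0.01
chi-square, 3σ Monte-Carlo band), the noise-monotonicity grid at
n = 12,000 per level, logistic parameter recovery at n = 5,000 (within
3 SE), rule-equivalence by exhaustive enumeration over a discretized
record grid, and Clopper–Pearson coverage by full enumeration to n = 25.
The whole suite runs in well under a minute; `scripts/acceptance.R`
recomputes the headline quantities (simulator at n = 50,000) in a few
seconds.

## Known limitations

* The record format cannot distinguish presenting from corrected acuity;
  everything is treated as presenting.
* The counterfactual strategy comparison is implemented and tested on
  synthetic cohorts; the published strategy accuracies require the
  unpublished individual-level data and are not reproduction targets.
* The single-exclusion-reason flow accounting cannot split exclusions
  into missing-index vs missing-reference, as the published flow does
  not break them down either.
* Kappa reconstruction from rounded published marginals is exact only
  when the printed agreement is consistent with an integer concordant
  count; the second rater pair in the published interrater data rounds
  to a kappa of 0.59 vs the printed 0.58, so only the first is pinned.
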