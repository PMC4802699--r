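---
title: "A discrete-event cost model of test-based versus empirical anti-TNF management in Crohn's disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A discrete-event cost model of test-based versus empirical anti-TNF management in Crohn's disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdmcost)
```

## The clinical question

Crohn's disease patients who respond to infliximab (IFX) frequently lose
response over time. Clinicians then face a choice: escalate empirically
(double the dose, shorten the infusion interval, add an immunosuppressant,
switch to adalimumab (ADA), intensify ADA to weekly dosing), or measure the
drug's trough level and anti-drug antibodies first and let pharmacokinetics
decide. The two policies imply very different drug bills, and anti-TNF
agents dominate the cost of care in inflammatory bowel disease. `tdmcost`
simulates both policies patient by patient and compares their direct
anti-TNF costs over 1, 3 and 5 years.

A Markov cohort model is a poor fit here because a patient's options depend
on their whole history (which drugs have already failed, whether a test was
already done), not just on their current state. The package therefore uses
a discrete-event formulation: each patient is an independent stochastic
process on a weekly clock, and the full course history is retained.

## Model structure

**Entry state.** Patients enter at week 0 on IFX 5 mg/kg every 8 weeks as
responders at risk of losing response. The alternative reading — entering
at the moment of the first loss of response — is inconsistent with the
per-consultation maintenance-dose event probability that drives the first
transition, and with the gradual divergence of the two arms over time, so
the maintenance reading is used.

**Consultations.** Events are only observed at scheduled administrations:
every 8 or 6 weeks on IFX, every 2 or 1 weeks on ADA. The first
consultation of a course always delivers the dose without an event draw — a
treatment cannot fail before it has been received. At each later
consultation a serious adverse event (AE) is drawn first; only if none
occurred, a loss of response (LOR). The two never co-occur; the order is a
modelling convention (the source tables specify marginal probabilities
only) and is fixed and tested.

**Transitions.** A consultation that draws an event is a *trigger*: the
patient leaves the current course and the same visit delivers the first
dose of the successor regimen, which is therefore billed under the
successor. In the empirical arm, LOR walks the escalation chain

> IFX 5 q8w → IFX 10 q8w → IFX 10 q6w → IFX 10 q6w + IS → ADA induction →
> ADA q2w → ADA q1w → failure,

while an AE on any IFX regimen switches to ADA induction and an AE on ADA
exhausts the anti-TNF class (AE routing is not stated in the source tables;
a serious AE is taken to contraindicate the current drug, and after ADA no
anti-TNF option remains). The ADA induction block (160/80 mg) is a single
4-week course billed once, with no event draws.

In the test-based arm, the *first* LOR on IFX triggers a trough/antibody
test (EUR 100) with three outcomes: high trough (50%) — the patient leaves
the anti-TNF class; low trough without antibodies (29%) — IFX dose
optimization with 80% 1-year retention; low trough with antibodies (21%) —
switch to ADA with 75% 1-year retention. The first LOR on ADA maintenance
triggers the second (and last) test: high trough (43%) — leave the class;
low trough without antibodies (24%) — weekly ADA with 67%/57% retention at
6 months/1 year; low trough with antibodies (33%) — back to standard-dose
IFX with 80%/57%. Any event after the second test's routing ends the
anti-TNF sequence. At most two tests are ever performed.

**Exits.** Three exit states are distinguished: still on treatment at the
horizon; *switch of drug class* after a high-trough test result (no further
anti-TNF cost, not a candidate for surgery in this model); and *failure* of
both anti-TNFs (surgery-eligible). Treating high-trough exits as
non-surgical is required for internal consistency: the source reports fewer
surgical procedures in the test-based arm, which is only possible if the
class-switch exit bypasses surgery.

## Probabilities and hazards

Per-consultation LOR/AE probabilities are published as `[min, max]` ranges
(e.g. LOR on maintenance IFX: 0.019–0.023 per consultation). One concrete
value per parameter is drawn uniformly per *simulation* — not per patient —
mirroring the published sensitivity design; all patients of a run share the
draw. The published ranges are already rescaled to each regimen's
consultation interval (the weekly-ADA LOR row is half the biweekly row);
the one missing entry, an AE row for weekly ADA, is filled by the same
rule: half the biweekly AE range. The ranges for response after
optimization are complementary to the LOR ranges (sums equal 1 within the
printed rounding of 0.005), which `validate_config()` enforces.

Test-arm efficacies are published as retention probabilities at a horizon,
not per-cycle hazards. `retention_to_cycle_loss(r, k)` converts them by
solving `(1 - p)^k = r`, with `k` the cycles per year (6.5 for q8w, 26 for
q2w, 52 for weekly). Two-point efficacies (6 months and 1 year) yield a
piecewise-constant hazard via `piecewise_cycle_loss()`: one per-cycle
probability for weeks 0–26 of the routed course and one for weeks 26–52,
chosen so survival through both periods reproduces the 1-year retention
exactly. Beyond week 52 the second-period hazard is kept constant — the
source states nothing about post-horizon behaviour, and constant
extrapolation adds no structure that is not in the data. These
efficacy-derived hazards absorb *all* discontinuation on routed courses, so
no separate AE channel is drawn there (a separate channel would
double-count). For q8w cycles the 26-week period holds a fractional 3.25
cycles; the hazard is exact at the period boundaries and the consultation
grid approximates in between, the best a discrete grid can do.

## Costs

All arithmetic is in integer euro-cents, so cohort totals are exactly
additive; euros appear only at reporting time. Per-cycle tariffs: IFX
standard dose EUR 1,840.18 (three 100 mg vials at 492.81 plus one infusion
at 361.75), double dose EUR 3,318.61, double dose + immunosuppressant
EUR 3,348.42, ADA EUR 306.72 per cycle (q2w or weekly), ADA induction
EUR 1,884.20 once, test EUR 100 per event. The per-cycle ADA tariff of
306.72 is used for accounting even though the quoted 40 mg pen price is
417.05; the tariff table wins, and the discrepancy is inherited from the
source, not resolved here. The optional surgery extension adds EUR 12,000
at each failure exit and, for a random 25% of those patients,
standard-dose IFX q8w from the exit week to the end of follow-up.

One billing convention deserves a note: since the trigger consultation
delivers the successor's first dose, a forced event at probability 1 bills
exactly one cycle of each regimen along the chain — the degenerate
scenarios in `forced_path_scenario()` and the `geometric_oracle()` both
encode this convention independently of the engine, and the tests require
exact agreement. Billing the trigger under the old course instead would
shift totals by less than one cycle per transition.

## Randomness and reproducibility

Every exported simulation function takes an integer seed. A cohort derives
one substream seed per patient up front, so patient `i` is reproducible
independently of simulation order. `compare_strategies()` pairs the arms at
the parameter level — both arms use the same drawn parameter set but
independent patient streams, as in the source design — and simulates each
patient once at the longest horizon; shorter horizons are obtained by
truncating the billing, never by re-simulating, so per-arm costs are
non-decreasing in the horizon by construction. The surgery draws use their
own substream, so base-mode totals are independent of the extension.

## What the degenerate scenarios establish

`no_event_scenario()` (all probabilities zero) has the closed form
`ceiling(H / 8) × 1840.18`; `forced_path_scenario()` walks any chosen chain
deterministically and enumerates its cost by independent arithmetic;
`geometric_oracle()` gives the exact finite-sum expectation for a single
regimen with a constant per-consultation event probability. The test suite
requires the engine to match all three exactly (or within Monte-Carlo
error for the stochastic check). These scenarios validate the accounting
and the event lattice; they do not validate the clinical realism of the
published probabilities, which the model takes as given.

## Problem sizes and defaults

The headline analysis uses 10,000 patients per arm over 260 weeks with the
published probability ranges, matching the source's largest cohort; the
secondary analysis uses 3,000. The sensitivity design is 30 simulations
with fresh uniform draws and a 3,000-replicate bootstrap of the 30
simulation-level mean savings (percentile 95% interval; the source does
not name its interval method). A 10,000-patient paired run takes a few
seconds; the full 30-simulation sensitivity analysis a few minutes. The
package's own test suite uses smaller cohorts (hundreds to a few thousand
patients) chosen so that each asserted contrast exceeds three standard
errors of its Monte-Carlo noise.

```{r example}
cfg <- build_default_config()
cmp <- compare_strategies(cfg, n = 2000, horizons = c(52, 156, 260), seed = 1)
cmp
```

## Known limitations

* The source's statechart figure is not machine-readable; the transition
  graph is reconstructed from the prose and tables. Quantities that depend
  on fine routing details (how many patients exhaust both drugs, and when)
  are the least constrained: this implementation reproduces the 5-year
  per-patient saving and its direction robustly, while absolute arm means
  carry an upward offset of roughly 10–15% relative to the published
  figures and failure counts run higher.
* Probabilities are interpreted per consultation, as the source tables are
  captioned. Any within-cycle timing of events is invisible to the model.
* Only direct anti-TNF drug, test, surgery and post-operative drug costs
  are modelled — no hospitalization, no indirect costs, no discounting, no
  QALYs, and no biologics beyond IFX and ADA.
* The number of *billed* tests is at most two per patient; the published
  per-simulation test counts (~15,700 per 10,000 patients) are only
  approachable if trough and antibody assays are counted separately, which
  the `tests_counted_as = "assays"` switch provides for reporting.
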