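---
title: "Scripted CPR scenarios and automated performance assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scripted CPR scenarios and automated performance assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cprsim)
```

## The problem

Performance during simulated cardiopulmonary resuscitation (CPR) is usually
scored by human raters with checklists.  A scripted scenario on a
model-driven patient simulator can instead produce objective,
observer-independent feedback: the scenario reacts dynamically to what the
team does, and its log files contain enough information to reconstruct the
quality of the resuscitation — hands-off time, defibrillation timing and
appropriateness, drug timing, ventilation rate, generated cardiac output.

`cprsim` packages that idea as a self-contained, hardware-free pipeline:

1. a **scenario engine** (`run_engine()`): a deterministic state machine
   driven by a clocked stream of trainee actions;
2. a **log dialect** (`write_scenario_logs()` / `read_scenario_logs()`):
   three plain-text streams (events, physiology, drugs) that fully
   determine the assessment;
3. a **metrics layer** (`compute_metrics()`, `summarize_cohort()`): the
   per-scenario performance variables and their cohort mean ± SD;
4. a **synthetic team generator** (`team_profile()`, `generate_actions()`,
   `run_scenario()`): parameterised rescuer behaviour, so the whole
   pipeline can be exercised and validated without a simulator.

## The scenario model

The patient starts in cardiac arrest with one of three rhythms — asystole
(`ASY`), coarse ventricular fibrillation (`cVF`) or pulseless ventricular
tachycardia (`pVT`) — and a common baseline: cardiac output 0, fixed
neuromuscular blockade 100 %, inspired oxygen fraction 0.80, ischemic index
averaging 0.99, ischemic index sensitivity 0.5, and both ventricular
contractility factors 0.5.  The three initial patients differ *only* in the
rhythm override.

The scenario machine switches among the states *no chest compression*,
*chest compression* (entered when systolic pressure exceeds 40 mmHg),
*ventilation*, *ineffective resuscitation*, *defibrillation* and its
classification states, plus six observer-clicked **marker states** (IV
line, intubation, first and second adrenaline, atropine, amiodarone); after
every marker state the machine returns to *no chest compression*.

Three rules give the scenario its clinical logic:

* **Shock classification.**  Every shock delivered with strictly more than
  10 J is recorded and classified *indicated* (rhythm cVF/pVT) or
  *non-indicated* (ASY/SR).  Shocks at or below 10 J are ignored.  Energies
  above the advisory 200 J cap are processed but flagged with a `WARN`
  record.
* **The drug → compressions → shock chain.**  The second-adrenaline or
  amiodarone marker arms drug conditioning (ischemic index sensitivity
  0.5).  Chest compressions performed afterwards circulate the drug,
  raising the left-ventricular contractility factor to 0.8 — the sole
  condition under which a subsequent indicated shock converts the rhythm
  to sinus (the ROSC event).  Atropine analogously sets the
  right-ventricular factor to 0.8, without influence on conversion.
* **Degeneration.**  A shockable rhythm left without compressions for
  strictly more than 60 s degenerates to asystole, which no shock can
  convert — an absorbing failure.

### The ineffective-resuscitation trigger

The original scripted scenario names an *ineffective resuscitation* state
but its entry condition is not fully enumerated.  We define it as the
complement of the stated compression-state rule: compressions are active
but systolic pressure is at or below the 40 mmHg gate.  With the default
kernel (compressions always generate 60 mmHg) the state is unreachable, but
it becomes live whenever the kernel constants are reconfigured below the
gate.

### The arming flag

The baseline already sets the ischemic index sensitivity to 0.5, yet the
second-adrenaline/amiodarone markers are described as *setting* it to 0.5
as the arming step.  Taken literally, the baseline would satisfy the arming
condition before any drug is given.  We resolve this with an explicit
`drug_conditioning_armed` flag that only the two markers can set; the index
itself is kept as a recorded variable for log fidelity.  This preserves the
intended causal chain (drugs, then compressions, then an effective shock)
and is what the conversion gate tests exercise.

## The surrogate hemodynamic kernel

The original simulator's physiologic model is proprietary and unpublished.
The metrics need only two signals with the right gating behaviour — systolic
pressure and cardiac output — so a three-regime piecewise kernel stands in
for it (it is a deliberate simplification, not an approximation of any
particular model):

| regime                     | SBP (mmHg) | CO (L/min)        |
|----------------------------|-----------:|-------------------|
| arrest, no compressions    | 0          | 0                 |
| arrest, compressions       | 60         | team's `cc_output`|
| post-ROSC (sinus rhythm)   | 120        | 5.0               |

The per-team compression output (`cc_output`, bounded to (0, 3] L/min)
models the variable quality of mechanical compressions.  HR, DBP and SpO₂
are carried in the physio log as fixed per-regime constants purely for
realism of the files; no metric reads them.  All kernel constants live in
`guideline_config()` and can be read from a flat key-value file.

## Timing conventions and numerical choices

* Events carry integer-second times; simultaneous events are processed in
  stream order (stable).
* All thresholds are strict inequalities ("more than 10 J", "more than
  60 s", "superior to 40 mmHg"), matching the scenario's wording.
* The asystole degeneration is *logged* at the instant the 60 s deadline
  elapses (conceptually just past it); an action timed exactly at the
  deadline is processed first and can still rescue the rhythm.
* Physio sampling (default every 5 s) records the state immediately
  *before* any event at the sample time, so the sample at the ROSC instant
  is still a pre-ROSC sample and the post-ROSC plateau can never leak into
  the windowed median cardiac output.
* The scenario ends with an operator `EXIT` record at the horizon; `EXIT`
  is reachable by no other route.

## The metrics

The **assessment window** runs from scenario start to the ROSC event, or to
the last record for a censored scenario that never converted (then
`time_to_rosc` is `NA` and the full log duration is the denominator).
Within the window, `compute_metrics()` extracts:

* **no-flow time** and **no-flow-time fraction** — hands-off arrest time
  and its share of the window (the complement of the chest-compression
  fraction);
* **median cardiac output** (plus a supplementary mean) over the windowed
  physio samples, midpoint convention for even counts;
* **time to first defibrillation**, counts of indicated and non-indicated
  shocks, the indicated fraction, the **mean inter-shock interval**
  (mean of consecutive differences) and the **mean absolute deviation** of
  those intervals from the 120 s guideline cycle;
* **time to first adrenaline** — the first-adrenaline marker, falling back
  to the earliest adrenaline drug-log record when the marker was skipped;
* **pre-intubation ventilations** — count of ventilations strictly before
  the intubation marker (before the window end if never intubated) and
  their frequency over that denominator.  Post-intubation ventilation is
  deliberately out of scope: with an intubated airway compressions continue
  without pauses and the log stream cannot attribute breaths reliably.

Shock metrics are computed over the shocks recorded **inside the window**.
A real scenario ends at ROSC, so this matches an analysis of recorded
files; the open-loop synthetic generator, which does not observe ROSC, can
emit shocks afterwards, and windowing keeps them out of the assessment.

`summarize_cohort()` aggregates report lists with available-case means and
**population** standard deviations (divisor *n* — the convention that
reproduces reference summary cells such as 0.26 ± 0.10 from per-team
no-flow fractions, which the sample SD does not).  Formatting follows the
printed precision of the field's tables: times as `MM:SS`, fractions to
two decimals, counts and rates to one.

## The synthetic team generator

`team_profile()` abstracts a resuscitation team as a small set of rates and
times: first-shock time and inter-shock interval (mean ± SD), a peri-shock
pause carved out of compressions around every shock (rescuers clear the
patient; default 10 s), compression segment and pause lengths (mean ± SD),
a pre-intubation ventilation rate, marker times, and the compression
cardiac output.  Draws are left-censored normals, so `sd = 0` profiles are
exactly deterministic — which is what makes the parameter-recovery
properties sharp: a deterministic profile's measured mean shock interval
equals the profile parameter *exactly*, the measured ventilation frequency
equals the configured rate when the intubation time is a whole number of
breath spacings, and the measured no-flow fraction equals the analytic
pause fraction over whole compression cycles.  With `sd > 0`, means are
recovered within three standard errors over repeated seeded runs.

The generator is **open loop**: it does not react to the patient (it will
keep compressing a converted patient until the horizon).  It emulates the
*structure* of real team behaviour — alternating compression blocks,
roughly 2-minute shock cycles, sparse early bag-mask ventilation, drug
markers minutes into the arrest — but none of the adaptivity, fatigue or
communication dynamics of real teams.  Passing tests therefore validate
the engine and the extraction arithmetic, not any claim about human
performance.

A fixture cohort of five profiles ships under
`inst/extdata/profiles/` (`cohort_profiles()`), spanning slow versus fast
defibrillation cycles, tight versus ragged compression coverage and sparse
versus frequent ventilation.  They are tuned to realistic orders of
magnitude only — reconstructing any particular historical team would
require the original logs, which do not exist in public form.

## Problem sizes used by the checks

The validation suite runs each scenario over a 10–20-minute horizon
(600–1200 s) with 5 s physio sampling; the brute-force oracle comparison
covers 200 randomly parameterised teams at the 20-minute horizon, and the
noisy parameter-recovery study uses 100 seeded runs.  These sizes keep each
scenario at a few hundred events while exercising every rule of the
machine.

## Known limitations

* The surrogate kernel is piecewise-constant; it reproduces gating, not
  physiology.  Oxygenation and CO₂ are intentionally absent.
* Ventilation is an instantaneous counted event; there is no lung-volume
  model, no tidal-volume or inflation-quality assessment, and nothing is
  assessed after intubation.
* Compression depth and rate are not modelled (beyond the scalar
  `cc_output`), mirroring the fact that such channels are not present in
  the logs this tool consumes.
* Repeated marker clicks are idempotent; the second-adrenaline marker does
  not require a recorded first dose.
* The tool is descriptive: it derives guideline-adherence quantities but
  does not score pass/fail, and no validity or reliability claims are
  attached to the metrics.

## A worked run

```{r}
p <- cohort_profiles()$team3
res <- run_scenario(p, initial_rhythm = "cVF", horizon = 1200)
res$report
```

```{r}
reps <- lapply(cohort_profiles(), function(p) run_scenario(p)$report)
summarize_cohort(reps)[, c("metric", "n", "formatted")]
```
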