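---
title: "Auditing creatinine self-monitoring: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing creatinine self-monitoring: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smssaudit)
```

## The problem

After a kidney transplantation, serum creatinine is the key early indicator
of graft failure. When patients measure creatinine at home with a
point-of-care meter and report the values through a web-based
self-management support system (SMSS), three questions decide whether the
arrangement is safe:

1. **Adherence** — do patients measure (and register) as often as the
   protocol requests?
2. **Reliability** — do the registered values correspond to what the meter
   actually recorded, and do they represent the full set of measurements?
3. **Responsiveness** — do patients act on the system's feedback when a
   value rises alarmingly?

`smssaudit` answers all three by reconciling two event logs: the meter's
internal memory (the *device log*, the ground truth of what was measured)
and the SMSS registration log (what the patient claimed, valued and dated).
Because such trial datasets are not public, the package ships a behavioral
simulator that generates both logs from a known ground-truth model, so the
entire pipeline is testable end to end and every estimator can be checked
against injected parameters.

## The feedback engine

The SMSS compares each newly registered value $y$ against the rolling
baseline $\bar{y}_5$, the arithmetic mean of the previous five registered
values. The relative increase $r = y/\bar{y}_5 - 1$ maps to a traffic
light: green for $r \le 0.15$, orange for $0.15 < r \le 0.20$, red for
$r > 0.20$ (both thresholds strict, matching the historical system's
">15%"/">20%" rule). After the *first* value of a day an orange or red
light is *action feedback*: perform and register a second measurement now.
After the *second* value the light is the *day conclusion*: continue
(green), measure again tomorrow (orange), or contact the hospital (red).
At most two values can be registered per day.

Three details are not fixed by the historical description and were decided
here:

* **Cold start.** With fewer than five prior values the baseline is the
  mean of whatever is available; with none, the result is green/continue.
  Patients practised in hospital before monitoring at home, and a
  non-alarming default is the only sensible choice for the first
  registration.
* **Second-value baseline.** The day conclusion is judged against the
  *pre-day* baseline, excluding the day's first value, so that a spike
  cannot mask itself (a first value of +100% would otherwise drag the
  baseline up and turn any confirmation green). A policy switch
  (`include_first_in_second_baseline`) restores the inclusive variant.
* **Registration time, not measurement time.** `replay_feedback()`
  processes records in registration order and computes baselines over
  previously *registered* values. This mirrors the live system and is what
  makes delayed registration dangerous: the advice attached to a
  week-old measurement is stale when it finally appears.

## The reconciliation taxonomy

Device and SMSS values are joined per patient-day — device values by the
timestamp's date, SMSS values by the patient-claimed measurement date —
and every active day is classified:

| category | condition |
|---|---|
| reliable | equal counts, every value identical in order |
| noncorresponding | equal counts, at least one value differs |
| phantom | registrations on a day with no measurement |
| omission | measurements but no registration |
| selection | more measured than registered (cherry-picking possible) |
| mixed | more registered than measured (both nonzero) |

Only equal-count days enter the one-on-one correctness comparison, exactly
as in the underlying study. Mixed days are rare and ambiguous; the matched
prefix is compared in order and surplus registrations are reported
separately (`phantom`-like, but kept out of the headline phantom count,
which retains the strict no-measurement definition).

Noncorresponding pairs get a cause attributed automatically,
operationalizing what was originally a manual review:

* **date shift** — the registered value exactly equals a device value on a
  date within ±3 days that has no matching registration of its own;
* **rounding** — the difference is at most 5 µmol/l and the registered
  value is a multiple of 5;
* **typo** — the decimal strings are one edit apart (substitution,
  adjacent transposition, dropped or added digit);
* **unexplained** — everything else; these are the *incorrect entries*
  used for the paired mean comparison.

Precedence is date shift > rounding > typo: a small difference landing on
a multiple of 5 reads as rounding even when it is also a single edit away.
All windows and thresholds are `reconcile_params()` settings. An automatic
attribution approximates but cannot reproduce a human audit, so the
explained/unexplained split should be read as an operational estimate.

Equality is exact integer equality in µmol/l (the meter reports integers);
a tolerance exists for other assays. On selection days the registered
values are paired to the closest measured values (exact matches first,
ties to the earlier measurement), because in-order pairing is undefined
when counts differ.

### Test-strip values

Patients occasionally ran quality-control strips without flagging them.
Flagged test values are always excluded; unflagged values are marked
*candidate* test values when (1) never registered that day, (2) differing
by more than 10 µmol/l from both temporal neighbours, (3) inside the
manufacturer's 133–239 µmol/l test range, and (4) measured within 30
minutes of a registered same-day value. The pipeline runs with and without
the candidates (`drop_candidates`), mirroring the original sensitivity
analysis. The 10 µmol/l and 30-minute operationalizations of "differed"
and "shortly after one another" are package choices, both configurable.

## Adherence, delay, feedback audit

The monitoring year has four phases — daily (weeks 1–4), every other day
(5–9), twice weekly (10–15), weekly (16–52) — with 28, 15, 12 and 37
requested measurement days. Per patient and phase the number of *distinct*
days with at least one event is compared against the requested count:
below 25% extremely nonadherent, 25% to below 75% nonadherent, 75% through
100% adherent (closed on both ends), above 100% overadherent. Patients
enter a phase's denominator only if their observation window covers the
whole phase. The every-other-day phase nominally contains 18 alternating
days but the protocol requests 15; the generator's calendar is truncated
to the requested count so that calendars and denominators agree and a
perfect patient scores a ratio of exactly 1.

Registration delay is `registration_date - measurement_date` in whole
days. Where the claimed date carries no device value equal to the
registered one but a nearby date (±3 days) does, the device date is used —
a mis-dated registration should not masquerade as a delay. Negative
delays are clamped to zero and counted as data-quality warnings.

The feedback audit checks, for every action feedback, whether a second
value was measured *and* registered on the same day; failures are
attributed to delayed registration (advice stale when shown) or to
pre-measured series (two or more device values already existed). Orange
day conclusions are followed when any registration claims the next
calendar day. Red day conclusions are followed when the contact log shows
a telephone or outpatient contact on the registration day or the day
after; the two-day window is a package choice (none was specified
historically), anchored at the registration date because that is when the
advice is shown. Without a contact log, hospital-contact adherence is
*not evaluable* — never zero.

## The paired comparisons

All mean comparisons are paired t tests computed from first principles:
$t = \bar{d} / (s_d/\sqrt{n})$ with $n-1$ degrees of freedom, two-sided
p values, significance at 0.05, no multiple-testing correction (matching
the original analysis strategy, noted in the report metadata). Zero
variance of differences is flagged rather than silently producing
`NaN`. Because the original analyses mix pairing units (per value for
noncorrespondence, per patient elsewhere), `summarize_reliability()`
produces both variants with explicit labels, and callers of `paired_t()`
always pass explicit pair lists. Blood-pressure diaries are compared on
daily mean arterial pressure, $\mathrm{MAP} = (2 D + S)/3$, restricted to
equal-count days.

## The simulator

`simulate_cohort()` generates, per patient, a true creatinine trajectory

$$c(d) = \left[c_\infty + (c_0 - c_\infty)\,2^{-d/h}\right]
          \cdot \varepsilon_d \cdot b_d,$$

an exponential recovery from $c_0 = 160$ to $c_\infty = 125$ µmol/l with
half-life $h = 10$ days, multiplied by lognormal day-to-day noise
$\varepsilon_d$ (mean 1) and optional multiplicative rejection bumps
$b_d$. Noise is lognormal rather than Gaussian because creatinine is
positive and right-skewed; the noise CV compounds biological variation
and the meter's imprecision, which for this class of point-of-care
devices is substantial.

**Noise calibration.** The default CV is 0.09. With a five-value baseline
and a strict 15% threshold, the log-ratio of a new value to the baseline
has standard deviation $\approx \sigma\sqrt{1.2}$ ($\sigma$ the lognormal
sdlog), so the alert probability per registration is about
$1-\Phi\!\big((\log 1.15 + \sigma^2/2)/(\sigma\sqrt{1.2})\big)$: roughly
7% at CV 0.09 — the repeat-request rate a stable cohort should produce.
A CV of 0.06 would imply under 2% and visibly too-smooth series.

On top of the trajectory sits the behavioral model (`behavior_profile()`),
whose defaults are the study conditions the pipeline is validated
against:

* measurement probability per requested day of 0.80/0.95/0.95/0.85 across
  the four phases (adherence dips when daily measuring is burdensome and
  again late in the year);
* registration of a measured day with probability 0.9, *reduced by 0.15
  when the value exceeds the recent mean by more than 5%* — patients are
  likelier to leave unflattering values unregistered, which makes omitted
  values run higher than registered ones;
* batched registration: same-day with probability 0.5, otherwise
  $1+\mathrm{Geom}$ with mean 6 days, truncated at 81 (the longest delay
  on record), giving an overall mean delay of 3 days;
* selective registration: with probability 0.7 only the lowest of
  multiple same-day values is registered;
* value distortions: deliberate under-reporting by 10–40 µmol/l
  (probability 0.06, echoing a documented patient who shaved round tens
  off half his entries), digit typos (0.02), rounding to the nearest ten
  (0.03);
* phantoms on 12% of missed requested days, drawn 15 µmol/l below the
  patient's recent mean (SD 10) — both the share of registrations (~2%)
  and the downward shift are the documented structure;
* alert response: a value more than 15% above the recent mean prompts a
  confirmatory repeat that is registered alongside the original with
  probability 0.6. Whether that response reaches the system in time still
  depends on the delay model, so delayed registrants reproduce the
  dominant observed failure mode (stale advice);
* unflagged test strips: about one every two months, uniform in 133–239
  µmol/l, flagged on the device only half the time;
* hospital contact after a red day conclusion with probability 1 when the
  registration was same-day and 0 when delayed — the pattern that makes
  same-day red follow-up 100%.

Every registered value carries ground-truth labels (`truth`):
phantom/typo/rounded/under-reported/selected-low flags, the true device
counterpart and the delay. One global seed drives per-patient substreams
(seed × 131071 + patient index), so any single patient can be regenerated
in isolation and growing the cohort never perturbs existing patients.

**What the simulator does not emulate.** Hospitalization episodes,
device swaps, patient-specific phantom propensity (phantoms concentrate
in a few real patients but are spread uniformly here), mis-dated
registrations (simulated patients claim the correct date, so date-shift
causes arise only coincidentally), and any dependence of behavior on
clinical state. Passing tests therefore demonstrate that the *estimators
recover what the generator injected*, not that real cohorts behave like
the generator.

## Numerical and testing choices

Problem sizes were chosen to keep the whole suite comfortably
interactive: cohorts of 43 patients over 364 days (the reliability
cohort's size), 20 seeds for parameter-recovery checks, and bookkeeping
fixtures built at the exact published marginal counts (3963 equal-count
registrations, 4606 registrations with 93 phantoms, 5779 measurements
with 1300 unregistered, 258/39/24 feedback cases). The published margins
do not close into a single dataset — the study's own figure caption and
text disagree by a handful of values — so each family of fractions is
realized by its own minimal fixture, with the running text's figures
treated as canonical.

Determinism: reconciliation, replay and audit are pure functions of
their inputs; the only randomness is in the simulator, which is fully
seed-driven. Report JSON is written with six significant digits so
repeated runs diff cleanly.

## Known limitations

* Cause attribution is an approximation of a manual audit; its
  explained/unexplained split is sensitive to the configured windows.
* The mixed-day rule (compare the prefix, flag the surplus) is one of
  several defensible conventions; counts are reported separately so users
  can apply their own.
* Day-level matching cannot see clock drift or measurements straddling
  midnight.
* The blood-pressure comparison aggregates per day, then per patient; the
  original report's degrees of freedom suggest a different (unstated)
  aggregation, so no numeric equivalence is claimed there.
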