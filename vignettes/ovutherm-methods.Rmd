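---
title: "Methods: temperature-based ovulation confirmation, prediction, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temperature-based ovulation confirmation, prediction, and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Progesterone released after ovulation raises core body temperature by
roughly 0.3–0.5 °C, producing a biphasic nightly temperature curve: a
follicular plateau, then a higher luteal plateau. Overnight sensors (worn on
the skin, or vaginally as a core-temperature proxy) record one or more
readings per night; from the resulting per-night series one wants to

1. confirm whether ovulation occurred in a completed cycle (anovulatory
   cycles stay monophasic),
2. date it, and
3. predict the ovulation day — and hence the fertile window, operationally
   the ovulation day ±3 days — of the *next* cycle.

This is hardest exactly where it matters most: in women with ovulatory
dysfunction (e.g. PCOS), whose curves are noisier, whose cycles are
irregular and right-skewed in length, and of whose cycles a substantial
fraction (roughly a quarter in the population this package models) are
anovulatory.

ovutherm implements the detectors, the next-cycle predictor, the evaluation
framework used to compare such methods against a gold-standard reference,
and a synthetic cycle generator that reproduces the statistical structure of
a side-by-side skin/vaginal sensor study population, so that every stage is
testable without access to any participant data.

## Nightly reduction

Sensors record several readings per night; analyses use one representative
overnight temperature per night. How that reduction is done is essentially
never reported, so `representative_overnight_temperature()` makes it an
explicit, configurable step: the default is the **median** of the night's
readings — robust, parameter-free, and equal to the reading itself on
single-reading nights — with a trimmed mean available. Temperatures are
carried at 3 decimal places (0.003 °C, the resolution class of the modelled
sensors). Missing nights stay missing at this layer; each detector decides
its own gap policy, because gap handling is part of what distinguishes the
detector families.

## Detectors

All detectors consume a vector indexed by cycle day (day 1 = first day of
menstruation, the standard clinical convention), with `NA` for missing
nights; all are deterministic and stop at the first confirmed shift,
mirroring the practice of measuring until ovulation is confirmed.

### Three-over-six (`tos_detect`)

The classical basal-body-temperature rule: ovulation is confirmed when 3
consecutive nightly temperatures are each at least 0.3 °C above the
preceding 6 consecutive nights, and the ovulation day is the day before the
first of the 3 high nights. Two points the verbal rule leaves open are made
explicit:

* *Comparator.* "Higher than the previous 6 days" is read as higher than
  the **maximum** of the six (the strict reading; a mean comparator is
  available via `low_summary = "mean"`). The strict reading is what makes
  the rule brittle on noisy data, which is the documented failure mode of
  manual application.
* *Ties.* Exactly +0.30 °C qualifies (the rule says "at least"); a small
  numeric guard (1e-8) protects the ≥ against binary representation of
  3-decimal temperatures.

With `allow_gaps = FALSE` (default) any missing night inside a candidate
9-night window disqualifies it. This is deliberate: insufficient data points
inside the window are precisely how strict rule application generates false
negatives, and the evaluation framework is designed to expose that.

### Moving window (`moving_window_detect`)

Rolling means of `window_len` observed nights; a shift is confirmed when the
rolling mean exceeds the minimum of all preceding rolling means by the
threshold for `confirm_nights` consecutive windows. The running *minimum* —
not the previous window — anchors the comparison, so slow upward drift
cannot launder a shift.

### Robust trend detector (`beam_detect`)

A reconstruction of the "spring-loaded beam" family of proprietary
detectors, which use all previous recordings of the cycle to suppress
single-night noise while staying sensitive to sustained trends. No public
description of the actual update rule exists; this implementation is **not**
a claim of equivalence to any commercial algorithm, and its acceptance
surface is property-based (noise-free agreement with the three-over-six
rule, spike robustness, missing-data tolerance), never the clinical accuracy
tables.

The reconstruction maintains, over observed nights:

* an exponentially weighted baseline (a night's weight halves every
  `half_life = 7` nights),
* a running robust scale: the exponentially weighted mean absolute
  residual,
* residual clipping: each residual is clipped at `residual_clip = 3` scale
  multiples before updating the baseline, so a +2 °C outlier night moves the
  baseline barely more than a +0.3 °C night does.

A shift is confirmed when the raw temperature exceeds the baseline by
`deflection_threshold = 0.20` °C on `confirm_nights = 3` consecutive
observed nights after `min_history = 6` nights; missing nights are simply
skipped, which is why this detector keeps working where the strict rule
cannot.

One design decision deserves emphasis: nights inside an active candidate
run are **withheld** from the baseline and scale until the run fails, and
absorbed (clipped, in order) only then. This is the standard out-of-control
treatment in EWMA/CUSUM-style monitoring — an observation that may *be* the
shift must not drag the null baseline toward itself while it is being
tested. Without it the baseline climbs during the 3-night confirmation and
erodes the deflection of the later run nights; with it, on simulated cycles
with 0.10 °C nightly noise against a 0.40 °C shift, the beam call lands
within ±1 day of truth in about 92% of cycles (measured across repeated
seeds; the residual misses are dominated by late-ovulation cycles whose
luteal phase offers only three nights before the cycle ends).

The deflection threshold (0.20 °C) is deliberately below the three-over-six
rise (0.30 °C): the beam compares single nights against a *smoothed*
baseline rather than against the maximum of six raw nights, so its
comparison is less noise-inflated and a lower threshold achieves the same
specificity on flat cycles.

## Next-cycle prediction

`predict_next_ovulation()` implements the median rule: when a new cycle
starts, take the confirmed ovulation days of up to the 12 most recent
previous *ovulatory* cycles (anovulatory cycles are skipped, not counted —
a window-of-12-cycles-of-any-kind variant is available via
`window = "all"`), sort them, and return the middle value; with an even
count, the **higher** of the two middle values. Because cycle days are
discrete, the prediction is always a day that actually occurred, never an
interpolated half-day. With no ovulatory history the prediction is
*unavailable* — not zero and not an error — which is what generates
prediction false negatives for fragile confirmation methods whose histories
are all negative.

## Evaluation framework

Each cycle is one independent statistical unit (the convention of the
clinical literature this package serves; no participant-level clustering
correction is applied, a documented limitation). Two complementary analyses:

**Days difference.** Over cycles where both methods confirmed ovulation,
the signed difference (test − reference), summarized by mean, SD (n−1
denominator), and the normal-approximation interval mean ± z·SD/√n.
Negative means the test method confirms earlier in the cycle.

**Threshold method.** Each cycle is classified TP/FP/TN/FN at a day
tolerance (±1 day = day-of-ovulation agreement; ±3 days = fertile-window
agreement): both positive within tolerance → TP; test positive otherwise →
FP; both negative → TN; test negative, reference positive → FN. Metrics use
the standard forms — sensitivity TP/(TP+FN), specificity TN/(TN+FP), PPV
TP/(TP+FP), NPV TN/(TN+FN), accuracy (TP+TN)/total, F score
TP/(TP+(FP+FN)/2) — with zero-denominator metrics reported as absent
(`NA`), never as 0.

Confidence intervals are exact binomial (Clopper–Pearson, Beta quantiles),
generalized to the F score's possibly half-integer denominator by using the
same Beta shape parameters with continuous arguments; a Wilson interval is
available behind a flag. For the prediction analysis TN is identically zero
(predicting "no ovulation" has no meaning), so accuracy reduces to
TP/(TP+FP+FN).

Ovulation timing classes use strict inequalities: *late* when
day/length > 0.65, *early* when < 0.40, otherwise *normal* (day 20 of a
30-day cycle is 66.7% → late). Group comparisons of cycle lengths and of
absolute days differences delegate to `stats::wilcox.test` (Mann–Whitney)
and `stats::kruskal.test`.

Report tables round the way comparative reports print: rates to whole
percent, accuracy to one decimal percent, F to two decimals — **half-up**
(81.25 → 81.3), which is the convention such reports use, rather than R's
round-half-even; full-precision values are always retained. No
multiple-testing correction is applied anywhere, matching the analysis
framework being reproduced.

## The synthetic generator

`generate_population()` emits side-by-side cycle pairs — a vaginal core
channel and a skin channel — with the statistical structure of a
skin-vs-vaginal sensor study population of women with ovulatory
dysfunction. The temperature model is a **step function** plus Gaussian
noise: follicular plateau at the participant's baseline, luteal plateau
`luteal_shift` higher starting `shift_onset_lag` days after the true
ovulation day. A step is the minimal form on which the three-over-six rule
is exactly interpretable, and deliberately omits a pre-ovulatory nadir/dip
(the clinical literature dismisses the nadir as a marker). With the default
lag of 1, a noise-free cycle yields a three-over-six call of exactly the
true ovulation day.

Defaults, chosen once to match the modelled population:

| parameter | default | rationale |
|---|---|---|
| `baseline_temp_mean` | 36.40 °C | typical follicular nightly temperature |
| `baseline_sd_between` | 0.15 °C | between-participant spread |
| `luteal_shift` | 0.40 °C | typical biphasic shift, comfortably above the 0.3 rule |
| `anovulation_prob` | 0.23 | 47 anovulatory of 205 cycles in the modelled population |
| `cycle_length_log_median` | 32 d | the population's median cycle length |
| `cycle_length_log_sd` | 0.30 | log-normal right skew; lengths truncated at ≥21 d |
| `late_ovulation_prob` | 0.335 | 53 of 158 ovulatory cycles later than 65% of the cycle |
| `noise_sd` | 0.07 °C | nightly core-channel noise |
| `skin_lag_days` | −1.5 d | skin channel confirms ~1.5 d earlier on average |
| `skin_attenuation` | 0.9 | slightly damped shift at the skin |
| `skin_extra_noise_sd` | 0.05 °C | extra skin noise, in quadrature |
| `missing_night_prob` | 0.05 | unrecorded nights |

Ovulation timing is drawn as a fraction of cycle length — U(0.65, 0.85) for
late cycles, U(0.38, 0.65) otherwise, which leaves a small <40% early tail
like the modelled population's — and clamped to [7, length−3] so that six
reference nights and three elevated nights structurally exist. The skin
onset lag is day-quantized: per cycle, U(lag−1, lag+1) rounded to a whole
day, so the population mean of the integer skin−core detected-day
difference equals `skin_lag_days` exactly. Long-cycle outliers (167–290
days, as occur in such populations) are generated only when
`long_cycle_prob > 0` is explicitly requested, keeping default runs fast.
Everything is a pure function of the parameter object including its seed;
the caller's RNG stream is left untouched.

**What the generator does not emulate** — and therefore what passing tests
do *not* demonstrate about real data:

* no within-participant correlation of ovulation timing across cycles: each
  cycle's timing is drawn independently. Real participants re-ovulate on
  similar days more often than chance, which is exactly what makes median
  history prediction clinically useful; on this generator the prediction
  pipeline scores ~22% at ±3 days, the no-correlation floor, versus ~60% in
  the modelled study. The prediction *rule* is verified exhaustively; its
  clinical accuracy is not reproducible from simulation alone and is not
  claimed.
* no hormone dynamics, no circadian within-night curve, no gradual
  temperature ramps — the shift is instantaneous;
* skin-channel physics reduced to three effects (onset lag, attenuation,
  extra noise), tuned only to the sign and rough magnitude of the earlier
  skin confirmation, not claimed as physiological truth.

## Numerical and boundary conventions

* Temperature comparisons carry a 1e-8 guard so that serialized 3-decimal
  values compare as intended at exact thresholds.
* Timing fractions use a 1e-12 guard; exactly 0.40 and 0.65 are "normal".
* `days_difference_summary` of a single pair reports mean only, SD and
  interval `NA`; of zero pairs, `NULL`.
* The exact binomial lower bound is exactly 0 at zero successes and the
  upper exactly 1 at complete success, by construction rather than by
  quantile evaluation.
* Bundled study-reported days-difference bounds reproduce from their
  printed mean/SD/n to within one printed ulp (±0.01): the printed inputs
  are themselves rounded to two decimals, which is the attainable
  precision.
* Simulated problem sizes in the test suite (populations of 240–1000
  cycles, 500-cycle detector-recovery runs) are chosen to give stable
  Monte-Carlo estimates in seconds on one CPU.

## Pipeline defaults

In the simulate → detect → evaluate pipeline (`cmd_evaluate`), the
reference call is the **beam detector on the core channel** — standing in
for a gold-standard core-temperature algorithm — and the test call is the
beam detector on the skin channel. Strict three-over-six is available as
either role but makes a poor reference: under realistic noise and missing
nights its strict windows fail on most cycles, which is an object of study
here, not a standard to score against.

## Known limitations

* The beam detector is a reconstruction; results obtained with it
  characterize this implementation, not any proprietary product.
* Cycles are treated as independent units; participant-level clustering is
  ignored in the intervals, as in the framework being reproduced.
* The generator's independence of ovulation timing across cycles bounds
  what simulation can say about prediction accuracy (see above).
* In-cycle (current-cycle, real-time) prediction is out of scope; only
  completed-cycle confirmation and next-cycle prediction are implemented.
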