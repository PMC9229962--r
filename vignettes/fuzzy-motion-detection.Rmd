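---
title: "Fuzzy-logic motion detection for a two-module bracelet sensor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy-logic motion detection for a two-module bracelet sensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motionfuzz)
```

## The problem and the model

A bracelet worn on the forearm carries two film-based sensor modules over
the extensor carpi ulnaris and the flexor carpi ulnaris. Muscle contraction
and relaxation flex the skin surface, bend the films, and modulate their
surface resistance; a bridge-and-amplifier stage turns this into two
voltage channels sampled at 1 kHz. Each forearm motion — wrist extension,
ulnar deviation, finger flexion, wrist flexion — leaves a characteristic
pair of quasi-constant voltage plateaus while the motion is held, and the
resting state sits near zero on both channels. Wrist extension drives both
channels negative; the other three motions produce channel-specific
positive excursions.

`motionfuzz` classifies this signal with a Mamdani-style fuzzy inference
system rather than a learned model: the entire classifier is three small,
inspectable pieces.

**Fuzzification.** The mean of every five consecutive samples per channel
(one 5 ms window) is mapped onto six linguistic labels
(`High_N, Low_N, Off, Low, Med, High`) by triangular membership functions
with 50% overlap. The triangle peaks are placed by three calibration
anchors: `x_n` (mean of the negative samples during wrist extension),
`x_o` (mean during rest) and `x_p` (mean of the positive samples during
the other three motions), giving peaks at `(3x_n - x_o)/2`, `x_n`, `x_o`,
`(x_o + x_p)/2`, `x_p` and `(x_o + 3x_p)/2`. Between adjacent peaks the two
bracketing labels receive complementary linear weights, so interior weights
always sum to one and at most two labels are active; beyond the outer
peaks a single label saturates at weight 1. Only the ordering
`x_n < x_o < x_p` is enforced — the geometry needs nothing more, and signs
are a property of the hardware, not the algorithm.

**Rule evaluation.** A 36-entry table maps every ordered label pair
(module 1, module 2) to a strength `Low`/`Med`/`High` (center values 0.5,
1, 2) for each of the five output states. A rule fires only if both its
labels carry nonzero weight, with firing strength
`m = min(weight_1, weight_2)`; since each channel activates at most two
labels, between one and four rules fire per window.

**Defuzzification and decision.** Each state's score is the centroid
`sum(m_i * w_i) / sum(m_i)` over the fired rules. The denominator is the
same for all five states, so each score is a convex combination of
`{0.5, 1, 2}` and lies in `[0.5, 2]`. The decision is the argmax; an exact
tie keeps the previous decision when it is among the tied states,
otherwise the tied state earliest in the fixed order
(wrist extension, ulnar deviation, finger flexion, wrist flexion, off).
The continuity preference is our choice — the decision rule itself does
not specify tie handling — and it prevents label flicker on symmetric
score vectors while staying deterministic. No other temporal smoothing is
applied; a debounce filter would be a plausible extension but would change
the algorithm being studied.

## The rule table and its completion

Only 18 of the 36 rules are published. The shipped default table
(`default_rule_table()`, also on disk as `inst/extdata/default_rules.csv`)
transcribes those 18 rows verbatim and completes the rest with `Low` for
every output, with one exception: the unpublished (Off, Low) entry mirrors
the published (Low, Off) rule. We apply that mirror only where one
direction of a pair is unpublished; where both directions are published
they are *not* symmetric (e.g. (Low, Med) and (Med, Low) differ), so
symmetry is evidently not a law of the table and we do not impose it more
widely. Every completed row carries `inferred = TRUE`, so inferred rules
are never silently presented as published ones, and the whole table is a
first-class configuration artifact replaceable via `load_rule_table()`
(JSON or CSV).

A note on center values: the published pseudocode annotates some rules
with parenthetical center values that contradict its own definition
(e.g. a `High_motion` consequent annotated `= 0.5`). We follow the
definition — `High = 2`, `Med = 1`, `Low = 0.5` — which also matches the
strength names in the table.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `window_samples` (`k`) | 5 | samples | The classifier's native unit: the mean of every five 1 kHz samples. |
| `sample_rate` | 1000 | Hz | Nominal DAQ rate of the bracelet. |
| `transition_margin_s` | 0.25 | s | Windows this close to a ground-truth change are not scored; movements are performed at constant speed, so the signal ramps rather than steps, and scoring mid-ramp is ill-posed. 0 disables. |
| `ramp_s` | 0.2 | s | Linear transition ramp in the generator; kept inside the default margin so in-plateau scoring is exact. |
| `noise_sd` | `0.1·(x_p − x_o)` | V | Simplest noise model that exercises the 50%-overlap regions of the membership grid. |
| `delta` (saturated plateaus) | `0.05·(x_p − x_o)` | V | How far beyond a saturation boundary the saturated motions sit. |
| `we_ud_factor` | 1 (no stress) | — | Fraction of the ulnar-deviation module-1 excursion retained when it directly follows wrist extension; 0.2 in the stress scenario. |
| `failure_min_s` | 1 | s | Minimum contiguous in-plateau misclassification that flags a sequence as a detection failure. |

## The synthetic generator

No recordings from the physical bracelet are publicly deposited, so the
generator is a first-class module, not a test fixture. It emulates the
documented signal structure: per-motion plateau levels held for ~5 s,
linear ramps between motions, i.i.d. Gaussian noise, optional linear
drift, and per-sample ground-truth labels (ramp samples take the incoming
motion's label, consistent with the transition margin). The canonical
level set places each motion exactly on the label pair of its dominant
rule — rest at (Off, Off), wrist extension at (High_N, High_N) just past
the lower boundary, ulnar deviation at (Low, Off), finger flexion at
(Med, High), wrist flexion at (High, High) — which is the configuration
the rule base was designed around. `all_motion_sequences()` enumerates the
experimental protocol: all 24 orderings of the four motions, each wrapped
in resting segments (30 s at 1 kHz).

The stress scenario reproduces the bracelet's documented hard case: when
ulnar deviation directly follows wrist extension the change in sensor
contact area is small, so the module-1 plateau only partially recovers. We
model that as history dependence — the ulnar-deviation module-1 level is
pulled toward the rest level by `we_ud_factor` only when the preceding
segment is wrist extension — so stressed runs fail exactly at that
transition and nowhere else, qualitatively matching the observed failure
mode. This is a mechanism for reproducing a failure class, not a fit to
any measured failure rate.

**What the generator does not emulate:** inter-channel noise correlation,
plateau-level variability between repetitions (muscle fatigue, strength
and speed of motion), baseline drift of the film resistance, and sensor
placement shifts. Passing tests on synthetic data therefore demonstrate
that the inference pipeline is a faithful, internally consistent
implementation — not that the bracelet achieves any particular accuracy on
real forearms. In particular, the 100% in-plateau accuracy on canonical
synthetic signals is a property of the generator placing plateaus on the
rule peaks; real recordings sit off-peak and between labels, which is
precisely why the real system's reported per-motion accuracies are below
100%.

## Numerical choices and degenerate inputs

- Branch boundaries are upper-inclusive / lower-exclusive, matching the
  published half-open branches; because the interpolated weights are
  continuous at every interior breakpoint, this is only observable at the
  saturation edges, where it agrees with the printed branch order
  (a value exactly at the lower outer peak saturates `High_N`).
- "Nonzero weight" means exactly `> 0`: weights are constructed by the
  fuzzifier, not measured, so no tolerance is needed.
- An empty activation set is impossible for valid weights and is treated
  as an error rather than defaulting to rest: silent defaults mask
  upstream bugs.
- Calibration pools both channels into one shared set of anchors (the
  inference applies one grid to both modules); per-channel overrides are
  possible by building two grids, but asymmetric hardware is out of scope
  for the default pipeline. `x_p` pools the three positive motions rather
  than being computed per motion; with sign-definite calibration segments
  the two readings coincide.
- A window spanning a label change takes the majority label, ties to the
  earlier label; a trailing partial window is dropped (`floor(n/5)`
  decisions for `n` samples).
- Accuracy is per-window: the classifier emits exactly one decision per
  5-sample window, so the window is the only unit the algorithm defines.
- Detection failures are operationalized as >= 1 s of contiguous
  misclassification inside one motion plateau — a reproducible stand-in
  for what is otherwise a visual judgment on the decision traces — and
  the exclusion set for `rate_2` can also be set manually.

## Problem sizes

The test suite and the acceptance script work at the protocol's native
scale: 24 sequences of 30 s at 1 kHz (30 000 samples, 6 000 windows each;
144 000 windows per condition), membership properties on 10^4 random
inputs, and the defuzzification engine checked against a literal 36-term
rule-sum transcription on 10^5 random weight pairs at 10^-12 tolerance.
These sizes run in seconds because the pipeline is vectorized across
windows (the 36 rules are evaluated as 36 vectorized `pmin` operations).

## Known limitations

- The 18 completed rules are a documented stand-in, not a recovered
  artifact; conclusions that depend on unpublished rule entries should
  supply their own table.
- The classifier has no notion of signal quality: a disconnected channel
  reading a constant voltage will be classified confidently.
- Calibration assumes the annotated segments are sign-definite where the
  protocol expects them to be (negative excursions during wrist
  extension, positive during the positive motions); segments violating
  the resulting `x_n < x_o < x_p` ordering are rejected with a diagnostic
  rather than repaired.
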