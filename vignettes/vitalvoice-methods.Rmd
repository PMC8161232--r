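---
title: "Voice-derived vitality and mental activity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voice-derived vitality and mental activity: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitalvoice)
```

## The model

The package scores depressive mood from the emotional composition of
speech. The unit of analysis is the *utterance*: a stretch of continuous
voice delimited by breaths, detected from the signal volume by a
threshold. Each utterance carries five integer emotion components in
0–10 — anger, joy, sorrow, calmness, excitement — produced by an
external emotion recogniser. The recogniser itself is outside this
package: its output table is the package's input contract, and anger,
while carried through, does not enter any index.

From the four used components, each utterance gets two ratios:

$$\mathrm{vivacity} = \frac{\mathrm{joy}}{\mathrm{joy} + \mathrm{sorrow}},
\qquad
\mathrm{relaxation} = \frac{\mathrm{calmness}}{\mathrm{calmness} + \mathrm{excitement}}.$$

Both lie in $[0,1]$: vivacity is high when joy dominates sorrow (the
depressive episode is characterised by the opposite), relaxation is high
when calmness dominates excitement (tension and stress load the
denominator). A recording's vivacity and relaxation are the unweighted
means over its utterances, and its short-term mood index is

$$\mathrm{vitality} = 0.60\,\overline{\mathrm{vivacity}} +
0.40\,\overline{\mathrm{relaxation}},$$

with the line $0.60x + 0.40y = 0.52$ separating the healthy from the
patient side of the (vivacity, relaxation) plane. Because a single
recording is as labile as a single blood-pressure reading, a long-term
index accumulates recordings per subject:

$$\mathrm{mental\ activity} =
0.75\,\overline{\mathrm{vitality}} +
0.25\,\overline{\mathrm{vitality}_{SD}},$$

where $\mathrm{vitality}_{SD}$ is the within-recording standard
deviation of per-utterance vitality — chronically low *and flat*
vitality marks low mental activity — and the corresponding boundary is
$0.75x + 0.25y = 0.426$. All four weight pairs and both boundaries are
stored constants (`index_weights()`), not refit at run time.

### Undefined components

The published definitions leave $0/0$ open (e.g. joy = sorrow = 0). We
treat the affected index as missing for that utterance and exclude it
from the recording mean, with a notice, rather than imputing 0.5: an
imputed midpoint would drag every sparse recording toward the decision
boundary. Recording vitality is always computed from the component means
(`w_viv * mean_vivacity + w_rel * mean_relaxation`); when no utterance
is missing this equals the mean of per-utterance vitalities exactly, and
the test suite asserts that identity at `1e-12`.

`vitality_sd` uses the sample ($n-1$) standard deviation; the source
description says only "standard deviation", so the denominator is
exposed (`index_weights(sd_denominator = "n")`) and a single-utterance
recording gets SD 0. Recording-level means weight every utterance
equally, and subject-level means weight every recording equally,
regardless of length.

### The separating-line fit

How the published weight pairs were originally fitted is not stated.
`fit_separating_weights()` is this package's reconstruction of such a
procedure, used to *verify recoverability* on synthetic data rather than
to produce the constants: a grid search over $w_x \in \{0, 0.01, \dots,
1\}$ with $w_y = 1 - w_x$, scoring each point $w_x x + w_y y$ and
placing the boundary at the midpoint of the score split that maximises
balanced accuracy (either side may be the "high" group). Ties prefer
$w_x$ nearest 0.5, then the smaller $w_x$ — a deterministic rule that
avoids over-committing to an axis when the data do not force it.

## Segmentation

"Volume" is realised as framewise RMS amplitude on normalized samples
(integer PCM divided by $2^{\mathrm{bits}-1}$, so thresholds are
bit-depth independent). Defaults: frame 30 ms, hop 10 ms — ordinary
short-time analysis settings; no frame scheme is prescribed by the
method itself. The state machine is: a frame is speech when RMS exceeds
the threshold; silence shorter than `min_silence_s` (default 0.3 s) does
not end an utterance; speech runs shorter than `min_utterance_s`
(default 0.3 s) are discarded. Both 0.3 s defaults are breath-group
scale conventions and are configuration, not reproductions of published
values. Span boundaries are refined to hop resolution with hop-length
windows, because a 30 ms frame that merely grazes an onset already
fires; the two-burst fixture test pins boundary error to at most one
hop.

The reference deployment adjusted the threshold manually per recording;
that remains available as a numeric `volume_threshold`. The `"auto"`
rule — the geometric midpoint of the 10th and 90th RMS percentiles, with
RMS floored at $10^{-5}$ before taking logs — is a stand-in for
unattended runs, logged whenever used, and it refuses near-constant
recordings (percentile ratio < 1.5) instead of guessing.

## The evaluation layer

Patients are grouped by the Zimmerman HAM-D cutoffs: $\le 7$ no
depression, $\ge 8$ depression; healthy subjects carry no HAM-D. The
battery in `evaluate_cohort()`:

* **Correlation** of vitality with HAM-D over patient recordings:
  Pearson by default (the published result reports an unqualified
  *r*), Spearman as an option.
* **Tukey–Kramer** pairwise comparisons of the three groups, via
  `aov()` + `TukeyHSD()`, whose studentized-range p-values include the
  Kramer unequal-$n$ adjustment.
* **ROC/AUC** for healthy vs depression, oriented so higher vitality
  indicates health. The curve is evaluated at every midpoint between
  distinct pooled scores; the AUC is the normalized Mann–Whitney
  statistic (ties count ½), an identity the tests verify by exhaustive
  pair counting and against pROC.
* **Operating point** by Youden's $J$, ties broken toward higher
  sensitivity — a screening-oriented choice; the published
  sensitivity/specificity pair comes with no stated rule, so a
  fixed-specificity mode is also provided (`min_specificity`).
* **Cohen's d** with the pooled-SD denominator, and a
  summary-statistic variant for printed means/SDs.
* **Power and sample size** for the two-sided two-sample t-test from
  the noncentral t distribution with $\nu = n_1 + n_2 - 2$ and
  noncentrality $d\sqrt{n_1 n_2/(n_1+n_2)}$; `required_n_two_sample_t()`
  inverts the power function by root-finding and returns a fractional
  size. Note the inversion is not always feasible: with one group held
  fixed, power plateaus below 1 as the free group grows, and the solver
  reports unattainability rather than extrapolating.

Repeated recordings of one subject are treated as independent data
points, matching how the published verification pooled 46 recordings
from 30 patients; the report logs this clustering caveat. Under a
subject-level random effect this inflates the nominal type-I error of
the group comparison — visible in the package's own simulations when
multiple sessions are generated — which is precisely why the
mental-activity index aggregates within subject before any comparison.

## The synthetic cohort generator

Real patient audio for this method cannot be redistributed, and the
emotion recogniser is proprietary. The generator therefore emulates the
recogniser's *output*: per utterance, each component is drawn from a
Gaussian with a group-specific mean and common SD (default 2), rounded
and clipped to the 0–10 integer contract. HAM-D scores are rounded
Gaussians, rejection-sampled into the group's Zimmerman range, with
defaults mean 3.1 (SD 2.3) and 16.1 (SD 7.4) for the no-depression and
depression groups. Default cohort sizes are 14 healthy, 19
no-depression and 11 depression subjects with 1–2 recordings of 15–30
utterances each.

Two calibrations fix the generator's default operating point, chosen
once and documented here:

* **Group emotion means** (joy/sorrow/calmness/excitement: healthy
  5.9/3.1/5/5, no depression 5.5/4.1/5/5, depression 4.55/4.5/4.5/5,
  anger 1 throughout) were set by a two-million-draw Monte-Carlo of the
  ratio statistics so expected recording vitality lands near 0.60,
  0.55 and 0.49 — the published group means. These are calibration
  targets for the generator, not claims about any real recogniser's
  distribution.
* **The subject-level random effect** (a shared mean shift, positive
  for joy/calmness and negative for sorrow/excitement, SD 0.85) was
  calibrated so the cohort-wide SD of recording vitality is near 0.10,
  the dispersion implied by the published standard errors
  ($0.027\sqrt{14} \approx 0.10$). Without it, averaging ~20 utterances
  per recording would shrink within-group spread to ~0.03 and make
  groups implausibly separable (d ≈ 4); with it, the default cohort
  lands near the published regime (d ≈ 1, AUC ≈ 0.77).

What the generator does **not** model: any acoustic basis for the
scores (components are drawn, not computed from audio — the bundled
`proxy_score()` exists only so the audio path can be exercised
end-to-end and is explicitly not an emotion model); dependence among the
five components (their true joint distribution is unknown; independence
is the generator's assumption); session-to-session drift within a
subject; and any direct coupling between HAM-D and vitality beyond
group membership — so the severity correlation in synthetic cohorts is
attenuated relative to clinical data, and passing tests demonstrate
pipeline correctness and statistical calibration, not clinical
validity.

## Numerical and testing choices

* Power/sample-size oracles: a vectorized 50,000-replicate Monte-Carlo
  of pooled t-tests checks the noncentral-t power within 0.01; the
  solver's inversion identity is checked at `1e-6`.
* AUC: exhaustive pair-count oracle for groups up to 30; binormal
  closed form $\Phi(d/\sqrt 2)$ checked with 200 simulated 20-per-group
  cohorts at a standardized gap of 1.
* Tukey–Kramer family-wise type-I error is simulated under the null
  (500 replicates at group sizes 14/24/22) and required to stay at or
  below 0.07 at nominal 0.05.
* The generator's group means are tested against a fresh
  one-million-draw Monte-Carlo oracle of the ratio statistics (200
  simulated cohorts, agreement within 0.02).
* Property sweeps (segmentation monotonicity in `min_utterance_s`,
  threshold-perturbation stability, index monotonicity and complement
  symmetry) run over small seeded batches; cohort simulations in tests
  use the default cohort or deliberately small ones (e.g. 10 utterances
  per session for the gap-monotonicity sweep over 3 gap levels x 100
  seeds), sizes chosen to make sampling error small relative to the
  asserted tolerances.

## Known limitations

The segmentation defaults are conventions, not published values; real
conversational audio (overlapping speech, noise) is out of scope — the
reference studies removed overlaps manually. The evaluation layer
deliberately mirrors the published analysis, including its treatment of
repeated sessions as independent; a mixed-effects treatment is out of
scope. Mental activity has no published verification cohort, so the
package validates its arithmetic and accumulation behaviour, not its
discriminative performance.
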