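---
title: "Quantifying startle reflex habituation: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying startle reflex habituation: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(startlehab)
```

## The behavioural assay and the data this package starts from

Larval zebrafish (4–5 dpf) respond to an abrupt vibratory or light stimulus
with a stereotyped whole-body escape — the startle reflex. Under repeated
stimulation the response decrements: habituation, a basic non-associative
form of learning that happens downstream of primary sensory transduction.
The standard assay presents a train of 20 square-pulse stimuli of 500 ms
(vibratory, with a frequency in Hz and power in dB, or light flashes with an
illuminance step in lux) separated by a fixed interstimulus interval, while
automated video tracking records the distance each fish travels inside each
500 ms stimulus window. Tracking counts only movements larger than 2 mm, and
movements during the ISIs are never quantified.

This package starts where the tracker stops: a long table with one row per
fish per stimulus window (`fish_id`, `group`, `condition`, optional `phase`,
`stimulus_index`, `distance_mm`). Everything upstream — hardware, video
processing, kinematic decomposition of the escape into scoots, R-turns and
C-bends — is out of scope.

### Threshold semantics

The 2 mm tracking threshold forces a storage decision. We store the tracked
distance when it exceeds the threshold and exactly 0 otherwise, and define
the discrete response indicator as `distance > 2`. This makes the continuous
measure (mm) and the discrete measure (response counts) mutually consistent,
makes thresholding idempotent, and reproduces the truncated-at-zero
response-magnitude distributions real assays show: a spike of exact zeros
(failed responses) next to a positive lobe that starts above 2 mm. A
consequence worth knowing: any steady-state response level below 2 mm is
indistinguishable from silence in this representation.

## Behavioural measures

For each fish, the **cumulative distance travelled (CDT)** is the sum of the
distance over all 20 stimulus windows; the group value is its mean. The
**response probability** of a cohort is the percentage of fish that moved
more than 2 mm during the *first* stimulus (a variant over all stimuli is
exposed but not the default). Per-stimulus group curves are reported as mean
± 1 SE, where SE is the sample standard deviation (n − 1 denominator) over
sqrt(n); published startle work plots "M ± 1 SE" without defining SE, and
this is the conventional reading. A one-fish cohort gets SE 0 with a
warning rather than an error, so degenerate subsets do not abort a pipeline
run.

## The habituation model

The per-stimulus mean response is described by a first-order exponential
decay,

$$y(n) = A\,e^{-(n-1)/D_C} + O, \qquad n = 1, \dots, 20,$$

with three parameters:

* **Amplitude** $A$ (mm) — the first-stimulus response above the offset;
  the model's value at $n = 1$ is exactly $A + O$.
* **Offset** $O$ (mm) — the steady-state response after habituation has
  occurred; the model's asymptote.
* **Decay constant** $D_C$ (stimuli) — the number of stimuli over which the
  amplitude component falls to $1/e$ (~36.8 %) of its initial value.

The index convention ($n - 1$ in the exponent) is the one under which all
three parameter definitions are simultaneously true; with $n$ in the
exponent the first-stimulus prediction would not equal amplitude plus
offset.

### Two fitting routes

`fit_habituation()` offers two methods, and reports which one produced each
result:

* **anchored** (default) follows the parameter definitions literally:
  $O$ is the mean of the last `tail_k = 5` points, $A$ is the first point
  minus $O$, and $D_C$ is the bounded one-dimensional least-squares
  minimiser of the residual sum of squares. The published definition of the
  offset ("the average response to the last stimuli") does not state how
  many trailing stimuli are averaged; 5 is the package default and is
  configurable. With $D_C \le 2$ the 5-point tail of a 20-point curve sits
  at least 6 decay constants from the first stimulus, so the tail mean
  overshoots the true offset by at most $A e^{-6}$ — about 0.25 % of $A$.
* **nls** is a full three-parameter least-squares fit (Levenberg–Marquardt)
  started at the anchored estimate, with the offset kept non-negative and
  the decay constant kept inside the search bounds. Because it starts at
  the anchored solution, its residual sum of squares never exceeds the
  anchored one. Whether published analyses fitted all three parameters
  jointly or extracted $A$ and $O$ directly and fitted only $D_C$ is not
  stated in the literature this package follows; both routes are provided
  and labelled.

### Numerical choices

The decay-constant search runs over $[0.05, 50]$ stimuli. The RSS as a
function of $D_C$ can be multimodal on noisy curves, so the 1-D search
first scans a 60-point log-spaced grid and then refines with Brent's
method inside the bracketing interval; tests verify agreement with a dense
$10^{-3}$-resolution grid. A solution at a search bound is flagged
`nonidentifiable_Dc` rather than treated as a failure, so bootstrap
replicates never abort. A completely flat curve is returned as $A = 0$,
$O$ = that value, $D_C$ undefined, flagged `degenerate_flat`. Negative
fitted amplitudes (sensitisation-like patterns) are permitted and flagged
`negative_A`, never silently clamped.

## The fish-level bootstrap

Parameter uncertainty is estimated by a bootstrap with **the fish as the
resampling unit**: each of the 250 replicates (the conventional depth)
resamples fish with replacement to the original group size, recomputes the
per-stimulus mean curve, and refits the model. Resampling whole fish
preserves the within-fish dependence of responses across stimuli, which
resampling individual stimulus values would destroy. The reported SE of
each parameter is the standard deviation of the replicate estimates;
percentile intervals are available from the stored replicates. The fit
target is always the replicate's *mean curve* — a population-level
description — not per-fish fits, which would be dominated by the
zero-inflation of single traces.

A group of identical fish yields bootstrap SEs of exactly zero, and the
amplitude SE agrees with the standard deviation of estimates across
independently regenerated datasets within a factor of 1.5 (both are part of
the test suite).

The percent-amplitude histogram (`amplitude_distribution()`) bins replicate
amplitudes as a percentage of a reference amplitude. The axis convention —
percent of the largest replicate amplitude, shareable across compared
conditions — is a documented package choice; the zero spike (non-positive
amplitudes, the signature of failed responses) is reported separately so
counts are conserved.

## Statistical comparison suite

Startle CDT distributions are non-Gaussian, so comparisons are rank-based:

* **Wilcoxon signed-rank** for paired designs (baseline versus re-test CDT
  per fish). Zero differences are dropped before ranking (the standard
  convention; the source protocols do not specify). The p-value is exact by
  signed-rank enumeration for $n \le 12$ tie-free pairs and uses the tie-
  and continuity-corrected normal approximation otherwise. Published
  startle reports print "Z" values that are actually rank sums; because
  software conventions differ, the package reports both the rank-sum
  statistic $W$ and the normal deviate $z$, explicitly labelled, rather
  than guessing.
* **Friedman test** on complete blocks (fish × condition CDT from the
  rotated within-subject design), with tie-corrected chi-squared statistic.
  Per-fish CDT feeds the blocks — subject-level values, not group means —
  because the test requires them.
* **Dunn's post-hoc** on within-block mean ranks with Bonferroni adjustment
  over all pairs (control included in the family), capped at 1.
* **Spearman correlation** between the per-stimulus mean count of responses
  and mean distance; exact permutation p for $n \le 8$ (valid under ties),
  t approximation otherwise.

Tests verify each against an independent oracle: full $2^n$ sign
enumeration, the rank-sum formula (including the worked 3×3 case with
$\chi^2 = 6$), the closed-form Dunn $z$, and rank-then-Pearson correlation.
The Friedman test holds its nominal 5 % size within [0.03, 0.07] over 1000
null simulations at the power-study design size (120 fish × 5 conditions).

## The synthetic-data generator

No public per-fish dataset accompanies the protocols this package
implements, so validation runs end-to-end on a generator whose structure
mirrors what the analysis assumes, with known ground truth. For fish $i$:

$$A_i = A\,e^{\eta_i},\quad O_i = O\,e^{\nu_i},\quad
  \eta_i, \nu_i \sim \mathcal N(0, \sigma_f^2),$$

and at stimulus $n$ the fish responds with probability $p$, emitting
$\max\!\big(0, (A_i e^{-(n-1)/D_C} + O_i)(1 + \varepsilon)\big)$ with
$\varepsilon \sim \mathcal N(0, \sigma_\varepsilon^2)$, and 0 otherwise.
Design choices, each with its reason:

* **Lognormal fish heterogeneity** keeps distances non-negative without
  truncating the mean structure. It implies the population mean amplitude
  is $A e^{\sigma_f^2/2}$ (2 % above $A$ at $\sigma_f = 0.2$); recovery
  tests measure bias against that estimand.
* **Failed responses are exact zeros**, matching the threshold storage
  convention and the zero spike of observed amplitude histograms.
* **Constant response probability across stimuli** within a condition (the
  protocols report a single per-condition probability); a per-stimulus
  probability vector is accepted for sensitivity analyses.
* **Memory carryover**: in multi-phase designs the per-fish amplitude and
  offset draws are shared across phases and every phase after the first
  starts from $c \cdot A_i$, $c \in [0,1]$; $c = 1$ reproduces the first
  phase in distribution. Because shared fish effects require a shared
  random stream, streams are derived per (preset, condition) — phases
  within a condition draw from one stream.
* **Deterministic seeding**: per-condition streams are derived from the
  master seed by a 31-bit polynomial hash of the (preset, condition)
  label, so adding a condition never perturbs the others.

The generator emulates decaying per-stimulus means, per-fish heterogeneity,
zero-inflated failures, truncated amplitude distributions, group-level
parameter differences and baseline→re-test memory decay. It does **not**
emulate within-stimulus kinematics, response latencies, slow drifts in
responsiveness over a session, or correlations between a fish's response
probability and its response magnitude — so passing recovery tests show
that the *analysis* is correct under the stated model, not that the model
captures every feature of real larvae.

### Study presets

`simulate_study()` ships five documented design presets matching the
published protocols' sample sizes and condition labels: a paired
habituation-memory design (3 groups × 48 fish, baseline + re-test at 1, 5
and 15 min), vibratory frequency (5 × 90 fish: control, 200–800 Hz),
acoustic power (5 × 120: control, 100–126 dB), ISI duration (5 × 120:
control, 0.5–5 s) and light-flash illuminance (4 × 96: control, +135 to
+240 lx). Fish identifiers repeat across conditions, encoding the rotated
within-subject design that gives complete blocks.

Per-condition generator parameters are fixed documented choices made once:
response probabilities follow the published per-condition values; decay
constants sit in the reported 1–2 stimulus range (longer for the 3 s/5 s
ISI conditions); amplitudes fall from 200 to 800 Hz and rise with acoustic
power; offsets rise with ISI duration. All per-response offsets are above
the 2 mm tracking threshold — necessarily so, since every *recorded*
movement exceeds 2 mm; a steady state below threshold would be stored as
silence. Control cells get a near-zero amplitude and the baseline response
probability. The presets reproduce the published *ordinal* patterns
(control below every stimulated condition; the amplitude, power and offset
orderings; re-test suppression only under partial carryover, with the
1-min group at carryover 0.5) and make no attempt to match published CDT
magnitudes, which depend on absolute locomotor scales that cannot be
recovered from summary tables. The habituation-memory preset changes only
the carryover between phases; published re-test response probabilities are
slightly below baseline, but modelling that would break the useful
invariant that carryover 1 reproduces baseline in distribution.

## Reproducibility and problem sizes

Every stochastic step takes an explicit integer seed, and a full
`run_study()` is byte-identical across repeated runs with the same
configuration; changing only the bootstrap depth leaves the descriptive
summaries untouched. The validation suite uses problem sizes chosen to
exercise the estimators at realistic scale while staying quick on a
laptop: 200 independent 24-fish datasets for parameter recovery (median
relative errors under 10 % for amplitude and offset and under 25 % for the
decay constant, at 20 % noise and heterogeneity), 250-replicate bootstraps,
and 1000 null simulations at the 120 × 5 design size for the Friedman
calibration.

## Worked example

```{r example, eval = FALSE}
run <- run_study(preset = "study2a", seed = 1, n_boot = 250)
run$summaries$overall         # mean CDT, SE, response probability per cell
tidy(run$fits$`200Hz`)        # bootstrap means and SEs of A, O, Dc
run$tests                     # Friedman + Dunn-Bonferroni on per-fish CDT
autoplot(summarize_group(run$datasets$`200Hz`))
```

## Known limitations

* The generator's distributional forms are stand-ins; no claim is made that
  real per-fish response magnitudes are lognormal-times-Gaussian.
* Single-exponential decay only; multi-exponential or hierarchical models
  of habituation are out of scope, as is kinematic decomposition of the
  startle into movement subtypes.
* Run-duration bookkeeping for tracking sessions often includes a constant
  per-run overhead beyond the stimulus train; schedules expose `lead_in`
  and `lead_out` so either reading can be configured, and no default is
  asserted.
* The percent-amplitude axis normalisation and the 5-point offset tail are
  documented package conventions where the source protocols are silent.
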