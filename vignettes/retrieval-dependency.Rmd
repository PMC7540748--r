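---
title: "Retrieval dependency: model, inference, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retrieval dependency: model, inference, and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eventdep)
```

## The scientific question

Episodic memories of multi-element "events" — say an *animal*, an
*object*, and a *location* bound into one episode — can be retrieved
holistically: cueing one element brings back the others together, the
behavioural signature of hippocampal pattern completion. In the
paradigm this package analyses, each event's three pairwise
associations are tested in both cue directions (six retrieval trials
per event, four-alternative forced choice, chance = 0.25). If retrieval
is holistic, success on one trial of an event predicts success on the
others; if each association is retrieved independently, it does not.

## The dependency statistic

For one participant and condition, six 2×2 contingency tables are
formed — for each element role, one table pairs the two directed trials
that share that role as **cue**, and one pairs the two trials that
share it as **target**. Every directed pair enters exactly one
common-cue and one common-target table. Each table classifies every
event by the joint outcome of its two trials; the observed proportion
of joint retrieval is

$$\hat{p}_{\text{data}} = \frac{n_{CC} + n_{II}}{n_{\text{events}}},$$

averaged over the six tables. The **independent model** replaces each
table's entry by the value expected if the two trials were independent
given the participant's marginal accuracies $P_1, P_2$ on the table's
two directed pairs:

$$p_{\text{ind}} = P_1 P_2 + (1 - P_1)(1 - P_2),$$

again averaged over the six tables. **Dependency** is the difference
$\hat{p}_{\text{data}} - \hat{p}_{\text{ind}}$; positive values
indicate holistic retrieval, and the subtraction scales the measure for
overall accuracy.

Two design choices are worth making explicit:

* the marginals $P_1, P_2$ are **participant-level accuracies per
  directed pair** within the condition (pooled over blocks), not
  event-level or group-level quantities;
* the six-table average is an unweighted mean (all tables cover the
  same events), and no smoothing or continuity correction is applied to
  0/1 marginals — degenerate accuracy is handled by exclusion instead.

The assignment of directed pairs to tables is the unique one consistent
with "shares a common cue or a common retrieval target"; it is asserted
(and property-tested) rather than configurable.

At ceiling the statistic is bounded: a participant with perfect
accuracy has $\hat{p}_{\text{data}} = p_{\text{ind}} = 1$ and
dependency 0, which can only deflate group means. This motivates the
inclusive ≥ 95% ceiling exclusion; a ≤ 30% floor rule removes
participants near the 4AFC chance level. `study_config()` applies these
thresholds either to the mean of per-condition accuracies
(two-condition within-subject designs) or to pooled accuracy
(single-condition designs); the scope is configurable because both
regimes occur in practice, and the default for multi-condition data is
the across-condition average. Missing (timed-out) responses are counted
as incorrect before any accuracy computation, with per-participant
missing rates retained for reporting.

## Inference

Group-level evidence for dependency comes from a two-sided one-sample
t test of the participant dependency scores against zero, with
Cohen's $d = \bar{x}/s$, identically $t/\sqrt{n}$. Between-group
contrasts use Welch's t with pooled-SD Cohen's d.

The Bayes factor is the Jeffreys–Zellner–Siow one-sample Bayes factor,
implemented from first principles: under the alternative the
standardized effect $\delta$ has a Cauchy$(0, r)$ prior (default
$r = \sqrt{2}/2 \approx 0.707$), the marginal likelihood of the
observed $t$ is

$$m_1(t) = \int_{-\infty}^{\infty}
  f_{t,\nu}\!\left(t \mid \delta\sqrt{n}\right)
  \,\mathrm{Cauchy}(\delta; 0, r)\, d\delta,$$

with $f_{t,\nu}(\cdot \mid \mathrm{ncp})$ the noncentral-t density, and
$\mathrm{BF}_{01} = f_{t,\nu}(t \mid 0)/m_1(t)$, so values above 1
favour the null. The integral is evaluated by adaptive quadrature with
an infinite-tail transform at absolute/relative tolerance $10^{-8}$;
non-convergence is an error, not a warning. The test suite verifies the
quadrature against an algebraically independent route — the
inverse-gamma $g$-mixture representation of the Cauchy prior — to
better than three significant figures, and `bf_robustness()` sweeps a
grid of prior widths (default $\{0.5, 0.707, 1\}$, a conventional
bracketing of the default scale). For Welch contrasts the BF is
evaluated at the Welch $t$ and df with effective sample size
$n_1 n_2/(n_1+n_2)$; this coincides with the standard pooled-variance
two-sample JZS value for equal variances and group sizes and is an
approximation otherwise.

Power is exact noncentral-t: with effect $d$ the statistic is
noncentral-t with $\nu = n-1$ and noncentrality $d\sqrt{n}$, so
two-sided power at level $\alpha$ is
$P(|T| > t_{1-\alpha/2,\nu})$. At the weighted-average published effect
size for this paradigm, $d = 0.86$, this gives 0.95 at $n = 20$
(`required_n(0.86, 0.95)` returns 20) and above 0.99 at $n = 45$. Tests
and prior are two-sided throughout — confirmed numerically: a one-sided
test would give ≈ 0.98 power at $n = 20$, not the published 0.95. No
multiple-testing correction is applied anywhere, matching the reporting
convention of the studies this mirrors.

## The synthetic-data generator

No generative model is published for this paradigm; the generator is an
artifact of this package, built to embody exactly the structure the
statistic assumes, so the pipeline can be validated end to end without
any data download. Each event is latently **holistic** (probability
$h$) or **independent**:

* holistic event: one Bernoulli$(a_h)$ memory draw applies to all six
  of its trials — shared fate, the all-or-none signature;
* independent event: six independent Bernoulli$(a_i)$ draws;
* any trial whose memory draw failed still succeeds by guessing with
  probability 0.25 (4AFC), independently across trials — no
  lure-similarity structure is modelled, since foil composition is
  unspecified in the designs this mirrors.

Participant heterogeneity is a single normal shift (SD `hetero_sd`,
default 0.5) applied jointly to $a_h$ and $a_i$ on the log-odds scale —
the simplest mechanism that reproduces a realistic between-participant
accuracy spread. Defaults ($a_h = 0.75$, $a_i = 0.55$, 15 events,
condition label "separated") give overall accuracy near 0.7, typical of
sub-ceiling performance in this task. Trials are laid on a
counterbalanced schedule faithful to the design: three separated
encoding blocks with one pair per event per block and `n_events/3` of
each pair type per block; retrieval as two direction sets of three
blocks, each block containing one trial per event balanced across
association types, block order following a reduced latin square, with
counterbalancing index cycling over participants. `n_events` must be
divisible by 3 for this balance.

Randomness uses per-participant substreams derived arithmetically from
the master seed (a fixed linear-congruential hash kept below $2^{31}$),
so identical `(config, seed)` reproduce a dataset byte for byte and
participant $i$'s data do not depend on how many participants are
generated. Exact stream matching across languages is not claimed;
distributional behaviour is what the oracle checks.

`expected_dependency_oracle()` gives the closed-form expectation for a
homogeneous configuration by enumerating the joint outcome law of a
table's two trials (all six tables share it by symmetry). The
independent model gives exactly 0; a pure holistic model with
$a_h = 0.5$ and no guessing gives exactly 0.5. The oracle evaluates the
independent model at the *population* marginal, so it is the
large-`n_events` expectation: finite designs add an $O(1/n_{\text{events}})$
bias from estimating marginals, visible only below Monte-Carlo noise at
the sizes used here.

### What the generator does and does not emulate

It reproduces: the event/trial structure, 4AFC guessing floor,
between-participant accuracy spread, the all-or-none dependence
signature at a controllable strength, and ceiling/floor cases for the
exclusion rules. It does **not** model trial timing, stimulus modality,
encoding order effects, response times, or lure confusability — those
are experimental manipulations, exposed here only through the
effect-size knobs. Passing calibration tests therefore shows the
*pipeline* is correct and well-calibrated under the assumed structure,
not that real data follow the mixture model.

## Calibration choices

Two simulation-based checks anchor the test suite, run at sizes chosen
to keep the full suite in minutes on one CPU:

* **Null calibration:** 2,000 replicate experiments of 20 participants
  × 15 events under the independent model. Mean dependency must sit
  within 3 Monte-Carlo standard errors of zero and the one-sample-t
  rejection rate at $\alpha = 0.05$ within [0.03, 0.07].
* **Signal recovery:** `config_power_demo()` fixes a mixture whose
  population effect size (mean dependency over its SD across simulated
  participants, 30 events) is ≈ 0.86. The mixture weight $h = 0.134$
  was set by moment-matching at very large participant counts
  (bracketing scan at $n = 20{,}000$, refinement at $n = 30{,}000$
  giving $d = 0.859 \pm 0.007$) and is not adjusted thereafter. Simulated power at $n = 20$ over 500 replicates must
  match the analytic 0.95 within 3 Monte-Carlo standard errors.

As accuracy approaches ceiling the ≥ 95% rule starts excluding
simulated participants; among the included remainder the dependency
estimate is mildly conservative relative to the oracle (selection on
accuracy). This bias is documented rather than asserted: it is a
property of the exclusion rule, not a defect of the statistic.

## Numerical and degenerate-input policy

* Thresholds are inclusive and compared with a $10^{-12}$ float guard,
  so a participant at exactly 95% (e.g. 114/120) is excluded.
* Zero-variance samples are an error for t tests (not NaN); empty
  scopes are an error for accuracy; `n_events = 0` is an error for
  joint-retrieval proportions; `n_participants = 0` simulations return
  empty results without error.
* An all-incorrect participant has dependency exactly 0 (both the data
  and the independent model put every event in the jointly-incorrect
  cell).
* Quadrature failures raise errors reporting the tolerance achieved.

## Known limitations

* The dependency statistic is descriptive; no guessing-corrected or
  odds-ratio variants (e.g. Yule's Q) are provided.
* Accuracy-side mixed-effects models are out of scope; the package
  analyses dependency, not accuracy differences between conditions.
* The two-sample Bayes factor with unequal variances is approximate, as
  described above.
* The published effect size $d = 0.86$ used in power analyses is an
  input (a weighted average over prior studies), not recomputed here.
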