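---
title: "Methods: exploration-based cognitive bias testing on the radial maze"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exploration-based cognitive bias testing on the radial maze}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mazecbt)
```

## The paradigm

Judgement (cognitive) bias tests infer an animal's affective state from
its response to ambiguous cues placed between a learned positive and a
learned negative reference cue. `mazecbt` implements an
exploration-based variant for mice on an eight-arm radial maze: two
adjacent arms are trained as *positive* (reaching the arm end darkens
the maze and delivers a 20 mg food pellet), the two diametrically
opposite arms as *negative* (entry restores the 400-lux overhead light;
reaching the end adds white noise until the arm is exited). After six
daily 10-minute training sessions with only the four reference arms
open, a single test session opens the four intermediate *ambiguous*
arms — "near-positive" or "near-negative" by adjacency — which trigger
no contingencies. Because the mouse is free to explore, relative
occupancy of the ambiguous arms (rather than approach latency) carries
the bias signal: reduced exploration of near-negative arms is read as a
more negative expectation of ambiguous locations.

## The contingency engine

`contingency_step()` is a pure transition function over session events
(`SESSION_START`, `ENTER_ARM`, `REACH_END`, `EXIT_ARM`, `ENTER_CENTER`,
`SESSION_END`). Choices the written protocol leaves open were resolved
as follows and are part of the engine's contract:

* **Centre timer.** After exiting a positive arm with the light off,
  a 20-s timer arms at the subsequent `ENTER_CENTER`; any `ENTER_ARM`
  cancels it; expiry re-lights the maze, stamped at the expiry time
  (evaluated lazily when the next event arrives).
* **Positive-to-positive transits** keep the light off: only a
  negative-arm entry or the 20-s centre dwell reverts it.
* **One reward per visit.** Repeated `REACH_END` within one visit is a
  no-op; re-triggering requires exiting and re-entering. This prevents
  unbounded pellet streams from a mouse dwelling on the trigger zone
  and matches operant-chamber convention. There is no satiation rule:
  every first-of-visit positive `REACH_END` dispenses.
* **Light-on episodes** end exactly when a positive arm's end is
  reached (treated identically to `REACH_END`).
* **Independent channels.** White noise and light do not interact;
  noise runs from negative `REACH_END` until that arm's exit,
  regardless of light state.
* Entering (as opposed to reaching the end of) a positive arm has no
  effect; the protocol describes none.

In `TRAINING` mode ambiguous-arm events are protocol errors (those arms
are physically closed); in `TEST` mode they update location but emit no
actions. Event-order violations raise errors naming the offending
event.

## Tracking conventions

Coordinates are cm, maze centroid at the origin, arm 0 along +x, arms
indexed counter-clockwise. The central arena is a disc of radius 14 cm;
each arm is a 46 x 9 cm rectangle extending radially from that circle,
with a configurable distal *end zone* (default 10 cm — the published
apparatus does not define the automated end-of-arm trigger zone, so it
is exposed as `end_zone_length`). Boundary tie-breaks: an arm beats the
centre and the end zone beats the arm, so entry/end triggers fire at
first touch. Intervals are half-open `[t_enter, t_exit)`.

`visits_from_track()` assumes a centre-point tracker at a constant
sampling rate (synthetic default 10 samples/s, a typical commercial
export rate). Undetected gaps of at most 0.5 s inside one zone are
bridged; longer gaps split visits (threshold configurable). Speed is
raw consecutive-detected-sample path length over elapsed time, no
smoothing. The QC rule is strict: a trial passes only if both the
percentage of samples with the subject not found and the percentage
skipped are `< 1%` (59/6000 passes, 60/6000 fails).

## Arm-preference scores

With role occupancies `T_pos`, `T_neg`, `T_nearpos`, `T_nearneg`
(proportions of trial duration), `T_ref = T_pos + T_neg` and
`T_amb = T_nearpos + T_nearneg`:

* reference arm score `(T_ref - T_amb) / (T_ref + T_amb)`
* positive arm score `(T_pos - T_neg) / T_ref`
* near-positive arm score `(T_nearpos - T_nearneg) / T_amb`

Denominators use time in arms only (centre time excluded). A zero
denominator yields a missing value — never zero — and propagates into
the statistics as missing. The scores are scale-invariant,
antisymmetric under swapping their numerator roles, and bounded in
`[-1, 1]`; these algebraic properties are enforced by property tests.

## Home-cage observation layer

The observation design mirrors dark-phase focal sampling: hours 2, 3, 6
and 7 of the dark phase on 2 days, the first 5 min of every 20 min,
one-zero sampling in 30-s slots — 30 slots per hour, 240 per mouse.
`schedule_observations()` generalises this to any design in which the
slot length divides the window.

Bout rules: same-form stereotypy intervals separated by pauses of at
most 3 s merge into runs; bar-mouthing qualifies at 10 s of summed
movement time (pauses excluded), cage-top twirling and back-flipping at
3 repetitions. Circling has no published threshold; it receives the
repetition rule as the closest analogue, configurable via
`repetition_forms`. Non-qualifying runs count as generic activity.

One-zero scoring gives a slot 1 for a category if any overlap exists.
Two resolved ambiguities: (1) the inactivity definition tolerates
twitches, so `ACTIVE` intervals of at most 5 s do not make a slot
active (stereotypy-form intervals always do); (2) a bout spanning two
slots scores both — the natural reading of one-zero sampling. A
stereotypic slot is by construction also an active slot, so
`stereotypy_level` (stereotypic / active slots) lies in `[0, 1]`; with
no active slots it is undefined. The square-root transform of the level
is applied in the statistics layer only, exactly once (guarded).

## Synthetic data

`simulate_session()` is a semi-Markov walk over zones, not a diffusion
model: the analysis consumes visits and occupancies, so kinematics only
need to support speed computation (piecewise paths with jitter inside
each zone). Arm choice is a softmax over
`u = valence_bias * v(role) - ambiguity_aversion * w(role) * novelty`,
with `v = +1/-1/+0.5/-0.5` for positive/negative/near-positive/
near-negative arms, novelty `1/(1 + visits)` on ambiguous arms only,
and `w` asymmetric (near-negative 1.3, near-positive 0.7) so aversion
expresses the neophobia-tilted conflict at near-negative arms. Dwell
means are modulated by `exp(0.4 u)`. The effective bias grows by
`learning_rate` per training session, emulating acquisition. All dwell
boundaries snap to the sample grid, which makes the tracking round
trip exact: `visits_from_track()` on a gap-free simulated track
reproduces the ground-truth visits bit-for-bit, and contingency replay
reproduces the simulator's actuator log.

Default rates were fixed once at values a behavioural lab would call
typical for this paradigm: ~5 arm transitions/min (≈50 entries per
10-min session), 10 cm/s running speed, 85% end-reach probability. The
cohort generator houses mice in pairs from two different litters with
within-cage tail/cupped handling assignment, makes ~24% of mice
non-stereotypic and distributes forms 13:4:3
(bar-mouthing : twirling : back-flipping) among stereotypers, with
back-flippers drawn at higher propensities. The planted cohort-level
effect — higher stereotypy propensity raising both valence bias and
ambiguity aversion, on the square-root scale the analysis models use —
is strong enough that the recovered mixed-model F statistics for the
stereotypy covariate are of the same order as a well-powered study
(median around 10 in the acceptance simulations); sign recovery across
cohorts is the acceptance target, not any specific F value.

What the simulator does not emulate: real locomotor kinematics,
satiation or motivational drift within a session, observer error in
home-cage scoring, and any fitting to real animals. A green test
therefore establishes that the pipeline recovers what the generator
planted — not that the generator is a model of mice.

`simulate_homecage()` is an alternating-renewal process (active phases
mean 300 s, inactive 110 s, giving ~73% activity). Stereotypy is
clumped: one contiguous block of runs per active phase, sized by the
propensity, with run lengths and repetition counts drawn to straddle
the bout thresholds. The generator tracks its own ground truth
(qualifying movement time over non-twitch active time) independently of
the bout classifier. The `windows` argument simulates only the observed
hours of a design, keeping multi-day cohorts cheap.

## Statistics

`fit_mixed_model()` fits the study's model family — outcome ~ handling
(+ session + handling:session for longitudinal outcomes) +
`sqrt(stereotypy_level)` with random intercepts for litter and cage —
by REML via `lme4`, with sum-to-zero factor contrasts (and a centred
session covariate when the interaction is present) so the 1-df
main-effect tests are Type-III-style. Session enters as a continuous
covariate by default; the longitudinal layout is not fully determined
by the df pattern alone, and continuous-session is the simpler model
consistent with it.

Denominator df use a Satterthwaite approximation implemented directly
on lme4's modular API: the REML deviance is re-expressed in the
(random-effect SD, residual SD) parameterisation; the df for a
coefficient is `2 (l'Vl)^2 / (g'Ag)` with `g` the numerical gradient of
`l'Vl` and `A` twice the inverse numerical Hessian of the deviance.
On a balanced within-cage design this reproduces the paired t-test's
`n_cages - 1` df exactly (a frozen test), and it was validated during
development to agree with the reference implementation of this
approximation to six decimals. If the Hessian is singular the residual
df is used and recorded.

Random-effect retention follows the study's own practice of excluding
grouping factors that explain nothing: each factor is kept only if its
restricted likelihood-ratio test against the reduced model (referred to
the `0.5 chi2(0) + 0.5 chi2(1)` boundary mixture) is significant at
`keep_alpha` (default 0.05, the analysis-wide significance convention).
Retaining a spurious zero-boundary variance component makes the Wald
tests anti-conservative in cohorts of this size (n = 24, 4 litters, 12
cages); with the retention rule the null rejection rate of the handling
test sits near the nominal 5% (slightly above — about 6% in the
acceptance calibration — which is the known residual small-sample
optimism of Satterthwaite plug-in tests; a Kenward-Roger correction
would shrink it further but is out of scope). Set `keep_alpha = 1` to
always keep all grouping factors.

Post-hoc arm preferences use paired t-tests computed from the closed
form (`mean(d) / (sd(d)/sqrt(n))`, df `n - 1`) with Bonferroni
correction over the declared contrast family — by default the family is
exactly the contrasts requested in the call, since no fixed family size
is prescribed. The stereotypy-form comparison is a Kruskal-Wallis test
implemented from the rank-sum formula with tie correction (all-tied
data give statistic 0 by convention); it matches `stats::kruskal.test`
and a permutation null in the acceptance suite.

## Pipeline

`run_study()` orchestrates QC → visits → metrics/scores → ethogram →
models → paired comparisons → form test, logging every exclusion
(manifest-flagged mice, e.g. the bundled "circler" profile, and
QC-failed trials) with its rule. The schedule defaults to 6 training
sessions + 1 test. Runs are deterministic given seeds; a simulated
study written to disk and re-read re-analyses identically.

## Known limitations

* The Satterthwaite implementation covers the 1-df contrasts these
  models need; multi-df factors would fall back to residual df.
* The entry-proportion summaries are computed per session and then
  averaged; pooled-across-sessions alternatives would differ slightly.
* The simulator's novelty decay and dwell modulation are convenient
  parametric choices; only their monotone relationships (bias → positive
  score; propensity-linked aversion → reference/near-positive scores)
  are validated.
* The exclusion flag for maze-incompatible behaviour (circling) is a
  manifest annotation, not an automated detector.
* The default synthetic cohort ends training with a strong positive
  bias, so at test it occupies reference arms more than ambiguous ones;
  real cohorts with a strong exploratory drive can show the opposite
  preference. Only the planted monotone relationships are validated,
  not this aggregate preference direction.
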