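---
title: "Models and methods behind reclamp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind reclamp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reclamp)
```

## The scientific problem

In visuomotor adaptation, participants reach to targets while cursor feedback
is perturbed; the implicit adaptation system gradually shifts the reach
direction to compensate. With *task-irrelevant clamped feedback* the cursor
follows a fixed path offset from the target (here 15°) regardless of where the
hand goes, which isolates implicit recalibration from aiming strategies.
A striking property of this system is that relearning a previously
experienced perturbation is *attenuated*, not facilitated, and the attenuation
behaves like anterograde memory interference: it appears whenever the same
movement context has previously been paired with feedback whose
action–outcome contingency is discrepant from the clamp — a reversed clamp,
an individually tailored counter-rotation, or simply a long stretch of
ordinary veridical feedback.

`reclamp` packages everything needed to study this phenomenon
computationally: machine-readable protocols for five experiment designs,
a closed-loop synthetic learner with a context-tagged interference mechanism,
the preprocessing rules that turn raw reaches into analyzable series, and the
statistical layer (cluster-based permutation tests, JZS Bayes factors,
Greenhouse–Geisser repeated-measures ANOVA, random-slope mixed models, and
noncentral-t power analysis).

## Protocols

The five designs share a grammar: baseline blocks (no feedback, then
veridical), clamped *learning* blocks, 10-cycle no-feedback *aftereffect*
blocks, and a washout manipulation that differs across designs.

* **E1** (`-C|CV|-C`): 300 cycles of 4 targets (45/135/225/335°). The
  110-cycle washout starts with a reversed clamp and switches to veridical
  feedback adaptively.
* **E2** (`-C|N|-C`): identical, but the washout has no feedback at all.
* **E3** (`-C|-R_G V|-C`): the washout applies a hand-contingent rotation
  initialized to the participant's own mean aftereffect (so the cursor lands
  near the target), decremented by 1°/cycle to zero, veridical thereafter.
* **E4** (`-C|CV|-C` vs `V_85|-C`): two 2-target contexts 180° apart run
  concurrently over 150 cycles; one relearns after a standard washout, the
  other receives 85 cycles of veridical feedback (with a 10-cycle no-feedback
  insert after veridical cycle 50) before its single learning block.
* **E5** (`V_5 / V_45 / V_85 |-C`): three 2-target contexts 120° apart enter
  the veridical block at staggered onsets (cycles 1, 41, 81 of that block), so
  they carry 85, 45 and 5 veridical cycles into a joint 40-cycle learning
  block and a 10-cycle aftereffect block.

Within every cycle each active target appears exactly once in seeded
pseudorandom order, so schedules are reproducible and per-cycle target
multisets are exact.

**Adaptive washout.** The reversed-clamp phase ends when the per-cycle
*median* signed direction error has magnitude strictly below 5° for five
consecutive cycles. The published criterion ("median reach direction within
5° of the targets") does not state whether the median is taken over signed or
absolute errors; we take the median of the signed errors and compare its
magnitude, which is the more literal reading and is robust to motor noise at
the 4-trial cycle size. Monitoring begins from the first reversed-clamp
cycle. If the criterion is never met, the transition is forced at washout
cycle 40 in the 110-cycle washouts, which guarantees at least 70 veridical
cycles; the 40-cycle washout of E4 uses a cap of 15 cycles, preserving the
same proportion (≥ 25 veridical cycles). Angles are handled in degrees,
counter-clockwise positive, 0° rightward, with differences wrapped into
(−180°, 180°].

Demonstration trials that the on-line task used for instruction have no
behavioral consequence and are not simulated; movement times are drawn
lognormal (median 180 ms, log-SD 0.25) independent of adaptation and only
feed the "too slow" (> 300 ms) flag, since slow trials were not excluded
from analysis.

## The synthetic learner

No generative model was fit to the original participants, so the cohort
generator is this package's own construction; its job is to emulate the
*statistical structure* of the behavior — adaptation to a 15–25° asymptote in
80 cycles, slow no-feedback decay, fast feedback-driven washout, and
context-specific attenuation that grows with prior discrepant-feedback
exposure — not to reproduce the published participant-level numbers.

Each context `c` has an adaptation state `x_c` (degrees) and a count `P_c` of
prior discrepant-feedback trials. On a trial in context `c` with interference
multiplier `s = 1 / (1 + kappa * P_c)`:

* clamped: `x_c <- a_f * x_c - s * u * sign(cursor - target)`
* veridical / rotated: `x_c <- a_f * x_c - s * b * (cursor - target)`
* no feedback: `x_c <- a_n * x_c`

`P_c` increments on every visible-cursor trial whose contingency differs from
the learning clamp (veridical, rotated, reversed clamp), and not on learning
clamp or no-feedback trials — encoding the conclusion that interference is
between discrepant feedback signals rather than opposite-signed errors.
Neighboring contexts receive the update scaled by
`exp(-d^2 / (2 * sigma_g^2))` for center distance `d`, so with the default
20° width, contexts ≥ 90° apart are effectively independent (< 1% leak).
The hand angle is emitted as `target + x_c + N(0, sigma_m)`, and the cursor
is computed from that hand angle by the protocol's feedback policy, closing
the loop; the adaptive washout and the E3 rotation schedule are driven by the
simulated behavior itself.

**Defaults** (`agent_params()`): `a_f = 0.98`, `a_n = 0.998`, `u = 0.4`°,
`b = 0.15`, `sigma_m = 4`°, `kappa = 0.003`, `sigma_g = 20`°. With `kappa = 0`
the clamped fixed point is `u / (1 - a_f) = 20°`; retention `a_n` gives the
observed slow, incomplete no-feedback decay (about 40% of the state survives
110 no-feedback cycles); `kappa` is sized so that one standard washout
(~440 discrepant trials) roughly halves the subsequent learning rate.
Interference deliberately scales the *update*, not retention: a single
parameter then yields graded attenuation across the E5 exposures and spared
relearning after the no-feedback washout of E2. The linear growth of
interference in `P_c` is a default, not a claim — the published data only
constrain a monotone trend over 5/45/85 veridical cycles.

What the generator does *not* emulate: between-participant parameter
variability (all simulated participants share one parameter set, so
between-subject variance is noise-driven and smaller than in real cohorts,
and synthetic effect sizes are correspondingly larger), explicit strategy
use, demonstration-trial behavior, reaction/movement-time coupling to
adaptation, and session-to-session consolidation. Passing the qualitative
suite therefore shows that the analysis machinery detects the right patterns
under realistic noise — not that the generator is a measurement model of real
participants.

Cohorts are counterbalanced exactly: clamp direction in halves; the E4
context-role assignment in quarters; the E5 exposure-to-context assignment in
thirds (cyclic rotations) crossed with clamp direction. Sizes not divisible
by these cells are rejected.

## Preprocessing

The reach angle is the signed angle between the start→target and start→hand
lines at the target's radial distance, wrapped into (−180°, 180°]. Reach
angles of counter-clockwise-clamp participants are sign-flipped so positive
always means the adaptive direction. Exclusion is a single chronological pass
per participant on the sign-aligned series: a trial is dropped when its
magnitude exceeds 100° or when it differs from the immediately preceding
trial's *raw* (pre-exclusion) value by more than 20°; both thresholds are
strict, the first trial is exempt from the delta rule, and the pass runs
across block and target boundaries (the published rules do not specify this;
the chronological raw-predecessor reading matches a one-pass implementation).
Retained trials are averaged within participant × context × cycle; cycles
emptied by exclusion are filled by linear interpolation from neighboring
cycles of the same block (nearest value at block edges) and flagged, never
silently zeroed. The aftereffect measure is the unweighted mean of a
10-cycle aftereffect block's cycle means, and the retention ratio divides
the first aftereffect cycle by the mean of the last 10 learning cycles
(flagged undefined when the denominator is within 0.5° of zero).

## Cluster-based permutation inference

For two within-participant condition matrices (participant × cycle), a paired
t test is run per cycle; maximal runs of consecutive cycles with
`p < 0.05` *and* a single sign of t form clusters scored by their summed t
("t sum"). The null distribution flips each participant's condition
assignment independently (a sign flip of their difference series), re-forms
clusters, and records the largest absolute t sum per permutation — zero when
no cluster forms, the standard convention that keeps the null well defined.
A cluster's p value is the fraction of null values at or above its absolute
t sum (a tiny tie tolerance, 1e-8 relative, keeps algebraically equal
permutations from being lost to floating-point jitter); the observed
statistic is not added to the null set, matching the "larger than 95% of the
null t sums" convention, with the conservative (+1)/(+1) variant available
behind a flag. Sign-homogeneous runs scored by |t sum| against a max-|t sum|
null are an interpretation: the published description says "largest t sum"
without addressing sign, and the observed effects are one-signed.

The E5 variant regresses, per cycle, the pooled (participant, condition)
reach angles on the number of prior veridical cycles (with intercept) and
clusters the slope t statistics. Permutations shuffle the covariate values
independently *within* each participant, preserving the within-subject
structure; the published description does not spell out the permutation
scheme for this variant, and the within-participant shuffle is the choice
consistent with the paired test. Degenerate zero-variance cycles are treated
as significant with the sign of the effect (paired case) or as null slopes
(regression case). Families of cluster comparisons (three in E4) use a
Bonferroni-adjusted cluster threshold, 0.05/3 ≈ 0.017, i.e. the 98.3% null
quantile.

## Aftereffect statistics

* `paired_t()` reports the mean difference, t, 95% CI, `d = t / sqrt(n)`, and
  the JZS Bayes factor computed by numerical integration of the noncentral-t
  likelihood against a Cauchy prior on the standardized effect (default scale
  `sqrt(2)/2`, exposed because the published analyses do not state it; the
  package's recomputed values agree with the printed BF10s to within 1%).
* `correlation_with_bf()` uses the Jeffreys approximate likelihood for r
  under a uniform (stretched-beta width 1) prior. This calibration gives
  larger null-consistent BFs than the values printed alongside the published
  correlations (e.g. 0.19 vs 0.12 at r = 0.02, n = 44), whose exact method
  is not stated; they are treated as order-of-magnitude checks.
* `rm_anova_gg()` implements the univariate within-subject decomposition with
  the Greenhouse–Geisser epsilon from the double-centered condition
  covariance; it agrees with `car::Anova` to machine precision and collapses
  to the squared paired t for two conditions. The Bayes factor printed for
  the published ANOVA is out of scope (its computation method is not
  stated).
* `mixed_model_slope()` fits `y ~ x` with correlated random intercept and
  slope per participant by ML (lme4), falling back to uncorrelated random
  effects on singular fits, and uses the residual-df convention
  `N_obs - 2` for the fixed-slope t — the convention consistent with a
  t(178) at 60 participants × 3 conditions.
* `required_sample_size()` iterates the exact noncentral-t power from n = 2
  upward. At d = 0.6, α = 0.05, power 0.95 it returns 38 participants' worth
  of power only at n = 39 (power at n = 38 is 0.9496), consistent with
  `power.t.test`'s continuous solution of 38.6.

## Numerical and design choices

* All randomness flows through explicit seeds; simulation, schedules and
  permutation tests are bit-reproducible given (input, seed), and seeded
  helpers restore the caller's RNG state.
* The permutation null is fully vectorized (one sign-matrix product per
  test), which is what keeps the null simulations cheap; cluster extraction
  works on run-length encodings.
* Problem sizes used in the validation suite: the family-wise error
  simulation uses 500 null datasets of 24 participants × 40 cycles with
  1,000 permutations each; exact-enumeration agreement uses 8 participants
  (2^8 sign patterns) on 20 datasets at 10,000 permutations; the qualitative
  reproduction suite runs 20 Monte-Carlo cohorts per design at the study
  sizes (44, or 60 for E5) with 400-permutation cluster tests. These sizes
  give Monte-Carlo error well below the margins being asserted.
* The JZS integrand is evaluated in its inverse-gamma mixture form, which is
  smooth on (0, ∞) and avoids noncentral-t tail warnings.

## Known limitations

* The generator's single shared parameter set understates individual
  differences; anything sensitive to between-participant variance (e.g.
  realistic effect sizes, correlation analyses across participants) should
  not be calibrated against synthetic cohorts.
* The E3 demonstration-trial generalization rule (25% of the aftereffect) is
  recorded in the protocol documentation but not simulated.
* The deposited dataset of the original study is an optional input: the
  published cohort-level statistics (aftereffect differences of −3.48° and
  −3.09°, the E4 F of 7.96, the E5 slope of −0.04, the 1.97% exclusion rate)
  are properties of those participants and are not reproduction targets for
  synthetic data; `read_trials()` accepts any conforming long-format CSV for
  running the same pipeline on real data.
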