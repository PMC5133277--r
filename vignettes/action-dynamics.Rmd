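---
title: "Action dynamics of cross-modal verification: models, measures, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Action dynamics of cross-modal verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtverify)
```

## The paradigm and what the package models

In a cross-modal verification trial a participant reads a sentence and
sees a photographic scene (in either order), then moves the mouse from a
calibration circle at the bottom-center of a 1024×768 screen to a "yes"
or "no" button in the top corners to report whether the two stimuli
conveyed the same content. Two expectancy sources are crossed: the
*plausibility* of the depicted event (within-stimulus, prior world
knowledge) and the *congruency* of the pair (between-stimuli match), with
presentation *order* varied between participants. The theoretically
interesting cell is *implausible + congruent*: the plausibility violation
pre-activates a "no" that must be overridden by the congruency-mandated
"yes", and this competition plays out in the cursor path.

`mtverify` implements the full analysis chain for this paradigm — design
construction, trajectory measures, trial filtering, and contrast-coded
maximal mixed-effects inference — together with a synthetic-data
generator, because no raw data for this class of study are publicly
deposited. The generator is a first-class, tested component: its defaults
*are* the study conditions the package emulates (64 participants × 100
trials, 225 base scenes × 2 plausibility × 2 congruency = 900 items, 4
Latin-square lists of 225, 60-Hz sampling, 50-px start region,
counterbalanced yes/no buttons).

## The trajectory simulator

Movement on each trial is generated by a two-attractor model. After a
pre-movement dwell at the start point (the latency channel), the cursor
advances in 60-Hz steps. The deterministic velocity is a *constant-speed
direction mixture*:

$$v_i \;=\; s\,\cdot\,\widehat{\big(\hat u_{\text{target}} + \tfrac{\lambda\, w_i}{s}\,\hat u_{\text{competitor}}\big)} \;+\; \varepsilon_i, \qquad \varepsilon_i \sim \mathcal N(0, \sigma_m^2 I),$$

where $s$ is the base speed (px/step), $\hat u$ are unit vectors from the
current position to the responded and competitor buttons, and
$w_i$ decays linearly from 1 to 0 over the first 60% of the ideal path.
The conflict strength is $\lambda = \mathrm{softplus}(\beta_\lambda \cdot
x)$, with $x$ the trial's ±0.5 contrast codes (plus participant and scene
random intercepts), so conditions modulate how strongly the competitor
bends the path.

Two modeling choices deserve comment:

* **Renormalization to constant speed.** An additive competitor pull
  would *accelerate* the cursor, because both buttons share a large
  upward component from the start position; empirically that makes paths
  under conflict *shorter* in time and slightly *less* wiggly, inverting
  the expected relation between conflict and x-flips. Renormalizing the
  deterministic velocity to the base speed makes conflict bend the path
  without speeding up the hand — and makes both mean AUC and mean
  x-flips monotone in $\lambda$, which is the behavior the construct
  demands (and which the acceptance checks verify on the grid
  $\lambda \in \{0, 2, 4\}$ at $\sigma_m = 5$ px).
* **Linear decay of the conflict weight.** Any nonincreasing early-
  deviation weight is defensible; linear over the first 60% of the path
  was chosen for transparency and is exposed via `conflict_w_frac`.

Correctness is drawn per trial from a Bernoulli whose logit is
$\beta_a \cdot x$ plus participant and scene intercepts; the trajectory
then heads to the *responded* button. The dwell is
`latency_base_s` $+\,\beta_{rt} \cdot x\,+$ participant intercept $+$
jitter. Response time is the final sample's timestamp, i.e. dwell plus
movement duration, so condition effects reach RT through both channels.

### Default parameter values

Defaults were fixed once, by pilot simulation, to land in the magnitude
regime typical of this paradigm, and are not intended as fits to any
dataset:

| parameter | default | rationale |
|---|---|---|
| `beta_accuracy` | (2.87, 0.51, 0.005, −0.45, 0.83, 0.26, −0.49, 0) | published accuracy-model coefficients used as generator truth; with the coding below they make implausible+congruent the least accurate cell |
| `participant_sd`, `scene_sd` | 1.5, 1.2 (logit) | with the 2.87 intercept, marginal accuracy comes out near the observed ≈87% |
| `beta_conflict` | intercept 18, plausibility −2, congruency 0.5, plaus:cong −7 | implausible+congruent gets the largest λ; magnitudes give AUC ≈ 0.4–0.7 in standardized units |
| `beta_rt_s` | published latency-row effects (s) | seconds-scale condition effects on the dwell |
| `base_speed_px_per_step` | 12 | ≈0.9 s movement over the ≈730-px ideal path; RT ≈ 1.4 s with dwell |
| `motor_noise_px` | 2.5 | x-flip counts ≈ 1.5–2.5 with the 3-px jitter rule |
| `latency_base_s`, `latency_jitter_s` | 0.42, 0.08 | measured movement latency ≈ 0.46–0.50 s |

What the generator does **not** emulate: heavy-tailed RT distributions
and machine artifacts (so the 4-SD filter removes far fewer than the ~8%
reported for real data), velocity profiles within a movement (constant
speed), post-decision ratings, and the reading phase (simulation starts
at choice-display onset, where all the measures are defined). Passing
tests therefore certify the *pipeline* — measures, filters, models — and
the qualitative effect structure, not distributional realism of human
movement. Note also that at the default (strong-conflict) regime the
x-flip count is no longer ordered across condition cells the way AUC is:
a strong *consistent* pull produces large smooth deviations with few
reversals. x-flip cell ordering tracks conflict faithfully in the
low-λ regime, and the monotonicity checks are run there.

## Design construction

`build_latin_lists()` uses a cyclic Latin rotation: scene $s$ contributes
condition cell $k$ to list $((o_s + k) \bmod 4) + 1$, with per-scene
offsets $o_s$ either deterministic (scene index) or randomized by seed.
This guarantees the partition property, no within-list scene repeats, and
each scene contributing each cell exactly once across lists.
`build_schedules()` assigns participants to lists round-robin, crosses
order and counterbalance with list assignment in balanced blocks, draws
`per_participant/4` items per cell from per-cell queues consumed
cyclically across participants (equal item usage up to remainder — the
published design states equal usage but not within-participant cell
balance; balanced cells were chosen to maximize the power of recovery
tests), and shuffles trial order per participant.

## Preprocessing decisions

* The RT outlier rule is applied to the **grand** distribution, upper
  tail only (`rt > mean + k·sd`, k = 4): the simplest reading of a
  "greater than 4 standard deviations" exclusion, applied before the
  correctness restriction (matching the reported analysis sequence:
  accuracy is analyzed on the RT-filtered set, the dynamics measures on
  its correct subset).
* Canonical space puts the start at the origin, the button row at
  y = 1.5 and the buttons at x = ±1, with **positive x toward the
  incorrect response**; the ~0.7 magnitude of published AUC values
  implies such a normalized space (pixel units would be ~10⁵). The
  canonical object carries the px-per-unit factors of both axes so that
  pixel-defined quantities (50-px start radius, 3-px x-flip jitter,
  movement angles in degrees) are evaluated in screen metric, where a
  circle is a circle.
* AUC is **signed net** area (excursions past the ideal line subtract),
  the dominant convention; it preserves the "greater area = stronger
  competition" reading. The trapezoid is taken on perpendicular
  deviations against position along the ideal line, which is exactly the
  shoelace area of the closed polygon — the acceptance suite checks this
  equivalence on random polylines.
* The initial-degree exit point is the first *sample* outside the radius
  (no circle-crossing interpolation): at 60 Hz and ~12 px/step the
  difference is sub-degree.
* x-flips collapse sub-jitter displacement into the running segment
  (anchor logic); `jitter_px = 0` reproduces the naive sign-change count,
  and the exhaustive enumeration oracle covers all short delta-sign
  sequences.
* Time normalization (101 bins by default) linearly interpolates
  position onto an equal-time grid; the per-bin angle is the
  *displacement* angle from vertical (signed toward the incorrect side),
  chosen over a cumulative-position angle for consistency with the
  initial-degree measure. Growth-curve analysis then averages angle
  profiles per participant × cell before fitting — the standard
  aggregation, which also keeps within-trial autocorrelation from
  dominating the fit.

## Inference decisions

Contrast coding is fixed: Plausible = +0.5, Congruent = +0.5,
Scene-First = +0.5 (their counterparts −0.5), products for the
interactions; on a balanced design all seven predictors are centered, so
main effects are grand-mean effects and a label flip exactly negates the
corresponding β.

The maximal random structure enters, per grouping factor, an intercept
plus *uncorrelated* slopes on every requested predictor that varies
within that factor's units — hence no Order slope by participants
(between-participants), and intercept-only for counterbalancing (a
two-level grouping factor cannot support slope estimation in practice).
The default slope set is the three main effects plus the
plausibility×congruency interaction, the predictors of substantive
interest. Singular fits are pruned by removing boundary slopes (all
essentially-zero ones in one pass, otherwise the smallest) and refitting
until the fit is non-singular or only intercepts remain; zero-variance
random *intercepts* are never removed, only flagged. This full pruning
matters for calibration: retaining spurious slopes inflates the
interaction's standard error and makes the test markedly conservative
(observed type-I ≈ 0.02 instead of ≈ 0.05 in null calibration).

p-values use **Satterthwaite degrees of freedom** by default
(`df_policy = "normal"` switches to the normal reference). With modest
participant counts the t reference matters; Satterthwaite keeps the
type-I error of the interaction test inside [0.025, 0.075] at 16
participants × 40 trials, which the calibration harness
(`calibrate_type1()`) verifies over 200 null simulations. Estimation is
REML via bobyqa with derivative re-checks disabled — identical optima at
a fraction of the cost on these models. The accuracy GLMM (binomial
logit, Laplace) defaults to random intercepts only, the usual concession
to GLMM estimation, and records that reduction on the fit object; x-flip
counts use a Poisson log link (the published count-model intercept ≈ 0.29
matches a log-scale mean, exp(0.29) ≈ 1.34).

### Recovery harnesses and their sizes

Two coverage studies accompany the calibration, both run at sizes chosen
to keep a full re-run affordable while leaving the estimators in their
asymptotic regime; the vignette states them as the package's choices:

* **RT interaction** (`recover_rt_interaction()`): 100 replicate
  experiments at 24 participants × 40 trials with the generating
  plausibility×congruency dwell coefficient −0.06 s, conflict held
  condition-constant so the dwell coefficient is the unconfounded truth
  of the fitted β; 95% Satterthwaite-t intervals must cover it ≥90% of
  the time.
* **Accuracy intercept** (`recover_accuracy_intercept()`): 100
  replicates at 32 participants × 48 trials, generating intercept 2.87
  with no other effects (fixed effects and random-intercept sds zero);
  the fitted model still estimates its random-intercept variances. The
  interval uses a t critical value at participant-cluster degrees of
  freedom. A caveat worth knowing: with *substantial* true random-effect
  variance, Wald-type GLMM intervals for the intercept undercover,
  because the interval width tracks the noisy estimated random-effect
  sd — low-variance realizations produce jointly low estimates and
  narrow intervals. The harness therefore certifies fixed-intercept
  estimation under its stated null random structure, not interval
  calibration under strong clustering.

## Numerical and degenerate-input conventions

* All randomness flows from one root seed through named substreams
  (design, participants, scenes, accuracy, motor), so stages can be
  re-run independently and byte-identical CSV export is part of the
  determinism contract.
* A trajectory that never leaves the start region yields missing initial
  degree and latency (a value, not an error); zero-duration trajectories
  and sub-2-sample inputs are errors.
* SD of a single-trial cell is displayed as 0 (population convention);
  empty cells carry n = 0 and missing statistics.
* Simulation aborts with a runaway error if the button is not reached
  within 10 s of samples.
* Fit non-convergence is surfaced via flags and warnings rather than
  silent acceptance; the pruning path is logged on the fit object and in
  the pipeline's model-spec sidecar.

## Known limitations

* The simulator's conflict channel produces smooth competitor-ward
  curvature; it does not generate discrete changes of mind (abrupt
  mid-flight reversals). As a result the x-flip response to conflict,
  while monotone, is small relative to the count's noise (≈0.4 flips
  between λ = 0 and λ = 4 against a within-condition sd of ≈2.6), and
  monotonicity checks on x-flips bound sampling error with bootstrap
  intervals rather than demanding strict separation at every grid step.
* Counterbalancing has exactly two levels; treating it as a random
  intercept follows the published model description, but its variance is
  weakly identified and often estimated at the boundary.
* The growth-curve module fits participant-aggregated profiles;
  trial-level GCA with autocorrelation-aware errors is out of scope.
* Published cell means/SDs and model coefficients from human data are
  *inputs* to the generator (effect directions, magnitude regimes), not
  quantities the package claims to reproduce: the raw data behind them
  were never deposited.
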