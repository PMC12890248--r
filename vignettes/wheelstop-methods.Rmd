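---
title: "Models and methods behind wheelstop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind wheelstop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheelstop)
```

# The paradigm

`wheelstop` implements the computational core of a wheel-stopping
behavioural paradigm for studying the subjective sense of control and its
relationship with subjective stress. A yellow segment rotates inside a
circle and the participant must brake so that it stops over a red break
zone. Difficulty — and thereby the sense of control the task affords — is
manipulated within subjects through three trial parameters: the rotation
`speed`, the `segment_fraction` (a value in (0, 1] where *larger* means a
*smaller* visible segment) and the `deceleration_increment` governing how
quickly braking stops the wheel. During the session, slider probes (0–100)
ask how in control the participant feels, how difficult the task feels,
and how stressed they are.

The package provides (i) the deterministic trial physics and probe
scheduler, (ii) synthetic-cohort generators with the exact statistical
structure the downstream analyses assume, (iii) the trial-by-trial model
of control ratings with MAP estimation and BIC model selection, (iv)
split-half ICC(A,1) psychometrics, and (v) the mixed-effects coupling and
stress-buffering analyses. Everything runs from simulation; no data
download is required anywhere in the tests.

# Trial physics

A trial's kinematics are simulated in discrete time (default
`dt = 1/60` time units) with the angle accumulating modulo $2\pi$. In
multi-press mode each brake press adds one `deceleration_increment` of
braking strength, applied per step as `presses × increment` with the speed
floored at zero. In single-press mode a single press stops the wheel under
constant deceleration.

Two conventions exist for the single-press deceleration. The assignment
formula for the per-trial increment is $\sqrt{v}/(2\theta_\mathrm{stop})$
(`deceleration_increment_single_press()`), but under constant-deceleration
kinematics that value does not stop the wheel exactly
$\theta_\mathrm{stop}$ radians after the press: the distance travelled is
$v^2/(2a)$, so the deceleration that honours the stopping-angle semantics
("a stopping angle of $\pi/2$ stops the wheel a quarter rotation after
the press") is $a = v^2/(2\theta_\mathrm{stop})$
(`required_deceleration()`). The engine's default single-press mode
enforces the semantics, because the semantics are the testable statement;
the assignment formula remains available via
`single_press_deceleration = "printed"`. `simulate_trial(mode = "closed")`
replaces the post-press stepping with the closed form, eliminating
time-discretisation error; the discrete and closed forms agree to $O(dt)$.

A trial is won when the resting segment overlaps the break zone. The
segment's drawn width is `(1 − segment_fraction) · 2π · base_width` with
`base_width = 0.5` by default; only the encoding "greater fraction =
smaller segment" is fixed by the paradigm, so the width scale is a
declared configuration choice. The win criterion is arc overlap (a
centre-in-zone variant is available).

```{r physics}
stop_distance(1, 1 / pi)             # a quarter rotation
required_deceleration(2, pi / 2)     # enforces the stopping angle at v = 2
```

# Sessions and probe scheduling

Trials come in blocks of 5. After every block a slider probe is shown,
control and difficulty alternating, so each kind recurs every 2 blocks
(10 trials). Stress probes are added every 16 blocks (80 trials) in the
Study-1 design and every 9 blocks (45 trials) in Study 2. The default
session lengths — 64 blocks for Study 1, 27 for Study 2 — realise 4 and 3
stress timepoints. Study-1 parameter orders are randomized per
participant; Study-2 sessions order the parameter grid from hardest to
easiest (decreasing speed and segment fraction, increasing deceleration)
to elicit growing feelings of control.

The supplementary parameter combinations of the original experiments are
not part of the package; `default_parameter_grid()` is a declared 3×3×3
grid spanning easy to hard trials, and every function accepts a custom
grid.

```{r schedule}
sched <- build_session("study2", seed = 1)
sched
```

# The control-rating model

Control ratings are modelled from the trial parameters. Per participant,
the three regressors (log-transformed deceleration increment, segment
fraction, speed) are z-scored over that participant's trials and
exponentially smoothed with a discount $\gamma$:

$$\hat{x}^t_i = x^t_i + \gamma\,\hat{x}^{t-1}_i,\qquad \hat{x}^1_i = x^1_i$$

The predicted rating is the weighted sum
$\hat{y}^t = \sum_i \beta_i \hat{x}^t_i + \beta_0$, and parameters maximise
the penalised objective

$$\ell = -\sum_{t \ge 2,\ t\ \mathrm{rated}} \left(y^t - \hat{y}^t\right)^2
      - \sum_i \frac{(\beta_i - \mu)^2}{\nu},\qquad \mu = 0,\ \nu = 1,$$

a MAP criterion with a mild Gaussian prior on the regressor weights; the
intercept and $\gamma$ are unpenalised. Three indexing decisions are
deliberate: the smoothing recursion runs over *every* trial while the loss
is evaluated only at trials with an observed control rating (sliders exist
only at probes); the first trial initialises the recursion; and the loss
starts at the second trial. An earlier-rating-discount reading of the
recursion (smoothing the *ratings* rather than the regressors) is
rejected in favour of the regressor-smoothing equation.

Fitting uses multi-start BFGS with an analytic gradient (default 10
starts; betas from N(0, 1), intercept from N(mean rating, 10), $\gamma$
from U(0, 0.9)); the best start wins and the optimisation is unconstrained
in $\gamma$ with a warning outside [0, 1]. The model family comprises all
seven non-empty regressor subsets, each with $\gamma$ and an intercept.
Model comparison uses the Gaussian profiled-variance BIC
$n\log(\mathrm{RSS}/n) + k\log n$ with $k$ counting the included betas,
the intercept and $\gamma$; the group winner has the lowest BIC summed
over participants, with ties broken by smaller $k$ and then the family's
enumeration order. A zero residual sum of squares is floored at $10^{-10}$
so the criterion stays finite.

Two properties of this estimator matter for testing. With the prior
active, the MAP is intentionally biased towards zero (ridge shrinkage of
order $\beta/(S+1)$ where $S$ is the smoothed-regressor Gram mass), so
exact-recovery checks disable the prior (`prior_nu = Inf`), in which
limit the fit equals ordinary least squares on the smoothed regressors.
And $\gamma$ is only weakly identified from probe-cadence data — the
recovery harness reports its truth–estimate correlation honestly rather
than asserting a bound on it.

```{r fit, eval = FALSE}
fits <- fit_control_models(trial_table)   # participant x 7-model tibble
select_best_model(fits)
```

# Synthetic cohorts

The generators are the package's definition of the study conditions, and
every stage of the analysis is tested against them.

* **Control/difficulty ratings** follow the smoothed-regressor model plus
  Gaussian noise (default SD 10 slider units), clipped to [0, 100] in
  realism modes. Full-cohort simulation draws each participant's model
  parameters from a population (betas normal around the group means with
  SD 3.5, intercept N(50, 10), $\gamma$ uniform on [0.1, 0.7]) so that
  between-participant variance — and hence split-half ICC — is realistic;
  `individual_differences = FALSE` freezes all participants at the config
  values. Difficulty is `100 − latent` plus its own noise (SD 10):
  a declared affine coupling that induces the negative control–difficulty
  relationship the analyses assume while leaving unique variance.
* **Stress ratings** follow the within-task coupling model: intercept
  31.13, −0.13 per control unit, +0.38 per difficulty unit, random
  participant intercepts (variance 346.20), random timepoint intercepts
  (3.63) and residual variance 208.61. For direct coupling-recovery
  simulations (`simulate_coupling_cohort()`), per-timepoint mean control
  and difficulty are drawn from a truncated normal (mean 50, SD 20 on
  [0, 100]) — the predictor distribution is not pinned down by the
  paradigm, and coefficient recovery in a linear model is insensitive to
  it.
* **Stage datasets** (`generate_buffering_dataset()`) draw
  participant × two-timepoint stress from the reported induction and
  relief fixed effects with participant random intercepts (variances
  470.40 / 510.27) and residuals (301.09 / 222.45), over the observed
  allocation: 295 participants split ≈201 wheel-task (high control,
  crossed over stressor intensity and win/loss domain) versus ≈94 video
  (neutral control, crossed over stressor intensity). Condition cells are
  apportioned by largest remainder, so every cell count is within
  rounding of its target.

Clipping stress ratings to the slider range biases linear recovery, so it
is off by default in the generators and on in the demo pipeline (which
emulates observable data). Timepoints in the stage models are coded 0/1;
the reported relief intercept implies the original coding used the raw
timepoint labels 2/3, but all slope and interaction terms — the terms the
recovery targets — are invariant to that shift, and only the intercept's
interpretation changes. Video participants carry the reference ("win")
level of the domain dummy since the win/loss manipulation exists only in
the wheel task.

What the generators deliberately do *not* emulate: real slider
distributions (bimodality, anchoring), serial correlation of residuals,
physiological stress dynamics, and any content of the stressor tasks
beyond their condition labels. Passing recovery tests therefore
demonstrates the correctness of the estimation machinery under the
assumed model, not the realism of the model itself.

# Split-half internal consistency

`icc_a1()` implements the single-measure, absolute-agreement intraclass
correlation from the two-way ANOVA mean squares:

$$\mathrm{ICC}(A,1) = \frac{MS_R - MS_E}
  {MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)},\qquad k = 2,$$

with the F statistic and confidence interval computed from the
absolute-agreement formulas using a Satterthwaite denominator df (two-
sided $\alpha = 0.05$). Unlike a Pearson correlation, a constant offset
between the halves lowers the ICC — the property that makes it the right
internal-consistency measure for slider scales. Halves are built per
participant from the chronological slider sequence: odd/even indices
(1-based) or first/second half, with the middle element of an odd-length
sequence assigned to the first half. Stress ratings are pooled across all
session stress probes exactly as ordered, mirroring the original
analysis. Participants with fewer than two ratings are excluded with a
warning.

# Mixed-effects analyses

`fit_coupling_model()` regresses each stress rating on the mean control
and mean difficulty ratings given since the previous stress probe
(`align_probes_to_stress()`), with random intercepts for participant and
timepoint, by REML via `lme4`. If the timepoint intercept renders the fit
singular it is dropped with a warning. Win rate (a percentage, entered
unstandardised) and win/loss domain are optional covariates.
`fit_stage_model()` fits stress at two timepoints on
timepoint × control condition × stressor intensity with a domain
covariate and a participant random intercept.

Inference is large-sample (Wald/normal). The original analyses used
Satterthwaite and Kenward–Roger df; at the study sizes simulated here
(≥295 participants) the difference in CI coverage is negligible, and
exact small-sample df methods are out of scope. The marginal/conditional
R² pair is the variance-partition form: fixed-effects variance over
total, and fixed plus random over total.

`emm_timepoint_contrasts()` computes model-implied timepoint changes per
group on a *balanced* reference grid (each level of every other factor
weighted equally), with standard errors from the fixed-effect covariance
— this reproduces the dummy-coding arithmetic of the reported post-hoc
contrasts exactly (e.g. the induction contrast for the high-control group
is $\beta_t + \tfrac12\beta_{t\times s}$). The buffering statistic is the
difference of the two group contrasts, which equals the difference row by
construction. The balanced (rather than observed-frequency) grid is a
declared choice; an `emmeans` cross-check test keeps the hand-rolled
algebra honest. Benjamini–Hochberg adjustment is applied to the per-group
contrast p-values, and `adjust_pvalues()` accepts bound tokens like
`"<0.0001"`, entering them at their upper limit before adjustment.

# Numerical and design choices

* Optimisation: BFGS, `reltol 1e-10`, up to 2000 iterations; the
  objective surface is kept finite when $|\gamma| \gg 1$ overflows the
  smoothing recursion. A fit errors only if no start converges.
* Zero-variance regressor columns are set to zero (with a warning), never
  dropped, so the regressor order is stable across participants.
* Determinism: every stochastic function takes a seed; cohort simulations
  derive per-participant streams by fixed offsets from the master seed.
  The demo pipeline writes byte-identical artifacts for identical
  configurations.
* Degenerate inputs: a brake policy that never presses ends the trial
  after 3 rotations (lost); empty probe windows yield `NA` aligned
  covariates; a single-participant recovery run is flagged unstable
  rather than crashing.

# Problem sizes used by the test-suite simulations

Simulation sizes in the tests are chosen to make each check sharp at
desk scale: coupling recovery runs 20 replicates at the full study size
(473 × 4), stage recovery 20 replicates at 295 × 2, parameter recovery
100 participants on the Study-1 session, and group BIC model recovery 20
replicates of 24 participants on the Study-2 session. The recovery
harness defaults to the Study-1 session because it is the larger study
and carries 32 control probes per participant; with the Study-2 session
(13 control probes for 5 free parameters) per-parameter recovery
correlations drop substantially, which the harness reports rather than
hides. The truth distribution for the recovery study (betas normal around
the group means 2.33 / −2.25 / −3.09 with SD 3.5, $\gamma$ uniform on
[0.1, 0.7], intercept N(50, 10), noise SD 10) reflects the reported
population spread of the fitted parameters.

# Known limitations

* The smoothing weight $\gamma$ is weakly identified at probe cadence;
  its recovery correlation is low even when the betas recover well.
* No hierarchical (group-prior) fitting of the control model; each
  participant is fit independently.
* The external-validity questionnaire battery is out of scope; only the
  task-side measures are modelled.
* The CLI of the analysis chain is the R API itself (plus
  `scripts/acceptance.R`); there is no shell entry point.
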