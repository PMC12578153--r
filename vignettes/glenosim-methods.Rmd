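---
title: "Methods: simulating glenohumeral stability under graded rotator cuff tears"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating glenohumeral stability under graded rotator cuff tears}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glenosim)
```

## The problem

Rotator cuff tears weaken the muscles that compress and steer the humeral
head into the glenoid fossa. Clinically, many people with substantial tears
still manage daily activities, which suggests that uninjured muscles around
the joint raise their forces to keep the joint reaction force (JRF) seated in
the socket. `glenosim` quantifies that compensation *in silico*: it simulates
a cohort of virtual participants performing six activities of daily living
under eight tear scenarios of graded severity, estimates per-posture muscle
forces by static optimization, scores glenohumeral stability from the
position of the JRF on the glenoid, and runs a repeated-measures statistical
battery over the results.

## The shoulder model

The packaged model reduces the shoulder to the eight scapulohumeral muscles
whose forces are analyzed: the rotator cuff (supraspinatus SSP, infraspinatus
ISP, subscapularis SSC, teres minor Tm), the three deltoid segments (AD, MD,
PD), and the long head of biceps (LHB). Each muscle `i` is characterized by

* a maximum isometric strength `F_max_i` (N),
* a posture-dependent moment-arm vector `r_i(q)` (m) about the glenohumeral
  centre, and
* a posture-dependent unit line of action `u_i(q)` at the humeral head.

Moment arms are low-order polynomials in glenohumeral elevation with a
cosine modulation by the plane of elevation (so the anterior deltoid is an
effective elevator near the flexion plane, the middle deltoid nearly
everywhere, and so on), plus constant axial-rotation and horizontal-plane
lever terms. Lines of action interpolate between a superior-shear-dominated
pull of the deltoid at low elevation and a compressive pull at high
elevation, while the cuff muscles pull the head into the fossa with small
inferior/rotational shear components. All values live in a YAML
configuration (`inst/extdata/shoulder_model.yaml`) and are stand-ins seeded
from published anatomical moment-arm curves; they are not fitted to any
subject, so absolute force magnitudes are not expected to match any
particular experiment. What the defaults are required to achieve is
structural: the intact model completes all six activities feasibly, and the
muscle actions have the anatomically correct signs.

A muscle may alternatively be declared by an origin point and an insertion
radius (`type: two_point`); its moment arm is then the cross product of the
insertion position and the line of action, which the test suite checks
against the tendon-excursion principle (moment arm = length change per unit
joint rotation).

Scapulohumeral rhythm is fixed: elevation below 30 degrees is purely
glenohumeral, and above it each additional thoracohumeral degree is split
2:1 between the glenohumeral joint and scapulothoracic upward rotation. The
split is identical across tear scenarios — tear-induced rhythm changes are a
known limitation of this class of model and are deliberately not modelled.
The scapular tilt matters mechanically: it rotates gravity into the scapular
frame, so at high elevation part of the arm's weight becomes glenoid
compression.

The glenoid articular surface is a planar ellipse, 28 mm anterior-posterior
by 38 mm superior-inferior, facing the humeral head centre from a 25 mm
standoff.

### Tear scenarios

Tears are modelled purely as reductions of maximum strength. The packaged
registry holds eight scenarios — intact; isolated partial and full
supraspinatus tears (S50, S0); a supraspinatus-plus-subscapularis pattern
(S0/SS50); three supraspinatus-plus-infraspinatus patterns of increasing
severity (S0/IS75, S0/IS50, S0/IS25); and a massive three-muscle pattern
(S0/IS25/SS50). Teres minor keeps full strength in every scenario.
`apply_tear()` multiplies the named muscles' `F_max` by the residual
fractions and touches nothing else.

```{r}
scenario_table()
```

## Activities and synthetic kinematics

Six activities are simulated: arm elevation in the flexion and abduction
planes (both analyzed from 10 to 120 degrees), contralateral shoulder
reaching (10-40), head reaching (10-110), and lifting a 1 kg object between
a low and a high shelf (UpL 40-60, UpH 80-100). Elevation trajectories are
minimum-jerk profiles spanning each activity's movement range — 5 s for the
two elevation tasks, shorter self-paced durations for the reaches and lifts —
sampled at 100 Hz and low-pass filtered with a zero-phase second-order
Butterworth filter at 6 Hz, the standard motion-capture smoothing. The
reaches carry prescribed plane/axial-rotation profiles (cross-body with
internal rotation for the shoulder reach, external rotation for the head
reach); these profiles are plausible stand-ins, configurable in the activity
registry, since endpoint tasks do not pin them down.

Trial-to-trial motor variability is injected as smooth low-frequency noise
(three random sinusoids, tapered at the movement ends) added to the
elevation and plane traces, with a per-participant amplitude
(`motor_noise_scale`, default 2 degrees — a typical trial-to-trial
repeatability for filtered elevation traces). White measurement noise is not
simulated separately: the 6 Hz filter would remove it anyway.

Net glenohumeral moments are quasi-static: gravity on a lumped upper-limb
segment (5% of body mass, centre of mass at 16.8% of stature, hand at 35.5%)
plus the handheld load, with no inertial terms. The activities are slow and
the analysis is per 10-degree elevation bin, so velocity- and
acceleration-dependent moments are second-order; dropping them removes any
dependence on unreported segment inertia. Kinetics are then sampled at the
first ascending crossing of each 10-degree bin centre (the movements are
elevation progressions; descending re-crossings under noise are ignored).

## The recruitment problem

At each binned posture the muscle forces solve

```
minimize    sum_i (f_i / F_max_i)^3
subject to  R f = M_net            (moment equilibrium, 3 equations)
            0 <= f_i <= F_max_i
            JRF line inside the glenoid ellipse
```

The cubic load-ratio objective is the classical polynomial recruitment
criterion: strictly convex in the load ratios, so the optimum is unique, and
it penalizes high activations hard enough to spread load across synergists
in proportion to capacity. The JRF is the reaction balancing muscle pulls
and the gravity/load force transmitted at the joint,
`jrf = -(U f + F_ext)`. Requiring its line of action to cross the glenoid
ellipse is, after multiplying through by the (sign-constrained) normal
component, a convex second-order-cone constraint in `f`, so the whole
problem is convex and the solver's local optimum is global. A simulation
cell whose constraints cannot be met — for instance when every depressor and
the deltoid are zeroed — is flagged infeasible ("aborted"), never silently
dropped.

The solver is an augmented-Lagrangian outer loop (multiplier updates on the
three equilibrium equations and the cone constraint, penalty growth factor
4) around box-constrained L-BFGS-B inner minimizations with analytic
gradients. Convergence demands a relative equilibrium residual below 1e-8
and cone violation below the same relative tolerance; solutions along one
trajectory warm-start from the previous bin's forces and multipliers. When
the outer loop stalls, a pure feasibility minimization distinguishes genuine
infeasibility (reported on the solution) from numerical failure (raised as a
distinct error condition). Muscles with zero residual strength are removed
from the problem — their load ratio would be 0/0 — and reported with zero
force. The cone's Euclidean norm is smoothed with a 1e-12 N^2 additive
constant so its gradient exists at the apex; the bias this introduces is
orders of magnitude below the solver tolerance.

Stability is then scored from the intersection of the JRF line with the
glenoid plane:

```
stability = 1 - d_center / d_edge
```

where `d_center` is the intersection's distance from the ellipse centre and
`d_edge` the centre-to-rim distance **along the same ray** — the only
direction-consistent reading that makes the index exactly 0 everywhere on
the rim and 1 only at the centre. For semi-axes `a` and `b` the rim distance
at ray angle `theta` is `a*b / sqrt(b^2 cos^2 theta + a^2 sin^2 theta)`.
Intersections that fall outside the ellipse by no more than the solver's
feasibility tolerance are clamped to the rim; anything further out is
flagged `out_of_glenoid`.

Because the optimizer buys glenoid compression only as cheaply as the torn
cuff allows, the emergent behaviour reproduces the qualitative clinical
picture without being programmed in: with an intact cuff the
moment-producing muscles themselves seat the JRF well inside the fossa; as
severity grows the deltoid takes over elevation, its superior shear pushes
the JRF toward the superior rim, stability falls — most sharply at low
elevation, where the deltoid's line of action is most shear-dominated — and
the remaining depressors (teres minor, long head of biceps, subscapularis)
are recruited as compensators.

## The synthetic cohort

`generate_cohort()` draws participant mass and stature from truncated
normal distributions (63.5 +/- 7.1 kg, 1.715 +/- 0.063 m, +/- 3 SD) matching a
cohort of fifteen young healthy males, and derives arm segment parameters
from the standard anthropometric proportions above. Sex and age covariates
are not modelled — the emulated cohort is homogeneous. Five trials per
activity are generated per participant. The entire study — cohort, trials,
sweep, statistics — is a pure function of one master seed; sub-seeds are
derived by an integer LCG folding so that any cell can be regenerated in
isolation.

The generator also provides `inject_compensation_structure()`, which adds to
chosen muscles' forces increments proportional to each cell's stability loss
plus Gaussian noise (default SD 0.3 N/kg, about a third of a typical
normalized muscle force in these simulations). This creates a ground-truth
negative delta-force/delta-stability correlation of known sign, used to
measure the power of the correlation stage rather than to alter the science.

### What the synthetic data do and do not emulate

The generator reproduces the statistical structure the analysis assumes:
anthropometric spread, trial-to-trial kinematic noise, repeated measures
across eight within-participant conditions, and feasibility-censoring of
aborted cells. It does not emulate marker-level kinematics, inverse
kinematics error, tear-altered scapulohumeral rhythm, co-contraction beyond
what the optimization produces, or pain-mediated recruitment changes.
Passing tests therefore demonstrate that the pipeline recovers what this
model family can express — directional effects and their statistics — not
that the absolute force or stability magnitudes match any in-vivo
measurement.

## The statistical battery

Per (activity, bin) cell and per variable (stability, then each muscle's
body-mass-normalized force), participant-level five-trial means enter a
normality gate: Shapiro-Wilk per scenario sample, parametric route only if
every sample passes at p >= 0.05 (constant samples, for which the test is
undefined, force the rank route with a degeneracy note). The parametric
route runs a one-way repeated-measures ANOVA with plain eta squared
(`SS_effect / (SS_effect + SS_subject + SS_error)` — the classical, not the
partial, variant); the rank route runs the Friedman test with Kendall's
`W = chi^2 / (n (k-1))`. Post hoc, each tear scenario is compared with the
intact model by paired t or Wilcoxon signed-rank tests with Bonferroni
adjustment over the seven comparisons (`p_adj = min(1, 7 p_raw)`).
Significance is fixed at p < 0.05 throughout. Participants with an aborted
cell are excluded from that cell's tests (both omnibus tests require
complete blocks) and the exclusions are counted in the output.

The compensation analysis pairs, within each (activity, bin), the
participant-by-scenario changes from intact of a depressor muscle's force
against the stability change, pooling the seven scenarios — the unit of
analysis is the participant-scenario delta, a choice the data format leaves
open; pooling across bins instead is possible by filtering the long results
table. Pearson's or Spearman's coefficient is chosen by Shapiro-Wilk on each
margin. A significantly negative correlation (force up when stability down)
classifies the muscle as compensatory; `classify_compensation()` applies a
Bonferroni correction across the muscles tested within a family before
classifying, while single calls to `delta_correlation()` use the raw p.

## Numerical and design choices

* **Solver tolerances** — equilibrium and cone: 1e-8 relative; activation
  bounds enforced exactly by the box constraints (activations are capped at
  1; overload is reported as infeasibility, not penalized).
* **Tie-breaks** — the cubic objective is strictly convex in the load
  ratios, so duplicated muscles split load equally and the optimum is
  unique whenever `F_max > 0`.
* **Binning** — first ascending crossing per bin centre, no interpolation;
  a bin never reached raises an error naming the bin.
* **Filter edges** — the forward-backward Butterworth pass uses
  odd-symmetric end reflection to suppress start-up transients.
* **Degenerate statistics** — all-tied blocks return zero statistics with
  p = 1; zero-variance correlation margins return an unclassified result
  with a degeneracy note.

## Problem sizes used by the packaged checks

The full synthetic study is 15 participants x 5 trials x 6 activities x 8
scenarios over 45 elevation bins — 27,000 recruitment solves — and runs in a
few minutes on a single core; the package's end-to-end checks run it once at
that scale. Monte-Carlo calibrations of the statistics use 200-500
replicates, sizes at which the binomial error of an estimated rate is about
a percentage point. The brute-force recruitment oracle enumerates a
two-dimensional null-space grid at 0.1 N; the exact Friedman oracle
enumerates all (3!)^4 within-block permutations of a 4 x 3 table.

## Known limitations

Absolute forces and stability values depend on stand-in moment arms and
strengths and should be read comparatively (scenario vs intact), not as
subject-level predictions. The rigid 2:1 rhythm, the planar-ellipse glenoid,
the lumped arm segment, and the quasi-static moment balance are all
deliberate simplifications; each is localized behind a module boundary
(model configuration, geometry, activities) so a richer component can
replace it without touching the recruitment or statistics stages.
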