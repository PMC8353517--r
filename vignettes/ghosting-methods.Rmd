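---
title: "Ghosting defensive trajectories: models, training and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ghosting defensive trajectories: models, training and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ghostr)
```

## The problem

In a pass play, seven defenders react to six offensive players (a quarterback
and five receivers) between the snap and the forward pass. ghostr learns
*league-average* defensive movement from tracking data and replays
("ghosts") it against the observed offense, so an analyst can ask: given
this offensive motion, where would an average defense have been — and would
the pass have been more or less likely to be completed against it?

The package has three statistical components:

1. **Role alignment.** Tracked defenders have no canonical order, so a
   feature-vector slot ("left corner", "deep safety") must be assigned per
   play. A Gaussian mixture model (GMM) over snap positions defines static
   tactical roles; the Hungarian algorithm turns per-player role densities
   into a per-play bijection. A hidden Markov model (HMM) with Gaussian
   emissions assigns roles *per training window*, because a player's duty can
   change mid-play.
2. **Ghosting policies.** One recurrent policy per role (two LSTM layers, a
   linear head emitting a per-frame displacement) trained by multi-agent
   imitation learning in three phases: teacher-forced pretraining,
   single-policy rollouts with dataset aggregation (DAgger), and joint
   rollouts in which all seven policies impute each other's positions.
   Alternating ("cross-update") optimisation interleaves policy training
   with HMM refits and role re-assignment.
3. **Pass-completion model.** An order-invariant binary classifier of the
   formation at the pass event: \(P(y=1\mid X) = 1/(1+e^{-f(X)})\), with
   \(f\) either a feed-forward network (64/64/32 with batch normalisation
   and dropout) or gradient-boosted trees (depth 10, 60 leaves, learning
   rate 0.03). It is the "third-party" metric that compares ghosted and
   observed defenses without requiring positional identity.

## Coordinates, units and normalisation

All computation is in the tracking data's yard units: the field is
120 x 53.3 yards including end zones, sampled at 10 Hz. `normalize_play()`
applies a pure rotation that puts the line of scrimmage on the x'-axis
(y' = 0), the offensive backfield at positive y', and the offense advancing
toward negative y'. Left- and right-directed plays map to one handedness
(the offense's right sideline is always at x' = 0), so formations from both
directions pool into one distribution. The transform is stored and exactly
invertible; it preserves all pairwise distances to machine precision.

Event windows are inclusive: `clip_to_pass_window()` keeps both the
`ball_snap` and `pass_forward` frames, since the snap configuration seeds
the rollout and the pass configuration feeds the completion model. Plays
with a missing frame for any rostered entity inside that window are dropped
by `filter_plays()` — the policies need dense inputs. Both documented
season splits are available (`by_week`: weeks 1–14 train/validation, 15–17
test; `random_70_30`), with `by_week` the default.

## Role alignment details

The defense model has 7 mixture components, the receiver model 5 (the
quarterback is identified by position and kept fixed). Components are
canonicalized by sorting means along x' then y', so role indices are stable
across refits. Assignment costs are negative log densities of snap
positions under each role; mixture weights are ignored because the
assignment is a bijection (every role is used exactly once). Covariances
carry a 1e-6 diagonal ridge so tight formations never produce singular
densities.

The dynamic model is a 7-state Gaussian-emission HMM fitted by Baum–Welch
over per-defender position sequences (one sequence per defender per play,
snap to pass). Emission features are positions only — velocity, distance to
the quarterback and ball position are deliberately excluded — matching the
static model's use of raw positions. Window-level assignment minimises the
negative emission log-likelihood of each defender's trajectory under each
state by Hungarian matching; this is the plain per-role log-density sum, the
quantity the posterior-weighted version converges to when states are well
separated, and the form under which a defender parked on an emission mean is
costed exactly at the mode density.

One physical caveat found with the switch fixtures: a position-only model
registers a coverage hand-over only once the defender has crossed toward its
new duty region. With adjacent duties ~10 yards apart and an 11 yd/s speed
cap, the Viterbi change point lags the commanded switch by ~4–5 frames; the
tests therefore locate switches relative to the mid-transit crossing.

## Ghosting policies

**State.** Each frame is encoded as 7 defender positions (role order), the
quarterback, 5 receivers (receiver-role order), the ball, and the game-state
triple (yards to go, down, distance to the end zone) — 31 numbers.
Receivers must be role-aligned too: with roster order, mirrored plays put a
policy's key receiver in a different slot and the one-step regression
problem becomes unlearnable.

**Role-centred inputs.** Each policy receives the state with every *other*
entity expressed as an offset from the policy's own (possibly imputed)
position; its own position stays absolute. This is an affine, information-
preserving re-parametrisation of the same positions-only state, but it makes
the pursuit relation (step toward your receiver) directly visible. Without
it we observed the classic imitation pathology: one-step error near the
noise floor yet rollouts drifting ~10 yards within 3 s, because the policy
leaned on momentum cues instead of its own input slot. Inputs are
standardised per role with moments from the teacher-forced windows.

**Targets and caps.** Policies predict the next-frame displacement
(Δx', Δy'), integrated to positions during rollout. Expert corrections in
DAgger — the displacement from the policy's current predicted position to
the true next position — and rolled-out steps are capped at 1.1 yards/frame,
the 11 yd/s physical speed limit. Uncapped corrections can demand
super-physical "teleport" steps that conflict with the teacher-forced
targets and destabilise refits.

**Training schedule.** Windows of 25 frames at stride 15 (10-frame overlap);
a trailing shorter window keeps the play's tail. Hidden state resets at
window starts during training and at the snap during rollout. Adam at
2e-3 with a staged decay (60% of epochs at the base rate, then 25% at a
quarter, 15% at a tenth): the pursuit map is nearly linear and benefits from
a precise final fit. DAgger defaults to 5 iterations; the aggregate always
retains the teacher-forced data, and refits run at half the base rate.
Joint training rolls out all seven policies simultaneously, so each trains
against simulated teammate positions. Reference capacity is two LSTM layers
of 128 units; the bundled tests and the acceptance script use 16–32 units
and tens of epochs, which this generator's first-order pursuit dynamics are
comfortably within — problem sizes chosen so the whole suite runs on one
CPU in minutes.

**Alternating optimisation.** Cycle = (train policies with window roles
fixed) then (fit the HMM on the current plays, re-assign every window's
roles by Hungarian matching). The loop stops when the validation
window-level rollout MAE fails to improve by more than `tol` over a cycle,
returning the best-validation model. Window-level MAE under each arm's own
labelling is also the coordination metric reported by
`window_rollout_mae()`: full-play rollout error from the snap is dominated
by exogenous, unpredictable duty switches and cannot distinguish a
coordinated from an uncoordinated model.

## The pass-completion model

The feature vector at the pass frame has five 13-entry receiver blocks
(receiver position and speed; for each of its two nearest defenders —
nearest by Euclidean distance at that frame, ties broken by entity id — the
absolute position, receiver-relative position and speed), a quarterback
block (position, speed; no self-distances), and a meta block (distance to
the end zone, down, yards to go): 71 features. Defenders may repeat across
blocks. Orientation is excluded; speeds come from the tracking `s` column.

Because receiver order within the vector is arbitrary, training augments by
random receiver-block permutation: a fresh permutation of every sample each
epoch for the network, and permuted replicates (4 by default) for the trees.
`order_invariance_score()` measures the residual sensitivity as the largest
spread of predicted probability across all 120 block permutations of a test
vector. Validation rows are split off *before* augmentation — a permuted
copy of a training formation in the validation set silently disables early
stopping and calibration.

Predicted probabilities are recalibrated by default on the held-out
validation split: a spline-logistic map of the raw score (natural cubic
spline, 3 df) when the split is large enough, affine Platt scaling
otherwise, so `logit(predict_proba(m, X))` remains exactly the (calibrated)
score. The boosted trees otherwise run overconfident with a curved
mid-range bias (they also use 0.8 row/column subsampling, which
measurably smooths their probability surface); the network runs shrunken.
Accuracy is
reported at the 0.5 threshold, the ROC by a full threshold sweep, AUROC by
the trapezoid rule, and the baseline is the all-catch classifier.

## What the generator emulates — and what it does not

`generate_play()` writes the Big Data Bowl 2021 dialect: 7 defenders, a
quarterback and 5 receivers plus the ball at 10 Hz, pre-snap frames, event
tags, per-play metadata, and left/right directions. Receivers follow route
templates (go, hitch, crossing, flat) toward waypoints under a 11 yd/s
speed cap; the quarterback takes a three-yard drop. Man defenders run
first-order pursuit — next step `gain` times the gap to their assigned
receiver plus Gaussian reaction noise (`sigma`, yards/frame) — and the two
safeties hold deep zone anchors with local reaction. Snap-to-pass durations
are `2 + min(Gamma(2, 0.8), 6)` seconds, giving the 2–8 s range with a 3.6 s
mean. Default pursuit gains are drawn per play from U(0.08, 0.4) with
sigma = 0.12.

The completion ground truth is a logistic model of three interpretable
geometry features at the pass frame — the most open receiver's separation
from its nearest defender, the closest defender's distance to the
quarterback, and the deepest receiver's depth — with weights
(2.0, 0.15, −0.5) and bias 6.4. These were fixed once to give a ~65%
completion rate (the league's naive all-catch baseline) and a probability
spread wide enough that recovery is a meaningful test (Bayes-limit AUROC
≈ 0.95). Outcomes are Bernoulli draws; per-play truth probabilities are
stored for calibration checks.

What passing tests on this generator do **not** show: real defenses are not
first-order pursuers with two static zones; real routes, play-action and
coverage disguises produce far richer motion; real completion probability
depends on far more than three geometry features, and a real season's
completion signal is much weaker (published formation-based models sit near
AUROC 0.75, not 0.95). The generator is a test oracle with known structure,
not a football simulator: it verifies that the machinery recovers what it
is pointed at, on data where the answer is known.

Two dedicated fixtures sharpen specific mechanisms. The *scripted
man-coverage fixture* (fixed gain 0.3, sigma 0.05) makes the expert exactly
reproducible, isolating the rollout-drift question: there, DAgger clearly
beats pretraining-only on final-frame error, while the 2-yard bound at 3 s
holds under the default mixed-gain config as well. The *switch fixture*
(hitch routes, 4–8 s plays, 60% of plays swapping two man assignments
mid-play) keeps duty regions stationary so the HMM's state regions match
coverage duties, isolating the coordination question.

## Numerical choices

- GMM/HMM: k-means initialisation (10 restarts) for mixtures, and the
  static role fit runs 5 independently seeded EM restarts keeping the best
  final log-likelihood — single-start EM occasionally merges a corner slot
  with a neighbouring safety slot and splits another, which silently
  scrambles every downstream role index. The mixture fit initialises the
  HMM emissions; 1e-6 covariance ridge; per-frame shifted
  and scaled forward–backward recursions so distant observations do not
  underflow; EM stops on < 1e-8 (GMM) / 1e-6 (HMM) log-likelihood gain.
- Hungarian algorithm: O(n³) shortest augmenting paths with dual
  potentials; validated against exhaustive enumeration for n ≤ 7.
- Networks: hand-rolled batched matrix code with Adam; both backward passes
  are verified against central-difference numerical gradients in the test
  suite. Batch normalisation uses batch statistics in training and running
  moments at inference; dropout 0.3 after the first two hidden layers
  (the reference architecture names the layer without a rate; 0.3 is a
  conventional default, recorded in the config). Binary cross-entropy is
  computed in the numerically stable log1p form.
- Early stopping: patience 10 over a stratified 15% validation split, cap
  200 epochs; trees cap at 400 rounds with 20-round early stopping.
- Ties among equidistant defenders break by entity id; undefined Pearson
  correlations (zero variance) are reported as flagged `NA`, not errors.
- CSV output writes coordinates at 10 decimal places, so a write/read round
  trip is exact to < 1e-9 (and byte-identical under a fixed seed).

## Known limitations

- The ghost policies are trained and validated on scripted coverage; no
  claim is made about capacity (128-unit layers were never needed here).
- The HMM assigns roles per window, so a switch inside one window is
  labelled by the window's majority duty.
- Per-timestep completion curves reuse the pass-event feature builder at
  every frame, extending a pass-frame model over time exactly as the
  headline comparison requires; early-window probabilities are
  extrapolations of that model, not estimates of "completion probability if
  thrown now".
- `down`, `yards_to_go` and field position enter both models as raw
  features; the generator gives them no causal effect on motion, so tests
  cannot detect steerability by game state.
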