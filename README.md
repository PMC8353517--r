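# ghostr

Defensive "ghosting" for American football pass plays: ghostr learns
league-average defensive movement from 10 Hz player-tracking data (the NFL
Big Data Bowl 2021 CSV dialect) and replays it against the observed offense,
producing counterfactual defender trajectories between the snap and the
forward pass. A formation-based, order-invariant pass-completion probability
model serves as the evaluation statistic: it scores the observed and the
ghosted defense on the same offensive motion, so defensive positioning can
be compared to the league average without matching trajectories point by
point.

It is intended for sports scientists and analysts working with football
tracking data, and for anyone who wants a self-contained, testable
implementation of coordinated multi-agent imitation learning on movement
data.

## What is inside

- **Tracking data handling** — `read_tracking()` / `write_tracking()` for the
  Big Data Bowl dialect (`weekN.csv`, `plays.csv`, `games.csv`);
  `filter_plays()` keeps clean 7-defender / 6-offense pass plays (snap and
  pass events present, no sack, no handoff, dense frames);
  `normalize_play()` rotates every play into scrimmage-line coordinates
  (line of scrimmage at y' = 0, offense advancing toward negative y');
  `clip_to_pass_window()`, `split_collection()`.
- **Role alignment** — tactical roles independent of listed position:
  a Gaussian mixture over snap formations with Hungarian matching
  (`fit_static_role_model()`, `assign_roles_static()`, `solve_assignment()`)
  and a Gaussian-emission hidden Markov model for window-level, time-varying
  roles (`fit_dynamic_role_model()`, `assign_roles_dynamic()`,
  `role_state_path()`).
- **Ghosting** — seven per-role recurrent policies (two-layer LSTM, 128
  units by default, displacement head) trained by teacher-forced
  pretraining, single-policy rollouts with dataset aggregation (DAgger) and
  joint rollouts (`pretrain_policies()`, `dagger_train_single()`,
  `joint_train()`), with alternating policy/role optimisation
  (`alternate_optimize()`) and autoregressive `rollout()`.
- **Pass completion** — `P(y=1|X) = 1/(1+e^{-f(X)})` with `f` a
  feed-forward network (64/64/32, batch norm, dropout) or gradient-boosted
  trees (depth 10, 60 leaves, eta 0.03), made receiver-order invariant by
  permutation augmentation (`build_feature_vector()`, `train_classifier()`,
  `predict_proba()`, `evaluate_classifier()`, `order_invariance_score()`).
- **Evaluation** — per-timestep / per-role rollout errors (`rollout_mae()`,
  `window_rollout_mae()`) and the ghost-vs-observed completion-probability
  comparison (`compare_completion()`).
- **Synthetic data** — `generate_play()` / `generate_dataset()` write the
  tracking dialect with route-running receivers, scripted man/zone pursuit
  defense, optional mid-play duty switches (`inject_role_switch()`), and a
  known logistic completion ground truth, so the whole pipeline is testable
  without the NFL dataset.

## Worked example

```r
library(ghostr)

# a small synthetic season in the Big Data Bowl dialect
season <- generate_dataset(300, synth_config(), seed = 42)
season <- filter_plays(season)
attr(season, "filter_counts")
#> before  after
#>    300    300

season <- split_collection(season, "by_week")   # weeks 1-14 train, 15-17 test
train <- collection_subset(season, c("train", "validation"))
test  <- collection_subset(season, "test")

# formation-based pass completion model (gradient-boosted trees)
tr <- build_pass_dataset(train)
te <- build_pass_dataset(test)
clf <- train_classifier(tr$X, tr$y, classifier_config("gbt", seed = 1))
report <- evaluate_classifier(clf, te$X, te$y)
#> accuracy 0.784 (baseline 0.725), AUROC 0.882

# tactical role alignment from snap formations (x', y' role means in yards)
plays <- lapply(train$plays, function(p) clip_to_pass_window(normalize_play(p)))
def_roles <- fit_static_role_model(plays, n_roles = 7, seed = 1)
rec_roles <- fit_static_role_model(plays, n_roles = 5, side = "receivers", seed = 1)
round(def_roles$means, 1)
#>   [,1]  [,2]
#> 6  6.2  -6.0      five press corners ~6 yards past the line...
#> 7 16.6  -6.0
#> 2 17.4 -13.0      ...and two deep safeties ~13 yards back
#> 4 26.7  -6.0
#> 5 35.7 -12.9
#> 3 36.8  -5.9
#> 1 47.4  -6.0

# ghost policies: pretrain + joint rollout training
prep <- prepare_ghost_plays(train$plays, def_roles, receiver_roles = rec_roles)
model <- ghost_model(def_roles, receiver_roles = rec_roles,
                     config = ghost_config(hidden = 32, pretrain_epochs = 60,
                                           joint_iterations = 1, seed = 1))
windows <- make_training_windows(prep)
model <- pretrain_policies(model, prep, windows)
model <- joint_train(model, prep, windows)

# ghost the held-out plays; compare the defenses through the classifier
held <- prepare_ghost_plays(test$plays, def_roles, receiver_roles = rec_roles)
ghosts <- rollout(model, held)
mean(mapply(function(tp, g) rollout_mae(tp, g)$overall_mae, held, ghosts))
#> mean ghost position error: 1.03 yards
cmp <- compare_completion(held, ghosts, clf)
#> completion probability, observed vs ghost: r = 0.706
#> mean completion prob: observed 0.698, ghost 0.778
```

The ghosts track the scripted defense to about a yard on held-out plays, and
the completion model scores the ghosted defense close to — and strongly
correlated with — the observed one, which is the property the ghosting
approach is built to deliver. (The example takes a few minutes on one CPU;
all numbers are deterministic given the seeds shown.)

To use the real Big Data Bowl 2021 season instead of the generator, point
`read_tracking()` at the downloaded `week*.csv`, `plays.csv` and `games.csv`
files; everything downstream is identical.

A thin command-line front end over the same functions is included at
`inst/cli/ghost.R` (`synth`, `filter`, `roles`, `passprob`, `rollout`
subcommands).

## Method notes

See the methods vignette (`vignettes/ghosting-methods.Rmd`) for the models
and their assumptions, the training schedules, what the synthetic generator
does and does not emulate, and known limitations.
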