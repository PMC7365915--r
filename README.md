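# prwmix

Multi-state persistent random walk models for 2-D cell migration tracks:
simulation, analytic step densities, mixture fitting by simulated
annealing, windowed Bayesian state prediction, and rule-based detection of
high-activity foci in ratiometric biosensor images.

## Who this is for

Labs quantifying *random* cell migration from time-lapse centroid tracks
(fibroblasts, epithelial lines, ...) who want more than mean-squared
displacement: biologically interpretable parameters (step size,
persistence), evidence for multiple coexisting migration states, per-step
state calls along individual tracks, and a way to correlate those states
with signaling readouts such as Rac1 biosensor activity.

## The model

A track sampled at fixed intervals is a persistent random walk: over
interval *i* the cell moves a signed distance
*r<sub>i</sub>* ~ N(μ<sub>r</sub>, σ<sub>r</sub>²Δt) along direction
θ<sub>i</sub> = θ<sub>i−1</sub> + η<sub>i</sub>,
η<sub>i</sub> ~ N(0, σ<sub>θ</sub>²Δt). Negative *r* lets a polarized cell
slip rearward. A cell occupies one of *n* states — each with its own
(μ<sub>r</sub>, σ<sub>r</sub>, σ<sub>θ</sub>) — drawn i.i.d. per step with
occupancies α<sub>i</sub> (Σα<sub>i</sub> = 1). Tracks are reduced to the
displacement components parallel and perpendicular to the previous step,
(Δx<sup>∥</sup>, Δy<sup>⊥</sup>), whose exact densities the package
evaluates by quadrature; the *n*-state density is the mixture
f = Σ<sub>i</sub> α<sub>i</sub> f<sub>i</sub>. Fitting minimizes the sum of
squared differences between the analytic bin-averaged Δx<sup>∥</sup>
density and its empirical histogram (simulated annealing + BFGS
refinement), with a bootstrap-calibrated SSE threshold for profile
confidence intervals and state-count selection, and a held-out
Δy<sup>⊥</sup> consistency check with a simultaneous-fit fallback. Per-step
state posteriors come from Bayes' rule with the occupancies as priors.

## Worked example

```r
library(prwmix)

## two-state fibroblast-like synthetic cohort with known ground truth
fx <- make_mef_like(n_tracks = 20, n_steps = 150, seed = 7)
persistence(fx$steps)
#> [1] 0.09954793

## per-step state calls with the generating model, window length 1
cl <- classify_track(fx$steps, fx$model, window_length = 1)
mean(cl$assigned_state == cl$true_state)
#> [1] 0.9010067

## recover a single migration state from ~20,000 pooled steps
fx1 <- make_one_state(state_params(2.5, 1, 0.5), n_tracks = 50,
                      n_steps = 400, seed = 11)
fit <- fit_migration_model(fx1$steps, n_states = 1,
                           acfg = annealing_config(seed = 1),
                           pcfg = pdf_eval_config(n_quad = 200))
fit$model
#> <mixture_model> 1 state(s), dt = 1
#>   state 1 (alpha = 1): mu_r = 2.52215, sigma_r = 1.00423, sigma_theta = 0.510469
fit$consistency$ok
#> [1] TRUE
```

`persistence()` near 0.1 says the pooled two-state motion is only weakly
persistent — most steps come from the meandering state. The
classification accuracy (90% here) is the fraction of steps whose
maximum-posterior state matches the generating label. The one-state fit
recovers the generating parameters (2.5, 1, 0.5) to within ~2%, and the
fitted model reproduces the held-out perpendicular-displacement histogram
(`consistency$ok`). Two-state mixture recovery (the fibroblast-like
α = 0.12 scenario) needs ~10⁵ pooled steps; the acceptance script below
runs that experiment in full.

For images, `detect_foci()` counts contiguous regions ≥60% above the cell
mean, >100 px, within 5 px of the cell edge, and `foci_by_state()` groups
per-frame counts by predicted state.

A thin command-line interface wraps the same functions
(`inst/cli/prwmix`): `simulate`, `fixtures`, `transform`, `fit`,
`profile`, `predict`, `foci`, `pdf`.

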