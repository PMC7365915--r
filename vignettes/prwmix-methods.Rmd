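---
title: "Multi-state persistent random walks: model, inference, and state prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-state persistent random walks: model, inference, and state prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prwmix)
```

## The model

Randomly migrating cells move persistently: the direction of one step is
correlated with the direction of the previous one. `prwmix` models a cell
track sampled at fixed intervals as a two-dimensional random walk with
persistence. Over the interval \(i\) the cell moves a signed distance
\(r_i \sim N(\mu_r, \sigma_r^2\,\Delta t)\) along a direction
\(\theta_i = \theta_{i-1} + \eta_i\), with turning increment
\(\eta_i \sim N(0, \sigma_\theta^2\,\Delta t)\). Negative \(r_i\) is allowed:
a cell can keep its orientation while its centroid slips rearward. Small
\(\sigma_\theta\) gives nearly straight motion; for large \(\sigma_\theta\)
the direction becomes uniform on \((-\pi, \pi]\) and the walk is purely
diffusive. With the default \(\Delta t = 1\) convention, parameters are
per-sampling-interval quantities (\(\mu_m\) in \(\mu m\), dispersions in
\(\mu m\) respectively rad per square-root interval).

Cells may further occupy one of \(n\) **migration states**, each with its own
\((\mu_r, \sigma_r, \sigma_\theta)\); a state is drawn independently at every
step with occupancy probabilities \(\alpha_i\) summing to 1. This i.i.d.
mixture is the reduced form of a hidden Markov model whose transition
probabilities do not depend on the current state.

### Step coordinates

Raw \((r_i, \theta_i)\) cannot be read off a track unambiguously: a direction
change larger than \(\pi/2\) could be a genuine turn or a rearward slip.
Each consecutive position triplet is therefore rotated rigidly so the
previous displacement points along \(+x\), and the current displacement is
recorded as \((\Delta x^{\parallel}, \Delta y^{\perp})\) — the components
parallel and perpendicular to the previous step (`track_to_steps()`). All
candidate \((r, \theta)\) pairs compatible with an observation contribute to
the analytic densities of these coordinates, which is what makes them
fittable. Under isotropic conditions \(\Delta y^{\perp}\) is symmetric about
zero, so \(\Delta x^{\parallel}\) is the informative component. The
persistence statistic \(P = \langle\cos\theta\rangle\) (`persistence()`)
summarizes a dataset in one number: 1 for straight-line motion, 0 for
diffusive motion.

### The direction reference and negative steps

The simulator references each turning increment to the direction of the
previous **realized displacement** (after a negative-\(r\) step, that
direction is the polarity flipped by \(\pi\)). This convention makes the
simulated \((\Delta x^{\parallel}, \Delta y^{\perp})\) agree *exactly*, step
by step, with the analytic densities evaluated in the displacement frame:
the transform's round trip recovers \((r_i\cos\eta_i, r_i\sin\eta_i)\) to
machine precision, and 10^6-step empirical histograms match the analytic
curves within exact binomial sampling bands. Referencing turns to an
unflipped internal polarity instead would make the observed parallel
component a sign-contaminated mixture \((1-q)f(x) + qf(-x)\) with
\(q = P(r < 0)\) — for the bundled two-state fixture \(q \approx 0.44\) —
and no fit of the analytic mixture could then recover the generating
parameters. Since the coordinates exist precisely to stay faithful to what
is observable, the displacement frame is the consistent choice.

## Analytic step densities

For one state, the density of \(\Delta x^{\parallel}\) is the integral over
the turning angle of the magnitude density divided by \(|\cos u|\), weighted
by the wrapped-Gaussian angle density; the \(\Delta y^{\perp}\) density is
the same construction with the angle window shifted by \(\pi/2\). `prwmix`
evaluates these by Gauss–Legendre quadrature in the angle variable after
the \(h = \cos u\) substitution, which cancels the \((1-h^2)^{-1/2}\)
endpoint singularity of the \(h\)-form. Numerical choices that matter:

* **Wrap truncation.** The wrapped-Gaussian sum over \(2\pi k\) shifts is
  truncated at \(K = \lceil 6\sigma_\theta\sqrt{\Delta t}/2\pi\rceil + 1\),
  leaving tail mass below 10^-8^; beyond
  \(\sigma_\theta\sqrt{\Delta t} = 8\) the wrapped density is uniform to
  better than 10^-14^ and the closed-form limit is used.
* **Adaptive angle window.** The quadrature interval covers
  \(\pm 12\sigma_\theta\sqrt{\Delta t}\) of angular mass (the full
  \((0, \pi)\) when wider). A fixed full-interval rule cannot resolve
  \(\sigma_\theta \to 0\); with the adaptive window the persistent limit
  reproduces the closed-form normal magnitude density to
  10^-4 absolute at \(\sigma_\theta = 10^{-4}\).
* **Panel split at \(\cos u = 0\).** Bin probabilities are normal-CDF
  differences whose arguments sweep through \(\pm\infty\) as \(\cos u\)
  crosses zero, creating a boundary layer at \(u = \pi/2\). The rule is
  split there into two panels; Gauss–Legendre nodes cluster at panel ends,
  which resolves the layer (bin averages converged to ~10^-6 at 200
  nodes in the regimes used here, verified by node-doubling).
* **Bin-averaged scoring.** The pointwise density has an integrable
  logarithmic singularity at \(x = 0\) whenever the magnitude density is
  positive at zero. All fitting compares **bin-averaged** analytic
  densities (exact under the quadrature rule, via CDF differences) against
  empirical bin densities, so the objective never touches the singularity;
  pointwise evaluation at exactly \(x = 0\) returns the average over a
  narrow default bin (`zero_width`, 0.01 um).
* **Sign of the \(1/h\) factor.** The change of variables divides by the
  magnitude-direction factor as \(1/|h|\); a signed divisor would produce
  negative "densities" for rearward-compatible angles. The Monte-Carlo
  equivalence suite (analytic curves vs 10^6-step simulated histograms)
  is the arbiter and confirms this reading.

Mixtures are convex combinations \(\sum_i \alpha_i f_i\) of the per-state
densities (`mixture_pdf_parallel()` and relatives).

## Fitting

`anneal_fit()` scores a parameter set by the sum of squared differences
between the bin-averaged mixture density and the density-normalized
empirical histogram (Freedman–Diaconis binning by default; density scale
keeps the objective comparable across sample sizes). Minimization uses
Metropolis-accept simulated annealing with geometric cooling
(\(T_e = t_0 c^e\)): downhill proposals are always accepted, uphill ones
with probability \(e^{-\Delta s/T}\). Proposals are Gaussian in a
transformed space — identity for \(\mu_r\), log for the dispersions, logit
for \(\alpha\) — so every proposal is feasible without rejection bias. By
default \(t_0\) is set to the standard deviation of the objective over 100
random perturbations of the initial point (targeting roughly half of early
proposals accepted), the cooling factor is 0.95 over 50 epochs of 100
steps, and 6 restarts are run from dispersed, moment-informed initial
points whose two candidate state means are separated (bulk vs upper
shoulder) so that restarts explore genuinely two-state explanations. Each
restart's endpoint receives a short quasi-Newton polish before restarts
are compared, and `refine_fit()` finishes the winner with BFGS in the
transformed space (which enforces \(\sigma > 0\), \(\alpha \in (0,1)\)).
These effort settings are package defaults chosen for histograms of
~10^5 steps and are all overridable.

### Calibration, confidence, and state count

Sampling noise alone makes the SSE nonzero. `bootstrap_sse_threshold()`
resamples the pooled steps with replacement, rebuilds the histogram on the
original bin edges, scores the fixed best-fit model on each replicate, and
returns a quantile (default 0.95) of the replicate SSEs — the scale of
misfit that repeating the experiment could plausibly produce.
`profile_parameter()` then fixes one parameter on a grid, re-optimizes all
others, and reports the contiguous region around the estimate whose
profiled SSE stays below the threshold. A parameter whose profile never
crosses the threshold across its whole plausible range is reported as
unidentified (its interval spans the grid). `select_n_states()` prefers the
one-state model when its SSE is within the bootstrap threshold, i.e. when
its misfit is indistinguishable from sampling noise; fitting two states to
one-state data instead drives \(\alpha\) to 0 or 1 or makes the two states'
parameters coincide, and is flagged as degenerate. The bootstrap quantile
and this operationalization of the state-count rule are package choices.

### The perpendicular consistency check and the joint fallback

Fitting uses \(\Delta x^{\parallel}\) only; the fitted model must then
reproduce the held-out \(\Delta y^{\perp}\) histogram
(`check_perpendicular_consistency()`, exact binomial 4-sigma-equivalent
per-bin bands — the Gaussian \(\pm4\sqrt{p(1-p)/N}\) band is used only
conceptually, since it spuriously rejects single-count tail bins). For some
generating regimes the parallel marginal genuinely cannot pin down a
state's angular dispersion: a state with \(\mu_r \approx 0\) contributes
\(r\cos\eta\) with symmetric \(r\), and that marginal is nearly invariant
to \(\sigma_\theta\) on its upper side. In that case the parallel-only fit
lands in a flat valley, the perpendicular check fails, and
`fit_migration_model()` repeats the estimation fitting both components
simultaneously (summed SSEs), warm-started from the parallel-only
solution. The final consistency verdict and whether the fallback ran are
recorded in the fit.

## State prediction

Given a fitted mixture, `classify_track()` assigns each step to a state by
Bayes' rule with the occupancies as priors, computed in log space. The
likelihood of a step window is the product of per-step parallel-component
densities (the perpendicular component can be multiplied in via
`use_perpendicular`, off by default to match the fitting surface). Windows
are odd-length and centered (default length 1, which performs comparably to
3 and 5 here); near track ends the window shrinks to the largest centered
odd window that fits rather than dropping steps. Ties are broken toward the
larger-occupancy state, the posterior of the non-assigned state is emitted
per step as a false-positive-rate-like quantity, and priors enter once per
window (a single Bayes inversion per step). On two-state tracks simulated
from the bundled fibroblast-like parameter set, the window-1 classifier
recovers the true state of well over 90% of steps (the acceptance suite
recomputes this).

## Foci detection

For ratiometric biosensor images (e.g. a Rac1 FRET ratio), `detect_foci()`
finds localized high-activity regions near the cell edge: contiguous
in-mask pixels that are simultaneously (1) more than 60% above the cell's
mean intensity, (2) strictly larger than 100 pixels, and (3) within 5
pixels of the cell edge. Package choices where the rules leave freedom:
components are 8-connected by default; the cell edge is the set of in-mask
pixels with at least one out-of-mask 4-neighbor (image borders count), with
distances from the Euclidean distance transform; the in-mask mean is taken
after normalization — immaterial, since all criteria are relative or
geometric, making detection invariant to positive rescaling (asserted on
random fixtures). `normalize_frame()` divides by the 5th percentile
(nearest-rank, floor rounding) of in-mask intensities so the dimmest 5% of
the cell maps to 1. `select_frame_count()` picks the per-cell frame count
\(n\) maximizing \(n \times m\) (with \(m\) the number of cells having at
least \(n\) frames; ties go to larger \(n\)), and `foci_by_state()` groups
per-frame counts by predicted migration state.

## Synthetic data: what it does and does not emulate

All tests and acceptance experiments run on synthetic data from the
`fixtures` generators, because no public cell-track dataset accompanies
this model family. `mef_like_model()` is a two-state, wild-type
fibroblast-like parameter set: a persistent state
(\(\mu_r = 3.2\,\mu m\), \(\sigma_\theta = 0.7\)) occupied
\(\alpha = 0.12\) of the time and a meandering state (\(\mu_r = 0\),
\(\sigma_\theta = 1.3\)) the rest. The step-size dispersions
\(\sigma_{r1} = 1.0\) and \(\sigma_{r2} = 2.0\,\mu m\) are package defaults
— chosen once so that state 1 has a well-defined ~3 um characteristic step
and state 2 a highly variable one — since no single established value
exists for them. Default cohorts are 50–100 tracks of 100–1000 steps;
the acceptance experiments use 100 tracks x 1000 steps (~10^5 pooled
steps) for recovery and ~3,000 steps for classification, sizes at which
the recovery tolerances quoted above hold comfortably. The generators
emulate exactly the model's assumptions — i.i.d. state draws, Gaussian
magnitudes and turns, noiseless centroids at uniform intervals. They do
not emulate segmentation jitter, tracking gaps, drift, cell–cell
interaction, or state dwell-time correlations; passing tests therefore
demonstrate correctness of the machinery under the model, not robustness
of the model on real microscopy data. Foci fixtures are disk masks with
flat-top blobs of known area, intensity and edge distance, so every
detection criterion can be violated singly by construction.

## Degenerate inputs and edge cases

Zero-length previous steps make the rotation frame undefined; such samples
are skipped and counted (threshold 10^-9 um) rather than erroring, since
stationary cells produce them. Non-uniform sampling intervals are an error
for fitting. Histograms refuse fewer than two finite values or zero range.
One-state models classify trivially with posterior 1. Log-space likelihood
evaluation keeps posteriors finite for displacements up to 10^6 um.

## Known limitations

The i.i.d. mixture ignores state persistence (no transition matrix, by
design); tracks are 2-D only; at most two states are fitted (the API
admits more, tests cover 1–2); SSE-based fitting is not a likelihood, so
the bootstrap threshold and profile intervals are calibration devices, not
formal confidence procedures; and for near-zero-mean states the angular
dispersion is only weakly identified even by the joint fit at ~10^5 steps
— the profile machinery makes this visible rather than hiding it.
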