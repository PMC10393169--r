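---
title: "Two-stage accumulation models of sensorimotor decisions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage accumulation models of sensorimotor decisions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

`litmodel` implements a two-stage accumulator of two-choice response times.
A primary stage accumulates sensory evidence as a constant-drift diffusion,

$$x_{k+1} = x_k + v\,\Delta t + \sigma^* \sqrt{\Delta t}\,\epsilon_k,
\qquad x_0 = a\,(z_r - \tfrac12),$$

with one drift $v_i$ per stimulus condition and the noise scale fixed at
$\sigma^* = 1$ for identifiability. A secondary, motor-related stage
re-integrates the accumulated evidence with an exponential leak,

$$\mathrm{d}y = \beta\,(x - y)\,\mathrm{d}t, \qquad \beta = \lambda,
\qquad y(0) = x_0,$$

and the response is triggered when $y$ — not $x$ — first reaches
$\pm a/2$. Solving the linear filter shows $y$ is the evidence convolved
with the kernel $\lambda e^{-\lambda \tau}$: a time-smoothed, lagged copy
of $x$ with memory $1/\lambda$ (the *inverse leak*, in seconds). Large
$\lambda$ removes the memory; `lam = Inf` is accepted as an exact
sentinel for the ordinary single-stage drift diffusion model (DDM). The
reported response time adds a non-decision time drawn from a Gaussian
truncated at zero with mean `Ter` and spread `nd_sd`. The convention
$\beta = \lambda$ removes the scale redundancy between the stages; the
convention "upper boundary = correct" maps stimulus categories onto
boundaries, and a category-to-hand map assigns the responding hand.

Simulation uses the Euler–Maruyama scheme at `dt = 1` ms by default.
Boundary crossings are detected on grid points with no sub-step
interpolation, consistent with that accuracy convention. Censored trials
(no crossing before `t_max`, or a response after the block deadline) are
retained as `choice = "none"` rows and excluded from fits downstream,
mirroring how too-slow trials are marked and discarded in the task this
package emulates. `motor_from_evidence()` integrates the same filter by
exact exponential stepping and serves as an independent check of the
Euler motor path (the two agree within $O(\Delta t)$).

# The effective single-stage approximation

The smoothed process $y$ behaves, over long stretches, like a diffusion
with the same long-run variance as $x$ but *smooth* sample paths. Mapping
the motor stage onto the classical weakly-colored-noise first-passage
problem (correlation-time parameter $\varepsilon = 1/\sqrt{\lambda}$,
mapped amplitude $\sigma = \sigma^*/\sqrt 2$) yields a boundary
inflation

$$a' = a + \frac{2\,|\zeta(1/2)|}{\sqrt 2}\,
\frac{\sigma^*}{\sqrt{\lambda}} = a + 2.0653\,\frac{\sigma^*}{\sqrt \lambda},$$

together with an apparent start shift $x_0' = x_0 + v/\lambda$ and an
apparent non-decision increase $T_{er}' = T_{er} + 3/(2\lambda)$.
`inflation_coefficient()` evaluates the constant from a Riemann-zeta
computation rather than storing it; `effective_params()` applies the full
mapping.

Two caveats, established by simulation during development and retained as
documented behavior:

* The three corrections are *alternative views of the same smoothing
  lag*, not additive pieces. At $v = 0$ the boundary inflation alone
  reproduces the LIT's mean first-passage lag (small-$\varepsilon$ scans:
  inflation-only matches within ~1.5 Monte-Carlo SE; adding $3/(2\lambda)$
  on top overshoots by more than 5 SE). The mapping is therefore best read
  as a *fitting family* — when $a$ and $T_{er}$ are free parameters the
  double counting is absorbed — and `reparam_fidelity_study()` reports how
  far the literal composition is from the simulated truth.
* The start shift $v/\lambda$ is only meaningful together with an equal
  shift of the boundary *center*; applied inside symmetric boundaries
  $\pm a'/2$ it distorts choice probabilities. The drift-ladder
  calibration of the prepaid grid consequently keeps the start at its
  physical position inside the inflated walls.

The distributional quality of the approximation degrades with
$\sqrt{\lambda^{-1}}$: at $\lambda^{-1} = 0.25$ s a Kolmogorov–Smirnov
distance of about 0.05–0.12 against the true two-stage simulation is
attainable at realistic boundaries, at $\lambda^{-1} = 1$ s it plateaus
around 0.15 under every composition we tried. The acceptance suite states
a stricter bound and is left failing by design rather than silently
weakened; the measured distances are in the acceptance report.

# First-passage densities and the combined urgency model

`grid_pdf()` solves the Fokker–Planck problem of the (possibly
collapsing-bound) one-dimensional diffusion with a Crank–Nicolson scheme:
the spatial domain is remapped onto the unit interval at every step, so a
linear collapse $a(t) = a - c\,t$ becomes an advection term; the first
steps are fully implicit (Rannacher startup) to damp the oscillatory
modes excited by the delta initial condition; absorbed-flux densities at
each wall come from second-order one-sided derivatives and are
renormalized against the interior mass (worst-case conservation error is
tracked and returned). Defaults: `dt = 2` ms, spatial resolution
`0.005 * a_eff`. Halving both changes the solution by less than 1 % in
sup norm; with collapse, all mass is absorbed before the bounds meet at
$a'(0)/c$.

The combined urgency-control family embeds three mechanisms in one
parameterization — drift per stimulus condition, relative start, inverse
leak (entering through the boundary inflation and start shift), basic
boundary separation, and collapse rate. Each variant lets exactly one of
{leak, bound, collapse} differ between speed and accuracy blocks, so all
variants have the same number of free parameters (9 with four stimulus
conditions) and their minimized objectives are directly comparable. The
non-decision component may differ between urgency conditions in *all*
variants — the leak variant implies it, and pinning it for the others
would bias the comparison.

# The fit criterion and estimation

`dstar_objective()` measures the distance between model and data as the
integrated squared difference between defective CDFs (upper and lower
boundary, all stimulus conditions), minimized over a single time shift
shared by every condition. The shift is scanned exhaustively over integer
grid steps, which makes invariance under a shared grid-aligned
translation *exact* (the acceptance suite checks $10^{-10}$), while a
shift applied to a single condition changes the objective. The shared
shift stands in for a non-decision component of unspecified shape common
to the conditions; the full nonparametric deconvolution of the criterion
this emulates is deliberately reduced to its translation component — the
invariance is the binding contract, and the reduction keeps the inner
loop of the optimizers cheap and exactly reproducible.

`time_scalar()` implements the spread-ratio estimator of the time scale:
the standard deviation of observed condition-mean RTs over that of the
model condition means on the unit scale. A non-decision component shared
across stimulus conditions cancels in the deviations, so the estimator
never sees it.

The prepaid estimator (`build_prepaid()`, `prepaid_fit()`) precomputes
unit-scale simulated first-passage distributions on a grid of relative
start ($z_r \in [0.1, 0.9]$, step 0.1) and inverse leak ($\lambda^{-1}
\in [0, 4]$, step 0.5, unit scale), with 100 drifts per node calibrated
by bisection of the effective-model absorption probability so the stored
accuracies span 0.001–0.999. Each node's drift ladder shares one random
stream (common random numbers), making stored accuracy monotone in the
drift index. Grid density is configurable; the default (9 × 9 × 100
distributions of 2000 trials at `dt = 2.5` ms, about five minutes to
build) was set by the recovery experiment below: with few hundred trials
per stored distribution, the *shared* ECDF noise of one database
realization can bias every fit along the leak-timescale ridge at once,
so the distributions are stored at a sample size where that shared noise
is well below the ridge's curvature.
Fitting matches drifts per condition by observed accuracy, estimates the
time scalar, *refines it over a small multiplicative grid* by the fit
criterion, and selects the node minimizing the criterion; the boundary
maps back as $a = \sqrt{s}$. The refinement exists because censoring of
slow conditions and drift-ladder edge saturation bias the raw spread
ratio, and an unmitigated bias lets a time-stretched zero-leak node
mimic a leaky node (the leak-versus-timescale degeneracy); the
shape-sensitive criterion resolves it once the scale is right. Speed and
accuracy blocks are always fitted independently.

`quantile_nll()` is the simulation-based alternative: per condition,
10 000 simulated trials define decile bins per choice with
defective-probability weighting, and the observed counts enter a
multinomial negative log-likelihood (floor probability $1/(2 n_{sim})$
for occupied empty bins; censored trials excluded; deterministic given
the seed). The two model configurations audited by `nll_model_config()`
carry 8 free parameters (DDM: four drifts, non-decision mean and spread,
one boundary per urgency condition) and 9 (LIT: four drifts, non-decision
mean and spread, one shared boundary, one leak per urgency condition);
`bic()` penalizes the extra parameter.

`fit_urgency_models()` minimizes the summed per-urgency criterion over
each variant's parameters with a small in-package bounded differential
evolution (rand/1/bin, reflecting bounds, fixed seed; no DE package is
assumed), helped by moment-style warm starts (boundary from mean decision
time, drifts from observed accuracies), a Nelder–Mead polish of the best
members, and a symmetric cross-variant pass in which every variant also
polishes from the other variants' optima translated into its own layout
(matching effective boundary separations), so no variant loses to a
single unlucky search. The inner shift scan uses a coarse-stride pass
with local refinement inside the optimizer only; the exported objective
keeps the exhaustive scan and its exact invariance. All remaining
randomness (init jitter, polish perturbations) runs under a stream
derived from the seed, so a fit is reproducible regardless of the
caller's RNG state. The default budget (population 27, 35 generations,
solver resolution `dt = 4` ms, 49 spatial nodes) holds one subject's
three fits to ~25 s; the comparison is relative across variants under
identical budgets, which is what the winner decision needs.

# Mechanism identifiability: what can and cannot be arbitrated

Within the one-stage effective family, the leak and bound variants span
*identical* sets of boundary-separation pairs once the per-urgency
non-decision component is free; the only leak-specific signature is the
condition-dependent start shift $v_c\,\lambda^{-1}_u$. Data simulated
from the true two-stage model do not carry that signature (the shift
cancels against a bound-center shift, see above), so two-stage-simulated
behavior cannot arbitrate the mechanisms through one-stage refits — at
the generating parameters the leak variant scores *worse* than a fitted
bound variant on such data. `mechanism_identifiability_study()` therefore
implements the standard model-recovery design: synthetic subjects are
generated from the combined family itself
(`generate_combined_behavior()`; leak mechanism: $\lambda^{-1}$ 0.3 s
speed vs 0.8 s accuracy with shared boundary; bound mechanism: boundary
0.15 vs 0.75 with shared leak; drifts 0.2–1.0 chosen to keep accuracies
in the 0.65–0.95 range and the start shifts inside the admissible
region), and the equal-parameter comparison is asked to recover the
generator. This reading is a deliberate design decision, documented here
because the alternative (generating from the two-stage model) is
provably uninformative for this comparison. Across seeds the 20-subject
leak win rate measures about 0.85–0.95; with twenty subjects that
estimate carries binomial noise of roughly ±0.08, so occasional dips
below any fixed threshold are expected sampling variation, much like the
winner rates real participant samples produce.

# Model-predicted signal-RT correlation curves

`response_locked_stack()` re-indexes each trial at its threshold
crossing; 100 000-trial ensembles use a memory-light stack assembled
inside the compiled simulator rather than full path matrices. Trials
shorter than an evaluated lag are dropped point-wise (ragged stacking).
`signal_rt_correlation()` computes, per response-locked time point, the
Pearson correlation across trials between the momentary signal value and
the final RT, optionally on the Fisher-z scale, then smooths with a 50-ms
moving average; `zero_crossing()` (latest positive-to-negative sign
change before the response, linearly interpolated) defines the *motor
lag*, and `peak_time()` the lag of maximum correlation. Measurement
noise of SD 0.015 is superimposed on the stacked signals before
correlating (`add_measurement_noise()`).

The reference simulation conditions ($v = 1.5$, $a = 1$, $z_r = 0.5$,
$x_0 = 0$, $\sigma^* = 1$, $\lambda^{-1} \in \{0.25, 0.5, 1\}$,
100 000 trials at 1 ms) are the package's own choice of a regime where
all qualitative signatures are well resolved; they are stated here once
and used by tests and the acceptance script alike. The signatures: the
single-stage evidence correlation stays non-negative and decays to zero
at the response; the two-stage evidence correlation switches sign and is
negative at the response, with a zero-crossing lag growing with
$\lambda^{-1}$; the motor correlation is zero at the response for every
leak, with its peak lag growing with $\lambda^{-1}$. "Never negative" is
asserted with a 0.02 floor: with $10^5$ trials the Monte-Carlo jitter of
a near-zero correlation is about $\pm 0.003$ per point before smoothing,
and the floor is three such standard errors below zero at the sparsest
evaluated lags.

# Synthetic EEG and the decoding pipeline

`generate_behavior()` simulates the full study layout (two urgency
blocks × four category-coherence cells × 160 trials/block, deadlines 1 s
and 1.6 s) and keeps the latent response-locked snippets as ground truth.
Defaults place the speed–accuracy trade-off in the motor leak
($\lambda^{-1}$ 0.30 vs 0.49 s — a 0.19 s block difference — with shared
boundary 0.5, drifts 0.55/1.1, non-decision 0.28 ± 0.05 s), calibrated
once to land near speeded-categorization benchmarks: mean RT 0.65 s
(speed) vs 0.83 s (accuracy), accuracy 0.76 vs 0.79, about 13 % deadline
misses.

`generate_eeg()` emulates the signal model the analyses assume: sensor
data are an evidence component — a centroparietal topography carrying
$|x(t)|$, the absolute deviation of the accumulator from its prestimulus
baseline, so both choice directions build up with the same sign — plus a
hand-specific frontocentral contralateral motor component carrying
$|y(t)|$, plus spatially correlated AR(1) Gaussian noise (random spatial
covariance with condition number 10, AR coefficient 0.5). The motor
amplitude is sign-folded because motor preparation builds *toward* the
threshold under the executed hand's topography on correct and error
trials alike; a signed convention would make error-trial motor activity
build negatively under the executing hand, which is physiologically
wrong and, in practice, lets small hand asymmetries in the decoded
evidence signal destabilize the weight regression. Planted topographies
are zero-mean over channels (so average referencing preserves them),
unit-norm, and deliberately disjoint between the evidence and motor
clusters so that ground-truth recovery is well defined. Component gains
(30 and 55 µV per evidence unit against 1.5 µV correlated noise) are set
for a moderately favorable single-trial SNR at which recovery is
decisive; real EEG is harsher, so passing these tests shows the pipeline
is correct, not that it would reach the same numbers on arbitrary
recordings. Epochs are locked at the threshold crossing (the small
motor-output delay between crossing and button press is not modeled).
`generate_blink_calibration()` and `tile_continuous()` provide
blink-rich calibration data and continuous recordings for the
preprocessing chain.

Preprocessing follows the minimal chain: zero-phase fourth-order
Butterworth band-pass 0.5–40 Hz (implemented as a high-pass/low-pass
cascade — a single band-pass section with a cutoff at 0.1 % of Nyquist
is numerically fragile), PCA blink removal using the leading calibration
component(s), average re-referencing, response-locked epoching.

Decoding (`sliding_discrimination()`) fits a Fisher discriminant on
50-ms window-averaged channel values every 25 ms from −575 to +175 ms,
with leave-one-trial-out Az (class statistics downdated per fold). The
pooled covariance is the *average* of the class covariances. Shrinkage
toward a scaled identity is configurable: the `"auto"` setting is a
Ledoit–Wolf estimate, which is the right default for ill-conditioned
covariances, but for *single-trial component extraction* the package's
recovery study fixes a strong intensity (0.7). The reason is worth
stating: at realistic trial counts the covariance is well estimated and
Ledoit–Wolf rightly barely shrinks, but the resulting whitened filter
suppresses exactly the high-variance direction the component lives in,
leaving projections nearly uncorrelated with the latent accumulator; a
heavily shrunk (matched-filter-like) discriminant trades a little Az for
a far more faithful time course. `forward_model()` converts any filter
into its topography ($a = X y / y^\top y$); `project_signal()` applies
the response-window filter at every time point and z-scores per
participant.

Motor extraction follows the model's defining relation — the momentary
slope of the motor accumulation is proportional to the momentary
evidence value. `slope_snapshots()` collects per-channel OLS slopes in
50-ms windows centered −150 to −50 ms before the response (high-evidence
trials only), paired with the window-averaged evidence signal;
`motor_weights()` solves the centered least-squares system through the
pseudoinverse. One disambiguation: the printed construction centers each
snapshot over sensors and the evidence over snapshots, but leaves the
channels' snapshot means in place, and solving that literal system
forces the aggregated slope's mean toward zero and visibly degrades the
fit; since the stated objective is a maximally *correlated* aggregated
slope — a location-free criterion — the package fits with an intercept
(each channel's snapshot mean removed as well). `motor_topography()`
correlates each channel with the extracted motor signal over a
−150…+50 ms window (at the crossing itself the motor state is pinned at
the threshold and has almost no across-trial variance to correlate), for
all trials and split by hand. The headline lateralization quantity is
the left-minus-right hand-map difference evaluated right-minus-left
hemisphere over the frontocentral strip: it cancels the evidence-coupled
activity common to both hands, which otherwise dominates single-subject
per-hand maps.

The end-to-end study (`eeg_recovery_study()`) checks, on one synthetic
participant at default settings: forward-topography recovery of the
planted evidence mixing (> 0.9 correlation); the two-peak discrimination
profile (an early Az elevation and a late one around the response,
separated by a dip where the low- and high-evidence traces cross — the
late elevation peaks at the analysis-window edge, so the structure is
quantified as early-max > mid-dip < late-max of the smoothed profile
rather than by interior local maxima); an earlier evidence-signal
zero crossing for the accuracy-like condition; near-zero motor
signal-RT correlation at the response; and positive contralateral
lateralization, with the weight estimation never seeing hand labels.

# Numerical and interface choices

* Times are seconds everywhere; response-locked `t = 0` is the crossing;
  windows are named by centers.
* All stochastic stages take explicit integer seeds; compiled simulations
  use per-trial counter-derived streams, so results are independent of
  trial order and bit-reproducible.
* Trial tables are plain CSV; epochs persist to a plain-text directory
  container (JSON header plus CSV tables) — lossless round trips without
  binary formats.
* `lit_cli()` exposes simulate / synth / predict-curves / fit-compare as
  a thin shell surface over the same functions, stamping seed and
  version into a JSON log next to each output.

# Problem sizes and limitations

The test and acceptance workloads are sized for a single CPU: 100 000
trials for distribution-level comparisons, a 9 × 9 × 100 prepaid grid,
20 replicates/subjects for recovery and identifiability, one synthetic
participant for the EEG pipeline. The generator emulates the *statistical
structure the analyses assume* — planted low-rank components in
stationary correlated noise — not volume conduction from a head model,
non-stationary artifacts, or inter-participant topography variability;
passing its tests validates the estimators' correctness, not their
robustness to everything real EEG contains. The effective-diffusion
approximation is asymptotic in $\sqrt{\lambda^{-1}}$ and visibly
imperfect at $\lambda^{-1} \ge 0.5$ s; model comparison results that
hinge on fine distributional differences at large inverse leak should be
interpreted with that in mind. Across-trial drift variability,
starting-point variability, multi-alternative races, other collapse
shapes, and drift-borne urgency signals are out of scope.
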