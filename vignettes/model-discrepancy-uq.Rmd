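---
title: "Quantifying predictive uncertainty from model discrepancy with an ensemble of voltage protocols"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying predictive uncertainty from model discrepancy with an ensemble of voltage protocols}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Mechanistic models of ionic currents are always simplifications of the
biology, so a fitted model never reproduces the true data-generating
process exactly — it is *discrepant* (misspecified).  Standard frequentist
and Bayesian machinery quantifies only the uncertainty that comes from
observation noise, and in the regime this package targets — long,
high-frequency current recordings — that uncertainty is minuscule.  The
result is familiar and dangerous: razor-sharp parameter estimates and
credible intervals around a model that is simply wrong, and whose
predictions for *new* experiments can be badly off with no warning.

The idea implemented here is to turn the choice of experiment into the
uncertainty probe.  An experimental design (in electrophysiology, a
voltage-clamp *protocol*) is a forcing function plus a set of observation
times.  Fitting the same model independently to data from several different
protocols yields an *ensemble* of parameter estimates.  If the model were
correct, all estimates would agree up to noise; under discrepancy each
protocol pulls the parameters to a different compromise.  For any unseen
validation protocol, simulating every ensemble member and taking the
pointwise envelope gives a *spread-of-prediction interval* whose width is
an empirical, assumption-light discrepancy signal, and whose midpoint
serves as a point prediction.

## Models and observation

Ionic currents are described by Markov-state models: linear ODE systems
over fractional state occupancies,

$$\frac{d\mathbf{x}}{dt} = A(V(t))\,\mathbf{x},$$

where the off-diagonal entries of $A$ are voltage-dependent transition
rates, each either constant or of the single-exponential form
$a\,e^{\pm bV}$ with $a, b \ge 0$, and the diagonal is fixed by the
requirement that columns sum to zero (conservation of the channel count,
so $\sum_i x_i \equiv 1$).  Current flows through one conducting (open)
state:

$$I = g \cdot [O](t) \cdot (V(t) - E_\mathrm{rev}),$$

with maximal conductance $g$ (µS) and reversal potential
$E_\mathrm{rev}$ (mV) from the Nernst equation.  Units throughout are
ms, mV, µS and nA, so no conversion factors appear anywhere.

Two literature hERG/IKr models are packaged with their published parameter
values (see the `provenance` field of each model object): a four-state
model (states C, O, I, IC; 8 kinetic parameters + $g$) and a five-state
linear chain (C1–C2–C3–O–I; 14 kinetic parameters + $g$, with one
voltage-independent step).  Both are declarative `markov_model()` objects
— a state list, a transition table and a parameter vector — so user-defined
structures inherit conservation, steady states and simulation for free.

On the reversal potential: the packaged ionic conditions fix
$E_\mathrm{rev} = -80.24$ mV with 120 mM internal and 5 mM external
potassium.  The recorded experimental temperature is 298 K, but
$-80.24$ mV is the Nernst value at 293 K ($-81.61$ mV at 298 K).  This
inconsistency is inherited from the source parameterisation; the package
keeps the fixed $-80.24$ mV default, records both numbers, and leaves
`nernst()` available — it does not silently "correct" either value.

## Protocols

A protocol is an ordered table of segments, each a constant step or a
linear ramp, within $[-120, 60]$ mV, preceded and followed by
equilibration at the holding potential ($-80$ mV).  Observations are taken
on the half-open grid $[0, t_\mathrm{dur})$ at `sample_rate` points per ms,
so the observation count is exactly `sample_rate * t_dur`.

The packaged suite contains six designs.  `d0-like` is a validation
protocol whose central portion is a train of action-potential-shaped ramp
waveforms — physiologically meaningful but numerically poorly identifying,
which is exactly why it is used for validation only.  `d1-like` …
`d5-like` are training protocols built from constant steps that explore
the full voltage range, with identical ramp-containing lead-in/lead-out
sections.  They are *stand-ins* that reproduce the published design class
(short, information-rich step/ramp protocols), not transcriptions of any
published protocol's exact segment table, which is not available in text
form.  The central portions were chosen so that, for the packaged
four-state model at the default noise level, each training protocol alone
constrains every parameter to a few percent (checked via the Fisher
information of the simulated experiment); a separate `recovery_protocol()`
pushes this below 2% for use as a sharp parameter-recovery control.

Two presets exist: `"desk"` (1 kHz sampling, 3 s per training protocol)
and `"full"` (10 kHz, durations scaled 4-fold, mirroring the scale of the
original study).  All experiment drivers and the shipped acceptance
checks run at desk scale; the full preset is provided for users with
hours, not minutes, of CPU budget.

## Simulation

Because the dynamics are linear in the states and protocols are piecewise
constant/linear in voltage, the default solver is not a general-purpose
integrator.  On constant-voltage steps the exact solution is a matrix
exponential, computed once per inter-observation interval and reused along
the segment; inside ramps a 4th-order Magnus integrator (two Gauss nodes
per step, default substep 0.5 ms) is used.  Both operations are
unconditionally stable, which matters during optimisation: arbitrarily
stiff parameter proposals cannot blow up the state, they just relax it
instantly.  Integration restarts at every segment boundary so voltage
discontinuities never fall inside a step.  The initial condition is always
the steady state at the holding potential, computed from the
conservation-reduced $(N-1)$-dimensional linear system with an SVD
nullspace fallback for ill-conditioned cases.

A conventional stiff-ODE path (`method = "lsoda"`, absolute and relative
tolerance $10^{-8}$, on the conservation-reduced system) is retained.  It
is slower by orders of magnitude but independent in both algorithm and
code, and the test suite requires the two paths to agree to $10^{-6}$ on
every packaged protocol; both are additionally checked against an
eigen-decomposition closed form on randomly generated small models.

Synthetic data add IID Gaussian noise of known standard deviation
($\sigma = 0.03$ nA by default) from R's seeded generator; every dataset
records its protocol, $\sigma$, seed and generating parameters, so any
run is reproducible bit-for-bit from its manifest.

What the generator deliberately does *not* emulate: patch-clamp artefacts
(series resistance, leak currents, capacitive spikes), temperature effects
on kinetics, single-channel stochasticity, and correlated or
heteroscedastic noise.  Passing tests therefore demonstrate the method's
behaviour under its own stated assumptions — an idealised whole-cell
recording — not robustness to real-data pathologies.

## Calibration

Fitting minimises the RMSE between simulation and data, which for known
$\sigma$ is exactly maximum likelihood under the Gaussian noise model.
The search works in transformed coordinates — log for rate scales and the
conductance, identity for voltage sensitivities — and is constrained by
the requirement that every transition's maximum rate over
$[-120, 60]$ mV lie in $[1.67 \times 10^{-5}, 10^3]$ ms$^{-1}$ (enforced by
rejection at initialisation and a graded additive penalty during search,
with negative parameters penalised more heavily than rate-bound
violations so the search is always pulled back towards feasibility).
Initial kinetic guesses are drawn with $\log_{10} p \sim U(-7, -1)$; the
conductance guess is the data-generating value in the synthetic studies.

The global optimiser is a compact CMA-ES (standard rank-one/rank-µ
covariance adaptation, population $4 + \lfloor 3\ln n\rfloor$), written
in-package, followed by a Levenberg–Marquardt polish of each restart and a
staged refinement of the winner that alternates a narrow CMA restart with
further polishing — weakly identified models produce long curved valleys
in which a single local polish stalls measurably short of the optimum.
Three engineering devices keep desk-scale fitting reliable and fast, and
all are pure optimisation heuristics that leave the estimator definition
unchanged:

* **Best-of-k seeding** — each restart draws 10 feasible guesses and
  starts from the best-scoring one.
* **Thinned search** — the global phase may evaluate the objective on
  every 3rd observation (`search_thin`); the final refinement and all
  reported RMSEs use the full grid.
* **Start sharing** — in ensemble training, each fitted member's estimate
  is offered as an extra warm start to subsequent members (and experiment
  drivers add a second pass that re-offers the best-converged estimate to
  every member).  Every member still minimises its own protocol's
  objective over the same multi-start scheme, applied identically to
  correct and discrepant models.

Ties across restarts break to the lowest index; restart counts default to
25 (primary) and 5 (continuation) and drop to 5/2 in the desk preset.
The stopping rule is a relative best-value change below $10^{-11}$ over a
30-generation window or a generation cap, recorded in the restart log.

The conductance-restricted variant pins $g = \lambda g^*$ and optimises
the kinetics only — the construction used to inject a controlled amount of
discrepancy, identical to a profile-likelihood computation in $g$.
`lambda_sweep()` fits $\lambda = 1$ first and continues outward in both
directions, warm-starting each fit from its neighbour and falling back on
the reference kinetics when those fit better.  The published $\lambda$
grid is $\{1/4, 1/2, 1, 2, 4\}$; the desk preset uses $\{1/4, 1, 4\}$.
A 17-point interpolation grid on $[1/4, 4]$ is provided log-spaced —
whether the original interpolation grid was linear or logarithmic is not
stated in the text, and log spacing treats the symmetric factors $1/4$
and $4$ symmetrically.

## Ensembles, bands and cross-validation

`train_ensemble()` fits one member per training protocol;
`predict_ensemble()` simulates every member (noise-free) on a validation
protocol and returns the pointwise min/max envelope with midpoint
$(\mathcal{B}_\mathrm{lower} + \mathcal{B}_\mathrm{upper})/2$ — the
midpoint of the envelope, not the mean of the members.  The envelope
cannot shrink as members are added, is invariant to member order, and a
percentile variant is available for users with many protocols (min/max is
the definition used everywhere by default, appropriate for the five
training protocols considered here).  `crossval()` computes the
training-by-validation RMSE matrix, optionally averaged over noise-seed
replicates; `band_coverage()` compares the envelope against the noise-free
truth, which is available because the data are synthetic.  The band is a
heuristic range of plausible predictions, not a calibrated interval:
under structural discrepancy the truth frequently falls outside it, and
the case-study checks assert exactly that (coverage strictly between 0
and 1).

## The two case studies

**Case I (misspecified conductance).**  Data are generated from the
four-state model; the same model is refitted with $g$ pinned to
$\lambda g^*$.  At $\lambda = 1$ this is a correctly specified control:
estimates cluster at the truth, every cross-validation entry sits at the
noise floor $\sigma$, and the validation band is far narrower than
$\sigma$.  Away from $\lambda = 1$ the kinetics compensate differently on
each training protocol; validation bands widen dramatically and
asymmetrically ($\lambda < 1$ hurts more than $\lambda > 1$), and the
mean validation RMSE as a function of $\lambda$ is minimised at 1.

**Case II (misspecified structure).**  Data are generated from the
five-state model; both models are fitted with free conductance.  The
correctly specified fits recover $g$ from every protocol to well within
one percent, whereas the four-state fits show protocol dependence in
$\hat g$ an order of magnitude beyond the noise-repeat spread — the
fingerprint of discrepancy in the high-data limit.  The four-state band
on the validation protocol is wider at its widest point than the
five-state band, concentrated at the current spikes where the structures
differ (the five-state chain forces inactivated channels to pass through
the open state when recovering at negative voltages).

Desk-scale problem sizes, stated once as the package's study conditions:
3 s training protocols at 1 kHz ($n_d = 3000$ per protocol), $\sigma =
0.03$ nA, 2 noise repeats, 5 primary / 2 continuation restarts (Case II
members get the second warm-start pass described above).  At this scale
the five-state kinetics are individually only weakly identified
(relative standard errors of tens of percent) even though $g$ is pinned
down to ~0.5%; this is why convergence heuristics matter and why the
correct-model band, while much narrower than the discrepant one, is not
as vanishingly narrow as in a full-scale run.

## The two-exponential toy example

The motivating example is self-contained: the truth is
$y^*(t) = e^{-t} + e^{-t/10}$ with Gaussian noise of variance $10^{-4}$,
and the fitted model a single exponential $\theta_1 e^{-t/\theta_2}$ with
uniform $(0, 10)$ priors.  Ten observation-time designs are encoded
(short-time, medium, shifted, long-time windows, their union, and dense
primed counterparts).  Two typographical ambiguities in the printed design
sets are encoded explicitly rather than guessed away: the first design's
endpoint is read as 0.1 (the only reading giving 11 equally spaced points
consistent with its dense counterpart), and the dense union defaults to
the union of the dense sets with the literal union-of-coarse reading
available via `tall_literal = TRUE`.  The printed likelihood omits the
minus sign in the Gaussian exponent; the standard (negative) form is
implemented.

Least-squares fits use a deterministic multi-start bounded quasi-Newton
search with an LM polish, validated in the tests against a brute-force
500×500 lattice (value-based comparison, since the SSE valley is flat in
$\theta_2$ for short-time designs).  Posteriors use Haario-type
adaptive-covariance Metropolis (proposal covariance $2.38^2/d$ times the
running sample covariance) with 4 chains; the published 25,000-iteration
runs are reduced to 5,000 iterations with 1,000 burn-in in the shipped
checks, which is ample for a 2-parameter Gaussian-like posterior, and a
split-chain $\hat R$ diagnostic flags non-convergence above 1.05.
Credible-region disjointness between the short-time and long-time dense
designs is assessed via within-sample Mahalanobis quantiles at the 99%
level.

## Numerical choices and degenerate inputs

* Steady states: direct solve of the reduced system; SVD nullspace
  fallback; occupancies clamped to $[0,1]$ and renormalised.
* Matrix exponentials: scaling-and-squaring Taylor evaluation specialised
  to the stack-allocated ≤6×6 matrices of the hot path.
* Non-integer observation counts (duration not a multiple of the sampling
  interval) truncate with a warning.
* A one-state model is a valid degenerate input (occupancy constant at 1).
* Disconnected transition graphs are rejected at construction, since the
  conservative steady state is then non-unique.
* Proposals with non-finite simulated currents score a large finite
  penalty rather than erroring, so a stochastic search can recover.
* All randomness (data noise, optimiser, MCMC) derives from per-component
  seeds below $2^{31}$, recorded in results and manifests.

## Known limitations

The desk preset trades statistical sharpness for runtime; full-scale runs
tighten every spread roughly as $\sqrt{n}$.  The packaged protocols are
design-class stand-ins, so numeric results are not comparable
trace-for-trace with any published figure.  The optimiser is a compact
CMA-ES, not a tuned reference implementation; the staged refinement makes
desk-scale fits reliable, but the five-state model's kinetic parameters
remain only weakly identified at 3 s / 1 kHz and individual kinetic
estimates (unlike $g$ or predictions) should not be over-interpreted at
this scale.  Noise is IID Gaussian with known $\sigma$ throughout;
estimating $\sigma$, correlated noise, and experimental artefacts are out
of scope, as are drug-block and temperature-dependent kinetics.
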