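---
title: "Estimating muscle activations under the redundancy problem: SO, SynO and SO-NMF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating muscle activations under the redundancy problem: SO, SynO and SO-NMF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 4)
library(synact)
library(dplyr)
```

## The problem

During gait, each lower-limb degree of freedom (DOF) is crossed by many
more muscles than there are DOFs: the net joint moments recovered by
inverse dynamics do not determine individual muscle forces. `synact`
implements and compares three standard resolutions of this redundancy
for a trial described by inverse-dynamics joint moments $Q^{ID}$
($f$ frames $\times$ $d$ DOFs), a signed moment-arm tensor $J$
($f \times d \times m$ muscles), and musculotendon lengths and
velocities ($f \times m$):

* **SO (static optimization)** — frame by frame, minimize
  $\sum_i a_i^2$ subject to the muscle-produced moments *exactly*
  reproducing $Q^{ID}$ and $0 \le a \le 1$.
* **SynO (synergy optimization)** — optimize over all frames at once,
  with activations constrained to a low-dimensional synergy product
  $a_{f\times m} = C_{f \times n_s} V_{n_s \times m}$, where each
  column of $C$ is a B-spline and each row of $V$ sums to one;
  moment tracking enters the cost as a weighted penalty rather than a
  hard constraint.
* **SO-NMF** — factorize the SO solution with a non-negative matrix
  factorization whose synergy vectors are L1-normalized, reconstruct
  activations from the synergies, and push them back through the
  muscle model.

The well-known contrast these methods expose: SO tracks moments
perfectly but produces activations with no imposed temporal structure;
SynO trades a small tracking error for an explicit synergy structure;
SO-NMF inherits SO's activations in a compressed form whose
reconstruction no longer satisfies the moment constraints, so its
implied moments can deviate badly at low synergy counts.

## Muscle model

Muscles are modeled as rigid-tendon Hill-type actuators. With the
tendon fixed at its slack length $l^{ts}$, the fiber state follows
algebraically from musculotendon kinematics: along-tendon projection
$l^{MT} - l^{ts}$, constant-thickness pennation
($h = l_0 \sin\alpha_0$), fiber length
$\sqrt{(l^{MT}-l^{ts})^2 + h^2}$, and fiber velocity
$v^{MT}\cos\alpha$. Force is

$$F = F^{max}\,\bigl(a\, f_L(\tilde l)\, f_V(\tilde v) +
f_{PE}(\tilde l)\bigr)\cos\alpha,$$

which is *affine in activation* for fixed kinematics. This is not an
approximation but a structural property of the rigid-tendon model, and
the package exploits it throughout: per frame the moment constraints
are linear in $a$, SO becomes a strictly convex quadratic program, and
the SynO objective has a closed-form gradient. No separate "general
nonlinear path" exists to solve because no rigid-tendon instance needs
one.

The normalized curves are pluggable (`hill_curves()`): defaults are a
Gaussian active force-length ($f_L(1)=1$, width 0.45), a logistic
force-velocity with $f_V(0)=1$, an eccentric plateau at 1.5 and
near-zero force at the maximum shortening velocity, and a $C^1$
quadratic passive curve that engages above optimal length. The exact
shapes are deliberately replaceable — `unit_hill_curves()` reduces the
model to $F = F^{max} a \cos\alpha$, which is what every closed-form
test oracle uses. Passive force defaults to enabled and can be switched
off per muscle (`passive_enabled`).

## Static optimization

Each frame solves

$$\min_a \sum_i a_i^2 \quad \text{s.t.} \quad M a = c, \;\; 0 \le a
\le 1,$$

with $M$ the moment-arm-weighted activation gains and $c$ the demand
left after passive moments. The solver maximizes the smooth concave
dual over the $d$ equality multipliers $\lambda$ (the primal map is
$a(\lambda) = \mathrm{clip}(M^\top\lambda/2, 0, 1)$), then polishes
with an exact active-set KKT solve, driving the residual far below the
default tolerance of $10^{-6}$ relative to each DOF's peak moment. A
frame whose demand exceeds the muscles' moment capacity raises an
infeasibility error reporting the best residual; an optional
reserve-actuator mode replaces the hard constraints by a quadratic
residual penalty instead. The first frame takes the best of five seeded
random starts (the problem is convex, so these agree; the multi-start
mirrors standard practice and is kept for interface parity), and every
later frame warm-starts from its predecessor, which is why a full
43-muscle, 101-frame trial solves in well under a second.

Because the constraints are enforced exactly, the muscle-produced
moments reproduce $Q^{ID}$ to solver tolerance and the per-DOF VAF,

$$\mathrm{VAF} = 100\Bigl(1 - \tfrac{\sum (q^{ref}-q^{est})^2}
{\sum (q^{ref})^2}\Bigr),$$

prints as 100.00 on any feasible trial. The uncentered VAF definition
above is the one standard in the synergy literature; a mean-centered
variant is available via `centered = TRUE`.

## Synergy optimization

Each of the $n_s$ synergies contributes a B-spline-parameterized time
course and an $m$-vector of weights. The node count follows the
one-node-per-5%-of-cycle rule $p = (f-1)/5 + 1$, rounded half-up
(`node_count()`); the spline is cubic on a clamped uniform knot vector
(degree reduced automatically when a short trial cannot support a
cubic). The knot layout and degree are design choices of this package:
smoothness comparable to gait activations with the prescribed number
of free nodes.

The cost (`syno_cost()`) is

$$J = \sum_{j=1}^{f}\Bigl(\beta \sum_{k=1}^{d}
\Bigl[\tfrac{Q^{MT}_{jk}-Q^{ID}_{jk}}{\max_t |Q^{ID}_k|}\Bigr]^2 +
\sum_{i=1}^{m}\bigl(a_{ij}^2 +
\lambda_{pen}\,(a_{ij}-1)^2\,\mathbf 1\{a_{ij}\notin[0,1]\}\bigr)\Bigr)$$

with $\beta = 100$ weighting tracking against effort and
$\lambda_{pen} = 10^5$ penalizing activations above one (activations
are non-negative by construction, so only the upper bound is active;
the penalty is $C^1$ at the boundary). The per-DOF normalizer is the
peak absolute inverse-dynamics moment over the whole trial; an
identically-zero DOF falls back to a unit normalizer with a warning.

The design vector has $n_s(p + m)$ entries: the non-negative spline
nodes and unnormalized synergy weights. Row weights are kept on the
sum-to-one simplex by normalizing inside the objective
($v = u / \sum u$), so the equality constraint is satisfied exactly at
every iterate while the solver — L-BFGS-B with the analytic gradient —
sees only box constraints. Multi-start policy: one data-driven start
(NMF of the SO solution, with spline nodes least-squares fitted to the
NMF time courses) plus seeded random starts (flat-Dirichlet rows,
uniform nodes), five in total by default. When sweeping synergy counts,
`run_full_comparison()` additionally passes the previous count's best
solution padded with an inactive synergy (zero nodes, uniform weights)
as an extra start; since L-BFGS-B never returns a value above its
starting point, the best cost is non-increasing in $n_s$ by
construction — the nested-model property the sweep is meant to
exhibit. A genetic-algorithm initializer would serve the same purpose
as these seeded starts; it adds nothing on the synthetic trials and is
not included.

## SO-NMF

`fit_nmf_l1()` is a multiplicative-update Frobenius NMF with one
modification: after each iteration every row of $W$ is rescaled to sum
to one and the scale absorbed into the matching column of $H$. The
rescaling is cost-neutral (it reparameterizes the same product), so
the monotone-descent property of multiplicative updates is preserved
while the factorization carries the same sum-to-one constraint SynO
imposes — making $W$ directly comparable to $V$. "Unit norm" here
means the L1 norm; an L2 interpretation would break that comparability
and is not used. Convergence is declared when the relative Frobenius
error change drops below $10^{-6}$ (500 iterations cap); the best of
10 seeded restarts is kept. Reconstructed activations $a^* = HW$ are
pushed back through the muscle model (`reconstructed_moments()`); the
resulting moments satisfy no constraint, which is exactly why their
VAF degrades at low $n$ — the package's analogue of the finding that
synergy-compressed SO solutions track moments poorly.

## Synthetic trials and what they do (and do not) show

No subject data ships with the package; the generator builds trials
with known ground truth instead.

* `generate_plant()` — moment arms are low-order (≤ 4 harmonics)
  Fourier series in gait-cycle phase, each muscle spanning 1–3 DOFs
  with a fixed sign and magnitudes bounded by 0.08 m (physiological
  moment arms are a few centimeters; the study's own magnitudes are
  not published, so the bound is a choice, not a fit). The first $2d$
  muscles deterministically give every DOF an agonist and an
  antagonist so both moment directions are actuatable. Musculotendon
  lengths are periodic harmonics around rest lengths of 0.2–0.5 m with
  ±5% excursion; velocities are the exact analytic derivative.
* `synthetic_muscle_params()` — Hill constants sized from the plant:
  $F^{max} \in [300, 3000]$ N, pennation up to 0.25 rad, optimal fiber
  length scaled to each muscle's excursion so normalized fiber length
  stays near 1 (the force-length curve's operating region in walking).
* `generate_ground_truth()` — synergy time courses are Gaussian bursts
  in cycle phase (burst-like recruitment as reported for gait), synergy
  vectors are flat-Dirichlet rows summing to one, and the product is
  scaled to a peak activation of 0.8 so the truth is strictly feasible.
* `forward_consistent_trial()` — $Q^{ID}$ is *computed from* the
  ground-truth activations through the same muscle model, so a
  feasible SO solution exists by construction and synergy recovery has
  a defined answer.
* `synthesize_emg()` — channels are delayed, crosstalk-mixed, rectified
  images of true activations with additive Gaussian noise on the
  envelope. Raw interference-pattern EMG is deliberately not modeled:
  the pipeline consumes envelopes, and envelope-level noise is the
  disturbance that matters to it.

Defaults ($m = 43$, $d = 6$, $f = 101$, $dt = 0.01$ s) mirror a
100 Hz, one-gait-cycle, 43-muscle lower-limb analysis.

What passing tests show: the estimators behave correctly on trials
satisfying their assumptions — exact moment reproduction for SO,
recovery of planted synergy structure for SynO, monotone
reconstruction quality for SO-NMF. What they do not show: robustness
to modeling error in moment arms or Hill constants, to inverse-dynamics
moments that no bounded activation can reproduce (real gait labs meet
these daily), or to EMG whose envelope is not an image of any model
muscle's activation. On real data SO feasibility must be earned with
reserve actuators (`so_config(reserve_weight = )`), and synergy
recovery has no ground truth to recover.

## EMG processing

Envelopes are rectified, zero-phase low-pass filtered, clipped and
max-normalized per channel over the record (`process_emg()`). The
Butterworth path (5th order, 15 Hz, forward-reverse so the effective
attenuation doubles and no phase lag is introduced) is the default and
is exactly specified; the filter is applied with odd-reflection padding
and level-shifted passes, without which forward-reverse filtering
leaves large edge transients. The SSA alternative embeds at window 250
and keeps dominant SVD components; components are selected by a
per-component energy floor (≥ 1% of the leading component) rather than
a cumulative-energy target, because broadband noise spreads its energy
across many small components — a cumulative rule keeps adding them
until the target is met and reconstructs the noise, while the
per-component rule rejects them. Max-normalization is per record; with
single-cycle trials the distinction from per-cycle maxima is empty.

Comparisons against activations use the maximum *signed* Pearson
correlation over integer-sample lags within ±100 ms
(`lagged_pearson()`), ties broken toward the smallest absolute lag —
maximizing over lags absorbs electromechanical delay, and the signed
maximum (not $|r|$) is used because an anti-correlated envelope should
score poorly, not well.

## Numerical choices

* SO constraint tolerance: $10^{-6}$ relative to each DOF's peak
  $|Q^{ID}|$; dual BFGS capped at 500 iterations with an exact KKT
  polish (≤ 50 active-set iterations).
* SynO: L-BFGS-B, `factr = 1e5`, 2000 iterations cap per start;
  unnormalized weights bounded below by $10^{-9}$ to keep the simplex
  normalization well-defined.
* NMF: $10^{-12}$ additive guards in the multiplicative updates; dead
  (zero-sum) rows of $W$ fall back to uniform weights with their $H$
  column zeroed.
* Degenerate inputs: $l^{MT} \le l^{ts}$ raises a geometry error
  naming muscle and frame; all-zero EMG channels are returned as zeros
  and flagged; an all-zero reference DOF makes VAF an error and the
  SynO normalizer fall back to 1 with a warning.
* Trial I/O is a CSV bundle (wide files per matrix, long
  `frame,dof,muscle,value` for the moment-arm tensor, JSON metadata)
  written at 17 significant digits and parsed with correctly-rounded
  conversion, so write/read round-trips are bit-exact.

## A worked example

```{r example, eval = FALSE}
run <- run_full_comparison(m = 12, d = 6, f = 51, n_true = 3,
                           n_s = 2:6, seed = 1)
run$report$moment_vaf |>
  group_by(method, n_s) |>
  summarise(vaf = mean(vaf), .groups = "drop")
autoplot(run$report)
```

On this trial (sizes chosen so the sweep completes in about half a
minute) SO sits at VAF 100.00; SynO climbs from the mid-90s at
$n_s = 2$ towards SO as synergies are added; SO-NMF starts far lower
and improves with $n$, its activation similarity to SO rising
steadily — the three qualitative signatures that motivate comparing
the approaches in the first place. The same sweep at full scale
($m = 43$, $f = 101$) behaves identically but takes correspondingly
longer.

## Limitations

* Everything upstream of the trial container — motion capture, marker
  processing, whole-body inverse dynamics, model scaling — is out of
  scope; `trial_data` is the entry point.
* Activation dynamics (excitation-to-activation filtering) and
  compliant tendons are not modeled; for walking-speed kinematics the
  rigid-tendon model is the accepted approximation.
* SynO's landscape is non-convex; the multi-start policy makes the
  sweep reproducible and monotone but cannot certify global optimality.
* The synthetic generator's realism is structural (smoothness,
  periodicity, sign patterns, feasibility), not anthropometric; its
  moment-arm magnitudes and Hill constants are plausible, not fitted.
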