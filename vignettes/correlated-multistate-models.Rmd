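---
title: "Correlated multistate models with shared gamma frailties"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlated multistate models with shared gamma frailties}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmsm)
```

## The model

cmsm models two (or more) reversible disease processes per subject — the
motivating application is kidney function (eGFR category) and proteinuria
(PU category) in lupus nephritis, each classified into three ordered severity
states — as continuous-time, time-homogeneous Markov chains observed only at
clinic visits (panel data). Movement of process $j$ is governed by a
generator matrix whose off-diagonal entries are transition intensities
$q^{(j)}_{rs}$, nonzero only for the allowed moves; in the kidney application
only adjacent moves $1\leftrightarrow 2 \leftrightarrow 3$ are permitted.
Over an interval of length $\Delta t$ the transition-probability matrix is
the matrix exponential $P(\Delta t) = \exp(Q\,\Delta t)$.

Two processes measured on the same subject are rarely independent: both
reflect the same underlying organ function, and a plain Markov model also
understates within-subject serial dependence. Both are addressed with one
subject-level random effect (frailty) $U_i > 0$, distributed
$\Gamma(1/\theta,\,1/\theta)$ so that $E(U_i)=1$ and
$\mathrm{Var}(U_i)=\theta$, acting multiplicatively on the intensities
through a link $g^{(j)}_{rs}(u)$:

* **none** — $g \equiv 1$: two independent Markov chains;
* **simple** — $g \equiv u$ on every transition of both processes: fast
  movers move fast in both directions;
* **inverse** — $g = u$ on worsening and $g = 1/u$ on improving transitions:
  subjects who deteriorate quickly also recover slowly;
* **power_inverse** — as inverse for process 1 and $u^{\alpha}$ /
  $u^{-\alpha}$ for process 2, letting the shared effect act with different
  log-scale variability on the second process ($\alpha = 1$ recovers the
  inverse link exactly);
* **separate** — an independent inverse-type frailty per process; the
  likelihood then factorises over processes, which the implementation
  exploits so no bivariate integral is ever needed.

Every link satisfies $g(1) = 1$: a subject with frailty 1 is the typical
subject with the baseline intensities. Covariates enter log-linearly per
transition, $q_{rs}(x) = q_{rs}\exp(\beta_{rs}^\top x)$, with values treated
as piecewise-constant over an observation interval at their left-endpoint
value — the standard panel-data convention.

Conditional on $u_i$, subject $i$'s likelihood is the product over processes
and consecutive visits of interval transition probabilities; the marginal
contribution integrates this against the gamma density, and subjects are
independent:

$$L_i(\phi,\theta) = \int_0^\infty \prod_j \prod_k
  P^{(j)}\!\left[x_{ik} \to x_{i,k+1};\, \Delta t_{ik} \mid u\right]
  f(u;\theta)\, du .$$

No closed form exists for this integral in reversible models, so it is
evaluated numerically (below).

## Numerical choices

**Matrix exponential.** An eigendecomposition fast path evaluates
$\exp(Q\,\Delta t)$ for all interval lengths at once; the decomposition is
accepted only if it reconstructs $Q$ to $10^{-9}$ relative and the resulting
rows are stochastic to $10^{-8}$, otherwise the code falls back to Padé
scaling-and-squaring per interval. Probabilities are clamped to $[0,1]$ and
floored at $10^{-300}$ before logging so a stray underflow cannot poison the
frailty integral.

**Frailty integral.** After the substitution $v = e^{-u}$ the integral lives
on $(0,1]$. Two engines are exposed through `quad_control()`: adaptive
quadrature (`stats::integrate`, default tolerances $10^{-7}$ relative /
$10^{-9}$ absolute) with a per-subject scaling constant taken from the
maximum conditional likelihood on a coarse frailty grid, and a deterministic
96-point Gauss–Legendre rule. Both integrate over the gamma distribution's
$[10^{-12}, 1-10^{-12}]$ quantile range rather than all of $(0,1]$: this
keeps either rule accurate when $\theta$ is tiny and the prior collapses
towards a point mass at 1 (the no-frailty limit), a region optimisers do
visit. The fixed rule is the default inside `cmsm_fit()` because it makes
the objective a smooth deterministic function of the parameters; the
adaptive rule is the default for one-off evaluations and empirical Bayes
estimates. For the separate-frailty link the integral is one per process.

**Optimisation.** `cmsm_fit()` maximises with BFGS on a working scale — log
for intensities and $\theta$ (positivity), identity for $\alpha$ and
covariate effects. This convention is what makes the reported intervals
asymmetric for intensities and variances but symmetric for $\alpha$.
Standard errors come from a central finite-difference Hessian with relative
step $10^{-4}$ on the working scale. Default starting values are crude
occurrence/exposure rates (transition counts over person-time at risk,
floored at 0.01/year), $\theta_0 = 0.5$, $\alpha_0 = 1$, zero covariate
effects. Degenerate parameter points (non-finite likelihood) are handled by
returning a large penalty so line searches back off.

**Occupancy times.** The expected years in state $r$ over $[0, h]$ starting
in $r_1$ is $\int_0^h P[r_1 \to r](t)\,dt$. The time integral uses a fixed
Gauss–Legendre rule (default 96 nodes) rather than an adaptive scheme: the
integrand is an entry of a matrix exponential — smooth, non-oscillatory —
so the fixed rule is accurate to well below $10^{-8}$ over a 5-year horizon,
conserves the row-sum identity $\sum_r \text{occ}(r) = h$ essentially
exactly, and makes the frailty-averaged double integral deterministic. The
frailty average reuses the same gamma quadrature as the likelihood (Fubini:
the $u$- and $t$-integrals commute), with weights normalised to unit prior
mass. Joint-state occupancy multiplies the two processes' conditional
transition probabilities inside the integrals — under the shared-frailty
model conditional on one $u$, under the no-frailty model unconditionally.
A Monte Carlo mode (`mode = "mc"`) instead averages conditional occupancy
over gamma draws; with 2000 draws it agrees with quadrature to a few
hundredths of a year and is mainly useful as a cross-check. Occupancy under
dynamic covariates is refused — expected sojourns are not well defined when
the intensity depends on a covariate whose own future path is random —
unless fixed covariate values are supplied.

## What the simulator emulates

`cmsm_sim_config()` defaults describe a lupus-nephritis-like inception
cohort: 568 subjects; between-visit gaps truncated-normal with mean 1.2 and
SD 0.55 years, floored at 0.1 (approximately annual visits); follow-up
duration normal with mean 5.2 and SD 3.1 years, floored at two mean gaps;
initial-state frequencies 504/58/6 (kidney function) and 244/239/85
(proteinuria); true intensities from the fitted shared inverse-frailty model
with $\theta = 0.549$. The truncated normal is a modelling choice — only the
gap moments are reported for the real cohort, and the truncated normal
reproduces them simply. Trajectories are simulated exactly (Gillespie:
exponential holding times, embedded jump chain) given each subject's frailty
and read off at the visit times with the right-continuous convention.
Per-subject random substreams are derived from the master seed, so cohorts
are bit-reproducible.

What the generator does **not** emulate: informative visit schedules or
dropout, death or other absorbing states, misclassification of the recorded
state, covariate processes, and time-inhomogeneous intensities. Passing
parameter-recovery tests on these cohorts therefore demonstrates the
estimator's correctness under the model's own assumptions, not robustness
to their violation in real registry data.

## Design decisions taken where the design was open

* **Direction labels are part of the specification.** Which transitions
  count as "worsening" is declared in `cmsm_spec()`, defaulting to
  $r \to r+1$, rather than inferred from state labels — so non-birth–death
  structures remain expressible and the inverse-type links stay meaningful.
* **$\alpha$ is unconstrained on the real line**, and $\theta$ is positive
  by construction (log working scale); no boundary handling is needed.
* **Interval bridging for missing states.** A visit at which one process's
  state is missing is skipped in that process's interval chain only; the
  other process is untouched. On complete data this is a no-op.
* **Single-visit subjects are retained** with likelihood contribution 0 and
  a warning, rather than dropped, so cohort bookkeeping stays intact.
* **`tie_theta`** constrains the two variances of the separate-frailty model
  to be equal, giving the natural nested pair for a likelihood-ratio test of
  equal heterogeneity across processes (1 df).
* **Wald intervals** are computed on the working scale and transformed. The
  published intervals' shapes (asymmetric for intensities and variances,
  symmetric for the power exponent) identify exactly this construction, but
  the original report does not state it; the convention is recorded here and
  in `?cmsm_confint`.

## Problem sizes used in the test suite

The package's tests run complete simulation studies at desk scale, chosen so
the whole suite stays fast while the binomial acceptance bands remain sharp
enough to detect real miscalibration: parameter recovery uses 600 subjects
with eleven annual visits; interval-coverage checks use 20 replicates of an
80-subject cohort (exact-binomial band around 95%); the equal-variance
likelihood-ratio test's size is checked with 12 replicates of a 60-subject
cohort; oracle-agreement checks compare against 20 000-point trapezoid
integration and uniformization-based matrix exponentials on small fixtures.
Published occupancy tables are reproduced from the published (3-decimal)
intensity estimates, so agreement is asserted to one unit in the last
printed digit; the third decimal of the underlying integrals depends on
quadrature tolerances that the original analysis does not report.

## Known limitations

* One shared frailty per subject (or one per process): general multivariate
  frailty distributions would need higher-dimensional quadrature.
* Time-homogeneous baselines only; no phase-type sojourns and no
  hidden-state misclassification layer.
* Expected first-passage times, visit counts and mean sojourn times are out
  of scope.
* Fitting cost grows linearly in quadrature nodes and parameter count;
  models with many covariate effects are markedly slower, as in any
  nonlinear random-effects model.
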