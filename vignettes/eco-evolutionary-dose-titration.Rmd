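---
title: "Eco-evolutionary tumor dynamics and dose titration with evotitrate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eco-evolutionary tumor dynamics and dose titration with evotitrate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evotitrate)
library(dplyr)
```

## The model

Metastatic castrate-resistant prostate cancer under abiraterone is treated
here as an ecological competition between three tumor-cell types: `T+`
cells that need exogenous testosterone, `TP` cells that express CYP17α and
produce testosterone as a public good, and `T-` cells that are
androgen-independent and hence resistant to the drug. Densities
$x_i$ follow Lotka–Volterra competition dynamics

$$\dot x_i = r_i x_i \left(1 - \frac{\sum_j \alpha_{ij} x_j}{K_i}\right),$$

with growth rates $r_i$ derived from cell-line doubling times (60, 48 and
25 hours for `T+`, `TP`, `T-`), converted to per-day rates and scaled by
$10^{-2}$ to tumor-realistic values $(2.7726, 3.4657, 6.6542)\times
10^{-3}$ per model time unit. Growth rates set the tempo only; equilibrium
compositions are governed by the competition matrix and the carrying
capacities.

The abiraterone dose $\Lambda(t) \in [0, 1]$ (0 = no drug, 1 = maximum
tolerated dose) acts through two affine laws:

* $K_{TP}(\Lambda) = 10000 - 9900\,\Lambda$ — the producer carrying
  capacity collapses from 10000 to 100 at full dose;
* $\mu(\Lambda) = 1.5 - \Lambda$ — the symbiosis coefficient, the per-cell
  contribution of producers to the `T+` carrying capacity
  $K_{T+} = \mu(\Lambda)\, x_{TP}$.

$K_{T-} = 10000$ is dose-independent: the resistant type cannot be touched
by the drug, only competed against. Patient death is modeled as the total
burden exceeding the viability cap of 9000 cells; because the drug-free
capacities reach 10000–15000, an untreated tumor always kills.

The competition matrix has unit diagonal and off-diagonals
$(\alpha_{12}, \alpha_{13}, \alpha_{21}, \alpha_{23}, \alpha_{31},
\alpha_{32}) = (0.7, 0.8, 0.4, 0.6, 0.5, 2)$. The key choice is
$\alpha_{32} = 2$: producers must suppress the resistant type strongly
enough that stable equilibria below the viability cap exist at all, yet
weakly enough that `T-` persists in some of them. Any other matrix can be
supplied through `lv_params()` (or a YAML/JSON file via
`read_lv_params()`), which is also how the classical
$\alpha_{32} \in [0, 1]$ variant or stronger suppression scenarios are
explored; no other code changes are needed.

### Regularization choices

Because $K_{T+} = \mu x_{TP}$ vanishes with the producers, the `T+`
bracket is undefined at $x_{TP} = 0$. The field is regularized with
$K_{T+} = \mu \max(x_{TP}, \varepsilon)$, $\varepsilon = 10^{-6}$ cells
(`tp_floor`). This keeps the ODE well-posed while preserving the biology:
with no producers, $K_{T+}$ is microscopic and `T+` collapses at rate
$\approx -r_1 x_{T+}^2/(\mu\varepsilon)$. The same regularized field is
used for Jacobians, so the stability of boundary equilibria inherits the
invasion-analysis interpretation: the row of an absent species reduces to
its invasion growth rate, and the `T+` row at $x_{TP} = 0$ contributes a
large negative eigenvalue rather than an undefined one.

Integration uses fixed-step RK4 with $dt = 1$. Rates are $O(10^{-3})$ per
time unit, so this is deep inside the stability region and makes the
forward/backward bookkeeping of the control solver exact (shared grids, no
interpolation error from adaptive steps). Densities below $10^{-9}$ are
snapped to zero after each step, preventing negative drift and the
spurious revival of extinct clones. Breach of the viability cap is checked
at every step — a patient can die between clinical measurements — and the
constraint is read literally: total burden strictly greater than 9000
counts as death, equality does not.

## Equilibrium structure over constant dose

`candidate_equilibria()` enumerates all supports (supports with `T+` but
no `TP` are infeasible by construction), `stability_classify()` inspects
Jacobian eigenvalues, and `sweep_equilibria()` maps the stable branches
across the dose axis. Eigenvalue real parts are compared to zero with a
$10^{-12}$ margin; exact zeros are reported as marginal, not stable. The
default sweep grid step of $10^{-3}$ resolves the narrow three-species
window.

```{r thresholds}
analytic_thresholds()
```

Four thresholds organize the picture (closed forms where available):

* $\Lambda \ge 0.40404$: the resistant monoculture $(0, 0, 10000)$ is
  stable (producer invasion fails once
  $\alpha_{23} K_{T-} \ge K_{TP}(\Lambda)$). Its total volume 10000 always
  violates viability.
* $\Lambda < 0.48278$: the stable branch is the two-species `T+`/`TP`
  equilibrium, e.g. $(2082.76,\ 5206.90,\ 0)$ at $\Lambda = 0.4$.
* $\Lambda \in (0.48278,\ 0.48775)$: the stable branch carries all three
  species. Both endpoints matter: at the lower one `T-` invasion turns on
  (root of $495\lambda^2 - 2476\lambda + 1080$), and at the upper one the
  three-species equilibrium loses *stability* — its leading eigenvalue
  pair crosses the imaginary axis while the equilibrium itself remains
  positive until $\Lambda \approx 0.4886$. The window therefore ends at
  the stability-loss root, which the sweep confirms empirically.
* Viability on the stable branch holds for
  $\Lambda \in (0.28615,\ 0.48775)$; the lower endpoint is the root of
  $495\lambda^2 - 1211\lambda + 306$ (two-species total hitting the cap).

Only a narrow corridor of constant doses can hold a tumor at a viable
stable composition — the quantitative heart of the analysis.

## Optimal control: reaching an equilibrium

Given an initial composition $x_0$ and a target stable equilibrium $x^*$,
`fbs_solve()` minimizes $\int_{t_0}^{t_f} \lVert x - x^* \rVert^2\,dt$
over dosing schedules by Forward–Backward Sweep: forward state
integration, backward costate integration from the transversality
condition $\lambda(t_f) = 0$, and a relaxed pointwise
Hamiltonian-minimizing control update. The Hamiltonian is assembled from
the implemented dynamics (running cost plus costate-weighted vector
field), with analytic state-gradients cross-validated against central
finite differences ($h = 10^{-4}\max(1, x_i)$, agreement required to
$10^{-3}$ relative).

Only the `T+` and `TP` drift terms depend on the dose, so the pointwise
minimization is one-dimensional:
$h(\Lambda) = -b/\mu(\Lambda) - d/K_{TP}(\Lambda)$ with state/costate
coefficients $b, d$. Both terms are monotone in $\Lambda$, so for most
(state, costate) pairs the minimizer sits at a bound — the control problem
is of bang-bang/singular type, and the constant equilibrium dose is a
singular arc. A plain relaxed update $\Lambda \leftarrow (1-\omega)\Lambda
+ \omega\Lambda_{\min}$ therefore limit-cycles around the singular arc.
The solver guards the update with backtracking: the relaxation step is
halved until the objective does not increase by more than 0.1%, and an
iteration with no improving step terminates the sweep as stationary.
Accepted iterations are thus monotone by construction; `glance()` reports
the count of rejected full steps. Defaults: $\omega = 0.2$, tolerance
$10^{-3}$ on the maximum absolute control change, 500 iterations, dense
dose grid of 1001 points refined by golden section, initial control 0
(optimal schedules start drug-free).

Two numerical artifacts are worth knowing:

* *Transversality tail.* At $t_f$ the costates vanish, the Hamiltonian is
  flat in the dose, and the tie-break keeps the final node at its
  initialization. Terminal doses are therefore read from a window just
  inside the horizon (the last ~100 time units before the final node).
* *Singular-arc bias.* Started from the drug-free guess with the default
  tolerance, the solver approaches the equilibrium dose to within
  $O(10^{-4})$ but cannot remove the residual bias in a reasonable
  iteration budget (the update direction is bang-bang, so progress near
  the arc is by ever-smaller accepted steps). The degenerate-target
  identity — $x_0 = x^*$ implies objective 0 — is exact when the control
  is initialized at the target's own constant dose, which is how the
  property is verified.

Across an ensemble of sampled initial tumors (`ensemble_mean_control()`,
sample-SD error bars), the mean optimal schedule is an increasing
titration: near zero drug initially, rising to the target's equilibrium
dose 0.4. A minority of tumors — those starting with producer shares of a
few percent — cannot be steered to the equilibrium without the burden
crossing the viability cap on the way.

## Clinically feasible protocols

`protocol_catalog()` builds the six closed-loop policies compared in the
virtual trial: maximum tolerated dose; adaptive therapy (full dose until
the burden halves from baseline, holiday until it returns); and four
titration variants crossing the maintained volume (incoming baseline
$V_a$ vs fixed $V_b = 7000$) with the starting dose (1 vs 0). All measure
total volume every 100 time units (~3 months); titration moves the dose
by ±0.1 on the $\{0, 0.1, \ldots, 1\}$ grid when the measurement leaves
the 90–110% band around the target. The adaptive cadence is the same 100
units (a uniform-monitoring assumption; the on-trigger is $V \ge V_0$ and
the off-trigger $V \le 0.5 V_0$, both evaluated at measurement times).
Dose 0 is admitted to the grid since two protocols start drug-free and
successful schedules hold zero dose for long stretches. Titration targets
are fixed at treatment start and never re-baselined.

```{r protocols, eval = FALSE}
cohort <- sample_cohort(300, seed = 7)
runs <- lapply(protocol_catalog(V_b = 7000), run_cohort, cohort = cohort)
dplyr::bind_rows(lapply(runs, glance))
plot_km_protocols(runs)
```

Under MTD every patient dies: the drug suppresses `T+`/`TP`, the
resistant type is competitively released, equilibrates at
$K_{T-} = 10000 > 9000$, and every breach composition ends in the >80%
`T-` corner of the simplex (`breach_composition_class()`). Upward
titration to a large target volume is the best policy — it reproduces, in
closed loop and with no knowledge of the equilibrium, the ramp the
optimal-control analysis finds; survivors settle at the $\Lambda = 0.4$
two-species equilibrium, since the 0.1 dose grid cannot park inside the
narrow three-species window. The survival ordering (titration
$V_b, \Lambda_0{=}0$ best; starting at full dose worse than starting
drug-free; MTD worst) is the robust, sampler-independent content of the
trial comparison.

## The virtual-patient generator

`sample_cohort()` draws initial compositions uniformly on the solid
simplex $\{x \ge 0,\ \sum x_i \le 9000\}$ by cube rejection — the
simplest law consistent with a space-filling scatter of viable initial
tumors — seeded and independent of the caller's RNG state, with the
sampler recorded as an attribute for provenance. An optional minimum
volume `v_min` (default 0) restricts to larger tumors. What the generator
emulates: arbitrary viable mixtures of the three types with no
correlation structure. What it does not: any clinically realistic joint
distribution of composition and burden at presentation — real incoming
patients are not uniform on this simplex. Cohort-level percentages (death
fractions, mean breach times) are therefore distribution-dependent
summaries of the model, not clinical predictions; the protocol *ordering*
and the MTD certainty-of-death result are the transferable conclusions,
and they are what the tests pin down. Survival summaries use the
product-limit estimator (`kaplan_meier()`, censoring at the horizon), and
`surviving_initials_summary()` quantifies the selection effect — under
burden-feedback protocols, survivors skew to large initial volumes and
small resistant shares.

## Problem sizes and limitations

The packaged checks run at desk scale: cohorts of 300–500 patients
(versus 10000 in a full trial run) and control ensembles of 20 initial
tumors, sizes chosen so the full suite completes in minutes while leaving
the stochastic conclusions (breach fractions at 100%, orderings, ramp
shapes) stable across seeds. Known limitations: no pharmacokinetics (the
dose acts instantaneously on carrying capacities), no demographic noise,
no spatial structure, no mutation or phenotype switching, and total
volume is observed exactly (no PSA measurement error). The FBS solver
returns a locally optimal stationary schedule — no claim of global
optimality is made, and for singular-arc problems the terminal-node and
bias artifacts above apply.
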