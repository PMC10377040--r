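---
title: "Modeling antibody repertoire dynamics with somatic hypermutation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling antibody repertoire dynamics with somatic hypermutation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abdyn)
```

## The models

`abdyn` simulates humoral immune dynamics with deterministic mass-action
ODEs. All concentrations and times are dimensionless; the parameter sets
shipped with the scenario presets are qualitative, literature-inspired
values rather than fits to data.

### Single-antibody kinetics

Three species interact: free antibody $y$, antigen $z$, and the
antibody–antigen complex $x$. Six processes drive them — antigen
replication ($k_1$), reversible binding ($k_2$, $k_{-2}$), immune
clearance of complexes ($k_3$), complex-stimulated production of new
antibody ($k_4$), antigen degradation ($k_5$) and antibody decay
($k_6$):

$$
\begin{aligned}
\dot x &= k_2 y z - k_{-2} x - k_3 x\\
\dot y &= k_{-2} x - k_2 y z + k_4 x - k_6 y\\
\dot z &= k_{-2} x - k_2 y z - k_5 z + k_1 z
\end{aligned}
$$

For a *self*-antigen, consumption by binding is assumed to be balanced by
host regeneration, so $\dot z = 0$ exactly and $k_1$, $k_5$ drop out
(`rhs_self()`). The regeneration coefficient $k_4$ is the biological
switch in this family of models: it encodes how strongly the peptides
presented from a bound antigen stimulate T-helper cells, and hence how
much new antibody each complex elicits. Self-peptides stimulate weakly
(small $k_4$), foreign peptides strongly (large $k_4$).

This single dial produces the central qualitative result: with small
$k_4$, a strongly binding antibody forms complexes faster than
production can replace them, so the *strong* self-binder is eliminated
first (clonal deletion); with large $k_4$, production outruns clearance
and the strongest binder proliferates fastest (affinity selection). The
`clonal_deletion` and `pathogen_selection` presets realize the two
regimes. For several antibodies competing for one replicating pathogen
we use the natural mass-action generalization (`rhs_competition()`):
each antibody binds with its own $k_2^{(j)}$, $k_{-2}^{(j)}$ and the
antigen balance sums all binding fluxes; it reduces exactly to the
single-antibody system when $m = 1$.

### The affinity grid and the mutation kernel

Observed antigen–antibody equilibrium dissociation constants are well
described by $\log_{10} K_d \sim \mathcal N(\mu, \sigma^2)$ with
$\mu = -9$, $\sigma = 1$; the package takes this summary as given.
Binding affinity is discretized into $n = 9$ classes with association
rates $k_2 = 10^{-13}, \dots, 10^{-5}$ and a shared dissociation rate
$k_{-2} = 10^{-18}$, so $\log_{10} K_d$ runs $-5, -6, \dots, -13$: one
decade-wide bin per class, class 5 sitting on the mean, class indices
ascending in binding strength. Finer discretizations are supported by
`affinity_grid()` (any $n$ with decade spacing, any $\mu$, $\sigma$),
but only the nine-class presets are shipped.

Somatic hypermutation (SHM) is modeled in affinity space, not sequence
space. A mutated offspring of class $i$ conceptually redraws its
$\log_{10} K_d$ from the normal distribution; the mass inside class
$i$'s own bin is the probability of an affinity-neutral mutation, and
the two tails are lumped into the single adjacent weaker and stronger
classes (`mutation_split()`). Mass that would leave the grid at either
end is absorbed into "stay", which keeps every kernel row summing to 1
without inventing off-grid classes; under the defaults the affected mass
is below $3\times10^{-4}$, so the choice is numerically inconsequential.
For class 6 this gives the split $0.6915 / 0.2417 / 0.0668$ toward
class 5 / staying / toward class 7. Because the distribution is centered
on class 5, the kernel is mirror-symmetric about it and always drifts
mutants toward moderate affinity — the mechanism behind every SHM result
below.

### The repertoire model

Each class keeps its own $x_i$, $y_i$ against one shared antigen. SHM
acts only on the *production* term $k_4 x_i$ — existing antibodies never
convert. With SHM rate $p \in [0,1]$ and kernel rows
$(S_i^-, S_i^0, S_i^+)$:

$$
\dot y_i = k_{-2,i} x_i - k_{2,i} y_i z
 + \bigl[(1-p) + p S_i^0\bigr] k_4 x_i
 + p S_{i+1}^- k_4 x_{i+1} + p S_{i-1}^+ k_4 x_{i-1} - k_6 y_i
$$

Since each kernel row sums to 1, redistribution conserves the total
production flux $k_4 \sum_i x_i$ exactly — an identity the test suite
checks at random states. At $p = 0$ the classes decouple into $n$
independent single-antibody systems, which provides a strong reduction
oracle for the integrator. SHM is a deterministic expected flux, as in
the rate equations; no stochastic sampling is involved anywhere in the
core.

## Scenario presets, horizons and what they show

The sources of the scenario parameter sets give initial conditions and
rate constants but no time axes, so the horizons are package choices,
fixed once so that each experiment's qualitative contrast is realized
and then documented here:

* **`clonal_deletion`** ($z = 3\times10^7$, $y_0 = 10^5$, $k_4 = 0.1$,
  strong binder $k_2 = 10^{-8}$ vs weak $10^{-9}$): horizon 15. The
  stopping rule is that the strong binder falls below 10% of $y_0$,
  which happens at $t \approx 9.4$.
* **`pathogen_selection`** (five antibodies, $k_2$ from $10^{-5}$ down
  to $6\times10^{-6}$, $k_1 = 0.1$, $k_4 = 2$): horizon 200. The
  pathogen grows exponentially, is crushed by the expanding antibody
  response around $t \approx 165$, and the final free-antibody ordering
  (strongest binder most abundant) is stable from there on.
* **`shm_self_tolerance`** (seed $10^5$ in the strongest class,
  $k_4 = 0.6$, $p = 0.1 \dots 0.4$): horizon 300, long enough that at
  $p = 0.4$ every class has passed its peak and is declining.
* **`shm_foreign`** (seed $10^5$ in the *weakest* class, $k_4 = 1.1$,
  $p \in \{0, 0.5\}$): horizon 800, see the numerical note below.
* **`aging_sweep`** (initial $10^6$ distributed over the grid by the
  normal bin masses, $k_4 = 0.7$, $p \in \{0, 0.2, 0.5\}$): horizon
  100, with composition snapshots on the ladder $t = 0, 25, 50, 75,
  100$. From $t \approx 80$ the $p = 0.2$ repertoire is dominated by
  class 7: classes 8 and 9 produce offspring that overwhelmingly mutate
  back toward weaker binding, so the drift toward self-reactivity stalls
  one class short of the strongest binders.

One parameter-set note: the published description of the
foreign-antigen SHM experiment seeds the initial $10^5$ in the weakest
class in its narrative while the accompanying parameter listing places
it in the strongest class. The preset follows the narrative (seeding the
weakest class is what makes affinity maturation observable); the seeded
class is exposed as the `seeded_class` config override for anyone who
wants the other reading.

## Numerical choices

* **Solver.** `deSolve::ode` with `lsoda`, which switches automatically
  between stiff and non-stiff methods. The binding rates $k_{2,i} z$
  span seven orders of magnitude across classes, so stiffness handling
  is not optional.
* **Tolerances.** Defaults `rtol = 1e-8`, `atol = 1e-6`; state
  magnitudes in the presets span roughly $1$ to $3\times10^7$. Both are
  configurable per run.
* **The `shm_foreign` exception.** Its preset carries `rtol = 1e-10`,
  `atol = 1e-20`. The mutational cascade out of the weakest class passes
  through intermediate concentrations some fifteen orders of magnitude
  below the seeded scale before the high-affinity classes take off; with
  the default `atol` the cascade is flattened to solver noise and the
  maturation never appears. Tightening `atol` further (to $10^{-30}$)
  changes the horizon totals by less than one part in $10^6$, so
  $10^{-20}$ is safely converged.
* **Negativity.** Concentrations may undershoot zero by solver error; an
  excursion beyond $-10\,\mathrm{atol}$ aborts the integration with an
  error rather than being clipped, so stiffness failures cannot
  masquerade as valid runs.
* **Ties.** The dominant class reported by `trajectory_metrics()` breaks
  ties toward the lower index; ties are measure-zero along actual
  trajectories, but the rule makes runs bitwise reproducible.
* **Exact zeros.** Classes that start empty and receive no mutational
  inflow (any non-seeded class at $p = 0$) have identically zero
  derivatives and remain exactly zero through the integration — the test
  suite asserts equality with 0, not smallness.
* **Early transients.** The seeded strong binder in
  `shm_self_tolerance` loses half its free antibody to complex formation
  within $t \approx 0.035$, far below the default sampling interval.
  Analyses of the fast transient (e.g. `time_to_fraction()` at large
  fractions) should re-run the scenario with a short horizon and dense
  `n_points`, as the test suite does.

## What the simulations do and do not show

The presets are synthetic experiments: they encode the study conditions
(initial concentrations, rate ladders, SHM rates) exactly and are fully
deterministic. Passing tests therefore demonstrate that the *mechanisms*
— kinetic clonal deletion, $k_4$-mediated selection, SHM drift toward
moderate affinity — follow from the stated mass-action assumptions. They
do not validate the parameter values against clinical or experimental
data: rates are not fitted, time is unitless, antigen diversity is
reduced to a single species, and B-cell populations are identified with
their antibody concentrations. T-cell dynamics, regulatory cells,
receptor editing and sequence-level mutation structure are outside the
model; mutations never skip an affinity class, because the kernel lumps
both tails into the adjacent classes by construction.

Test-suite problem sizes are deliberately modest — nine classes, 19
coupled equations, horizons up to 800 with ~200 output points, and a
$10^5$-step fixed-step RK4 oracle on the three-state system — which
keeps the full suite in the ten-second range while still exercising the
stiff regime.

## Reproducibility

`run_scenario()` involves no random numbers; repeated runs produce
bitwise-identical trajectories and CSVs on a given platform. The only
randomness anywhere in the package's tooling is the fixed-seed random
state used by the `check` subcommand's conservation self-test.
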