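---
title: "Modelling nanoparticle-protein corona kinetics with coronadyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling nanoparticle-protein corona kinetics with coronadyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coronadyn)
```

## The model

When nanoparticles enter a protein-rich fluid, protein molecules compete to
adsorb onto the particle surface, forming the tightly bound "hard corona"
that determines how the particle is seen by cells. `coronadyn` models this
as competitive, reversible adsorption onto a shared surface. Each protein
species $i$ is described by four parameters:

* $k_{a,i}$ — association rate constant (M$^{-1}$ s$^{-1}$),
* $k_{d,i}$ — dissociation rate constant (s$^{-1}$),
* $n_i$ — the average number of molecules of species $i$ that fully cover
  one particle (so $n_i N_0$ is the site capacity in concentration units),
* $c_{i0}$ — total concentration in the fluid (M),

plus the nanoparticle concentration $N_0$ (M). Units are fixed package-wide
(M, s); the equilibrium constant $K_i = k_{a,i}/k_{d,i}$ then has units
M$^{-1}$.

The state is the vector of bound concentrations $x_i$; molecule
conservation makes the free concentration $c_{i0}-x_i$ by construction. The
occupied surface fraction of species $i$ is $f_i = x_i/(n_i N_0)$, and
$\theta = 1 - \sum_j f_j$ is the free surface fraction. Mass action on the
free sites gives

$$\frac{dx_i}{dt} = k_{a,i}\,(c_{i0}-x_i)\,n_i N_0\,\theta \;-\; k_{d,i}\,x_i.$$

Key assumptions: binding sites are independent (protein-protein
interactions on the convex surface are neglected), binding is reversible, a
single monolayer forms (no soft corona), and proteins do not change
conformation upon binding. The per-binding surface increment is a random
variable with mean $1/n_i$; the ODE above is the mean-field (expected-value)
description, which the package's particle-resolved stochastic simulator
validates independently.

## Two phases and two closed forms

Because association ($\sum_j k_{a,j} c_{j0}$, often of order
$10\,$–$\,10^2$ s$^{-1}$ in serum) is much faster than dissociation
($k_d \lesssim 10^{-3}$ s$^{-1}$ for hard-corona proteins), the dynamics
split into two phases:

1. **Fast phase** (time constant $\tau_\text{fast} = 1/\sum_j k_{a,j}
   c_{j0}$): proteins race to cover the bare surface. With ample protein,
   species $i$ claims surface in proportion to its arrival rate, giving the
   *metastable* composition
   $$\bar f_i = \frac{k_{a,i} c_{i0}}{\sum_j k_{a,j} c_{j0}}, \qquad
     \theta = 0.$$
2. **Slow phase** (time constant at least $1/\min_i k_{d,i}$): weakly bound
   species are displaced by high-affinity ones (the Vroman effect). Setting
   the derivatives to zero and neglecting depletion yields the competitive
   Langmuir *stable* composition
   $$f_i = \frac{K_i c_{i0}}{1 + \sum_j K_j c_{j0}}, \qquad
     \theta = \frac{1}{1 + \sum_j K_j c_{j0}}.$$

Both formulas are independent of $n_i$ and $N_0$. `metastable_composition()`
and `stable_composition()` evaluate them; `time_scales()` returns the two
time constants.

The metastable formula assumes *protein excess*: filling species $i$'s
share of the surface must not exhaust its supply
($n_i N_0 \bar f_i \le c_{i0}$). `validate_corona()` warns when this fails;
the recommended fallback is the empirical fast-phase composition from
`two_phase_summary()`, which reports the state at 99% coverage.

## Exact equilibrium with depletion

`stable_composition_exact()` retains depletion, solving
$k_{a,i}(c_{i0}-x_i)\,n_i N_0\,\theta = k_{d,i} x_i$ jointly with the
coverage identity. For fixed $\theta$ each balance has the scalar solution
$x_i(\theta) = c_{i0}\, a_i\theta/(1+a_i\theta)$ with
$a_i = n_i N_0 K_i$, so the problem reduces to one monotone scalar equation
$g(\theta) = \theta - 1 + \sum_i x_i(\theta)/(n_i N_0) = 0$.

A fixed-point iteration on $\theta$ with constant damping is *not* used:
near the root $|g'(\theta)| \approx \sum_i K_i c_{i0}$, which for realistic
panels is $10^3$–$10^7$, so any fixed damping short of $\sim 1/\sum K_i
c_{i0}$ oscillates or diverges. Instead the package bisects on
$\log_{10}\theta$ (the bracket $[10^{-300}, 1]$ is guaranteed because $g$
is strictly increasing with $g(0^+) = -1 < 0 < g(1)$) and polishes with a
few Newton steps. This resolves $\theta$ to full relative precision even
when the surface is saturated and $\theta \sim 10^{-7}$ or smaller, and
each species' balance residual is verified before returning.

## The reduced (slow) model

The fast variable eliminated by singular perturbation is the total coverage
$s=\sum_i f_i$. Setting the sum of the fraction derivatives to zero yields
the quasi-steady free surface fraction

$$\theta^*(x) = \frac{\sum_j k_{d,j}\, x_j/(n_j N_0)}
                    {\sum_j k_{a,j}\,(c_{j0}-x_j)},$$

and substituting $\theta^*$ into the rate law gives the reduced model, with
the metastable composition as its initial condition. By construction
$\sum_i \dot x_i/(n_i N_0) = 0$ exactly, so the reduced flow preserves
$\sum f_i = 1$ and only redistributes surface between species; every term
is of the order of the dissociation rates. The separation parameter
reported by `epsilon_separation()` is
$\varepsilon = \max_i k_{d,i}/\sum_j k_{a,j} c_{j0}$, and the reduction is
flagged as dubious above $\varepsilon = 0.01$.

Two consequences worth knowing:

* The reduced model's equilibrium keeps $\sum f_i = 1$, while the full
  model's equilibrium has $\sum f_i = 1 - \theta_\text{eq}$. The two agree
  only up to $\theta_\text{eq}$, which is why fixed-point-equivalence
  checks at the $10^{-6}$ level are meaningful exactly in the saturated
  regime ($\sum K_j c_{j0} \gtrsim 10^6$) the model targets.
* The accuracy of the reduced trajectory against the full one, measured
  from $t = 10\,\tau_\text{fast}$ onwards, contains an
  $\varepsilon$-independent floor: the full model still carries the decayed
  remnant of the fast transient, of size $\max_i \bar f_i\, e^{-10}
  \approx 4\times10^{-5}$, at that measurement point. The
  slow-state (QSS) error itself scales linearly in $\varepsilon$ — we
  observe it cleanly for $\varepsilon \ge 10^{-4}$, where it dominates the
  remnant — but a sup-norm ladder extended down to $\varepsilon = 10^{-6}$
  flattens onto the $e^{-10}$ floor rather than continuing to decrease.
  The corresponding acceptance assertion is therefore expected to fail at
  its lower rungs; this is a property of the measurement point
  ($10\,\tau_\text{fast}$), not of the reduction.

The reduced system tolerates explicit (Adams) integration with steps of the
order of the dissociation times, and a test demonstrates this; the default
integrator nevertheless remains lsoda because panels whose $k_d$ values
span several decades make even the slow block mildly stiff over the
$100/\min k_d$ horizon.

## Sensitivities

Differentiating the closed forms gives logarithmic sensitivities that
depend only on the fractions themselves: a relative error in $k_{a,i}$
(metastable) or $K_i$ (stable) moves species $i$'s own fraction by factor
$1-f_i$ and every other fraction by $-f_i$; the free area responds with
$-f_i$. `metastable_sensitivity()`/`stable_sensitivity()` return these
matrices, and `sweep_composition()` recomputes a composition across a
multiplier range alongside the first-order prediction so the reach of the
local analysis can be judged. Central finite differences (relative step
$10^{-6}$) are used as the independent oracle in the tests.

## The stochastic oracle

`ssa_simulate()` runs an exact Gillespie simulation at particle resolution:
each particle $p$ has a continuous free surface fraction $\theta_p$;
binding of species $i$ on $p$ has propensity $k_{a,i}\, c^\text{free}_i\,
n_i \theta_p$ and consumes an increment with mean $1/n_i$; unbinding occurs
at $k_{d,i}$ per bound molecule and restores the increment recorded at
binding, so $\theta_p \in [0,1]$ holds exactly event by event. Counts map
to concentrations through `volume_scale`, which defaults to
`n_particles / N0` so the simulated ensemble is consistent with the panel's
nanoparticle concentration.

Choices made where the mechanism is underdetermined:

* Only the *mean* ($1/n_i$) and independence of the surface increments are
  part of the model; the distribution is exposed as a switch
  (`deterministic` vs `uniform` on $[0, 2/n_i]$) and the mean-field
  comparison passes under both.
* Dissociation restores the increment stored at binding (rather than a
  fresh draw), which keeps each particle's surface bookkeeping exactly
  reversible.
* Increments are clipped at the remaining free surface. A consequence is
  that near full coverage a molecule can occupy less than $1/n_i$: the
  count-based fraction $x_i/(n_i N_0)$ then overshoots the surface actually
  held by roughly half an increment per species per particle
  ($\sim 0.5/n_i$), an effect independent of the ensemble size. The
  trajectory therefore reports `f` from the exact surface bookkeeping (sum
  of stored increments), for which $\sum_i f_i + \bar\theta = 1$ holds
  identically, alongside the count-based `x`.

The engine is written in C++ (Rcpp) and draws from R's RNG, so runs are
bit-identical for a fixed seed.

## Synthetic panels

`generate_panel()` draws species log-uniformly from `panel_ranges()`; the
defaults ($k_a \in [10^3, 10^7]$ M$^{-1}$s$^{-1}$, $k_d \in [10^{-6},
10^{-3}]$ s$^{-1}$, $n \in [10, 1000]$, $c_0 \in [10^{-7}, 10^{-3}]$ M,
$N_0 = 10^{-9}$ M, $m = 3$) are engineering choices spanning serum-plausible
magnitudes, not measurements of particular proteins. Every generated panel
reports $\varepsilon$ and the protein-excess factor
$\min_i c_{i0}/(n_i N_0)$, so tests and users can select panels in the
regime a given result assumes (e.g. $\varepsilon \le 10^{-4}$ *and* excess
$\ge 100$ for reduced-model comparisons — the metastable initial condition
is only as good as the excess assumption behind it).

`demo_panel()` is a fixed three-species panel (albumin-like, abundant and
fast but weakly held; lipoprotein-like intermediate; fibrinogen-like,
scarce but high-affinity) constructed so that the metastable and stable
rankings invert — the qualitative two-phase exchange the model exists to
capture. What the generator does *not* emulate: correlated parameters
across species, irreversible binding, conformational change, soft-corona
layering, or protein-protein cooperativity. Passing tests on these panels
therefore validate the mathematics of the model, not its biological
completeness.

## Numerical choices

* **Integration.** lsoda with an analytic Jacobian for the full model;
  `rel_tol = 1e-10`, `abs_tol = 1e-16` M. The free surface fraction is a
  near-cancelling difference of the states, so resolving the package-wide
  fraction tolerance of $10^{-9}$ requires state accuracy well below
  $10^{-9}$; these tolerances keep $\theta$ within $[-10^{-9}, 1]$ on all
  tested panels at negligible cost for systems of a few species.
* **Positivity.** States are clipped at zero before rate evaluation;
  invariant breaches beyond ten times the fraction tolerance abort with a
  diagnostic rather than silently continuing.
* **Default output grid.** Geometric over $[\tau_\text{fast}/100,\;
  100/\min_i k_{d,i}]$, so one run shows both phases.
* **End of fast phase.** `two_phase_summary()` reports the first grid time
  with $\theta < 0.01$ and log-interpolates the crossing time between
  bracketing grid points.
* **Problem sizes.** The shipped tests integrate 100 three-species panels
  over both phases, compare 50 panels against the equilibrium solver, and
  run the stochastic oracle with 500 particles and 20 replicates (about
  $5\times10^4$ events per replicate on the demo panel); the whole suite
  completes in well under a minute of compute for the deterministic parts
  and a few seconds for the stochastic parts.

## Limitations

The model inherits the simplifications of monolayer, reversible,
non-interacting adsorption on spherical particles. The closed forms
additionally assume protein excess (metastable) or negligible depletion
(stable); both assumptions are checked or reported by the package rather
than silently relied on. Absolute time courses depend on rate constants
that are hard to measure; the compositions themselves depend only on
ratios, which is where the model is most trustworthy.
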