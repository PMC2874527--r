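---
title: "Methods: linlog dynamics and metabolic control analysis of hepatoma central carbon metabolism"
author: "linlogmca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linlog dynamics and metabolic control analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linlogmca)
```

# The modelled system

`linlogmca` implements a dynamic model of the central carbon metabolism of
HepG2 hepatoma cells: 49 reactions (glycolysis, the pentose-phosphate
pathway, the TCA cycle, cofactor turnover, lumped biosynthetic drains and 5
transport steps) converting 45 balanced species — 40 intracellular and 5
extracellular (glucose, lactate, pyruvate, alanine, serine).  Regulation
enters through 31 curated activator/inhibitor links.  Intracellular
concentrations are in mmol per litre cell volume, extracellular ones in mmol
per litre well volume; the volume ratio is pre-folded into the reference
fluxes, which are expressed in the concentration unit of each species row
they feed.  Time is in minutes throughout.

Three conserved moieties (ATP+ADP+AMP, NAD+NADH, NADP+NADPH) reduce the
dynamic dimension from 45 to 42 independent levels.  Moiety detection uses
exact rational elimination, so the conservation identities hold exactly,
not merely to rounding.

# The rate law

Every reaction rate is approximated by linlog kinetics,

$$ r_i \;=\; \frac{e_i}{e_i^0}\, J_i^0 \Big( 1 + \sum_x \varepsilon_{ix}
   \ln \hat c_x \Big), \qquad \hat c_x = c_x / c_x^0 , $$

anchored at a reference state $(J^0, c^0)$ with dimensionless scaled
elasticities $\varepsilon_{ix}$.  The sparsity pattern of
$\varepsilon$ is structural: one entry per balanced substrate or product of
each reaction plus one per regulatory link — 174 entries for the packaged
network.  Together with the 42 independent reference levels this gives the
216-parameter estimation problem; 30 of the reference levels carry direct
measurements in the packaged metadata.

**Logarithm singularity.** Linlog rates diverge as a concentration
approaches zero, which genuinely happens in the glucose-deprivation
experiment (intracellular glucose runs out).  Normalized concentrations are
floored at $\delta = 10^{-6}$ (configurable) inside the logarithm; the first
simulation that activates the clamp reports the affected species.  The rate
law is unmodified wherever concentrations are healthy.

# Steady state, batch culture, and what is frozen when

The five extracellular species are medium pools of a batch culture.  Each
appears in exactly one transport reaction, so a steady-state condition over
*all* 45 balanced rows would force every transport flux to zero — there is
provably no strictly positive flux vector in the null space of the full
45-row matrix (the feasibility check is a convex program and its optimum is
bounded away from zero).  The experiment itself shows drifting medium pools.
The package therefore distinguishes three situations:

* **Simulation** integrates all 45 species; the medium pools deplete or
  accumulate exactly as in the experiment.
* **The reference steady state** is imposed on the 40 intracellular rows
  (relative residual below $10^{-8}$), which is the condition the reference
  flux distribution from the isotopic-tracer study satisfies.
* **Control analysis** treats the extracellular concentrations as external
  parameters (frozen), the classic treatment of source and sink pools in
  metabolic control analysis.  The analysed subsystem has
  $40 - 3 = 37$ independent species.

Only with this convention do the summation and connectivity theorems hold
exactly, which is how the implementation is validated.

# Simulation: ODE to DAE reduction and the integrator

The normalized balances
$\mathrm{d}\hat c/\mathrm{d}t = \mathrm{diag}(c^0)^{-1} N\, r(\hat c)$ are
integrated over the independent species only; each moiety's dependent member
is reconstructed algebraically from its total at every step (the same
ODE-to-DAE reformulation used in the original analysis).  Moiety totals are
thereby conserved to machine precision rather than integrator tolerance.

The integrator is a 4-stage, 4th-order L-stable Rosenbrock method with an
embedded 3rd-order error estimate and the analytic Jacobian
$N_R\,\mathrm{diag}(eJ^0)\,\varepsilon\,\mathrm{diag}(c)^{-1}L$ — a linearly
implicit scheme in the same family as the extrapolation solver used
originally; acceptance of results is tolerance-based, not solver-identical.
Defaults: rtol $10^{-8}$, atol $10^{-10}$.  A compiled implementation is the
default engine; a pure-R reference implementation of the identical method
ships alongside and the two are cross-checked in the tests, as is agreement
with a brute-force fixed-step RK4 oracle and the invariance of trajectories
under tolerance halving.

The medium-exchange stimulus is modelled as an instantaneous reset at
$t = 0$: intracellular levels start at 1, extracellular levels at
$c^{post}/c^0$.  A zero medium concentration (glucose-free medium) starts at
the clamp floor.

# Parameter estimation

The reference flux distribution $J^0$ is a fixed input (two-step
identification: fluxes from tracer data, kinetics from stimulus-response
data).  The unknowns are the in-pattern elasticities and the reference
levels; the objective is the variance-weighted sum of squared residuals
between simulated and measured normalized time courses, replicates entering
individually, evaluated strictly at the measurement times (no
interpolation).  Replicate standard deviations are floored at 5 % of the
replicate mean (triplicate SDs can be spuriously tiny).

The optimizer is a self-adaptive $(\mu, \lambda)$ evolution strategy:
comma selection with $(\mu,\lambda) = (10, 70)$, per-parameter log-normal
step-size adaptation with learning rates $1/\sqrt{2n}$ (global) and
$1/\sqrt{2\sqrt n}$ (coordinate-wise), reflection at the box constraints,
a large finite penalty ($10^{12}$) for failed simulations, and restart
cycles every 100 000 evaluations reseeded from the incumbent best.  All
randomness flows from a single integer seed; identical seeds give
bit-identical traces.  Elasticities are searched sign-free in
$[-20, 20]$ by default (optional sign priors follow the substrate +,
product −, activator +, inhibitor − convention); measured reference levels
move within ±3 SD of their 0⁻ estimates, unmeasured ones log-uniformly over
three decades.  The initial mutation step defaults to
$\sigma_0 = 0.3$ — pilot runs on the packaged fixture showed that the
common textbook value 0.1 under-explores this landscape and stalls well
short of the optimum, while 0.5 overshoots; the pilot protocol and its
seeds are recorded in the test fixtures.  No confidence intervals are
computed, matching the original study's choice.

# Control analysis

With $M = N_R\,\mathrm{diag}(J^0)\,\varepsilon\,\mathrm{diag}(c^0)^{-1}L$
(the Jacobian of the analysed subsystem, eigenvalues of which also decide
asymptotic stability), the scaled control coefficients are

$$ C^S = -\,\mathrm{diag}(c^0)^{-1} L\, M^{-1} N_R\, \mathrm{diag}(J^0),
   \qquad C^J = I + \varepsilon\, C^S . $$

These explicit forms are an algebraic reconstruction validated by the
theorem identities (rows of $C^J$ sum to 1, rows of $C^S$ to 0), by
finite-perturbation re-solution of the steady state (enzyme modulation by
$\times(1 \pm 10^{-5})$, agreement to $10^{-3}$ relative on entries above
$10^{-3}$), and by the internal consistency of the published partial-control
tables, including the $+1$ direct term on the diagonal.

Partial flux control coefficients are the single-mediator summands
$\varepsilon_{ix} C^S_{xj}$ and are left unscaled (not divided by the
total).  The partial internal response coefficient of metabolite $x$ under
enzyme $j$ is the enzyme's partial control over its own flux through $x$;
for every species outside a conserved moiety these sum to $-1$ over the 49
reactions (connectivity theorem) — a perturbation of a moiety-conserved
pool cannot be relaxed, so ATP/ADP/AMP, NAD/NADH and NADP/NADPH are
reported as not applicable.  A Jacobian condition number above $10^{12}$
raises a hard error instead of silently regularizing, because a
pseudo-inverse would corrupt the theorem identities.

# The synthetic world

The generator emulates the glucose-deprivation experiment: 25 observed
metabolites (the 5 extracellular species plus a configurable default set of
20 intracellular species mirroring the GC-MS/LC-MS-MS/HPLC panels),
sampling at 0⁺, 1, 2, 5, 10, 30, 60, 120 and 180 min in triplicate, and a
0⁻ reference sample used for normalization.  The fresh medium carries zero
glucose, 10 % residual lactate and pyruvate, and alanine and serine at
reference levels.  Noise is multiplicative Gaussian, truncated at zero,
with a default CV of 0.15 per replicate (typical of MS-based metabolite
quantification); values are normalized by the 0⁻ replicate mean, exactly as
an experimenter normalizes.

Reference fluxes are sampled as strictly positive vectors in the null space
of the intracellular stoichiometry (convex hinge minimization over
null-space coordinates followed by a seeded in-cone randomization), with
the glycolysis : pentose-phosphate split at the glucose-6-phosphate branch
fixed to the reported 57 : 43 by default and glucose uptake scaled to
1 mmol/l/min.  Elasticities are drawn on the structural pattern with
conventional signs and magnitudes uniform in $[0.1, 2]$; reference
concentrations log-uniform over $[0.1, 10]$ mmol/l; draws are rejected
until both the full simulated system and the frozen-medium control
subsystem are asymptotically stable (cap 1000 attempts).

The 6-reaction estimation fixture (linear chain with a branch drain and one
feedback inhibition, substrate deprivation to 5 % as stimulus, chain flux
scaled so the relaxation time constants fall inside the sampling window)
additionally rejects truths that are (i) unphysical — the noise-free
trajectory must stay strictly positive and bounded, since the
multiplicative noise model is meaningless for a concentration that crosses
zero — or (ii) practically unidentifiable: the median Cramér–Rao bound of
the design, computed from noise-free sensitivities at the benchmark noise
level, must support recovery at the benchmark precision.  Elasticity
non-identifiability under a single-stimulus design is a known property of
linlog models (and the reason the control structure, not the individual
elasticity, is the robust quantity); benchmarking the estimator on an
unidentifiable instance would measure the instance, not the estimator.
What a green recovery test establishes is therefore that the estimator
recovers kinetics from informative, physically sensible stimulus-response
data at the stated noise level and budget — not that every conceivable
parameterization is identifiable, and not that real chromatographic
artefacts (drift, matrix effects, censoring) are handled.

# Numerical choices and degenerate inputs

* Moiety basis: exact rational RREF, scaled to smallest integers, ordered
  by smallest participating species id; a mixed-sign basis is returned raw
  with a warning.
* Dependent species per moiety: the last member in species-file order
  (AMP, NADPH, NADH in the shipped file).
* Dead-end scan: intracellular species only; extracellular pools
  legitimately occur in a single transport step.  Violations are demoted to
  boundary with a warning on load.
* Steady-state continuation: damped Newton from the reference state with a
  long-time-integration fallback; an unstable reference raises an error
  (the continuation would be meaningless), as does a runaway trajectory.
* Conjugate-pair counting uses a $10^{-9}$ relative tolerance on imaginary
  parts.
* All tabular artifacts serialize floats with 17 significant digits and
  round-trip bit-exactly.

# Known limitations

* No compartmentalization (cytosol vs mitochondria), matching the source
  model; TCA-cycle levels are cell-average values.
* The packaged reference state is synthetic unless the user supplies
  measured fluxes and levels; the published fitted control coefficients
  depend on an external flux distribution and are comparison outputs, not
  reproduction targets.
* Fitted elasticities inherit the identifiability limits of 25 observed
  species; no confidence intervals are attached.
* The clamp floor makes rates insensitive to species pinned at the floor;
  control analysis is only meaningful at reference states away from the
  floor.
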