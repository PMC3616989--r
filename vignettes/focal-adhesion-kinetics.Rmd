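---
title: "Kinetic modelling of focal adhesion assembly under RNA interference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic modelling of focal adhesion assembly under RNA interference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fadyn)
```

## The model

Focal adhesions are integrin-based contacts between a cell and the
extracellular matrix. They arise by hierarchical assembly: actin (A),
a lumped connector component (C, representing talin, vinculin, paxillin
and similar adaptors) and integrin (I) form the intermediate complexes
AC and CI, which complete into the focal complex ACI. Under contractile
force, focal complexes mature into focal adhesions, represented as a
separate species ACIm. Two antagonistic GTPase pools close the loop:
active Rac is produced in proportion to focal complexes and promotes
assembly, active Rho is produced in proportion to mature adhesions and
drives force; each inhibits the other through a steep Hill function
(coefficient 4), a double-negative feedback that makes the system
bistable.

`fadyn` implements this scheme as a mass-action ODE system over twelve
species — three mRNAs (MA, MC, MI), three monomers, two intermediate
complexes, ACI, ACIm and the two GTPases — decomposed into 22 net
reactions (`reaction_catalog()`). Every term of the right-hand side is
attributed to exactly one reaction, which is what makes the sensitivity
analysis below well defined.

### Force and the two bond scenarios

The per-bond force is

$$F = \frac{\chi + \rho_{RHO}\,[RHO]}{1 + \sigma([ACI] + m\,[ACIm])},$$

with basal contractility $\chi$, Rho force gain $\rho_{RHO}$, and a
load-sharing denominator in which mature adhesions are weighted $m = 3$
times (adhesion stress measurements put focal-adhesion stress about
three-fold above focal-complex stress). Force acts in four places: the
dissociation rates $\delta_A$, $\delta_I$ of the full complex acquire a
Bell factor, the maturation rate becomes $\tau_{ACI} F^n$ with $n = 2$,
and the mature-adhesion disassembly rate is the derived quantity
$\varepsilon\,(\delta_A + \delta_I)/2$ times the same Bell factor
(never an independent parameter).

The Bell factor is $e^{(2s-1)F}$ with slip fraction $s$
(`bond_factor()`): $s = 1$ is the classical slip bond ($e^{+F}$,
dissociation accelerates under load), $s = 0$ the catch bond
($e^{-F}$), and at $s = 1/2$ the mixture is force-insensitive. Slip and
catch runs therefore differ only in this sign; maturation always
accelerates with force.

### RNA interference

Each mRNA obeys production/degradation kinetics plus a purely
phenomenological, saturating knockdown term
$d_{max}\,[siRNA]^h/(\Gamma^h + [siRNA]^h)\cdot[MX]$ applied to the
targeted species only. The siRNA concentration itself rises
hyperbolically, $[siRNA](t) = [siRNA]_{max}(1 - e^{-r_{siRNA} t})$,
lumping uptake and transport into a single onset rate whose inverse
sets the roughly two-day knockdown timescale. With the reference
parameters the targeted mRNA plateaus at about 22% of its untreated
level (`mrna_knockdown_plateau()` gives the closed form).

### Parameters and units

Time is the model's rescaled unit, approximately minutes;
concentrations are dimensionless and of order one. The three reference
sets `fa_params("PS1")`–`"PS3"` (also shipped as JSON under
`inst/extdata/`) share the RNAi and signalling blocks and differ in
assembly rate constants and translation rates; they were calibrated so
that roughly 30% of connector is actin-bound and maturation takes tens
of minutes. Rate constants span more than five orders of magnitude, so
all integration uses the stiffness-switching `deSolve::lsoda` with
relative tolerance 1e-8 and absolute tolerance 1e-10 — tight enough to
resolve species down to about 1e-3, the smallest level that matters for
any readout here.

## Protocols

**Initial conditions.** Two canonical states select the two bistable
branches (`fa_initial_state()`): the Rac-IC (ACI = RAC = 1, everything
else 0) and the Rho-IC (ACIm = RHO = 1). With the RNA part included the
mRNAs start at 0.5.

**Steady states.** `fa_steady_state()` integrates to t = 999999 and
verifies against the state at t = 500000; the residual is relative with
a scale floor of 1e-3, so convergence demands agreement to 1e-6
relative or 1e-9 absolute, whichever is weaker. Non-convergence is
reported, never silently accepted. This acceptance residual was chosen
so that the summation-theorem check of the sensitivity analysis passes
below 1e-3 whenever the steady state is genuine.

**Timescales.** `time_to_steady()` reports the earliest time after
which all species stay within a relative tolerance (default 5%) of
their final value. Species whose final value lies below a resolution
floor of 1e-2 are measured against the floor instead: trace
concentrations of order 1e-4 (active Rho in a Rac-dominated state) are
biologically invisible and would otherwise dominate the metric.

```{r timescales}
ps1 <- fa_params("PS1")
cfg <- fa_config(include_rna = FALSE)
tr_rac <- fa_integrate(fa_initial_state("rac", include_rna = FALSE),
                       ps1, cfg, t_end = 1000, n_eval = 500)
tr_rho <- fa_integrate(fa_initial_state("rho", include_rna = FALSE),
                       ps1, cfg, t_end = 5000, n_eval = 500)
c(rac = time_to_steady(tr_rac), rho = time_to_steady(tr_rho))
```

Focal complexes assemble on a sub-minute timescale, the maturation to
the Rho state takes tens of minutes, and the knockdown itself (below)
plays out over days — the three separated timescales that structure all
results.

**Knockdowns.** `run_knockdown()` equilibrates the untreated full
model first, then restarts at t = 0 with the siRNA term active and
compares pre- and post-knockdown steady states (reductions in percent;
negative = increase). Pre-equilibration rather than co-starting is
deliberate: the scenario being modelled is treatment of an adhered,
settled cell. Rho knockdown (`run_rho_knockdown()`) instead shrinks
the total Rho pool from 1 to 0.2 with the same onset kinetics as the
siRNA curve — the functional form is our choice, mirroring the mRNA
onset, since only the endpoint and timescale are constrained. The
Z extension (`run_z_knockdown()`) adds a regulator of connector
degradation with dZ/dt = k_Z − d_Z Z and effective rate
d_C · Z/Z<sub>ss</sub>; the defaults k_Z = d_Z = 10 give protein-like
turnover with Z<sub>ss</sub> = 1 and leave the untreated system exactly
unchanged.

## Bistability and bifurcation

```{r bifurcation, eval = FALSE}
bi <- bistable_interval(ps1, fa_config(include_rna = FALSE),
                        "rho_RHO", lo = 0.01, hi = 10, threshold = 0.05)
c(lower = bi$lower, upper = bi$upper)
#>     lower     upper
#> 0.1074608 3.2761228
```

`bifurcation_sweep()` computes steady-state ACIm from both canonical
ICs across a parameter grid; branches are classified by the selecting
IC, not by continuation — the same two-IC procedure that generated the
original diagrams, so unstable branches are intentionally not tracked.
`bistable_interval()` brackets the region where the branches separate
by more than an absolute ACIm threshold (default 0.05) on a 60-point
log grid and refines both edges by bisection to 1% relative precision.
For PS1 the slip-bond window is about (0.11, 3.28); the lower edge is
sensitive to the separation threshold because the branches approach
each other smoothly there, so its second digit should not be
over-read. Above the window both ICs land on the same high-adhesion
state; at large force gain the slip model collapses to a low-adhesion
state while catch bonds keep adhesions high.

## Sensitivity analysis

Concentration control coefficients quantify how a steady-state
concentration responds to scaling one reaction's net rate:
$C^i_k = (\nu_k/S_i)\,\partial S_i/\partial \nu_k$. Because several
rate constants enter more than one reaction ($\delta_A$ appears in both
the complex disassembly and the derived mature-adhesion disassembly
rate), `ccc()` perturbs a dedicated per-reaction multiplier (default 1,
central differences with relative step 1e-3, chosen to balance
truncation error against the 1e-6 steady-state noise; a halved step
moves coefficients by under 1%). Runs in which the perturbed system
jumps to the other bistable branch are detected by disagreeing
one-sided differences and flagged invalid rather than reported.

The summation theorem $\sum_k C^i_k = 0$ (scaling all rates together
only rescales time) is the internal consistency check: `ccc_all()`
reports the residual, below 1e-3 for every converged steady state.

`parameter_path()` explores parameter space by geometric interpolation
$g(q) = g_1^{1-q} g_2^{q}$ between the reference sets, with PS1, PS2,
PS3 at path coordinates p = 0, 1, 2. What lies beyond p = 2 is an open
choice; the builder closes the loop back to PS1 at p = 3, so the
characteristic kinks at integer p (direction changes in parameter
space) appear at every anchor. `ccc_over_path()` evaluates the
coefficients of ACIm with respect to the three mRNA degradation
reactions — computed at the untreated steady state of the full model,
where the RNAi term vanishes and mRNA degradation is a single
well-defined reaction per species. All such coefficients are negative
(knockdown always lowers adhesions); their magnitudes are smaller for
the Rho-IC than the Rac-IC and smaller still under catch bonds — the
adhesion-dominated, catch-bonded state is the most robust to RNAi.

The test suite exercises this ensemble at 5 path points, and
`parameter_path(300)` reproduces the full published ensemble when more
resolution is wanted; the anchor sets are reproduced exactly at integer
p either way.

## What the simulations do and do not show

All quantitative checks in the package run against the model's own
reference parameter sets — printed constants, not data. Passing them
shows that the implementation reproduces the published dynamics
(steady-state levels, bistable window, knockdown reductions and
timescales), not that the model describes any particular cell line:
the species are lumped (one connector stands for dozens of adaptor
proteins), the system is well mixed with no spatial resolution, no
number/size/shape of individual adhesion sites, and siRNA delivery is
reduced to one onset curve. Known numerical limits: branch
classification near the lower bifurcation edge depends on the
separation threshold; control coefficients are undefined where a
species sits at numerical zero or where a perturbation crosses the
basin boundary (both cases are flagged, not guessed).
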