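# fadyn

Kinetic modelling of focal adhesion assembly and RNA interference.

Focal adhesions — the integrin-based contacts that anchor a cell to the
extracellular matrix — assemble hierarchically from actin (A), a lumped
connector component (C; talin, vinculin, paxillin, ...) and integrin
(I), and mature from focal complexes (ACI) into focal adhesions (ACIm)
under contractile force. `fadyn` implements a twelve-species mass-action
ODE model of this process for people designing or interpreting
RNAi experiments on adhesion components: it couples

- hierarchical assembly `A + C ⇌ AC`, `C + I ⇌ CI`, `A + CI ⇌ ACI`,
  `AC + I ⇌ ACI` and force-driven maturation `ACI → ACIm`;
- a per-bond force `F = (χ + ρ_RHO·RHO) / (1 + σ(ACI + m·ACIm))`
  entering the dissociation rates as a Bell factor `e^{(2s−1)F}` —
  slip bonds (`s = 1`) rupture faster under load, catch bonds
  (`s = 0`) slower — the maturation rate as `τ_ACI·F^n`, and the
  focal-adhesion disassembly rate as the derived
  `ε(δ_A + δ_I)/2 · e^{(2s−1)F}`;
- Rac/Rho double-negative feedback (Hill coefficient 4) that makes the
  system bistable between a focal-complex-dominated Rac state and an
  adhesion-dominated Rho state;
- saturating Hill-kinetic siRNA knockdown
  `d·[siRNA]^h/(Γ^h + [siRNA]^h)` of a chosen mRNA, with a hyperbolic
  siRNA onset over roughly two days.

On top of the simulator it provides the paper-grade analyses: the
long-horizon steady-state protocol, one-parameter bifurcation sweeps
with bistable-interval detection, knockdown scenario runners (mRNA
targets, Rho pool depletion, an auxiliary degradation regulator Z),
and metabolic control analysis (concentration control coefficients
with summation-theorem validation) over geometrically interpolated
parameter ensembles.

## Worked example

Connector knockdown in the full model (reference parameter set PS3,
slip bonds, starting from the adhesion-dominated Rho state):

```r
library(fadyn)
ps <- fa_params("PS3")
cfg <- fa_config(slip_fraction = 1, knockdown_target = "MC")
kd <- run_knockdown(ps, cfg, ic_kind = "rho")
kd
#> <fa_knockdown> target: MC  ps: PS3  ic: rho  s: 1
#>          pre    post reduction_pct
#> MA   1.00000 1.00000          0.00
#> MC   1.00000 0.22381         77.62
#> MI   1.00000 1.00000          0.00
#> C    0.10348 0.02316         77.62
#> ACI  0.01399 0.00234         83.26
#> ACIm 0.37766 0.12005         68.21
```

The targeted mRNA falls to 22% of its untreated level (the closed-form
plateau, `mrna_knockdown_plateau(ps$rnai)`, gives 22.38%), the
connector pool follows it almost immediately, and mature focal
adhesions lose about 68% — noticeably less than the ~77% loss of the
upstream species, because Rho signalling and force stabilise the
mature state. Rerunning with `slip_fraction = 0` (catch bonds) drops
the ACIm reduction to about 43%.

The bistability underlying this stability is visible in the assembly
model without RNA turnover:

```r
fa_steady_state(fa_params("PS1"), fa_config(include_rna = FALSE), "rho")
#> <fa_steady_state> converged: TRUE  residual: 2.18e-16
#>       MA       MC       MI        A        C        I       AC       CI
#> 0.000000 0.000000 0.000000 0.272826 0.272473 0.370695 0.098222 0.000353
#>      ACI     ACIm      RAC      RHO
#> 0.033987 0.594965 0.063650 0.999972
```

From the Rac initial condition the same system instead settles at
ACI ≈ 0.35 with essentially no mature adhesions. The bistable window
of the Rho force gain is found with
`bistable_interval(fa_params("PS1"), fa_config(include_rna = FALSE))`.

A thin command-line wrapper over the same functions ships in
`inst/cli/fadyn.R`:

```sh
Rscript inst/cli/fadyn.R knockdown --param-set PS3 --bond slip \
    --ic rho --target MC --out results.csv
```

See the vignette (`vignettes/focal-adhesion-kinetics.Rmd`) for the
model, protocols and numerical choices in full.

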