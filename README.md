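# fdcretention

Stochastic modelling and quantification of antigen retention on follicular
dendritic cells (FDCs).

Germinal centers need a durable antigen depot. FDCs provide it by holding
immune complexes (ICs) through many weak CR2–C3d bonds in parallel: each
bond lives only seconds (`1/k_off ≈ 7 s`), yet the complex persists for
days. This package is for immunologists and modellers who want to
quantify that avidity effect — how the IC retention half-life depends on
CR2 surface density — and to run the accompanying measurement analyses on
their own or synthetic data.

## The model

Bond number `m` on a membrane patch with `n_R` CR2 receptors and `n_L`
accessible C3d sites per IC follows a birth–death master equation

    dP_m/dt = r(m+1) P_{m+1} + g(m-1) P_{m-1} - (r(m) + g(m)) P_m

with unbinding `r(m) = m k_off`, rebinding `g(m) = C(m) k_on`,
all-to-all configuration count `C(m) = (n_R - m)(n_L - m)`, absorbing
state `m = 0` (`g(0) = 0`), and initial mass at `m = min(n_R, n_L)`.
Survival is `S(t) = 1 - P_0(t)`. Receptor counts per patch are Poisson
with mean `<n_R>` (one µm² patch ⇔ density in molecules/µm²); the
observable is `<S(t)> · <n_R>`, the mean IC surface level, and its
half-life. The transient block is solved exactly by eigendecomposition of
its symmetrized tridiagonal form (LAPACK `dstev`), with a stiff banded ODE
fallback where that representation is ill-conditioned, and a seeded
Gillespie simulator as an independent Monte-Carlo check.

Around the model sit the study's measurement computations: global 1:1
Langmuir fits of BLI sensorgrams, equilibrium binding fits,
fluorescent-bead calibration of receptor densities, exponential decay
fits of in-vivo IC levels, ELISA titer transforms, and concentric-shell
quantification of antigen position within follicle images — plus seeded
synthetic generators for every input, so the whole pipeline is testable
without any external data.

## Worked example

```r
library(fdcretention)

p <- bond_params(k_off = 0.15, k_on = 1.6e-4, n_L = 39)
p
#> IC-FDC bond kinetics parameters
#>   k_off      0.15 s^-1   (single-bond lifetime 6.67 s)
#>   k_on       0.00016 s^-1   (effective per-configuration rebinding)
#>   n_L        39 ligands per IC
#>   patch_area 1 um^2

times <- retention_time_grid()
hl <- vapply(c(150, 250, 375), function(d)
  half_life(poisson_mixture_survival(p, d, times)), numeric(1))
data.frame(density = c(150, 250, 375), half_life_h = round(hl / 3600, 2))
#>   density half_life_h
#> 1     150        0.08
#> 2     250        1.21
#> 3     375       36.44
```

A 1.5-fold increase in CR2 density (250 → 375 molecules/µm²) lengthens
the retention half-life ~30-fold — the super-linear avidity effect that
lets small receptor-density differences between FDC subsets decide where
antigen accumulates. The rebinding parameters above come from
`calibrate_rebinding()`, which root-finds `k_on` (and selects the IC
valency `n_L` over 2..128) so the model reproduces observed half-life
anchors at known densities.

The measurement side works the same way from synthetic or measured data:

```r
panel <- gen_sensorgram_panel(616154, 0.15, R_max = 1) # noiseless titration
fit_kinetic(panel)
#> 1:1 kinetic fit: k_on = 616154 M^-1 s^-1, k_off = 0.15 s^-1,
#>   R_max = 1 RU, K_D = 243.4 nM, ssr = 2.46e-15 (9608 points)
```

Here the fit recovers the generating constants exactly; `K_D` is
`k_off / k_on` by definition.

A command-line front end (`inst/exec/fdcretention`, a thin wrapper over
`retention_cli()`) exposes the workflows as subcommands —
`simulate-retention`, `calibrate`, `gillespie`, `fit-bli`, `fit-decay`,
`quantify-shells`, `generate-synthetic` — all driven by YAML configs and
a seed, writing CSV/YAML artifacts with embedded metadata headers.

See `vignettes/antigen-retention-model.Rmd` for the model's assumptions,
the numerical design (eigendecomposition vs. ODE fallback, Poisson
truncation, calibration search), what the synthetic data does and does not
emulate, and known limitations.

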