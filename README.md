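# smtkinetics

Single-molecule tracking (SMT) analysis of protein–DNA binding kinetics in
live bacteria, built around the case of the zinc-uptake regulator Zur in
*E. coli*. The package is for microscopists and quantitative biologists who
track fluorescently tagged DNA-binding proteins in rod-shaped cells and
want to go from localization tables to kinetic and thermodynamic
parameters: diffusion-state populations, DNA residence times, apparent
unbinding rate constants, their dependence on cellular protein
concentration, and the spatial statistics of binding sites.

## What it computes

**Diffusion states.** Per-lapse displacement lengths *r* of a tracked
molecule follow, for a 2D Brownian state with effective diffusion constant
*D* observed with localization precision σ,

    F(r₀) = 1 − exp(−r₀² / (4·D·T + 4σ²)),

so squared displacements are exponential and a mixture of states is a
mixture of exponentials. `fit_mixture()` fits this globally across
concentration groups (shared *D*, free per-group fractions) by maximum
likelihood (EM), resolving the freely diffusing (FD), nonspecifically
bound (NB) and tightly bound (TB) states.

**Residence times.** Runs of consecutive displacements below a threshold
r₀ (0.2 μm captures >99.5% of TB displacements at D_TB = 0.033 μm²/s) give
residence times τ. `fit_dwell_distribution()` models their distribution as
a discrete three-component mixture in which FD and NB passages are
deconvoluted and photobleaching/blinking (rate from the track on-time
distribution, `fit_on_times()`) is corrected, yielding the apparent
unbinding rate constant k₋₁ of the TB state.

**Biphasic unbinding.** Across concentration groups, k₋₁ versus the free
dimer concentration [P]_FD is fitted with the biphasic rate law

    k₋₁ = k_o^off + k_r·(exp(−[P]_FD/K_m) − 1) + k_f·[P]_FD,

where k_o^off is the spontaneous (zero-concentration) unbinding rate
constant, the exponential term is the oligomerization-impeded component
with effective oligomer dissociation constant K_m, and k_f·[P]_FD is the
facilitated (ternary-complex) component. `fit_unbinding()` returns the
parameters with bootstrap errors, compares against the nested
facilitated-only linear law, and locates the rate minimum
P_min = K_m·ln(k_r/(k_f·K_m)), which exists iff k_r > k_f·K_m.

**Populations and concentrations.** `quantify_cells()` converts tracked
counts plus residual photoconverted fluorescence into per-cell dimer
concentrations in a spherocylinder volume model; `fit_population_model()`
fits FD/NB/TB fractions versus concentration with a site-depletion
mass-action isotherm (K_d1, K_d2, site capacities). `residence_sites()`,
`pwdd()` and `ratio_curve()` test residence-site clustering against a
matched uniform null in the same cell geometry.

**Synthetic data.** `simulate_tracks()` / `simulate_cohort()` generate the
whole observation chain — three-state Markov switching, Brownian motion
confined in a spherocylinder, stroboscopic sampling, localization noise,
photobleaching — so every stage is testable with known ground truth.

## Worked example

```r
library(smtkinetics)

geom    <- cell_geometry(total_length = 3.0, radius = 0.5)
scheme  <- kinetic_scheme(D_FD = 6.7, D_NB = 0.82, D_TB = 0.033,
                          k1_on = 2, k_minus1 = 5, k2_on = 5, k_minus2 = 8)
imaging <- imaging_model(k_bleach = 2)   # 40 ms lapse, 20 nm precision

tracks <- simulate_tracks(geom, scheme, imaging, n_molecules = 900, seed = 25)

disp <- displacements(tracks)
fit  <- fit_mixture(disp$r_um, t_lapse = 0.04, sigma_loc = 0.02)
print(fit)
#> 3-state Brownian mixture (mle), logLik = 4514.25
#> D (um^2/s):  FD = 3.884, NB = 0.9932, TB = 0.03515
#> fractions per group:
#>         FD     NB     TB
#> all 0.3316 0.4986 0.1698
```

The TB diffusion constant and the NB state come back close to the inputs;
the apparent FD constant is compressed (3.9 versus 6.7 μm²/s input)
because a free 40 ms step at 6.7 μm²/s is larger than the cell radius —
confinement is a property of the cell, not a fitting artifact.

```r
kb    <- fit_on_times(table(tracks$track_id), t_lapse = 0.04)$k_bleach
taus  <- extract_tau(disp, r0 = 0.2, t_lapse = 0.04)
dwell <- fit_dwell_distribution(taus, fit$D, fit$f[1, ], k_bleach = kb,
                                r0 = 0.2, t_lapse = 0.04, sigma_loc = 0.02,
                                n_boot = 100)
print(dwell)
#> dwell fit: k_minus1 = 5.36 s^-1 (sd 0.359), k_bleach = 2.14 s^-1
#>   1407 events (250 censored); naive inverse-mean rate 13.1 s^-1
#>   weights: FD = 0.128, NB = 0.579, TB = 0.293
```

The simulation unbinds at k₋₁ = 5 s⁻¹; the naive inverse-mean rate
(13.1 s⁻¹) is badly inflated by bleaching and by fast-state passages, and
the dwell model recovers 5.36 ± 0.36 s⁻¹. The rate law itself:

```r
p <- biphasic_params(k_o_off = 22, k_r = 12, k_f = 0.018, K_m = 12)
unbinding_rate(p, c(0, 100, 1000))
#> [1] 22.00000 11.80288 28.00000
rate_minimum(p)
#> [1] 48.2086
```

— unbinding is impeded (22 → 11.8 s⁻¹) as the concentration rises to
100 nM, reaches its minimum at ~48 nM free dimers, and is facilitated
beyond it.

The `analysis/` directory chains the full study on a synthetic cohort:
`01_simulate.R` → `02_quantify_cells.R` → `03_diffusion_states.R` →
`04_residence_unbinding.R` → `05_population_model.R` →
`06_spatial_clustering.R`, each writing its tables under `results/`.

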