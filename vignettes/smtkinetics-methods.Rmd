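---
title: "Models and methods behind smtkinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smtkinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smtkinetics)
```

This vignette is the package's own account of the models it implements:
what is assumed, which knobs matter, what the synthetic-data generator does
and does not emulate, and where genuinely open design choices were made.

## The measurement being modeled

A photoconvertible tag on a DNA-binding protein is tracked in live
rod-shaped bacteria under stroboscopic time-lapse illumination: short
excitation pulses (default 4 ms) separated by a longer lapse (default
40 ms), so that even fast molecules appear as diffraction-limited spots.
Each molecule yields a short 2D localization trajectory that ends when the
tag photobleaches or blinks off. Three kinds of motion are expected: free
cytoplasmic diffusion (FD), diffusion while nonspecifically bound to and
moving on the chromosome (NB), and near-immobility while tightly bound
(TB), whose residual apparent motion reflects chromosome dynamics and
localization error.

## Diffusion-state deconvolution

For a 2D Brownian state with effective diffusion constant $D$ sampled at
lapse $T$ with localization precision $\sigma$ in each of the two
localizations, the squared displacement $r^2$ is exponential with mean
$4DT + 4\sigma^2$. A population mixed over states therefore has

$$P(r \le r_0) = \sum_i f_i\left(1 - e^{-r_0^2/(4 D_i T + 4\sigma^2)}\right).$$

`fit_mixture()` maximizes the $r^2$ likelihood with an EM algorithm.
Key choices:

* **Global fit.** Diffusion constants are shared across all concentration
  groups while fractions are free per group — states are physical
  properties of the protein, populations are not. The EM M-step pools the
  responsibility-weighted means across groups.
* **Likelihood, not curve fitting.** Least squares on the empirical CDF is
  provided (`method = "cdf-ls"`) as a cross-check, but MLE has
  better-behaved weights in the sparse tail. The two agree on clean data;
  the tests exercise both paths.
* **$\sigma$ is fixed, not fitted.** Localization precision is measured
  upstream of this package (default 0.020 µm); letting it float trades off
  directly against $D_{TB}$, whose scale ($4 D_{TB} T \approx
  5\times10^{-3}\,\mu m^2$ versus $4\sigma^2 = 1.6\times10^{-3}\,\mu m^2$)
  is comparable.
* **Initialization and degeneracy.** EM is started from three
  deterministic initializations (equal-count chunks, log-spaced means, and
  their geometric mixture) and the best likelihood wins, so fits are
  reproducible without consuming random-number state. When two components
  converge to nearly the same $D$ (ratio < 1.15) the weight split between
  them is arbitrary; the fit flags this and also reports a merged view
  (`D_merged`, `f_merged`) pooling such duplicates.
* **Errors.** Cell-level bootstrap (`bootstrap_sd()`): localizations
  within a cell are correlated, so the cell, not the displacement, is the
  exchangeable unit.

## Residence times and the dwell model

A residence event is a maximal run of consecutive displacements below
$r_0$ (default 0.2 µm, which captures more than 99.5% of TB displacements
at $D_{TB} = 0.033\ \mu m^2/s$:
`brownian_cdf(0.2, 0.033, 0.04)` $= 0.9995$). Its duration is quantized in
whole lapses, so the likelihood uses the discrete (geometric) form
directly — no binning bias at small $\tau$.

Each frame, a run in state $i$ continues with probability $s_i b$, ends
with an observed above-threshold displacement with probability
$(1-s_i)b$, or is censored by track termination with probability $1-b$,
where $b = e^{-k_{bleach} T}$ and

* $s_{FD} = p_{FD}$, $s_{NB} = p_{NB}$ with
  $p_i = P(r < r_0 \mid D_i)$ from the Brownian CDF — these states produce
  *apparent* residence runs whenever several small displacements happen in
  a row, and the model deconvolutes them;
* $s_{TB} = p_{TB}\, e^{-k_{-1} T}$ — a genuine dwell ends by unbinding.

Censored runs (ending with the track, not with a crossing) contribute only
the continuation factor for their $m-1$ complete frames; the terminal
censoring probability carries no kinetic information and is dropped as a
constant. Getting this right matters: including a crossing-survival factor
for the final censored frame biases $k_{-1}$ low by several percent, and
dropping censored runs altogether biases it high.

The mixing proportions are tied to the diffusion-state fit as **event
rates**: state $i$ produces runs at rate $\propto f_i\, p_i\, (1 - s_i b)$
(below-threshold displacements times runs per displacement). Tying them to
$f_i p_i$ alone — displacement counts rather than run counts — overweights
the long-lived TB component and in end-to-end recovery tests inflated
$k_{-1}$ by roughly a factor of two; the event-rate form recovers the
ground truth. A `weights = "float"` mode frees the proportions for
diagnostics.

The photobleach/blink rate is measured from the track on-time
distribution (`fit_on_times()`, exponential MLE) and held fixed in the
dwell fit. Throughout the package $k_{bleach}$ is the *effective
termination rate on the lapse-time axis* — the quantity the on-time
distribution actually measures — with blinking pooled in; tracks are built
without gap closing, consistently with that convention.

Assumptions and limits: runs are treated as single-state (a molecule that
switches state mid-run is attributed to one component), which leaves a
small upward bias in $k_{-1}$ at high switching rates — the end-to-end
simulation test bounds it at well under the bootstrap error for the
default parameter regime. $k_{-1}$ estimates pinned at the optimization
bounds are flagged non-identifiable rather than returned silently.

## The biphasic unbinding law

The microscopic rate from a site carrying an oligomer of $n$ dimers is
$k^{(n)}_{-1} = k_o + k_r\alpha^n + k_f [P]_{FD}$: an intrinsic term, an
oligomer-stabilized term attenuated by $\alpha \in (0,1)$ per neighbour,
and a facilitated (ternary-complex) term linear in the free dimer
concentration. Averaged over the occupancy distribution in the
weak-oligomerization limit, the apparent rate constant becomes

$$k_{-1} = k_o^{off} + k_r\left(e^{-[P]_{FD}/K_m} - 1\right)
           + k_f [P]_{FD},$$

with $k_o^{off} = k_o + k_r$ the zero-concentration rate and
$K_m = k_o^{off}/(k_1(1-\alpha))$ the effective oligomer dissociation
constant. The curve decreases from $k_o^{off}$, reaches a minimum at
$P_{min} = K_m \ln(k_r/(k_f K_m))$ iff $k_r > k_f K_m$, and grows with
slope $k_f$ — the biphasic signature. `rate_minimum()` reports the minimum
on the free-concentration axis; the mapping to the total-concentration
axis goes through the equilibrium model below, and the package reports
both rather than conflating them.

`fit_unbinding()` is weighted nonlinear least squares (weights $1/sd^2$
from the dwell fits, Levenberg–Marquardt) parameterized as
$k_o + k_r e^{-P/K_m} + k_f P$ with $k_o \ge 0$, which is the same law but
keeps the intrinsic rate physical under noise. A nested linear
(facilitated-only, $k_r = 0$) model is fitted alongside and compared by
AIC so purely linear kinetics are recognized as such. Parameter errors
come from case-resampling bootstrap over the concentration points;
replicates in which $K_m$ collapses onto a bound or $k_r$ exceeds ten
times the data range (typically resamples that lost the low-concentration
points) are non-identifiable and excluded from the spread. The inversion
$\alpha = 1 - k_o^{off}/(k_1 K_m)$ can be infeasible with rounded inputs
and is exposed as a flagged diagnostic (`implied_alpha()`), never clipped.

## Concentrations, populations, geometry

Cell volume uses the spherocylinder closed form
$V = \pi r^2(L-2r) + \tfrac43\pi r^3$; a typical cell (default
$L = 3.0\ \mu m$, $r = 0.5\ \mu m$) has $V \approx 2.1$ fL, and one dimer
in 1.66 fL corresponds to ~1 nM. The per-cell monomer count is
$(n_{tracked} + F_{res}/f_{single})/\eta_{pc}$, halved for the homodimer.
The photoconversion efficiency $\eta_{pc}$ is a configuration value
(default 1 in tests, where it is known exactly; set it to the literature
value for your fluorophore). Cells are grouped by equal-count binning
after a stable sort on concentration — group sizes equal to within one
cell, ties keep input order.

State populations versus concentration are fitted with the simplest
site-depletion isotherm consistent with the parameter set: TB sites of
capacity $[D_0]_{TB} n_o$ and dissociation constant $K_{d1}$ compete with
nonspecific sites ($[D_0]_{NB}$, $K_{d2}$) for free dimers, with
conservation solved by monotone root finding (`uniroot` on a strictly
increasing function, bracketed in $(0, P_{total}]$). The NB/TB partition
ratio $K_{d3}$ is carried as a derived diagnostic, not a free parameter —
at realistic group counts it is not identifiable jointly with the
capacities. How occupancy couples into the isotherm is genuinely open;
this model reproduces the parameter roles (and the competition signature:
$f_{FD}$ rises and $f_{TB}$ falls with concentration, proven monotone in
the property tests) but may differ in functional detail from other
reconstructions. $K_{d1}$ obtained this way should agree with
$k_o^{off}/k_1$ from the kinetic route; the pipeline reports the quotient
as a cross-check.

## Spatial clustering test

Each residence event contributes one site (centroid of the run's
localizations). Within each cell all pairwise distances are computed —
never across cells — and pooled within a concentration group. The null is
an equal count of uniform sites per cell in the same geometry (3D-uniform
in the spherocylinder projected to the imaging plane by default; a
2D-footprint mode exists because which convention upstream analyses use
varies). The statistic is the ratio of the fraction of pairwise distances
within radius $R$, observed over reference, averaged across groups; a
nearest-neighbour variant is available behind a flag and satisfies the
same calibration properties. Under a uniform truth the curve is flat at 1
within Monte-Carlo error; molecular-scale clustering raises it
increasingly toward small $R$. Sites contributed by the same track are
correlated (one molecule can rebind nearby), which leaves a small flat
offset above 1 even for independent binding — visible in the stage-6
analysis script — whereas genuine clustering grows steeply as $R$ shrinks.
Chromosome compaction also enters at a few hundred nanometers; the test's
discriminating regime is $R \lesssim 100$ nm, with ~20 nm localization
precision as the floor.

## The synthetic-data generator

`simulate_tracks()` propagates each molecule with 1 ms steps: state
switching by exact exponential waiting times on the FD/NB/TB generator
(binding treated as pseudo-first-order, so no site bookkeeping), 3D
Brownian motion with the state's $D$, mirror reflection at the membrane,
observation of $(x, y)$ at the pulse midpoint plus isotropic Gaussian
noise, and geometric track termination from the pooled
photobleach/blink rate, capped by the imaging cycle length (default 30
frames). `simulate_cohort()` layers the study design on top: lognormal
cellular concentrations (default median ~290 nM, the concentration scale
at which the displacement statistics it emulates were characterized),
per-cell state fractions from the equilibrium model, and the
concentration-dependent $k_{-1}$ injected from the biphasic law.

What it deliberately does not emulate: camera images and spot detection
(inputs are localizations); motion blur within the 4 ms pulse (at the
relevant $D$ the blur displacement is below the 20 nm precision); z-
dependent detection; gap closing and explicit blinking (pooled into
termination); chromosome structure (TB sites are not spatially fixed
between events, so clustering analyses of simulated cohorts calibrate the
null rather than reproduce oligomer clustering); and photophysical
heterogeneity. Passing recovery tests on this generator therefore
validates the estimators' statistics, not detection systematics of real
microscopes. One consequence shows up immediately in the analysis
scripts: confinement compresses the apparent $D_{FD}$ well below its
input value, since a free 40 ms step at $6.7\ \mu m^2/s$ exceeds the cell
radius. That is faithful to cells, which is why the simulate-and-refit
acceptance checks of the mixture fitter draw displacements from the
unconfined mixture law instead.

## Problem sizes and reproducibility

The test suite and analysis scripts are sized for a desk run: 50,000
displacements for mixture recovery, ~1,000–3,000 residence events per
dwell fit, 8 concentration points for rate-law recovery, a 48-cell cohort
(30 tracks each) for the end-to-end pipeline, and 50–200 bootstrap
replicates depending on the stage. Every stochastic step takes an explicit
seed, sub-seeds are derived deterministically from the configuration seed,
and the pipeline's summary is byte-identical across same-seed reruns —
asserted in the tests.

## Known limitations

* Apparent diffusion constants are not confinement-corrected; in 0.5 µm
  radius cells the FD constant is an effective, compressed value.
* The dwell model attributes each run to a single state; very fast
  state-switching regimes would need a hidden-Markov treatment, which is
  out of scope.
* The equilibrium isotherm ignores explicit oligomer occupancy
  distributions; $n_o$ enters only through the capacity product
  $[D_0]_{TB} n_o$ (default $n_o = 5$).
* Bootstrap errors assume cells (or points) are exchangeable; systematic
  day-to-day instrument variation is outside the resampling unit.
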