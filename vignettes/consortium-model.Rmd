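---
title: "An individual-based model of a sucrose-mediated synthetic consortium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An individual-based model of a sucrose-mediated synthetic consortium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The system

`consortsim` simulates a two-member synthetic microbial community in a thin
(100 x 100 x 10 um) chamber: a cyanobacterium engineered with an inducible
sucrose-export pathway (an *S. elongatus* CscB/SPS-type strain) and a
heterotroph that uses the secreted sucrose as its sole carbon source (an
*E. coli* W-type strain). The phototroph fixes CO2 and, under induction by
IPTG, diverts a large fraction of fixed carbon to extracellular sucrose — a
public good that supports the heterotroph. The package asks two kinds of
question of this system: how the induction level shapes the population
dynamics and steady-state composition of the consortium, and how much of a
colony's eventual fitness is already decided by the initial spatial
arrangement of the founder cells.

## The model

**Cells** are spherical agents with position, mass and a volume-equivalent
diameter tied to mass through a fixed species density
(`mass = density * pi/6 * d^3`). Each cell grows exponentially at its local
specific growth rate, `dm/dt = mu * m`, integrated exactly per step
(`m <- m * exp(mu * dt)`). A cell divides when its diameter reaches the
species' maximum volume-equivalent diameter (1.94 um for the
cyanobacterium, 1.39 um for the heterotroph); the mass splits into
fractions `f` and `1 - f` with `f ~ Uniform(0.45, 0.55)` — the model is
silent on the split, and a stochastic near-even split avoids artificial
division synchrony. Daughters separate along a uniformly random direction
by the sum of their radii and inherit the parent's founder label, which is
how colonies are tracked: a colony is a founder lineage, with no spatial
re-clustering.

**Kinetics.** The cyanobacterial growth rate is double-Monod in light and
CO2 with an empirical induction burden:

    mu = mu_max * [light]/(K_light + [light]) * [CO2]/(K_CO2 + [CO2])
         * (0.141 * exp(-[IPTG]/0.063) + 0.9)

so growth runs from 1.041 x mu_max uninduced down to 0.9 x mu_max at full
induction. The sucrose secretion flux is proportional to growth,

    Psi = mu * (-3.4897 * exp(-[IPTG]/0.048) + 3.4092),

clamped at zero: the raw factor is slightly negative near zero inducer and
sucrose uptake by the phototroph is not part of the model (the package
warns when the clamp engages). At 1 mM IPTG the secreted fraction of fixed
carbon, `Psi / (mu + Psi)`, is 0.773. The heterotroph grows double-Monod
on sucrose and O2 and carries a maintenance coefficient `m` whose
respiration persists when growth stalls. Source/sink terms couple the
cells to the fields: CO2 consumption `-(1/Y)(mu + Psi) rho` and O2/sucrose
production for the cyanobacterium; sucrose/O2 consumption and CO2
production for the heterotroph (stoichiometric coefficients 0.727, 0.65,
0.399, 0.2 are fixed constants of the model). IPTG is a global
per-simulation scalar, not a diffusing field: it enters only the two
empirical response terms and has no transport parameters.

**Nutrient fields** obey `dS/dt = div(D grad S) + R` on a uniform Cartesian
grid. Light and the dissolved gases have Dirichlet walls (an optically
transparent, gas-permeable chamber: light 0.1, CO2 3e-2, O2 9e-3 kg/m^3)
and light is a fixed, non-depletable field — at 10 um thickness neither
attenuation nor cell shading is represented. Sucrose starts at effectively
zero (1e-20 kg/m^3) with zero-flux Neumann walls: it can only leave by
consumption. Diffusion coefficients are not part of the published
parameter set; the package defaults to standard dilute aqueous values
(sucrose 5.2e-10, CO2 1.9e-9, O2 2.3e-9 m^2/s), all config-overridable.

## Numerical scheme

Nutrient diffusion across the 100 um chamber equilibrates in tens of
seconds, far faster than growth (hours), so the driver uses quasi-steady
operator splitting per biological step (default `dt_bio = 600` s, much
shorter than the ~10 h doubling time): rates are evaluated at the
step-start concentrations, the fields are updated with those rates, and
the cells then grow at exactly the rates — including any sink-limiting
scalings — that debited the fields. This closes the nutrient ledger:
consumption uses the effective per-step rate `(e^(mu dt) - 1)/dt`
(identical to `mu` as `dt -> 0`), so the sucrose a voxel loses is `1/Y`
times the biomass its cells gain, and where the solver scales sinks back
to keep a voxel non-negative the cells' mass gain is reduced by the same
factor. Schemes that instead grow cells at rates re-evaluated on the
updated fields were tried and rejected: during fast transients they
credit biomass with sucrose that was never debited (a growth-rate sweep
at 50x the default heterotroph rate inflated the population ratio
several-fold), and iterating them oscillates in the stiff late-stage
regime where one step's consumption capacity dwarfs the standing sucrose
stock. A stability cap additionally shortens the step to `0.2 / max
specific turnover rate`; at the default parameters the cap (~2300 s)
never engages. The field relaxation iterates implicit-Euler pseudo-time
steps —
each a sparse Cholesky backsolve of the 7-point Laplacian system, with
the factorization cached — until the relative change per sweep is below
1e-6.
Sucrose is handled differently: with zero-flux walls and a net secretion
source it has no steady state, so it is time-integrated over the
biological step with the same unconditionally stable implicit scheme
(mass-conserving up to the applied source). Sinks are limited per sweep so
no voxel is driven below zero at high cell density; the solver raises an
error naming the nutrient if the residual grows over 10 consecutive
sweeps.

The voxel size defaults to 2 um (the grid resolution is not part of the
published description; 2 um divides the default domain into 50 x 50 x 5
voxels). Cell overlaps created by growth and division are resolved by a
pairwise shoving relaxation (half the overlap along the centre line per
pair, cell-list neighbour search, positions clamped to the box). The
driver stops shoving once the largest overlap is below `relax_tol`
(default 5e-3 um, well under 1% of a cell diameter); tighter tolerances
make shoving cascades in dense colonies disproportionately expensive
without changing population-level results.

Runs stop at 100 h simulated time or 1.5e7 fg total biomass, whichever
comes first, so the chamber never fills; the stop criterion is recorded.

## Spatial metrics and fitness

All spatial features are computed at t = 0 from the founder layout:
nearest-neighbour distance, per-colony mean inter-colony distance (IC),
their ratio, inverse and log-inverse-squared neighbour distances, a scaled
inter-colony distance `zeta = IC / sqrt(D / mu_max)` (IC in metres), the
planar Voronoi tessellation area clipped to the chamber footprint, and the
3D distance from the chamber centre. Conventions the package fixes where
the formulas admit more than one reading: IC is per-colony (the mean of
the subject's distances to all others) because fitness is analysed
per-colony; the log uses base e (any base shifts the feature by a constant
factor, which a regression absorbs); `zeta` uses the dimensionless
diffusion-length scaling with species-specific primary nutrient and
growth rate (sucrose and the heterotroph's mu_max for heterotroph
colonies, CO2 and the cyanobacterial mu_max for phototroph colonies);
distances are 3D while the Voronoi tessellation is 2D in the xy plane, the
domain being only 10 um thick. Species-restricted variants of the
neighbour distances (to cyanobacterial and to heterotroph neighbours) are
computed alongside the unrestricted ones. A colony with no eligible
neighbour for a metric gets an undefined sentinel; such rows are dropped
from the regression table (not imputed) and counted.

Colony fitness is the summed mass of a founder's descendants at the end of
the run; the per-colony values partition the final biomass exactly, which
the test suite asserts for every simulation.

## Fitness regression

The regression maps the 15-column feature table (species indicator,
initial biomass, IPTG, the distance metrics, Voronoi area, distance from
centre) to fitness with a multilayer perceptron: input standardization,
three hidden layers of 512 ReLU units, batch normalization, dropout 0.5,
L2 penalty 1e-4, linear output, mean-squared-error loss. Data are split
70/15/15 into train/validation/test at the row (colony) level. Training
details the architecture description leaves open are package defaults, all
exposed: Adam with learning rate 1e-3, minibatch 256, early stopping on
validation loss with patience 20. The network is implemented in base R
matrix arithmetic; backpropagation (including the batch-norm backward
pass) is verified against central-difference numerical gradients in the
test suite. After training, batch-norm statistics are recalibrated to the
exact population statistics of the training set under the final weights
("precise" batch normalization): momentum-averaged running statistics lag
the weights and noticeably degrade held-out predictions, while the
recalibrated statistics match the dropout-free inference pass. Feature
importance is measured by permutation: the mean drop in test R^2 over
repeated shuffles of one feature column.

## Calibration

The induction-response coefficients are fit in two sequential steps —
growth first, then secretion with the growth result frozen — by bounded
derivative-free minimization. Each objective evaluation averages at least
3 stochastic batch-culture simulations with fixed per-replicate seeds
(common random numbers keep the objective deterministic). The default
optimizer is seeded Nelder-Mead with a penalty outside the bounds; the
optimizer slot is deliberately black-box so any derivative-free minimizer
can be substituted. Biomass curves enter the loss as fold-growth over
inoculum (normalized by their t = 0 value), which removes the latent
random inoculum size from the comparison; sucrose curves enter on their
absolute scale. Because the underlying wet-lab time series exist only as
figure points, calibration is validated by parameter recovery on synthetic
curves generated by the model itself: noiseless growth and sucrose series
across six inducer levels, from which the generating coefficients are
recovered (growth side to ~1e-5 relative, secretion side within a few
percent; the residual on the secretion side is the irreducible
inoculum-size stochasticity). Single-substrate Monod constants are fit by
Levenberg-Marquardt least squares. Note the published parameter set
carries two values for the CO2 half-velocity constant (1.38e-4 kg/m^3 in
the growth-parameter table, 8.1e-3 g/L from a supplementary single-factor
fit); the package defaults to the table value and leaves the other
available through the config.

## What the synthetic data do and do not show

The batch-culture generator used for calibration is well-stirred and
assumes saturating light and CO2, so it exercises the inducer-response
terms and the stochastic inoculum, but none of the spatial physics. The
randomly seeded chamber simulations used for the regression study carry
the full spatial model but inherit its idealizations: no light shading, no
cell death or motility, hard-wall placement, spherical cells (rod shapes
change colony morphology and are out of scope), Monod-only metabolism with
no additional exchanged metabolites. Passing tests therefore demonstrate
internal consistency of the implementation and recovery of planted
structure, not agreement with wet-lab measurements beyond the published
parameter values used as inputs.

## Problem sizes used by the test suite

The shipped tests scale the study designs down so the whole suite runs on
one CPU in tens of minutes, as a package choice: the steady-state and
growth-rate-sweep checks run the simulator at 5 um voxels, 1200 s
biological steps and 25 shoving passes (on the benchmark co-culture these
settings reproduce the default-resolution final ratio to three
significant figures and the time-to-steady-state within 1%); the
co-culture convergence runs keep the study's full 100 founders, because
the founder count — unlike the solver resolution — measurably shifts how
fast heterotroph-heavy seedings settle; the regression study uses 150
random simulations with a 24 h horizon in place of the full-scale 1,000
100-h runs, and accepts a lower test R^2 (>= 0.85) than the full-scale
study reports. The acceptance script (`scripts/acceptance.R`) runs the
six-ratio steady-state study at 100 founders and the full 100 h / 1.5e7 fg
stop rule.

## Known limitations

Strongly heterotroph-heavy seedings (around 1:9 phototroph:heterotroph
by count) settle the slowest in this model: the heterotroph excess
cannot shrink (there is no mass decay), so the biomass ratio undershoots
while the phototroph founders build up the sucrose supply and then
recovers asymptotically — roughly 2.9 simulated days to the +-5% steady
band at 100 founders versus 2.1-2.5 for balanced or phototroph-heavy
seedings, and slower still if the total founder count is reduced. Dense
late-stage populations (tens of thousands of cells) make the
shoving relaxation the dominant cost; the pass budget bounds it at the
price of transiently tolerated sub-tolerance overlaps. The quasi-steady
gas fields assume diffusion is infinitely fast relative to one biological
step, which slightly smooths sharp transients at high induction. The
regression's per-species accuracy is consistently lower for the
heterotroph than for the phototroph — heterotroph fitness depends on the
evolving sucrose field, which the t = 0 features summarize only coarsely.
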