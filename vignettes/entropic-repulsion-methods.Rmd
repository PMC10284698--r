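---
title: "Methods: quantifying entropic repulsion of sterol surface layers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying entropic repulsion of sterol surface layers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sterolentropy)
```

## The scientific question

Spin-coated sterol multilayers (SCLs) expose an interface whose molecules
keep their orientational mobility: interfacial cholesterol can tilt, wag and
even invert its polar hydroxyl head in response to the environment. When a
protein or a bacterial cell adsorbs, these orientational fluctuations must be
frozen, which costs entropy. The package quantifies that entropic repulsion
along five independent routes, each driven by a synthetic-data generator so
the whole chain is reproducible without instrument data:

1. **Adaptation kinetics** — contact-time-dependent adhesion forces follow an
   order-n site-adaptation law; third-order kinetics indicate cooperative
   trios of sterols.
2. **Adsorption thermodynamics** — the temperature dependence of the Gibbs
   energy of adsorption yields the entropy of adsorption per surface, and the
   SCL-minus-control difference is the entropic barrier.
3. **Geometric entropy** — a closed-form estimate of the same penalty from
   the ratio of constrained to fluctuating interfacial areas.
4. **Rotor simulations** — a coarse-grained Metropolis model of the
   interfacial layer reproduces back-reorientation, short-range orientational
   correlation and interfacial roughness.
5. **FRAP mobility** — lateral diffusion of the layer from spot-bleach
   recovery.

A sixth stage aggregates multi-assay bioadhesion results into a per-surface
index.

## Kinetics of interfacial adaptation

The density of not-yet-adapted cooperative sites decays as
$\mathrm{d}\sigma/\mathrm{d}t = -k\,\sigma^n$, with the closed form
$\sigma(t) = \sigma_0\,[1 + (n-1)\,k\,\sigma_0^{\,n-1} t]^{-1/(n-1)}$ for
$n > 1$. The measured force is proportional to *adapted* sites,
$F(t) = F_\infty\,(1 - \sigma(t)/\sigma_0)$: this is the only reading under
which force grows with contact time, so the package adopts it throughout.
$k$ and $\sigma_0$ are not separately identifiable from force data; the
fitter estimates the lumped rate $\kappa = k\,\sigma_0^{\,n-1}$ and the
saturation force.

Order selection uses AICc (curves have at most 16 points) with ties broken
by residual sum of squares. The best-fit curves of neighbouring orders
differ by well under 1% of $F_\infty$, while single-curve noise is 5%, so
order discrimination from one curve is impossible in principle. The package
therefore pools replicate curves into a mean curve with empirical standard
errors (`pool_curves()`), exactly as repeated force-spectroscopy experiments
are reduced to mean ± s.e.m. before regression; with 100 pooled curves on a
12-point, 0–60 s grid the generating third order is recovered in about 95%
of replicate experiments. Both per-curve and pooled modes are available.

Generator defaults: $n = 3$, $k = 0.15$ (half-recovery near 10 s, matching
the observed rise within a 60 s contact window), $F_\infty = 2$ nN,
multiplicative lognormal noise with 5% coefficient of variation (unit mean,
so the noise-free expectation equals the model).

## Adsorption thermodynamics and the entropic barrier

Areal masses come from QCM frequency shifts via the rigid-film Sauerbrey
relation $\Delta m = -C\,\Delta f/n$ with
$C = \sqrt{\rho_q \mu_q}/(2 f_0^2) \approx 17.7$ ng cm$^{-2}$ Hz$^{-1}$ for a
5 MHz crystal; no viscoelastic modelling is attempted. Coverage
$\theta = \Gamma/\Gamma_{max}$ is inverted through a Langmuir isotherm at
mole-fraction standard state, $K = \theta/[(1-\theta)x]$, and
$\Delta G = -RT\ln K$. The standard-state convention shifts $\Delta G$ by an
additive constant only; all conclusions rest on $\Delta G(T)$ *slopes*
($\Delta S$), which are convention-invariant. $\Delta H$ and $\Delta S$ come
from the linear fit $\Delta G = \Delta H - T\Delta S$, and the barrier is

$$\Delta S_{chol} = \Delta S_{SCL} - \overline{\Delta S_{controls}},$$

with quadrature error propagation. Both thiol-SAM controls enter through
their arithmetic mean, as both are orientationally fixed.

The generator applies the barrier (default $-200$ J mol$^{-1}$ K$^{-1}$)
only to SCL-class surfaces and adds an enthalpy–entropy compensation offset
$\Delta H_{offset} = \Delta S_{barrier}\,T_{ref}$ ($T_{ref}$ = mid-range
temperature) to the same surfaces. Without it, a 200 J mol$^{-1}$ K$^{-1}$
entropy difference at a common $\Delta H$ would push one surface class to
$\theta \approx 0$ or $\theta \approx 1$, where the isotherm cannot be
inverted; the offset keeps both classes at measurable mid-range coverage
while leaving every slope — and therefore the recovered barrier — untouched.
Defaults (six temperatures 288–313 K, three replicates, 2% relative mass
noise, lysozyme at bulk mole fraction $1.26\times10^{-7}$, i.e. 100 µg/ml,
$\Gamma_{max} = 250$ ng cm$^{-2}$) describe the temperature window in which
protein conformation is stable. The recovery chain is unbiased across
replicates and resolves the barrier to a few J mol$^{-1}$ K$^{-1}$, far
inside the $\pm 60$ experimental uncertainty.

`estimate_gamma_max()` provides a plateau-based capacity estimate for
imported tables that approach saturation; generated tables carry their
capacity as a known calibration input.

## Geometric entropy estimate

Freezing one cooperatively fluctuating unit reduces its accessible
interfacial area from $A_{fluct}$ to $A_{constr}$, costing
$\Delta S = R\ln(A_{constr}/A_{fluct})$ per unit. The default geometry is a
reconstruction from sterol dimensions consistent with the cooperative-trio
picture: the constrained state presents the upright molecular cross-section
($A_{constr} = 0.38$ nm$^2$, which is also the per-molecule lattice area of
128 molecules in a 7.1554 nm box), the fluctuating state explores an area of
the order of the molecular dimension ($A_{fluct} = 1.9$ nm$^2$), units are
trios, and a lysozyme-sized footprint (~13.5 nm$^2$) constrains 12 trio
units. This gives $12\,R\ln(0.38/1.9) = -160.6$ J mol$^{-1}$ K$^{-1}$ per
adsorbing protein — consistent with the measured barrier. The estimator is
exactly antisymmetric under area exchange, and every input is exposed, so
alternative geometries are one call away.

`hydrogen_bond_equivalent()` expresses a penalty as $T|\Delta S|/E_{HB}$;
the hydrogen-bond energy default of 20 kJ mol$^{-1}$ is a conventional
mid-range value and is configurable. The $-200$ J mol$^{-1}$ K$^{-1}$
barrier at 310 K is worth about three hydrogen bonds.

## The rotor model

The simulator replaces atomistic dynamics with the smallest model that
reproduces the phenomenology: molecules are unit orientation axes
$\mathbf{u}_i$ plus head-height offsets $\delta z_i$ on a fixed near-square
lattice (128 per layer in a 7.1554 × 7.1554 nm box, four layers stacked as
two double layers with heads down at the substrate, head-to-head between
double layers and heads toward water on top). Only the water-facing layer is
mobile, mirroring the restraint of the lower layers on a solid support. The
energy in units of $kT$ is

$$E = -J\sum_{\langle ij\rangle}\mathbf{u}_i\cdot\mathbf{u}_j
      - h\sum_i u_{iz} + \tfrac{1}{2} k_z \sum_i \delta z_i^2 .$$

Metropolis proposals are symmetric small-angle axis rotations (a folded-
normal angle about a uniformly random perpendicular direction), axis
inversions and Gaussian height steps; each satisfies detailed balance, and a
subsample of proposal energies, acceptance probabilities and decisions is
logged so the acceptance rule can be verified on every run. Proposals that
carry an axis across the equator pay an additional `flip_barrier`: because
the penalty applies in both directions it leaves the stationary distribution
untouched and acts purely kinetically, exactly the distinction between
analogues that can and cannot re-orient on the accessible timescale.

Preset constants were calibrated once and frozen: $J = 0.5\,kT$ and
$h = 0.1\,kT$ place the interfacial layer in the regime where the lateral
orientation correlation decays below $1/e$ of its first-bin value within
about 1 nm (an orientational cooperativity of two to three molecules), with
flip barrier 0 and $k_z = 20\,kT$ nm$^{-2}$ for cholesterol-like behaviour
versus 15 $kT$ and 80 $kT$ nm$^{-2}$ for the stigmasterol-like control.
Under these presets a 10% reverted start (13 of 128 molecules, matching the
steered-start protocol) fully recovers for cholesterol within a 20 000-sweep
relaxation run while the stigmasterol preset recovers none, and the
cholesterol interface is about twice as rough (late-time head-height RMSD
0.31 vs 0.15 nm).

Two conventions deserve note. First, the correlation function is the plain
mean dot product $C_r(d) = \langle \mathbf{u}_i\cdot\mathbf{u}_j\rangle$
(first-rank), computed over minimum-image lateral distances with empty bins
flagged rather than zeroed; a second-Legendre variant is available. The
plain estimator has a plateau at the squared net orientation $m^2$, so a
decaying $C_r$ requires weak net polarity — the calibrated regime. Second,
reorientation events are detected with a 60°/120° hysteresis band so that
angular noise around the equator never counts as a flip; the RMSD reference
is the first analyzed frame (a time-mean reference is available).

Monte Carlo sweeps are an abstract timescale: the model makes no claim of
quantitative correspondence to the microsecond atomistic dynamics, only to
the ordering of behaviours between analogues (relaxation vs arrest,
rough vs smooth).

## FRAP mobility

The generator releases Brownian tracers (default 100 000, keeping in-spot counting noise near 2% per frame) in a periodic
60 µm field, darkens everything inside a 10 µm disc at $t = 0$ and records
the normalized bright fraction inside the disc at 1 s intervals for 300 s.
Bleaching is binary and instantaneous and there is no acquisition bleaching,
matching the assumptions of the fitted model. Recovery is fitted with the
closed-form uniform-disc pure-diffusion solution
$f(t) = e^{-2\tau_D/t}\,[I_0(2\tau_D/t) + I_1(2\tau_D/t)]$ scaled by the
mobile fraction, and $D = w^2/(4\tau_D)$ with $w$ the spot radius. The
closed form is testable against a direct Bessel-series oracle and is a
deliberate methodological substitution for transform-based reference tools;
for an ideally bleached disc the two agree within the acceptance band used
here. Finite-field effects (the bleached population dilutes the reservoir by
about 2%) surface as a fitted mobile fraction slightly below 1 rather than
as a bias in $D$. Flat curves are flagged immobile instead of fitted; the
median recovered $D$ at a true 0.35 µm$^2$ s$^{-1}$ is within 15% of truth
across replicate simulations.

## Bioadhesion index

Replicate assay values (two bacterial-adhesion assays, three
protein-adsorption assays) are averaged per surface × assay, divided by the
reference SCL's mean for the same assay, and aggregated by arithmetic mean —
so the reference surface scores exactly 1 whatever the data. A geometric-
mean aggregation is available behind a flag, and medians can replace means
in the normalization (counting workflows sometimes normalize to a median
reference); the mean is the default and every report states the choice. The
index is invariant to per-assay rescaling and to assay order. The separate
reference value aggregates the bare-substrate control of each assay class
(SiO₂ for bacterial counts, gold for protein adsorption) normalized the same
way. Cell counts convert to densities as count × 10⁶ / area(µm²).

## What the generators do and do not emulate

The generators reproduce the statistical structure the analyses rely on:
order-n force kinetics with multiplicative noise, Langmuir adsorption with a
class-specific entropic term, a fluctuating quasi-2D orientational lattice,
ideal-disc FRAP, replicate assay tables. They do not emulate instrument
drift, baseline subtraction, cantilever calibration, viscoelastic QCM
response, protein conformational change (the reason the barrier is defined
on lysozyme), molecular exchange between layers, or photophysics beyond
binary bleaching. Passing tests therefore demonstrate that the analysis
chain is correct and well-conditioned under the stated models — not that
those models exhaust real instrument data.

## Numerical choices and problem sizes

Fits use Levenberg–Marquardt least squares with analytic model evaluation;
nonlinear fits report Jacobian-based standard errors, and degenerate inputs
(zero-force series, flat FRAP curves, saturated coverage, single-temperature
tables) are flagged or rejected with explicit messages rather than fitted.
Every generator seeds R's RNG from its own `seed` parameter and restores the
caller's RNG state, so all outputs are bitwise reproducible. The test suite
and the analysis scripts use 100-curve kinetic experiments, 200-replicate
barrier recoveries, rotor runs of 10⁴–10⁵ sweeps (the acceptance script uses
5 × 10⁵ sweeps for the correlation decay) and 100 000-tracer FRAP fields —
sizes chosen so each stage resolves its target quantity an order of
magnitude more finely than the tolerance against which it is checked.

## Known limitations

- The rotor model's weak-polarity regime under-represents the net head-up
  order of a real sterol–water interface; it is the price of a decaying
  first-rank correlation function and does not affect the kinetic contrast
  between presets.
- The Langmuir inversion requires sub-saturation coverage; strongly
  saturated adsorption data cannot be pushed through the chain.
- $A_{constr}$, $A_{fluct}$ and the footprint count of the geometric
  estimate are geometric reconstructions, not fitted quantities; the
  estimator should be read as an order-of-magnitude consistency check.
- The Soumpasis fit assumes an ideally bleached uniform disc; soft-edged or
  partially bleached spots bias $\tau_D$ and need the double-normalization
  route for imported data.
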