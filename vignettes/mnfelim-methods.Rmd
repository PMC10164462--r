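---
title: "Iron-manganese co-limitation in a multi-PFT quota box model: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iron-manganese co-limitation in a multi-PFT quota box model: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnfelim)
```

## The scientific problem

In the Southern Ocean both dissolved iron and dissolved manganese are
strongly depleted: surface dMn falls below 0.4 nmol l⁻¹ in the 60–70°S
band, while dZn is high south of the Polar Front. Manganese sits at two
choke points of phytoplankton physiology: four Mn atoms form the
water-oxidizing cluster of every photosystem II, and Mn is the cofactor
of the superoxide dismutase (MnSOD) that detoxifies the reactive oxygen
species (ROS) generated when photosynthetic electron flow leaks to
molecular oxygen — a leak that widens under iron stress. Iron scarcity
therefore does not only limit growth directly; it raises the manganese
a cell needs to survive. `mnfelim` implements this physiology for three
phytoplankton functional types (PFTs: diatoms, nanophytoplankton,
picophytoplankton) inside a desk-scale seasonal box model, and runs a
factorial set of trait experiments that probe how antenna size,
transporter competition and oxidative-stress strategies shape the
footprints of Mn and Fe deficiency and the biological carbon pump.

## Manganese requirement and use efficiency

The required Mn quota splits into a basal (maintenance) term and a
photosynthetic term proportional to the number of PSII reaction centres
per unit carbon:

$$Q_{Mn,req} = Q_{Mn,min} + 4\,\frac{\mathrm{Chl{:}C}}{\mathrm{Chl{:}PSII}},$$

with Chl:C converted from mg mg⁻¹ to mol mol⁻¹ (molar masses 893.5 g
mol⁻¹ for chlorophyll *a*, 12.011 g mol⁻¹ for carbon) and the result in
µmol Mn (mol C)⁻¹. The default antenna size is Chl:PSII = 1000 mol
mol⁻¹ and the default basal quota 1 µmol Mn (mol C)⁻¹. Manganese use
efficiency is the carbon produced per catalytic Mn atom per unit time,

$$\mathrm{MnUE} = \mu / Q_{Mn,req},$$

so `manganese_use_efficiency(mu, req) * req == mu` holds to machine
precision by construction, and a larger antenna (more chlorophyll per
reaction centre) always lowers $Q_{Mn,req}$.

A cell is *Mn-deficient* when $Q_{Mn}/Q_{Mn,req} < 1$; deficiency is
distinct from *limitation*, which refers to the nutrient whose
constraint actually binds realized growth. The *potential* Mn
deficiency asks what the requirement would be if iron were replete; we
evaluate the requirement at the growth rate with the Fe constraint
removed,

$$Q_{Mn,req}^{MAX} = \mu_{noFe} / \mathrm{MnUE},$$

which collapses to $Q_{Mn,req}$ when Fe is not the binding constraint
and exceeds it otherwise, making the potential-deficiency ratio
pointwise the more pessimistic metric. (The growth rate entering this
expression is stated ambiguously in the literature this model builds
on; we adopt the reading — requirement at Fe-replete growth — that
reproduces the stated purpose of the metric and its documented
inequality against actual deficiency.)

## The MnSOD/ROS balance

The fraction of photosynthetic electron flow leaking to O₂ is a step
function of the cellular Fe status, measured by the Fe-deficiency ratio
$Q_{defFe} = (Q_{Fe}-Q_{Fe,req})/Q_{OptFe}$: $\epsilon_p = 0.30$ when
$Q_{defFe} < 1$ and $\epsilon_p = 0.05$ when $Q_{defFe} \ge 1$ (the
boundary belongs to the replete branch; no interpolation). ROS
production scaled by the photosynthetic energy rate $v_e$ must be
balanced by consumption through MnSOD:

$$\omega = \frac{\epsilon_p v_e - \epsilon_a v_{ROS}}
               {\epsilon_p v_e + \epsilon_a v_{ROS}}, \qquad
  v_{ROS} = k_{cat}^{ROS}\,[\mathrm{MnSOD}],$$

and the steady state $\omega = 0$ gives the closed form

$$[\mathrm{MnSOD}] = \frac{\epsilon_p v_e}{\epsilon_a k_{cat}^{ROS}}.$$

We use the light-limited growth rate as the proxy for $v_e$. Neither
$\epsilon_a$ nor $k_{cat}^{ROS}$ is observationally constrained for
Southern Ocean taxa; the shipped calibration fixes their product so
that an Fe-replete cell at the 1 d⁻¹ reference growth needs a MnSOD
basal quota of exactly 1 µmol Mn (mol C)⁻¹ — the control basal quota —
which keeps the MnSOD configuration comparable to the control wherever
cells are Fe-replete ($\epsilon_a = 1$, $k_{cat}^{ROS} = 0.05$ d⁻¹ per
unit MnSOD, one catalytic Mn per accounted MnSOD unit). Under Fe
deficiency the demand is amplified by exactly
$\epsilon_p^{max}/\epsilon_p^{min} = 6$ at equal $v_e$.

When the MnSOD pathway is active, this SOD-derived maintenance quota
*replaces* the constant basal quota rather than adding to it, subject
to a floor at the control basal value representing non-SOD Mn
maintenance demands (other Mn enzymes). The floor guarantees that
activating the pathway never lowers any cell's Mn requirement — without
it, slow-growing Fe-replete cells would need less Mn than the control
basal quota, an artefact of extrapolating the reference calibration to
low growth. The raw SOD quota (`basal_mn_quota_from_sod`) is left
un-floored so the 6× amplification identity is exact at that level.

## Host physiology (the quota model around the Mn layer)

The Mn equations live inside a deliberately simple Droop-style host:

* **Light**: a saturating growth–irradiance law,
  $v_e = \mu_{max} f(T)\,(1 - e^{-\alpha\,\theta\,I /(\mu_{max} f(T))})$,
  with $\theta$ the Chl:C ratio and $f(T)$ an Eppley-style exponential
  (base 1.066, reference 20 °C).
* **Photoacclimation**: Chl:C relaxes (0.5 d⁻¹) toward a target that
  falls with irradiance and rises under nutrient-replete conditions,
  clamped to $(\theta_{min}, \theta_{max}]$.
* **Quota limitation**: Droop factors
  $\mathrm{lim}_X = \mathrm{clamp}((Q_X - Q_{X,min})/(Q_{X,req} - Q_{X,min}))$
  for N, P, Si and Fe, and the ratio form
  $\mathrm{clamp}(Q_{Mn}/Q_{Mn,req})$ for Mn; realized growth is the
  Liebig minimum $\mu = v_e \min_X \mathrm{lim}_X$, and $\mu_{noFe}$
  applies the same rule with the Fe term removed. The minimum (rather
  than a product) keeps "limiting" and "deficient" distinct.
* **Fe requirement**: $Q_{Fe,req} = Q_{Fe,min} + (3 + 12/r)\,
  \mathrm{Chl{:}C_{mol}}/\mathrm{Chl{:}PSII}$ with $r$ the PSII:PSI
  ratio. The default $r = 1$ gives 15 Fe atoms per PSII-normalized
  photosystem unit; $r$ is assumed fixed, so antenna-size experiments
  move the Mn and Fe requirements in parallel.
* **Uptake**: Michaelis–Menten in the dissolved pool with linear quota
  satiation. Mn uptake carries dissolved Zn as a competitive inhibitor
  on the shared transporter
  ($K_{Mn}^{eff} = K_{Mn}(1 + \mathrm{dZn}/K_{I})$, $K_I = 2$ nmol
  l⁻¹), and internal Zn above a hyperaccumulation threshold (15 µmol Zn
  (mol C)⁻¹) downregulates transport smoothly toward a floor of 0.2
  (exponential response, steepness 2). In the control only Zn uptake is
  downregulated; the corresponding trait experiment extends the same
  factor to Mn uptake.

## Trait experiments

Nine configurations: a control plus eight single-trait variants.
Antenna experiments override Chl:PSII for all PFTs — *larger antenna =
higher Chl:PSII* (2000 mol mol⁻¹; fewer reaction centres per unit
chlorophyll, lower Mn *and* Fe demand) and *smaller antenna* = 500 mol
mol⁻¹. (The source material for this model describes the mapping
between antenna size and Chl:PSII inconsistently in one passage; we
follow the reading under which an increased antenna size raises
Chl:PSII and lowers requirements, which is the one its own sensitivity
results use. Both values are configurable.) The SOD variants enable the
explicit MnSOD pathway, halve the reliance on Mn as SOD cofactor
("other SODs"), combine MnSOD with the large antenna, or double
$k_{cat}^{ROS}$ ("increase SOD efficiency"; the doubling factor is a
configurable choice, as no canonical value exists).

## The synthetic forcing generator

Every run is driven by a built-in idealized Southern-Ocean grid
(default 10 latitude bands spanning 30–75°S × 12 longitude sectors ×
12 monthly climatological steps) so the whole analysis is reproducible
without downloads. The generator encodes, as data in a single settings
block (`forcing_spec()`):

* PAR from top-of-atmosphere daily insolation (solar declination and
  day length), scaled by a single conversion folding PAR fraction,
  transmission and mixed-layer averaging — giving the austral-summer
  maximum and winter darkness poleward of the polar circle;
* dissolved Mn declining poleward to a 60–70°S band level of ~0.13
  nmol l⁻¹ with a hard ceiling of 0.38 nmol l⁻¹ enforced after noise,
  so the band contract (< 0.4 nmol l⁻¹) holds for every seed by
  construction;
* dissolved Zn stepping up south of the Polar Front (55°S) and rising
  further poleward;
* sparse sub-nanomolar dissolved Fe with multiplicative log-normal
  noise (σ = 0.3), combined Fe+Mn sedimentary hotspots at the
  Antarctic coast (south of 70°S, outside the constrained Mn band) and
  one subantarctic island column, and an Fe-enriched Indian-sector
  band near 40°S;
* macronutrients replete south of the front (HNLC character) with a
  mild winter resupply cycle.

Cell areas follow spherical geometry exactly, so footprint areas sum to
the analytic 30–75°S annulus. What the generator does *not* emulate:
real geography and coastlines, 3-D circulation and mixing, interannual
variability, sub-monthly (e.g. 5-day) forcing resolution, and
observation-based covariances between fields. Tests passing on this
grid therefore demonstrate the physiology's directional behaviour
under Southern-Ocean-like gradients, not quantitative fidelity to the
real region.

## Simulator and numerical choices

Each grid cell × PFT is an independent seasonal box model (no
transport; relaxation of the box's dissolved pools toward the forcing
at 0.1 d⁻¹ stands in for resupply). The update is explicit Euler at
dt = 0.25 d over a 360-day year (12 × 30-day months, forcing
piecewise-constant per month), guarded by a step-halving convergence
test (final-year NPP changes < 1% at dt = 0.125). Biomass loss uses a
linear-plus-quadratic closure (0.02 d⁻¹ + 0.05 d⁻¹ (mmol C m⁻³)⁻¹),
the quadratic term standing in for grazing: it equilibrates biomass at
realistic few-mmol-C m⁻³ levels so that macronutrients stay replete
(HNLC) while the micronutrient pools are meaningfully drawn down. A
purely linear closure lets biomass climb until every nutrient is
stripped, which erases the spatial contrast the deficiency footprints
measure. Losses feed a detrital pool (remineralization 0.2 d⁻¹,
sinking 10 m d⁻¹ through a 100-m production layer); the export proxy
is the sinking flux at the layer base, giving an annual e-ratio of
about 0.33.

Spinup repeats the annual forcing cycle until the year-over-year
maximum relative change of monthly biomass, quotas and Chl:C drops
below 10⁻⁴ (cap 20 cycles; the relaxation time scale makes the system
strongly contracting, and the default grid converges in 3 cycles to
near machine precision). Non-convergence is reported, never silently
truncated. All fluxes are applied pairwise to source and sink pools,
so in closed mode (relaxation and sinking off, losses returned to the
dissolved pools, inorganic carbon tracked) the elemental totals of C,
N, P, Si, Fe, Mn and Zn are conserved to ~10⁻¹² relative over
arbitrary horizons. Degenerate inputs are handled explicitly:
zero-denominator ratios are rejected with named errors; the
potential-deficiency ratio is computed as
$Q_{Mn}\mu/(Q_{Mn,req}\mu_{noFe})$ with a fallback to the actual ratio
when $\mu_{noFe} = 0$, keeping all monthly fields finite; deficiency
ties at exactly 1.0 classify as not-deficient.

## Calibration choices and what they mean

The host-model constants (maximum growth rates, half-saturations,
quota bounds, Chl:C ceilings, uptake maxima) are not printed in the
literature underlying the Mn layer; they are one-time calibration
choices and should be read as such. The contrasts encode standard
trait biogeography:

* picophytoplankton have the highest $\mu_{max}$ (1.2 vs 1.0 vs 0.8
  d⁻¹) and the largest Chl:C ceiling (0.050 vs 0.045 vs 0.040 mg
  mg⁻¹);
* Fe-uptake competitiveness declines with cell size
  (diatom $v_{max}/K$ = 10/0.5, nano 16/0.15, pico 20/0.08 µmol mol⁻¹
  d⁻¹ / nmol l⁻¹), reflecting surface-to-volume scaling, which
  produces the diatom ≥ nano ≥ pico ordering of Fe-deficient area;
* diatoms carry the slowest Mn uptake (giving them the lowest Mn
  quotas) and an obligate Si quota.

Changing these defaults changes footprint magnitudes; the directional
responses of the trait experiments (MnSOD extends Mn deficiency,
removing Zn–Mn competition shrinks it, a larger antenna relieves both
Mn and Fe stress, and SOD-mitigation traits relieve the MnSOD
extension) are mechanistic and robust across forcing seeds.

## Problem sizes

The shipped configuration uses the 10 × 12 × 12 grid (120 boxes × 3
PFTs), which runs one experiment in a few seconds and the full
nine-configuration suite in about a minute on one core. The
direction-of-effect checks run the full suite for three forcing seeds.
These sizes were chosen so that a complete desk-scale replication —
forcing, control, all experiments, diagnostics — runs in minutes while
leaving every qualitative contrast resolvable on the grid.

## Known limitations

* No transport between boxes: advection, mixing, sea-ice and
  mixed-layer dynamics are absent; relaxation resupply is a crude
  stand-in, and absolute footprint areas are not comparable to
  estimates from 3-D models.
* The electron-leakage step function is binary; a smooth transition
  would change behaviour near the Fe-repletion boundary.
* SOD parameters are shared across PFTs for want of taxon-specific
  measurements; per-PFT overrides exist in the configuration.
* The bioavailable fractions of dMn/dZn and the transporter inhibition
  constant are placeholders; the competitive-inhibition form itself is
  the standard shared-transporter assumption.
* No proteomic penalty on protein synthesis under unmet Mn demand; the
  MnSOD requirement acts only through the Mn quota.
* Zooplankton are a closure, not a state variable; export shares are
  set by the loss/remineralization/sinking constants.
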