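---
title: "Models and methods: rAAV capsid stoichiometry and particle heterogeneity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: rAAV capsid stoichiometry and particle heterogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vpstoich)
```

## The scientific problem

Recombinant adeno-associated virus (rAAV) capsids are T = 1 icosahedra built
from 60 copies of three protein isoforms — VP1, VP2 and VP3 — that share a
C-terminal common region, with VP3 sometimes accompanied by a slightly
shorter "VP3 clip" translated from a downstream non-canonical start. The
isoforms are incorporated roughly at random during assembly, so a vector
preparation is not one molecule but a *distribution* of particle
compositions. Because the VP1/VP2 N-terminal extensions carry the
phospholipase A2 domain and nuclear localization signals required for
transduction, the (VP1 + VP2)/VP3 stoichiometry is a potency-relevant
critical quality attribute; because the isoforms differ in mass, it also
shows up as buoyant-density heterogeneity in CsCl and as the width of
single-particle mass histograms.

`vpstoich` implements the quantitative chain that connects these readouts:

1. **CGE stoichiometry** — 214 nm peak areas divided by sequence-predicted
   molar absorptivities give molar ratios (`molar_extinction_214()`,
   `stoichiometry_from_areas()`).
2. **60-mer assembly model** — a multinomial null model converts molar
   fractions into particle-mass means, SDs and FWHMs, and enumerates the
   integer compositions compatible with a measured particle mass
   (`assembly_mass_moments()`, `sample_assembly()`,
   `compositions_for_mass()`).
3. **CDMS processing** — reference-protein m/z calibration, per-ion mass,
   the 3–5 MDa acquisition window, and mass histograms with a stabilized
   mode and FWHM (`calibration_factor()`, `ion_mass()`,
   `mass_histogram()`).
4. **Isopycnic gradient physics** — vbar/density conversion, theoretical
   particle vbar from residue composition, equilibrium CsCl gradients, band
   position/width, and the two-speed resolution argument behind a slower
   second fractionation spin (`equilibrium_gradient()`, `band_position()`,
   `band_width()`, `two_speed_comparison()`, `svedberg_sphere_mass()`).
5. **Assays** — potency normalization to a bulk reference, Pearson
   correlation of stoichiometry metrics with potency, and melting
   temperatures from DSF barycentric-mean scans (`relative_potency()`,
   `stoich_potency_correlation()`, `tm_from_bcm()`).
6. **Synthetic data** — seeded generators emulating every input, with
   ground-truth sidecars (`default_scenarios()`, `make_*()`,
   `simulate_scenario()`), orchestrated by `run_pipeline()`.

## The multinomial assembly model

Each particle draws its 60 subunits independently from the molar fractions
$p_i$ with monomer masses $m_i$, so particle mass is
$M = \sum_i c_i m_i + M_\mathrm{genome}$ with
$c \sim \mathrm{Multinomial}(60, p)$:

$$\mathbb{E}[M] = 60\sum_i p_i m_i + M_\mathrm{genome}, \qquad
\mathrm{Var}[M] = 60\left(\sum_i p_i m_i^2 - \Big(\sum_i p_i m_i\Big)^2\right).$$

The FWHM quoted for mass histograms uses the Gaussian relation
$\mathrm{FWHM} = 2\sqrt{2\ln 2}\,\sigma$. This is a *null* model — no
cooperativity, fixed subunit count — and that is deliberate: it is the model
that single-particle mass data can falsify. Note a consequence the package
is explicit about: an ensemble enriched in VP1/VP2 (heavier subunits) has a
*larger* compositional variance, so the narrow histograms observed for
engineered variants cannot be explained by composition alone; the stated
instrument widths carry the remainder (see "What the generator does and does
not emulate").

## 214 nm extinction coefficients

Denatured-protein absorbance at 214 nm is dominated by the peptide bond with
modest side-chain contributions. The package ships the Kuipers–Gruppen
(2007) coefficient table: 923 M$^{-1}$cm$^{-1}$ per peptide bond, per-residue
side-chain values (e.g. Trp 29050, Phe 5200, Gly 21), a distinct bond-aware
proline value (2675) and 30 for an N-terminal proline; N-terminal
acetylation is treated as adding nothing. For a sequence of length $L$:
$\varepsilon_{214} = (L-1)\,\varepsilon_\mathrm{bond} + \sum_r
\varepsilon_r$. The authors of the underlying method did not publish their
exact coefficients alongside the assay, so agreement with any particular
instrument is approximate by construction; what matters downstream are
*ratios* of $A_i/\varepsilon_i$, which are scale-invariant.

The reported summary ratio (VP1+VP2)/VP3$_\mathrm{total}$ is rounded half
away from zero at two decimals (2.3/7.3 = 0.3151 prints as 0.32); the full
precision value is always kept alongside.

## CGE peak processing

**Baseline.** A plain rolling-minimum (morphological opening) baseline is
biased by $O(\mathrm{slope} \times \mathrm{window})$ under peaks when the
baseline drifts, which alone would consume the error budget of small peaks
such as VP3 clip. `baseline_correct()` therefore uses the opening only to
*flag* peak regions; the baseline is the smoothed signal itself outside
those regions and a straight interpolation across them. This is exact for
locally linear drift, unbiased under additive zero-mean noise (no
minimum-statistic bias), and idempotent. Edge windows use local linear fits
so a sloped baseline is reproduced exactly at the trace ends.

**Detection and integration.** Local maxima above `min_height` (default 1%
of the maximum corrected signal — VP3 clip at ~4–6% of VP3 must survive) on
a 5-point-smoothed copy; apexes closer than `min_separation` (0.1 min)
merge; bounds at flanking valleys, truncated where the smoothed signal
reaches baseline (with a `support_pad` margin so Gaussian tails are kept);
trapezoidal integration on the native axis. Species assignment uses
configured migration windows (defaults in `cge_migration_defaults()`), in
the order VP3clip < VP3 < VP2 < VP1; absolute migration times are
instrument-specific and therefore configuration, not constants.

## CDMS processing

Calibration follows the reference-protein procedure: observed reference m/z
against theoretical m/z, fitted through the origin, giving a multiplicative
factor (`corrected = factor * observed`). Ion mass is
`charge * corrected_mz - charge * 1.00728` (the proton correction is
negligible at MDa scale but kept for exactness). Acquisition is emulated by
keeping the first `cap` ions (default 3000) inside the closed 3–5 MDa
window, in order.

Histograms use 0.01 MDa bins by default, sized so the widths of interest
(0.13–0.18 MDa) span ≥ 13 bins. Two estimator choices deserve note, both
made to keep single-run estimates stable at n ≈ 3000:

* **Mode mass**: a count-weighted quadratic fit to log-counts over the
  contiguous half-maximum neighbourhood of the *smoothed* tallest bin
  (≈ a Poisson maximum-likelihood fit of a Gaussian peak restricted to its
  half-height region). The raw tallest bin jitters by tens of kDa under
  counting noise; this estimator has an SE of ~2–3 kDa and passes a 0.2%
  calibration round-trip per seed.
* **FWHM**: linear interpolation of the half-maximum crossings of 5-bin
  moving-average-smoothed counts, using the crossings flanking the mode
  when the histogram is multimodal. Smoothing widens the FWHM by ~2%
  uniformly across samples, which cancels in the orderings the package is
  used to test.

Charge is treated as real-valued throughout (CDMS charge is a measurement),
and the low-charge subpopulation is reported as the fraction of in-window
ions below a user-chosen threshold — the threshold is exposed because no
quantitative cut is established for it.

## Isopycnic CsCl gradient physics

At equilibrium the density profile is
$\rho(r) = \rho_\mathrm{load} + \tfrac{\omega^2}{\beta^0}\,
\tfrac{r^2 - r_\mathrm{iso}^2}{2}$, with the isoconcentration radius fixed
by salt conservation under sector-shaped (weight ∝ r) geometry:
$r_\mathrm{iso}^2 = (r_\mathrm{top}^2 + r_\mathrm{bottom}^2)/2$. The
swinging-bucket tube is approximated as a sector; $\beta^0$ is a single
representative CsCl constant (1.17 × 10⁹ cm⁵ g⁻¹ s⁻² near 20–25 °C),
configurable, with no density dependence or activity corrections. At
34,000 rpm the implied gradient is steep enough that the top of the column
falls below 1 g/cm³; the profile flags this (`subisodense`) rather than
failing, since the particle bands of interest sit mid-column.

A particle bands where $\rho(r) = \rho_\mathrm{particle}$ (root-finding,
tolerance 10⁻⁹), with a Meselson-style Gaussian band width
$\sigma_r = \sqrt{RT / (M\,\bar v\,\rho'(r)\,\omega^2 r)}$.

**Two-speed comparison.** Exact band radii scale as $\omega^{-2}$ only to
first order (~1% deviation at these settings), so the dedicated
`two_speed_comparison()` uses the linearization about $r_\mathrm{iso}$:
$\Delta r = \beta^0 \Delta\rho / (\omega^2 r_\mathrm{iso})$ and $\sigma_r$
evaluated at $r_\mathrm{iso}$. Both are then exactly ∝ $\omega^{-2}$:
dropping from 34,000 to 24,000 rpm multiplies the physical gap between the
two full-particle bands by $(34/24)^2 \approx 2.01$ while leaving the
dimensionless resolution $\Delta r/\sigma_r$ unchanged — the quantitative
rationale for running the second fractionation cycle slower. The general
`band_position()`/`band_width()` functions keep the exact profile.

**vbar.** At the isopycnic point, vbar is the reciprocal of the banding
density. The *theoretical* water vbar combines a mass-weighted Cohn–Edsall
residue average for the protein shell with a configurable ssDNA vbar
(default 0.55 cm³/g). The method behind published theoretical water vbars
for this system is not specified, so only the direction and order of
magnitude of differences between ensembles are claimed (the default
scenarios give a 0.0003 cm³/g gap between the low- and high-density
ensembles, in the observed direction). The Svedberg sphere model
(anhydrous, frictional ratio 1) is a consistency check relating s-values to
mass ($M \propto s^{3/2}$), not a mass determination.

## Assay processing

Relative potency is the ratio of replicate means to the bulk reference mean
at the same MOI, with first-order SD propagation for a ratio of means; no
outlier rejection (3 wells). The correlation stage computes Pearson r and a
least-squares line for three metrics — VP1/(VP2+VP3$_\mathrm{total}$),
VP2/(VP1+VP3$_\mathrm{total}$), (VP1+VP2)/VP3$_\mathrm{total}$ — against
relative potency at one MOI.

For DSF, the melting temperature is read as the inflection of the
barycentric-mean redshift: the maximum of the 3-point-smoothed central
difference dBCM/dT, refined by a local quadratic fit over ±2 °C (the
logistic derivative peak is broad, so a 3-point parabola alone is
noise-limited). The description of "the point at which the integral value
of BCM peaked" is read as this standard sigmoid-midpoint definition; a scan
with no transition in range is an error, not a number.

## The synthetic world: what it emulates and what it does not

`default_scenarios()` encodes five ensembles with the stated
characteristics — molar ratios 1.0:1.3:6.9:0.4 (low-density fraction),
1.0:1.4:8.6:0.4 (high-density fraction), a clip-dominant variant at
(VP1+VP2)/VP3$_\mathrm{total}$ = 0.35, a clip-free variant at 0.32, and
bulk WT as their 50:50 mixture; densities 1.352/1.361/1.359 g/cm³; potency
effects +8.9% (MOI 5×10²), −17.8% (1×10³), +24.7%/+21.9% (1×10², 5×10²),
+11.9%/+8.2% (1×10³, 2.5×10³), interpolated linearly in log-MOI between
quoted endpoints and held flat outside (an assumption — per-MOI tables are
not published); melting temperatures 67.1/68.2/67.7 °C.

Choices where no value is stated, made once:

* **VP sequences are synthetic.** No capsid sequence is bundled; a fixed
  735-residue VP1 with AAV-like composition is generated deterministically
  and truncated into VP2/VP3/VP3clip, preserving the real architecture
  (shared C-terminus, 8-residue clip offset). Sequence-derived masses
  (~81/66/58/57 kDa) and ε214 values are realistic but not those of any
  real serotype.
* **Genome**: 2900 nt at 309 Da/nt ≈ 0.90 MDa, placing full-particle
  masses at 4.57–4.59 MDa.
* **CDMS instrument noise is calibrated to the stated FWHMs.** The
  multinomial compositional widths alone are ~0.12–0.14 MDa and do *not*
  reproduce the observed ordering (the clip-dominant variant has the
  largest compositional variance). Each scenario's Gaussian mass noise is
  therefore set to $\sqrt{\max(0, (\mathrm{FWHM}/2.355)^2 -
  \sigma^2_\mathrm{comp})}$ against its stated FWHM (0.18/0.13/0.16 MDa);
  for the clip-dominant variant the floor is 0 and its total width is the
  compositional ~0.136 MDa. The fraction scenarios reuse the bulk
  instrument noise (their FWHMs are not stated). A green FWHM-ordering
  test therefore establishes that the *pipeline recovers the stated
  world*, not that the multinomial model predicts the ordering — the
  package is explicit that it does not.
* **Charge model**: $z = a\,M^{2/3}(1 + \epsilon)$ (surface-area scaling
  for compact near-spherical ions), a chosen to put ~155 e at 4.7 MDa
  (m/z ≈ 30,000), 3% CV, and a 10% low-charge subpopulation at 60% of the
  trend — emulating the compact-particle population seen in charge-mass
  scatterplots.
* **Noise defaults**: CGE additive noise 0.2% of max peak height with a 2%
  linear drift; density SD 0.001 g/cm³; potency per-well CV 5%; BCM noise
  0.05 nm. These are plausible instrument magnitudes, fixed before any
  acceptance measurement.

Not emulated: electrokinetic injection bias, capillary temperature effects,
raw AUC radial scans, ion-trap signal processing, flow-cytometry gating,
CsCl activity corrections. Absolute experimental values that depend on raw
instrument data (4.70/4.58 MDa CDMS masses, 99.5/97.2 S, the printed FWHMs
as absolute numbers, Tm calibration, theoretical water vbars
0.6839/0.6837 cm³/g) are covered by direction/ordering tests and generator
round-trips only.

## Numerical choices and degenerate inputs

* Ratios are normalized to VP1 = 1 and error if the VP1 amount is zero;
  (VP1+VP2)/VP3$_\mathrm{total}$ errors if VP3$_\mathrm{total}$ = 0.
* `compositions_for_mass()` enumerates all weak compositions of 60 into k
  parts (≤ 39,711 tuples for k = 4) — no pruning is needed at this scale;
  ties are ordered by |deviation| then lexicographic counts.
* Valley ties in peak bounds break toward the earlier minimum; an empty
  composition search result is a valid return, not an error.
* A histogram of fewer than 10 ions, a thermal scan of fewer than 20
  points or with no transition, an empty ion-event set, and a missing bulk
  reference at a normalized MOI are errors by contract.
* All generator outputs are byte-identical under a fixed seed; generator
  seeds never leak into the caller's RNG state.

## Known limitations

* The ε214 table reproduces a published coefficient set, not the exact
  coefficients used with any particular instrument; absolute extinction
  agreement is approximate even though stoichiometric ratios are robust.
* The sector-geometry approximation and single β⁰ make the gradient model
  suitable for design reasoning (band spacing, speed trade-offs), not for
  reproducing absolute band radii in a swinging-bucket rotor.
* The Svedberg sphere model ignores hydration and shape; its mass ratios
  (e.g. $(99.5/97.2)^{1.5} \approx 1.036$) are directional checks only.
* Bulk WT as an exact 50:50 mixture of the two fraction ensembles is a
  modelling convention consistent with a two-band observation, not a
  measured mixing fraction.
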