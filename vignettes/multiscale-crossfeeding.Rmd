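---
title: "Methods: a multi-scale model of amino-acid cross-feeding consortia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a multi-scale model of amino-acid cross-feeding consortia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
two model layers, the conventions that glue them together, the choices we
made where the design was genuinely open, and what the synthetic-data tests
do and do not demonstrate about real plate-reader data.

## The cell scale: ppGpp-driven proteome allocation

The intracellular model is a coarse-grained growth-law model. The proteome
is split into a housekeeping sector (constant, not simulated), a metabolic
sector E containing an amino-acid-export sub-sector y, and a ribosomal
sector R. Six ODEs track ppGpp (Γ), the two sector mRNAs and the three
protein pools; `proteome_rhs()` is the vector field and `proteome_params()`
carries the published parameter table as defaults.

Three structural assumptions matter for everything downstream:

* **Joint uptake.** Glucose S and the focal amino acid A enter through one
  saturating flux u(S, A) = μ·S·A/(k + S·A). Either resource at zero shuts
  uptake off completely — this is how auxotrophy is encoded. A consequence
  worth knowing: because transcription also has a ppGpp-gated basal mode,
  the steady-state ribosome pool has a floor (R\* ≈ 11.5 at u = 0 with
  default parameters), so a starved strain still grows slowly rather than
  not at all.
* **ppGpp senses the ribosome pool.** Synthesis is θ_b + θ_i·R/(1+R); the
  alarmone is high whenever translation capacity is high, and it activates
  E-sector transcription while repressing R-sector transcription through
  Hill terms with threshold ω and coefficient n. The induced rate θ_i is
  the stringent-response knob: at θ_i = 0 the E sector loses its induced
  transcription (export collapses at low uptake) while the R sector loses
  its repression (the ribosome floor explodes) — both effects are probed by
  `theta_sweep()`.
* **Ribosome-capacity saturation.** Translation of each sector slows as its
  pool approaches the share of actively translating ribosomes: the printed
  capacity expressions are typographically ambiguous, and we adopt
  cap_E = 1 − (E/R)·J_E, cap_y = 1 − (y/R)·J_E, cap_R = 1 − J_R — the only
  reading in which J as a "fraction of translating ribosomes" is
  dimensionally coherent and non-degenerate at J = 0.5. At R < 10⁻¹² the
  capacity is set to 1; an exact R = 0 start with protein present sits on
  that guard's discontinuity, which the stiff solver crosses with a
  harmless complaint.

Sectors are simulated as free concentrations; no normalisation constraint
is imposed (the printed equations contain none), and the sector fractions
reported by `sector_fractions()` are computed post hoc relative to
E + y + R.

**Steady states.** `proteome_steady_state()` integrates from the documented
start (0.1, 0.1, 0.1, 0.1, 0.01, 0.1) to t = 200 with `lsoda`, then
polishes with damped Newton iterations (finite-difference Jacobian) until
the max-norm residual is below 10⁻⁸, extending the horizon fivefold once
before failing with the residual in the error. The Newton polish is what
makes the 10⁻⁸ residual achievable independently of solver tolerances.
Empirically the fixed point is unique: the test suite re-solves from five
random starts and compares.

**λ and β.** Ribosome content is proportional to growth rate in bacterial
growth laws, so the growth proxy is λ(S, A) ≡ R\* and the export proxy is
β(S, A) ≡ y\*; the proportionality constants (k1, k2) live at the
population scale. Note that β tracks uptake at steady state (the ppGpp pool
saturates in any environment with a sizeable ribosome pool), so the
*absolute* export proxy is larger in rich environments even though the
E-sector *fraction* — the allocation — is larger under amino-acid scarcity.

## The rate surface

`build_rate_surface()` grids λ and β over (S, A) and
`interpolate_rates()` evaluates them bilinearly (via `pracma::interp2`),
exactly on nodes and bounded by the surrounding corners. Queries outside
the hull are clamped to the nearest edge.

The default grids are {0} ∪ 24 log-spaced points, spanning S ∈ [0, 2] and
A ∈ [0, 4] — the concentration ranges the standard numerical experiments
explore (initial glucose 1; checkerboards to 2 in model units; experimental
supplementation up to 4× basal). The extent is a modelling statement, not
just a numerical one: beyond the surface edge the growth response
*saturates* by clamping. In co-culture the exported amino acid accumulates
(with the published conversion coefficients, production outruns
consumption), and it is the clamp at the surface edge that caps the
cross-feeding benefit; with an effectively unbounded amino-acid axis the
co-culture always outgrows everything and the competitive regime at high
supplementation never appears. Zero is included as an exact grid point
because uptake vanishes there and checkerboard axes start at 0.

Surfaces are deterministic given parameters and grids, fingerprinted with a
parameter hash, memoised per session and optionally persisted
(`cached_rate_surface()`); 25-point-per-axis builds take tens of seconds
and checkerboard sweeps re-use them.

## The population scale and the sequential coupling

Two strains compete for glucose and exchange amino acids (equations in the
README and `community_rhs()` docs). Per-capita uptake is Monod in glucose,
U = λ̂·S/(K + S), with λ̂ = k1·λ(S, A) carrying the amino-acid dependence;
growth is G = c·U with cell efficiency c. `simulate_multiscale()`
discretises [0, T] into intervals of length Δt (defaults T = 180, Δt = 1),
freezes λ̂ and β̂ from the surface at each interval's start, integrates the
five-state system with `lsoda` across the interval, clamps any negative
excursion to zero at the boundary (the printed amino-acid consumption term
lacks a multiplicative X factor, so small negative excursions are possible
and projected away), and repeats. Final densities change by about 0.2% when
Δt is halved from 1, and the refinement is Cauchy over Δt ∈ {2, 1, 0.5,
0.25} — asserted in the tests.

Three conventions here were genuinely open, and we fixed them by requiring
the model to reproduce its own published phenomenology (the
mutualism → parasitism → competition sequence at increasing amino-acid
supply, with the better-supplied strain the parasitism beneficiary, and
negative relative density in the competitive region):

* **K = 40.** The Monod half-saturation of glucose uptake appears in no
  parameter table. It controls whether the T = 180 horizon is
  growth-limited (slow strains do not finish their glucose) or
  yield-limited (everyone does, and all treatments converge to the same
  final density). Only K of the same order as the cell-scale
  half-saturation k = 50 places the standard conditions in the
  growth-limited regime where amino-acid treatment matters; we fixed
  K = 40 once. At K « 1 every condition classifies competition and the
  treatment effect vanishes.
* **k2 is indexed by the amino acid.** The published table lists k2 per
  strain column (0.5×10⁻⁹ for B_x, 1×10⁻⁹ for B_y) while the production
  terms are subscripted by the amino acid produced. We read the B_x column
  as the conversion of amino acid X — the resource *consumed* by B_x,
  produced by B_y. Under this pairing B_y is the better-supplied strain and
  the parasitism winner at intermediate supplementation; the opposite
  pairing makes B_x the beneficiary, contradicting the published
  description of the parasitic regime.
* **Share-inoculum monocultures.** The interaction comparisons
  (`interaction_assay()`, `checkerboard_sweep()`) inoculate each
  monoculture at the strain's co-culture share (half the 2×10⁴ total for
  50-50), so the contrast isolates the partner's effect rather than the
  inoculum's, and the simulated relative density is the co-culture total
  minus the *sum* of the two independent monoculture yields. Resource
  competition alone drives that quantity negative; cross-feeding pushes it
  positive — both signs occur on the default checkerboard. For saturated
  plate-reader yields, which are inoculum-insensitive, this expectation
  reduces to the fraction-interpolated line of additivity, which is what
  `relative_density()` implements for tabular data and what the packaged
  interaction table is checked against. Inoculum densities are otherwise
  unstated in the source material; 10⁴ cells per strain in a 50-50
  co-culture is the package default.

## The analysis layer

`fit_interaction_curve()` fits the through-origin quadratic αx² + βx by
ordinary least squares. The default response is the relative density
(which vanishes at both endpoints by construction); a switch fits raw
final densities, since the published α values' response convention cannot
be recovered unambiguously and those α values are not used as references
anywhere in the package. R² is the uncentered coefficient of
determination, guaranteed in [0, 1] for a least-squares through-origin
fit. `optimal_initial_frequency()` takes the argmax of the mean final
density over tested fractions, breaking ties to the lowest fraction for
deterministic reporting; with the default asymmetric k2 pair the
11-fraction profile in the standard low-resource environment is concave
with a peak flat enough that the discrete optimum lands on 0.5, the
asymmetry showing as a skew towards B_x-majority inocula.
`classify_interaction()` uses a relative tolerance of 10⁻³ so that
floating-point-equal outcomes do not masquerade as parasitism.

## The synthetic-data generator

`generate_plate_dataset()` emulates the statistical structure the analysis
assumes: per-well multi-scale simulations mapped to OD (density / c, which
lands standard runs in the familiar 0.1–1 OD range), two fluorescence
channels with linear gains (1000 a.u. per OD-equivalent, blank 50 a.u.;
CFP reports B_x, mCherry B_y), and multiplicative lognormal noise
(plate-reader coefficients of variation scale with signal; additive
Gaussian available). Default sampling mirrors a 20-minute reader cycle
over a day mapped onto the 180-unit horizon (73 reads). The noiseless
truth travels with the dataset, the seed fully determines the noise, and a
truth sidecar can be re-noised without re-simulating — that is how the
Monte-Carlo classification test affords 100 noise replicates.

What passing these tests shows: the analysis chain (fluorescence →
composition → per-strain density → classification; profile → quadratic fit)
inverts the generator's own assumptions correctly at realistic noise
levels. What it does not show: robustness to the things the generator
deliberately omits — non-linear OD-density response at high density,
channel bleed-through, well-to-well spatial effects, evaporation, growth
phases not captured by the model. Conclusions about real plate data rest
on those assumptions holding approximately.

## Numerical choices, sizes, limitations

* Steady states: `lsoda` rtol 10⁻⁸/atol 10⁻⁸ to t = 200, Newton polish to
  residual < 10⁻⁸; surface cells report their (S, A) on failure.
* Community integration: rtol 10⁻⁸, per-state atol (10⁻¹⁴ for
  concentrations, 10⁻⁴ for densities), projection to the nonnegative
  orthant at interval boundaries.
* Standard problem sizes, chosen to keep the full suite and the acceptance
  script at desk scale: 25-point-per-axis surfaces (13-point for the
  refinement cross-check, 10-point for the monotonicity audit), 9×9
  checkerboards, 11-fraction profiles, 100 noise replicates.
* Limitations: no spatial structure, dilution or death terms; no
  evolutionary dynamics; two strains only; both strains share one proteome
  parameterisation; the growth-rate floor at zero amino acid means
  auxotrophy is impairment, not arrest, at the cell scale — starved
  monocultures grow ~10³-fold over the standard horizon while
  cross-feeding co-cultures grow ~10⁶-fold; statistical hypothesis testing
  on experimental tables is out of scope.
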