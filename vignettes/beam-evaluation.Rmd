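---
title: "Evaluating BNCT neutron beams: models, kernels, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating BNCT neutron beams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnctbeams)
```

# The problem

Boron neutron capture therapy irradiates a ¹⁰B-loaded tumor with
thermal/epithermal neutrons; the short-range products of the
¹⁰B(n,α)⁷Li capture kill preferentially the cells that took up boron.
A clinical facility needs an epithermal beam (0.5 eV–10 keV, ideally
peaked at 1–10 keV for deep-seated tumors), intense enough for
acceptable treatment times, collimated enough to spare the rest of the
body, and clean of fast-neutron and gamma contamination. Designing the
beam-shaping assembly yields several candidates, and the in-air
recommendations alone often cannot rank them. This package evaluates
candidates in three tiers — in-air physics, in-phantom radiobiology,
out-of-beam safety — and selects the beam that is simultaneously useful
and safe.

# Tier 1: in-air figures of merit

`compute_foms()` forms the five standard ratios from beam-port tallies:
the epithermal flux φ_epi; thermal contamination φ_th/φ_epi; fast and
gamma dose contamination per unit epithermal flux; and collimation
J/φ_epi. Conventions that matter:

* **Band assignment.** A bin belongs to the band containing its
  geometric center; boundary energies (0.5 eV, 10 keV exactly) belong
  to the *closed* epithermal interval, because the thermal and fast
  bands are defined by strict inequalities.
* **Current.** J is the *total directed current* summed over all
  energy bins. Whether a facility reports total or net-forward current
  varies; users with a different convention can construct
  `beam_spectrum()` with their own per-bin current tally — everything
  downstream is agnostic.
* **Dose tallies.** Gamma and fast dose rates are accepted as scalar
  inputs (they come from transport codes folding fluence with kerma
  factors); `dose_rate_from_kerma()` is the hook for recomputing them
  from user-supplied per-bin kerma coefficients. No kerma library is
  bundled.
* **Compliance** (`check_compliance()`) uses strict inequalities in
  the recommended directions; thresholds are overridable via
  `iaea_thresholds()`.

# Tier 2: in-phantom radiobiology

## Geometry and dosimetry

The phantom (`cylinder_phantom_spec()`) is a mucosa cylinder of radius
10 cm and height 24 cm with a 2 cm radius tumor sphere centered 3 cm
below the irradiated face, at 7.5 cm from the port — the standard
simplified neck geometry for head-and-neck evaluations. One coordinate
convention is used everywhere: the cylinder axis is the beam axis,
depth z is measured from the irradiated face, and voxel centers sit at
(i + 0.5)·voxel_size for 0-based i. The default voxel is 0.5 cm
(4 voxels across the tumor radius); tests use 1 cm to stay fast.

Absorbed dose has four components: boron capture (stored per 1 ppm of
¹⁰B so any concentration can be applied later), thermal-neutron
nitrogen capture, fast-neutron recoil, and gamma. Boron concentrations
follow BPA clinical practice: 15 ppm in blood and generic normal
tissue, 30 ppm in mucosa, 52.5 ppm in tumor, 22.5 ppm in skin, 75 ppm
in kidneys (renal excretion). Fixed RBE/CBE conversion
(`weighted_dose_fixed_rbe()`) multiplies gamma by RBE_γ, *both* neutron
components by the single tissue RBE_n (factor tables list one neutron
RBE per tissue), and boron by the carrier CBE. More refined
radiobiological conversions (e.g. photon iso-effective dose models with
their own published parameters) plug in through `dose_conversion()`;
fixed RBE/CBE is the shipped default.

## Outcome models

* **TCP** is the Poisson linear–quadratic form for inhomogeneous dose,
  `exp(−Σ_i ρ v_i exp(−α D_i − β D_i²))`. It is exactly invariant
  under voxel subdivision and monotone in every voxel dose. Defaults
  α = 0.25 Gy⁻¹, β = 0.025 Gy⁻², ρ = 10⁷ cells cm⁻³ are in the range
  used for head-and-neck squamous carcinoma; they are configuration,
  not physics baked into the code.
* **NTCP** is the standard logistic curve
  `1/(1 + exp(4 γ₅₀ (1 − D/D₅₀)))` evaluated at the mucosal
  *dose-limiting point* — the healthy voxel with the highest weighted
  dose rate — not at a DVH reduction; clinical prescription for these
  treatments is stated at a limiting point, and the maximum-dose voxel
  is the natural automatic surrogate when no physician-selected point
  is available. Defaults D₅₀ = 8 Gy-Eq, γ₅₀ = 1.5 put severe-mucositis
  risk near 20% at a 6 Gy-Eq limiting-point dose, the order of the
  clinically prescribed limit.
* **UTCP** = TCP·(1 − NTCP). `optimize_time()` maximizes it over the
  irradiation time assuming dose rates constant in time (dose linear in
  t): an exhaustive scan on a uniform grid (default 0.5 min over
  0–120 min) followed by golden-section refinement inside the
  bracketing grid cell. Ties break toward the smaller time, and the
  refined point is accepted only if strictly better, so the result
  never falls below the grid optimum. Degenerate cases: an all-zero
  tumor dose rate flags a warning (UTCP cannot reward irradiation);
  saturating tumor dose drives the optimum to the lower bracket end,
  absent complication risk to the upper end.
* Multi-field plans are a weighted sum of the per-field dose-rate maps
  before outcome evaluation; no inter-fraction repair model is
  applied.

# Tier 3: out-of-beam safety

`assemble_organ_table()` reports, per organ: the absorbed components
(columns DN = fast recoil, DB = boron capture, DH = thermal capture,
Dγ = photons, in cGy), the ICRP-style equivalent dose DW (cSv; photon
weight 1, boron weight 20, neutron dose times the energy-dependent w_R
evaluated at the organ's mean neutron energy), and the biologically
weighted DEq (cGy-Eq, fixed RBE/CBE). Organs missing from the tissue
table take the generic normal-tissue factors (1, 3.2, 1.3, 15 ppm).
The neutron w_R implements the current ICRP continuous three-piece
log-normal formula; its branches meet only to ~0.1% at 1 and 50 MeV,
which is a property of the published parameterization, not of this
implementation.

How to condense a 19-organ table into one safety number is genuinely
open — published comparisons judge the organ-dose profile visually. The
default statistic is the *sum* of DEq over out-of-field organs (for a
head field: everything except brain, head, pharynx, thyroid), with
`max` and `mean` selectable; under organ-wise dominance all three agree
on the ranking. `select_safest_beam()` takes the argmin, breaking ties
by higher UTCP and then lexicographic id.

# The synthetic beamline

The generator module replaces Monte Carlo transport with analytic
stand-ins whose *structure* matches what the analysis assumes. It is
first-class, tested code, but it is emulation, not physics.

* **Spectrum** (`generate_beam_spectrum()`): Maxwellian thermal
  component at 293 K, 1/E slowing-down epithermal component under a
  log-normal window at the configured peak energy (default 1 keV,
  log-width 1.0), exponential fast tail (e-folding 0.5 MeV). This is
  the minimal parametric family producing realistic moderated-beam
  shapes. After mixing, per-band content is rescaled so the requested
  thermal/epithermal/fast fractions hold *exactly* on any grid —
  including under optional log-normal bin noise, which is applied
  before the calibration and is off by default. Current is
  `mean_directionality × flux` bin-wise.
* **Radial profile** (`radial_flux_profile()`):
  `1/(1 + ripple·(r/R)²)` inside the port — the edge-to-axis ratio
  equals exactly 1 + ripple (default 0.2, i.e. flat within 20%
  in-beam) — and an exponential fall-off (default 1.5 cm) beyond,
  giving the sharp out-of-beam decrease of a well-shielded assembly.
* **In-phantom kernels** (`deposit_dose_cylinder()`): the
  thermal-fluence-driven components follow a difference of exponentials
  `exp(−z/λ_fall) − exp(−z/λ_rise)` (defaults 6 and 0.8 cm), chosen
  because it has a closed-form maximum at
  `z* = λ_r λ_f/(λ_f − λ_r)·ln(λ_f/λ_r)` ≈ 1.86 cm — a typical thermal
  peak depth — which the tests compare against the gridded field. Fast
  and gamma components attenuate exponentially (4 and 13 cm). The
  lateral profile is the port disk softened by a Gaussian edge (σ = 1
  cm). Surface normalizations (0.0039 Gy min⁻¹ ppm⁻¹ boron, 0.0069
  thermal, 0.0073 fast, 0.065 gamma at 10⁹ cm⁻² s⁻¹) were chosen once
  so that a mucosa limiting point accumulates a clinically plausible
  ~6 Gy-Eq in ~25 min with a boron-dominated component split; they are
  parameters, not fit results. All components scale linearly with the
  total flux, so a zero-flux beam deposits nothing; in-phantom gamma is
  treated as capture-photon dominated (proportional to neutron
  fluence), and the port's incident gamma contamination enters the
  in-air tier only.
* **Organ doses** (`generate_organ_doses()`): per-component exponential
  decay with organ distance from the field (12 cm for neutron-driven
  components, 8 cm fast, 14 cm gamma), a mean-neutron-energy proxy that
  softens from ~200 keV in-field to thermal energies in the far trunk,
  and optional seeded log-normal noise. Components additionally scale
  with a leakage factor `1 − 0.8·(J/φ)`: out-of-field dose is leakage,
  and a better-collimated beam leaks less. Without this coupling the
  UTCP-optimal time would compensate source strength exactly and all
  beams would tie on safety, which contradicts how real assemblies
  differ. The default 19-organ set places head-region organs at small
  distances and pelvic organs ~70 cm away, so organ dose spans more
  than an order of magnitude down the body.

**What passing tests show — and do not show.** The generator
reproduces the *structural* features real beams exhibit (band
fractions, in-beam flatness, thermal build-up, distance-ordered organ
doses, collimation-dependent leakage). It has no cross-sections, no
scattering, no geometry beyond the kernels; absolute dose levels are
plausible placeholders. Tests passing on synthetic fields therefore
validate the analysis pipeline's arithmetic, invariants and ranking
logic, not the dosimetry of any physical beam — real use starts from
transport-code tallies read via `read_beam_spectrum()` and
`read_dose_field()`.

# Numerical and reporting choices

* Rendered probabilities use half-up rounding at two decimals
  (`round_half_up()`), irradiation times one decimal, figures of merit
  three significant digits.
* The bundled benchmark rows (`inst/extdata/`) record published values
  for five candidate assemblies and the FiR 1 clinical beam. One UTCP
  entry (0.47, fifth assembly, cylinder phantom) differs by one unit in
  the last digit from the two-decimal product of its own printed TCP
  and NTCP (0.58 × 0.82 = 0.4756 → 0.48), as happens when a published
  product is formed from unrounded inputs; the test suite records this
  discrepancy rather than papering over it, and the published
  uncertainty on that entry (±0.07) comfortably covers it.
* Two figures quoted for the same treatment time in different places of
  the benchmark source (24.5 vs 25.4 min) are treated as a typo pair;
  no reconciliation is attempted.
* Determinism: every stochastic option takes an explicit seed; noise
  defaults to off; `run_evaluation()` reruns byte-identically for a
  fixed configuration and seed, and stamps seed, configuration
  fingerprint and package version into the report.
* Problem sizes: tests run the phantom at 1 cm voxels (~9.2k voxels),
  spectra at 50–200 bins, DVH oracles at 10³ voxels, and the pipeline
  at a 1-minute time grid — small enough to run everywhere while
  exercising every code path; the defaults users see are finer.

# Known limitations

* No transport physics anywhere; the kernels cannot capture spectral
  hardening with depth, heterogeneity, or field-shaping accessories.
* Fixed RBE/CBE is a first-order conversion; iso-effective dose models
  are supported only through the pluggable interface.
* NTCP at a single limiting point ignores the volume effect of mucosal
  toxicity.
* Organ doses come from a distance kernel, not an anthropomorphic
  phantom; the organ list and distances are a stylized default.
* TCP/NTCP parameter defaults are order-of-magnitude clinical choices;
  conclusions about absolute outcome probabilities require published,
  disease-specific parameter sets supplied via configuration.
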