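---
title: "Attributing dissolved methane to microbial pathways: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing dissolved methane to microbial pathways: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ch4path)
```

## The problem

Dissolved methane in groundwater can originate from several microbial
pathways — CO2-reduction (hydrogenotrophic) methanogenesis, acetoclastic
methanogenesis — and be consumed by sulfate reduction's competition for H2
or by anaerobic oxidation of methane (AOM). In settings where a coal seam
gas reservoir underlies a shallow alluvial aquifer, telling *in situ*
production apart from inter-aquifer migration matters for both water
management and fugitive-gas attribution. No single measurement settles the
question: δ13C-CH4 ranges overlap between pathways, and concentrations
respond to redox conditions as much as to sources.

`ch4path` combines three complementary lines of evidence per sample:

1. **Thermodynamics** — in-situ Gibbs free energy of the candidate
   reactions, normalised per electron transferred;
2. **Compositional structure** — isometric log ratios (ilr) of the
   reaction-species activities, built from sequential binary partitions
   (SBPs) that mirror each reaction's products/reactants split;
3. **Isotope partitioning** — carbon and hydrogen fractionation factors
   between methane and its source pools, with Rayleigh curves for
   visualising reservoir evolution.

## Models and conventions

### Activities (speciation)

Ion activities use the Davies equation,
$\log_{10}\gamma = -A z^2\left(\frac{\sqrt I}{1+\sqrt I} - 0.3\,I\right)$,
with $I = \tfrac12\sum_i c_i z_i^2$ from all measured major/minor ions and
$A(T)$ interpolated through (0 °C, 0.4918), (25 °C, 0.5085),
(50 °C, 0.5319). A full speciation code would add ion pairing and
carbonate re-speciation; we deliberately do not. The reaction quotients
span tens of orders of magnitude across these aquifers, so the few-percent
difference between Davies and a full model is immaterial to the ΔG/e⁻
patterns, and the package stays dependency-free. Interpolation is
piecewise-linear between the three anchors (a single straight line cannot
pass through all three tabulated values; anchoring exactly at 25 °C is
what the downstream constants assume). Neutral dissolved gases (CH4, H2)
take unit activity coefficient — Setchenow salting-out is ignored, which
is defensible below I ≈ 0.25 mol/L; the Davies limit itself (~0.7 mol/L)
triggers a logged warning in hypersaline samples. a(H2O) is fixed at
exactly 1. Bicarbonate is taken as reported (alkalinity as HCO3) with no
carbonate-system correction.

### Dissolved H2

H2 is rate-limiting for both CO2 reduction and sulfate reduction but is
rarely measured. Three modes are offered, recorded per run:

* `assumed_constant` (default): a configured molarity, default 1e-9 mol/L,
  typical of sulfate-reducing zones;
* `measured`: pass-through of a supplied value;
* `redox_couple`: the a(H2) that places sulfate reduction at a configured
  ΔG threshold (default 0 kJ/mol) given the sample's SO4²⁻/HS⁻/H⁺
  activities — the hypothesis that sulfate reducers hold H2 at their
  thermodynamic threshold.

No mode is claimed to reproduce any particular field study's unstated
choice; the default keeps runs comparable across samples.

### Gibbs free energies

The three shipped reactions (products positive):

* CO2 reduction: HCO3⁻ + 4 H2 + H⁺ → CH4 + 3 H2O
* Sulfate reduction: SO4²⁻ + 4 H2 + H⁺ → HS⁻ + 4 H2O
* AOM: CH4 + SO4²⁻ → HCO3⁻ + HS⁻ + H2O

All three transfer 8 electrons, derived in code by oxidation-state
bookkeeping rather than asserted. Standard-state constants are per-species
aqueous formation values (ΔGf°, ΔHf°; H2O as liquid) shipped in
`extdata/thermo_species.csv`. **Aqueous** (not gaseous) standard states
are used for CH4 and H2 because they reproduce the canonical 25 °C
anchors: ΔG°(CO2 reduction) ≈ −229 kJ/mol and ΔG°(sulfate reduction)
≈ −263 kJ/mol (AOM ≈ −34 kJ/mol). The reaction entropy is derived as
ΔS° = (ΔH° − ΔG°₂₉₈)/298.15 K, so the temperature correction
ΔG°_T = ΔH° − T·ΔS° is exactly consistent with the 25 °C values; over the
0–60 °C domain this linearisation (constant ΔH°, ΔS°) is the standard
van't Hoff-level approximation. In-situ ΔG adds R·T·ln Q with Q over
activities, H2O exempt.

### Pathway balances (ilr)

Each reaction gets a four-part SBP whose first balance separates the
product from the reactants — so ilr.1 is a scaled log of the same activity
ratio as Q (for AOM it is exactly proportional to ln Q) — and whose later
balances partition the reactants, exposing which reactant limits the
pathway (e.g. the H2-vs-(H⁺, HCO3⁻) balance for CO2 reduction). Balances
are computed on **unclosed** activity vectors: ilr coordinates are scale
invariant, so closure to a constant sum would change nothing, and
activities, not mass fractions, are the thermodynamically meaningful
parts. The SBP validator enforces the hierarchy property (each row splits
one group kept together by previous rows), which is what guarantees the
basis is orthonormal and hence that ilr distances equal Aitchison
distances — a property the tests check against a brute-force clr oracle at
1e-10 over 1000 random compositions.

### Isotope partitioning and classification

The fractionation factor is defined as α = (1000 + δX)/(1000 + δCH4),
with δX = δ13C-DIC (carbon) or δ2H-H2O (hydrogen). Default classification
rules, all configurable in `pathway_thresholds()`:

* **CO2 reduction**: α_C within 1.07 ± 0.02 **and** α_H within 1.2 ± 0.05;
* **Acetoclastic/oxidation**: α_C ≤ 1.05 (with a lower sanity floor of
  1.02 — see below) **or** α_H ≥ 1.35 **or** δ2H-CH4 ≤ −310 ‰;
* both fire → `MIXED`; neither → `INDETERMINATE`.

Sulfate (meq/L) is attached as context evidence but is never decisive on
its own: high sulfate makes methanogenesis unlikely but does not identify
a pathway. The 1.02 floor on the acetoclastic carbon rule is a design
choice: α_C near 1.00 means essentially no carbon fractionation, which is
evidence of *no* methanogenic signature rather than of the acetoclastic
pathway, so the rule stays silent there instead of firing on any
unfractionated sample. Field literature is also not fully consistent on
the acetoclastic carbon factor (~1.04 in most compilations, sometimes
quoted alongside hydrogen at ~1.4); the classifier follows the 1.04 (C) /
1.4 (H) convention.

Rayleigh curves are exposed with reciprocal orientations —
R = R_i·f^(1−α) for carbon and R = R_i·f^(α−1) for hydrogen — for
visualising reservoir evolution only; no sample is force-fit to a
Rayleigh model, because open-system groundwater rarely follows one.

The Keeling-style mixing diagnostic regresses δ13C-CH4 on 1/CH4; its
intercept is the concentrated end-member δ13C-CH4 under two-component
mixing with a fixed background.

### Censored concentrations

Below-detection values are imputed per aquifer group (the groups occupy
distinct compositional ranges, so pooling would bias both). The default is
deterministic multiplicative replacement at 0.65·DL — reproducible with no
seed sensitivity. The `lrda` option runs a seeded Gaussian
data-augmentation chain on log concentrations: censored cells are drawn
from their conditional normal given the sample's uncensored major ions
(Na, K, Ca, Mg, HCO3, Cl, SO4), truncated above at the detection limit,
iterating regression and draw for `n_chains` sweeps (default 50). On
synthetic data with known sub-detection truths, the conditional chain has
materially smaller mean absolute log error than substituting the detection
limit. Groups too small to support the regression fall back to univariate
truncated draws; a species with no uncensored anchor falls back to
multiplicative replacement with a warning. Interval censoring (between two
limits) is out of scope.

## The synthetic catchment

No per-sample field table is distributed with studies of this kind, so the
generator is the package's test bed. Its defaults encode the published
per-aquifer summary ranges of the emulated setting: a deep gas reservoir
(200–500 m; Cl 1000–4500 mg/L; SO4 essentially always censored below
1 mg/L; CH4 2000–25000 µg/L; δ13C-CH4 −58..−49 ‰; δ2H-CH4 −210..−198 ‰;
δ13C-DIC +9..+23 ‰), shallow coal measures (<200 m; CH4 detected in 7 of
14 wells; δ13C-DIC −15.9..−3.5 ‰) and an alluvium (CH4 in 5 of 23 wells,
10–535 µg/L). Within-range draws are uniform — only ranges are published —
switching to log-uniform when a range spans more than one order of
magnitude. Ranges that are not published (HCO3, Na, K, Ca, Mg, Br,
temperature, pH per aquifer) are single field-realistic choices: e.g.
coal-measure HCO3 300–1500 mg/L (high-alkalinity Na-HCO3-Cl water),
reservoir temperatures 25–38 °C from a typical geothermal gradient at
200–500 m.

Two structural features are built in. First, the sulfate–methane
antagonism: CH4 detection probability declines logistically in log SO4
(meq/L) around a midpoint of 1 meq/L, and the CH4 concentration itself is
tied inversely to sulfate, reproducing the negative SO4–CH4 rank
correlation the analysis relies on. Second, pathway-consistent isotopes: a
latent pathway (CO2-reduction vs acetoclastic, mixture weights per
aquifer: 1:0 reservoir, 13:1 shallow coal measures, 4:1 alluvium) fixes
true fractionation factors (1.07/1.2 or 1.04/1.4), the source deltas are
drawn from their ranges, and the methane deltas are obtained by inverting
the fractionation-factor definition, plus Gaussian noise (default 2 ‰,
about the upper end of δ2H-CH4 analytical error). With zero noise the
classifier recovers every latent label exactly, by construction; at 2 ‰
recovery stays above 0.9, which is what the acceptance property checks.

What the generator does **not** emulate — and therefore what passing tests
cannot show about real data: spatial structure and well clustering,
transport and diffusion (δ37Cl is drawn as an uninformative passthrough),
correlated analytical errors, inter-ion charge-balance closure,
tritium-age structure, seasonal resampling, and real per-sample pairing of
deltas (only ranges are published; the pathway-consistent pairing is an
assumption, stated as such). Latent labels are written to a separate
table so pipeline code cannot accidentally consume them.

## Numerical choices and degenerate inputs

* Boundary ties in classification use a 1e-9 inclusive guard so a factor
  sitting exactly on a cutoff fires deterministically.
* `rayleigh()` rejects f = 0 (a plotting limit, not an evaluable point);
  `fractionation_factor()` rejects δ = −1000 ‰ (the zero of the delta
  scale) and warns outside the natural sanity band (0.8, 1.8).
* Truncated-normal draws clamp the uniform variate away from 0/1 and cap
  draws just below log DL, so imputed values are strictly inside (0, DL)
  even in extreme tails.
* Samples missing CH4 (or any reaction species) skip the affected
  reactions/balances with a logged reason; a run never aborts on a sample.
* Ionic strength treats unmeasured ions as zero contribution (logged by
  omission), rather than refusing the sample.
* CSV round-trips write numerics at full precision (`%.17g`), so
  write-then-read is bit-exact.

## Problem sizes

The shipped tests run the geometry checks on 1000 random 4-part
compositions, correlation and recovery properties on catchments of
200–500 wells, and the end-to-end determinism check on the default 61-well
catchment run twice; the whole suite completes in well under a minute.
These sizes were chosen as the smallest at which the stochastic
properties are stable across seeds.

## Known limitations

* Davies-level activities; no Pitzer model, so the hypersaline alluvial
  extreme (Cl ~ 8700 mg/L) carries a validity warning.
* No acetoclastic ΔG pathway (acetate is not measured), no kaolinite
  saturation index (requires Al), no quantitative δ37Cl diffusion model,
  no three-end-member mixing solver — the mixing diagnostic is strictly
  two-component.
* The gypsum Ksp (10^−4.58) is held at its 25 °C value.
* Classification thresholds are calibrated interpretive conventions, not
  fitted parameters; they live in configuration, and their defaults should
  be revisited for settings with very different temperature or salinity.
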