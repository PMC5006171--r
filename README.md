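# ch4path

Attribution of dissolved methane in groundwater to microbial production
and consumption pathways, for hydrogeochemists working in settings where a
coal seam gas reservoir underlies shallow aquifers and the question "is
this methane produced *in situ* or migrated?" has to be answered from
water chemistry and isotopes alone.

Per sample, the pipeline combines:

* **Thermodynamics** — in-situ Gibbs free energy
  ΔG = ΔG°_T + RT·ln Q, with ΔG°_T = ΔH° − T·ΔS° from shipped aqueous
  standard-state constants, for CO2-reduction methanogenesis
  (HCO3⁻ + 4H2 + H⁺ → CH4 + 3H2O), sulfate reduction
  (SO4²⁻ + 4H2 + H⁺ → HS⁻ + 4H2O) and anaerobic oxidation of methane
  (CH4 + SO4²⁻ → HCO3⁻ + HS⁻ + H2O), each normalised per electron
  (ΔG/e⁻, 8 e⁻ each);
* **Compositional data analysis** — isometric log-ratio balances
  z_i = √(r_i s_i/(r_i+s_i)) · ln(g(x₊)/g(x₋)) over the reaction-species
  activities, from per-reaction sequential binary partitions whose first
  balance separates products from reactants (so ilr.1 tracks ln Q) and
  whose later balances expose the limiting reactant;
* **Isotope partitioning** — fractionation factors
  α = (1000+δX)/(1000+δCH4) for the DIC–CH4 (carbon) and H2O–CH4
  (hydrogen) pairs, a rule-based pathway classifier (α_C ≈ 1.07 with
  α_H ≈ 1.2 ⇒ CO2 reduction; α_C ≤ 1.05, α_H ≥ 1.35 or
  δ2H-CH4 ≤ −310 ‰ ⇒ acetoclastic/oxidation), Rayleigh curves
  R = R_i·f^(1−α) (carbon) / R_i·f^(α−1) (hydrogen), and a Keeling-style
  1/CH4 mixing-line intercept.

Supporting machinery: a Davies-equation activity model with ionic
strength from the full ion suite, left-censored (below detection limit)
imputation — deterministic 0.65·DL replacement or a seeded conditional
data-augmentation chain — and a synthetic-catchment generator that
emulates the gas-reservoir / shallow-coal-measures / alluvium structure
(printed concentration and isotope ranges, sulfate-suppressed methane
detection, pathway-consistent isotope pairing) so every stage is testable
without any field download.

## Worked example

```r
library(ch4path)

sim <- generate_catchment(seed = 1)          # 61-well virtual catchment
res <- run_pipeline(run_config(sim$samples, seed = 1))

table(res$per_sample$aquifer_group, res$per_sample$pathway_call)
#>                         ACETOCLASTIC_OR_OXIDATION CO2_REDUCTION INDETERMINATE
#>   ALLUVIUM                                      2            10            11
#>   GAS_RESERVOIR                                 0            21             0
#>   KUMBARILLA                                    0             2             1
#>   SHALLOW_COAL_MEASURES                         1             7             6
```

`INDETERMINATE` wells are those without detectable CH4 (no methane
isotopes, no call) — by design the sparse alluvium has many. Inspecting
samples with isotope coverage:

```r
cols <- c("sample_id", "SO4_meq", "CO2_dG_per_e", "AOM_dG_per_e",
          "alpha_DIC_CH4", "alpha_H2O_CH4", "pathway_call")
head(res$per_sample[!is.na(res$per_sample$alpha_DIC_CH4), cols], 5)
#>  sample_id SO4_meq CO2_dG_per_e AOM_dG_per_e alpha_DIC_CH4 alpha_H2O_CH4
#>   ALLU_003  0.0228        0.370        -2.57          1.04           1.4
#>   ALLU_014  0.0590        0.211        -2.97          1.04           1.4
#>   SHAL_013  0.0135        1.299        -3.38          1.04           1.4
#>   ALLU_001  0.0135       -0.754        -2.48          1.07           1.2
#>   ALLU_004  0.3078       -0.209        -3.09          1.07           1.2
#>               pathway_call
#>  ACETOCLASTIC_OR_OXIDATION
#>  ACETOCLASTIC_OR_OXIDATION
#>  ACETOCLASTIC_OR_OXIDATION
#>              CO2_REDUCTION
#>              CO2_REDUCTION
```

Reading a row: `ALLU_001` has α_DIC-CH4 = 1.07 and α_H2O-CH4 = 1.2 — the
classic CO2-reduction signature — with CO2 reduction thermodynamically
favourable in situ (ΔG/e⁻ = −0.75 kJ/(mol·e⁻)) and AOM favourable but
uncorroborated; `ALLU_003` shows the acetoclastic signature (1.04 / 1.4).
The same tables, a per-aquifer min/median/max summary, the imputation
report and a per-sample skip log are written as CSVs when `out_dir` is
set.

A command-line wrapper ships in `inst/cli/`:

```sh
ch4path simulate --seed 1 --out sim/
ch4path run --input sim/samples.csv --out results/ --seed 1
ch4path validate
ch4path thermo-table --temp 25
#> reaction,temperature_C,dG0T_kJmol,dG0T_per_electron_kJmol
#> CO2_REDUCTION,25,-229.4,-28.68
#> SO4_REDUCTION,25,-263.0,-32.87
#> AOM,25,-33.5,-4.19
```

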