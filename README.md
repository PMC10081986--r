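# ipoctrace

Quantifying how much sea-ice algal carbon Arctic marine consumers use,
from highly branched isoprenoid (HBI) lipid biomarkers.

## The problem

Sea-ice diatoms and pelagic phytoplankton leave different lipid
fingerprints in the animals that eat them. Three HBI lipids, quantified
by GC-MS selected-ion monitoring, are source-diagnostic: **IP25**
(m/z 350.3) and **HBI II** (m/z 348.3) come from sea-ice diatoms, while
**HBI III** (m/z 346.3) comes from pelagic phytoplankton. `ipoctrace`
turns per-individual HBI peak intensities into a relative measure of
sea-ice versus phytoplankton carbon, and provides the downstream
statistics an Arctic food-web survey needs: ecological summaries, model
selection, a sensitivity analysis for unobserved confounding, and a
sediment-inventory calculation for sea-ice carbon stored on the shelf.
It is aimed at biogeochemists and food-web ecologists working with
response-normalized GC-MS intensity tables.

## The model

The pelagic share of the HBI signal is the **H-Print** (%):

```
H-Print = 100 * HBI III / (IP25 + HBI II + HBI III)
```

0 % is a fully sympagic (ice-associated) signal, 100 % fully pelagic.
A linear calibration from a controlled feeding experiment converts
H-Print into **iPOC**, the estimated percentage of sea-ice particulate
organic carbon in the animal's marine-origin carbon:

```
iPOC = 101.08 - 1.02 * H-Print        (R^2 = 0.97, df = 23)
```

Predictions are clamped to [0, 100] for reporting (the raw line is kept
alongside). Samples with no measurable HBIs at all carry no source
information and are excluded; samples with only HBI III are classified
`pelagic_only`; everything else shows `both_sources`.

On top of this the package provides:

* box-plot style summaries of iPOC by species and by sampling month,
  and the proportion of animals above the 50 % iPOC threshold (a
  stronger sea-ice than phytoplankton signature);
* ordinary least-squares fits of iPOC against month, year, latitude and
  habitat (plus the month x habitat interaction), ranked by AIC — both
  implemented from first principles (QR decomposition, full Gaussian
  likelihood) so every number is auditable;
* an omitted-variable-bias sensitivity analysis: the partial R^2 of a
  treatment term, `t^2 / (t^2 + df)`, and its robustness value — the
  minimal strength an unobserved confounder needs (as partial R^2 with
  both treatment and outcome) to explain the effect away, or to drop it
  below significance at a chosen alpha;
* a sediment module: per-layer theoretical-maximum iPOC
  (TOC x calibrated ice fraction), a constant-rate age model, and the
  min/max iPOC concentration accessible within a bioturbation horizon;
* a seeded synthetic-data generator that emulates the survey structure
  (habitat-stratified means, latitude gradient, seasonal dips, lognormal
  intensities, detection dropouts) with ground truth for testing.

## Worked example

```r
library(ipoctrace)

# a synthetic survey with the default study-shaped structure
samples <- generate_samples(synth_config(n_samples = 2334), seed = 1)$samples
pipe    <- run_pipeline(samples)
length(pipe$exclusion_log)
#> [1] 57
proportion_above(pipe$results, 50)
#> $count
#> [1] 1426
#> $proportion
#> [1] 0.6262626
#> $n_included
#> [1] 2277

ms <- model_stage(pipe$results)
ms$comparison[1:3, c("formula", "k", "aic", "delta_aic")]
#>                                      formula k      aic delta_aic
#> 1 month + latitude + habitat + month:habitat 6 19518.08   0.00000
#> 2                 month + latitude + habitat 5 19542.65  24.57034
#> 3                         latitude + habitat 4 19569.17  51.08900
ms$sensitivity
#> Sensitivity of 'habitat' (t = 12.696, df = 2272):
#>   partial R2 with outcome: 0.0662
#>   robustness value (q = 1): 0.2332
#>   robustness value (q = 1, alpha = 0.05): 0.2013
```

57 of 2334 simulated animals had no measurable HBIs and are excluded;
62.6 % of the rest carry a stronger sea-ice than phytoplankton
signature. The month+latitude+habitat+month:habitat model wins the AIC
comparison by ~25 points, and a confounder would need a partial R^2 of
about 0.23 with both habitat and iPOC to explain the habitat effect
away (0.20 to make it lose significance at alpha = 0.05).

For sediment cores:

```r
core <- generate_core(7, layer_thickness_mm = 10,
                      toc_mg_per_g = 20, hprint_pct = 30)
prof <- sediment_profile(core, sedimentation_rate_mm_per_y = 1,
                         sampling_year = 2008)
compute_sediment(prof, horizon_mm = 70)$inventory[1:3]
#> $min_ipoc_mg_per_g
#> [1] 14.096
#> $max_ipoc_mg_per_g
#> [1] 14.096
#> $oldest_accessible_age
#> [1] 1938
```

A uniform core with 20 mg/g TOC and H-Print 30 % stores 14.096 mg iPOC
per gram in every layer, and infauna burrowing to 70 mm reach sediment
deposited back to 1938 at 1 mm/yr.

A thin command-line front end over the same functions ships in
`inst/cli/ipoc.R` (subcommands `validate`, `compute`, `stats`,
`sediment`, `synth`, `run`).

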