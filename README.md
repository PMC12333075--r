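# peatspec

Spectral unmixing and α-diversity modelling for boreal peatland
vegetation.

## What this package is for

Boreal peatlands — major stores of soil organic carbon — are classified by
ecohydrology into **minerotrophic** fens (vascular-plant-dominated) and
**ombrotrophic** bogs (bryophyte-dominated). Close-range reflectance
spectroscopy of 1 m × 1 m vegetation plots can, in principle, recover the
fractional cover of individual plant species and the α-diversity of the
community from a single spectrum. `peatspec` implements that analysis
chain as a tested, reproducible pipeline for spectral ecologists:

* **Harmonization** of field and laboratory reflectance-factor spectra:
  segmented Savitzky–Golay smoothing (windows 15/39/75 nm, order 2),
  removal of the atmospheric water-absorption regions (retaining
  400–1329, 1550–1760 and 2025–2310 nm; 1427 samples on a 1-nm grid),
  and per-species averaging of replicate endmember spectra.
* **Sentinel-2 band simulation** via spectral response functions for the
  ten MSI bands B2–B8a, B11, B12.
* **Spectral unmixing**: per-plot non-negative least squares
  (Lawson–Hanson active set),

  a\* = argmin_{a ≥ 0} ‖E a − y‖₂,

  with the plot spectrum *y* as response and the endmember matrix *E*
  (six species per trophic level) as predictors; abundances are
  normalized post hoc and evaluated against observed covers with R²,
  RMSE and bias after removing pairs with zero observed cover.
* **Community analysis**: point-intercept cover estimation on a 100-cell
  grid, Shannon-Wiener (H = −Σ p ln p) and Simpson (D = 1 − Σ p²)
  indices.
* **Diversity-from-spectra models**: NIPALS PLS1 regression with seeded
  10-fold cross-validated component selection (one-standard-error rule)
  and a 70/30 train/test evaluation.
* A **seeded synthetic-data generator** that emulates the statistical
  structure of such a study (species spectral templates, Dirichlet
  communities, linear mixtures with brightness jitter and noise,
  point-intercept grids), so the whole pipeline is testable without
  external data.

See the methods vignette
(`vignettes/peatland-spectral-unmixing.Rmd`) for the models, assumptions
and design decisions.

## Worked example

Generate a synthetic study, harmonize, unmix the minerotrophic plots,
and model diversity from the spectra:

```r
library(peatspec)

study <- gen_study(simulation_config(seed = 1))
fen   <- study$minerotrophic

plots  <- harmonize(fen$plots)
enders <- harmonize(fen$endmembers, average_species = TRUE)
plots
#> <spectral_library> 60 samples x 1427 wavelengths (400-2310 nm)
#>   roles: plot=60

species <- select_endmembers(fen$communities)   # occupancy/cover rule
ems     <- endmember_set(enders, species = species,
                         trophic_level = "minerotrophic")
result  <- unmix(plots, ems, fen$communities)
result
#> <unmix_result> 60 plots, 360 (plot, species) pairs (247 in evaluation set)

unmix_metrics(result)
#>                  species  n        r2     rmse       bias
#> 1       Comarum palustre 17 0.9920278 1.067527 -0.3327670
#> 2    Filipendula ulmaria 25 0.9936735 1.117547 -0.1663778
#> 3                 Litter 60 0.9981472 1.167913  0.2768623
#> 4  Menyanthes trifoliata 39 0.9928752 1.301085 -0.2145815
#> 5 Sphagnum angustifolium 46 0.9942278 1.306998 -0.2257161
#> 6        Sphagnum fallax 60 0.9960525 1.483203 -0.3324004
```

Each row compares NNLS-predicted against observed cover (percent) over
the plots where the species occurs: `n` evaluation pairs, `r2`
(1 − SSres/SStot; can be negative), `rmse` in percentage points, and
`bias` (predicted − observed, positive = over-prediction). At the
generator's default noise level the mixture model is well specified, so
recovery is nearly exact; on field data these numbers degrade with
canopy effects the linear model omits.

```r
X   <- t(plots$rf)
div <- fen$diversity
ev  <- evaluate_diversity_model(X, div$shannon[match(rownames(X), div$plot_id)],
                                seed = 1)
ev$metrics
#>    n         r2      rmse      bias
#> 1 18 0.07472024 0.2851712 0.1076144
```

The Shannon index of the held-out 30% of minerotrophic plots is barely
predictable from their spectra (R² = 0.07) — diversity is a nonlinear
summary of composition, and the one-SE rule selected a single latent
component here; the ombrotrophic level fares noticeably better
(R² ≈ 0.5 at this seed).

```r
wavelength_r2_profile(plots, fen$communities, "Litter")
#> <wavelength_r2_profile> Litter: best r2 = 0.982 at 456 nm (60 plots)
```

The whole workflow, including Sentinel-2 band simulation and CSV/manifest
output, runs as one call: `run_pipeline(pipeline_config(seed = 1), "out/")`.

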