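# ecmorph

Digital morphometry of the fibrous extracellular matrix (ECM) in stained skin
histology, for researchers quantifying dermal aging from brightfield
micrographs. The package segments collagen and elastic fiber bundles from
H&E, Mallory's trichrome, silver-impregnation and Weigert's/orcein sections,
measures them (ECM area fraction, per-bundle pixel areas, maximum bundle
width via the local thickness transform), and models the strongly
right-skewed bundle-area histogram with a two-parameter generalized Pareto
distribution (GPD).

## The model

Per-bundle pixel areas are treated as i.i.d. draws from the GPD with
location 0, shape (tail index) *k* and scale *σ*:

    S(x) = P(X > x) = (1 + k x / σ)^(−1/k),   k ≠ 0
    S(x) = exp(−x / σ),                        k = 0 (exponential limit)

Both parameters are estimated by maximum likelihood (Nelder–Mead over
(k, ln σ) from moment-based and exponential starts, finished with an
analytic-gradient BFGS polish), with 95% confidence intervals from the
observed information matrix — normal on *k*, log-normal on *σ*. The GPD is
preferred over exponential and half-normal alternatives by AIC on
heavy-tailed bundle data (`compare_tail_models()`).

The fitted tail index discriminates two tissue regimes: *k* above a
threshold (default 0.66) indicates a dermis dominated by large fiber
bundles (younger tissue); *k* at or below it indicates small, fragmented
bundles (aged tissue). `separating_threshold()` computes the gap that
perfectly separates two groups of fits; on the package's built-in reference
fits (`reference_gpd_fits()`, eight non-silver estimates from a 10-year
longitudinal comparison) that gap is (0.6121; 0.6923) and contains 0.66.

Because the reference study's raw images are not publicly deposited, the
package ships a first-class synthetic micrograph generator
(`synthetic_spec()` / `render_micrograph()`): elongated ribbon bundles whose
pixel areas are exactly GPD-distributed, rendered in stain-appropriate
palettes with nuclei, artifact debris and sensor noise, plus ground-truth
masks — the validation substrate for the whole pipeline.

## Worked example

```r
library(ecmorph)

spec <- synthetic_spec(shape_k = 0.9, scale_sigma = 200, n_bundles = 300,
                       image_size = c(1024, 1024), noise_sd = 0, seed = 7)
out <- render_micrograph(spec)           # image + ground truth
seg <- segment_stain(out$image)          # HSV color thresholding
area_fraction(seg)                       # 30.9 (% of pixels that are fiber)
comps <- label_components(seg$fiber_mask, min_area = 4)
nrow(comps)                              # 277 bundles
fit <- fit_gpd(comps$area_px)
fit
#> Generalized Pareto fit (maximum likelihood)
#>   n = 277, log-likelihood = -2041.9862
#>   shape k     = 0.8393  95% CI (0.6352; 1.0435)
#>   scale sigma = 252.7611  95% CI (204.0786; 313.0566)
classify_by_k(fit)
#> k = 0.8393 vs threshold 0.6600 -> large_bundle_regime
```

The fitted shape 0.84 sits near the generator's 0.9 (segmentation
discretization trims the smallest bundles, pulling it slightly down — see
the methods vignette) and lands the sample firmly in the large-bundle
regime. Batch analysis over a manifest CSV, with per-image reports, CSV/JSON
outputs and figures, goes through `run_config()` + `run_pipeline()`; a thin
command-line wrapper lives in `inst/scripts/ecmorph`.

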