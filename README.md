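# finespot

Super-resolved spatial transcriptomics and ligand–receptor discovery from
histology and spot expression.

## What it does, and for whom

Spot-based spatial transcriptomics (10x Visium and similar) measures one
pooled transcriptome per ~55 µm capture spot, but ligand–receptor (LR)
signaling happens between neighboring cells. `finespot` is for
computational biologists who have (a) a spot × gene UMI matrix with pixel
coordinates, (b) the co-registered H&E whole-slide image, and (c) a curated
LR database (CellChatDB-style `ligand,receptor,pathway` CSV, multi-subunit
complexes joined by `_`), and who want cell-scale expression and
spatially-resolved cell–cell communication calls out of them.

The pipeline:

1. **Geometry** — each spot's 112 × 112-px image patch is split into an
   8 × 8 grid of 14-px tiles (≈ one cell each); gaps between spots get
   pseudo-centers (≈ 4 locations per probed spot); optional nucleus-centered
   tiles consume external segmentation coordinates.
2. **Features** — a pluggable extractor embeds every tile
   (`virchow2` 1280-d / `vit256` 384-d profiles as plugins; a deterministic
   built-in stub for fully offline work).
3. **Model** — four jointly trained maps: image autoencoder
   (g₁: ℝᶜ → ℝʰ, f₁), expression autoencoder (g₂: ℝᵖ → ℝʰ, f₂ with softplus
   output), optimized with
   `L = w₁·cosim(𝒳, f₁g₁𝒳) + w₂·cosim(Y, f₂g₂Y) + w₃·InfoNCE(h^img, h^expr; τ)
   + w₄·cosim(Y, Σᵢⱼ f₂g₁𝒳ᵏⁱʲ)`
   with τ = 0.03, K = 64 pairs per batch, w₁…w₄ = 1.
4. **Imputation** — per tile,
   `Yᵏⁱʲ = α·f₂(g₁(f₀(Xᵏⁱʲ))) + (1−α)·Σₛ wₛ·Yₛ` with the κ = 6 nearest
   measured spots, inverse-distance weights and α = 0.5.
5. **Discovery** — bivariate global and local Moran's R per LR pair with
   exact permutation-null moments, one-sided z-tests, Benjamini–Hochberg
   selection at FDR 0.05, and a sparse-pair filter (> 2 interacting
   locations).
6. **Patterns & interpretation** — EM clustering of local interaction maps
   under a Gaussian-process mixture (full covariance, or block-sparse for
   large location counts), Fisher-exact pathway enrichment, L→R→TF→TG
   network extraction, cell-type co-localization, per-pattern cell
   abundance, and PCC/SSIM evaluation utilities.

A seeded synthetic-slide generator (`make_slide()`) with known sub-spot
truth and planted LR co-expression drives the entire test suite with zero
downloads.

## Worked example

```r
library(finespot)
slide <- make_slide(slide_config(), seed = 11)   # 20x20-spot synthetic slide
slide$bundle
#> slide_bundle: 400 spots x 60 genes; image 1166 x 1360 px; platform visium

ex    <- feature_extractor("stub", embed_dim = 32, seed = 5,
                           tile_px = slide$tiles$tile_size_px)
feats <- extract_features(slide$tiles, slide$bundle$image, ex)
model <- train_finest(slide$bundle, feats, slide$tiles,
                      train_config(K = 64, h = 32, epochs = 120, lr = 2e-3,
                                   seed = 2))
model
#> finest_model: C = 32 -> h = 32 -> p = 60 ; best held-out epoch 41

pred    <- infer_subspot_expression(model, feats)
imputed <- impute_tiles(pred, slide$tiles, slide$bundle,
                        impute_config(kappa = 6, alpha = 0.5))
summary(pcc_per_gene(slide$truth$tile_truth, imputed))
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>  0.2705  0.3268  0.3462  0.3473  0.3685  0.4391

norm <- preprocess_counts(slide$bundle, normalize = TRUE)
res  <- discover_lr(norm$counts,
                    cbind(norm$spot_coords$x, norm$spot_coords$y),
                    slide$lr_db)
res
#> moran_result: 15 pairs on 400 locations; 6 selected, 6 eligible for patterns
head(res$pairs[order(res$pairs$p),
               c("pair", "pathway", "R_global", "z", "q", "n_interacting")])
#>        pair pathway  R_global        z            q n_interacting
#> 2 LG02:RC02     PW1 0.7675274 9.087449 7.604245e-19            82
#> 4 LG04:RC04     PW1 0.5878304 6.959854 1.277346e-11            73
#> 3 LG03:RC03     PW1 0.5443082 6.444556 2.898490e-10            75
#> 1 LG01:RC01     PW1 0.4068020 4.816496 2.739402e-06            54
#> 5 LG05:RC05     PW1 0.3737133 4.424728 1.448457e-05            59
#> 6 LG06:RC06     PW2 0.2198311 2.602779 1.155894e-02            27
```

Reading the output: the per-gene Pearson correlations compare the imputed
14-px-tile expression against the generator's known tile-level truth — the
blend beats neighborhood smoothing alone for essentially every gene on
this fixture. In the discovery table, the five planted pairs
(`LG01:RC01` … `LG05:RC05`, all assigned to pathway `PW1` by the
generator) occupy the top five ranks with BH-adjusted q-values ≪ 0.05 and
dozens of interacting locations each; one unplanted pair squeaks past the
threshold, which is within the expected false-selection rate at these
conditions. Downstream:

```r
enr <- pathway_enrichment(res$pairs$pair[res$pairs$selected], slide$lr_db,
                          res$pairs$pair[res$pairs$tested])
enr[1:2, c("pathway", "pairs_in_query", "pairs_in_pathway", "fraction", "p")]
#>   pathway pairs_in_query pairs_in_pathway  fraction          p
#> 1     PW1              5                7 0.7142857 0.03496503
#> 2     PW2              1                3 0.3333333 0.81538462
```

The planted pathway is the only enriched one. Pattern clustering
(`build_pattern_input()` + `fit_aeh_sparse()`), network extraction
(`extract_lr_tf_tg()` with the generated R-TF / TF-TG tables) and
co-localization (`colocalization()`) continue from `res` the same way; the
staged command-line interface in `inst/cli/finespot.R` runs
simulate → train → impute → discover → patterns → enrich from one YAML
config.

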