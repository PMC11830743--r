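# gclvae

Booster variational autoencoder (bVAE) for macular ganglion cell + inner
plexiform layer (GCIPL) thickness maps.

Optic neuropathies destroy retinal ganglion cells in spatially distinct
ways — glaucoma preferentially thins the inferior macula, optic neuritis
(ON) thins it diffusely, and NAION thins the superior macula after a
transient edema phase. `gclvae` is aimed at researchers who want a compact,
anatomically interpretable representation of these patterns: it encodes a
200 × 200 px (6 × 6 mm) GCIPL thickness map into two *display latents*
(d1, d2) plus eight *booster latents* (b1–b8), decodes latent-space montage
maps, tracks eyes through the space across visits, and classifies thinning
status and cause from longitudinal latent features.

## The model

An encoder `E` decomposes a map `x` into posteriors over `d` and `b`, a
fovea estimate `(f_x, f_y)` and a poor-quality flag `f_EXC`. A display
decoder reconstructs a fovea-centered crop `x_C` from `d` alone (`y_D`); a
booster decoder uses all ten latents to add residual detail (`y_B`), with

    y = y_D + y_B            (exact, elementwise)

During training the display latents are KL-regularized and *anatomically
anchored*: with `r_inf`, `r_sup` the inferior/superior mean thicknesses of
the Cirrus-style elliptical annulus (vertical radii 0.5/2.0 mm, horizontal
0.6/2.4 mm; sectors SN, S, ST, IT, I, IN) divided by 80 µm, the penalties

    (d1 − t(r_inf))²,  (d2 − t(r_sup))²,   t(r) = 10 (r − 0.8)

lay the space out with inferior thinning upper-left, normal upper-right,
diffuse thinning lower-left and superior thinning lower-right.

Because clinical scans are not distributable, the package ships a seeded
phantom generator: an elliptical annular ridge of peak thickness around the
fovea, disease-specific raised-cosine hemifield thinning, fovea
decentration, correlated noise, epiretinal-membrane (ERM) and poor-quality
artifacts, and linear severity progression across visits. Its calibration
constants are solved so class cohorts reproduce reference mean sector
thicknesses (normal 78.68, glaucoma 65.48, NAION 72.03, ON 71.29 µm).

## Worked example

```r
library(gclvae)

# train a small model on a seeded synthetic cohort (64 x 64 phantoms)
ck <- harness_train(seed = 7)           # ~4 min on one CPU
ev <- harness_eval(ck, seed = 7)

ev$quadrant_accuracy
#> [1] 1
round(c(display = ev$rmse_display_um, full = ev$rmse_full_um), 2)
#> display    full
#>    3.09    2.95
ev$fovea
#>   axis    mean_px    sd_px
#> f_x    x  0.3126019 1.207889
#> f_y    y -0.7112531 1.176442
round(ev$qc_auc, 4)
#> [1] 0.9978
```

All 200 held-out high-severity phantoms land in their expected latent
quadrant; the booster latents reduce reconstruction RMSE below the
display-only reconstruction (3.09 → 2.95 µm here, paired Wilcoxon
p ≈ 8e-4); the fovea is recovered to within a pixel on average
(0.03 mm pixels); and poor-quality scans are flagged with AUC ≈ 1.

Single maps work the same way:

```r
m  <- make_gcipl_map(phantom_params("inferior", severity = 0.8), seed = 1,
                     img_px = 64)
cd <- encode(ck$model, m)
cd$d                  # display latents: strongly negative d1 (inferior)
rp <- decode_full(ck$model, cd)     # y_D, y_B, y = y_D + y_B
mm <- make_montage(ck$model)        # 14 x 10 tile latent-space montage
plot(mm, file = "montage.png",
     contours = kde_contours(as.matrix(encode_table(ck$model,
       lapply(1:100, function(i)
         make_gcipl_map(phantom_params("normal"), i, 64)))[, c("d1", "d2")])))
```

A thin command-line wrapper (`inst/cli/gclvae`) exposes
`simulate`, `train`, `encode`, `montage`, `classify` and `evaluate`
subcommands over the same functions.

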