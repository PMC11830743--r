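Package: gclvae
Title: Booster Variational Autoencoder for Macular GCIPL Thickness Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes macular ganglion cell + inner plexiform layer (GCIPL)
    thickness maps into a two-dimensional, anatomically organized latent
    space plus eight booster latents using a booster variational
    autoencoder (bVAE). Provides a seeded synthetic GCIPL phantom
    generator (annular thickness model with disease-specific hemifield
    thinning, artifacts and longitudinal progression), the Cirrus-style
    elliptical annulus sector grid, latent-space montage maps with
    kernel-density normative contours, longitudinal trajectory tracking,
    gradient-boosted classification of thinning status and cause, and a
    reconstruction/QC evaluation battery (RMSE, SSIM, sector differences,
    fovea error).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    yaml,
    jsonlite,
    xgboost,
    pROC
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
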