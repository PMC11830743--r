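test_that("identical (params, seed) yield bit-identical maps", {
  p <- phantom_params("inferior", severity = 0.4, noise_sd = 2,
                      artifact = "erm_focal_thickening")
  a <- make_gcipl_map(p, seed = 42L, img_px = 64)
  b <- make_gcipl_map(p, seed = 42L, img_px = 64)
  expect_identical(a, b)
  expect_false(identical(unclass(a),
                         unclass(make_gcipl_map(p, seed = 43L, 64))))
})

test_that("severity-zero noise-free phantom is up/down symmetric with equal sector means", {
  p <- phantom_params("normal", severity = 0, noise_sd = 0)
  m <- make_gcipl_map(p, seed = 1L)
  prof <- sector_means(m)
  expect_equal(max(prof$sector_means) - min(prof$sector_means), 0,
               tolerance = 0.05)
  # exact hemifield symmetry of the rendered field
  msk <- sector_masks(annulus_geometry(200), attr(m, "fovea"))
  inf_mean <- mean(m[msk$IT | msk$I | msk$IN])
  sup_mean <- mean(m[msk$ST | msk$S | msk$SN])
  expect_identical(inf_mean, sup_mean)
})

test_that("inferior thinning removes the expected share of above-floor annulus signal", {
  # brute-force pixel-sum oracle: compare rendered maps directly
  p0 <- phantom_params("inferior", severity = 0, noise_sd = 0)
  p5 <- phantom_params("inferior", severity = 0.5, noise_sd = 0)
  m0 <- make_gcipl_map(p0, 1L)
  m5 <- make_gcipl_map(p5, 1L)
  msk <- sector_masks(annulus_geometry(200), attr(m0, "fovea"))
  inf <- msk$IT | msk$I | msk$IN
  ratio <- sum(m5[inf] - p5$base_floor) / sum(m0[inf] - p0$base_floor)
  # the raised-cosine shoulders leak ~2% of the bump outside the hemifield,
  # so the removed share sits slightly above 1 - severity
  expect_equal(ratio, 0.5, tolerance = 0.03)
  # independent pixel-loop oracle for the exact value
  w_mean <- local({
    num <- den <- 0
    idx <- which(inf, arr.ind = TRUE)
    for (k in seq_len(nrow(idx))) {
      g0 <- m0[idx[k, 1], idx[k, 2]] - p0$base_floor
      g5 <- m5[idx[k, 1], idx[k, 2]] - p5$base_floor
      num <- num + (g0 - g5); den <- den + g0
    }
    num / den
  })
  expect_equal(ratio, 1 - w_mean, tolerance = 1e-12)
})

test_that("affected-hemifield mean thickness is non-increasing in severity", {
  for (cls in c("inferior", "superior", "diffuse")) {
    sev <- seq(0, 1, by = 0.2)
    means <- vapply(sev, function(s) {
      m <- make_gcipl_map(phantom_params(cls, severity = s, noise_sd = 1),
                          seed = 9L, img_px = 64)
      msk <- sector_masks(annulus_geometry(64), attr(m, "fovea"))
      aff <- switch(cls, inferior = msk$IT | msk$I | msk$IN,
                    superior = msk$ST | msk$S | msk$SN, msk$annulus)
      mean(m[aff])
    }, numeric(1))
    expect_true(all(diff(means) < 0), info = cls)
  }
})

test_that("parameter validation rejects invalid and non-finite settings", {
  expect_error(phantom_params(severity = 1.5), "severity")
  expect_error(phantom_params(noise_sd = -1), "noise_sd")
  expect_error(phantom_params(ring_radius_mm = 3.5), "ring_radius_mm")
  expect_error(phantom_params(base_floor = NaN), "finite")
})

test_that("laterality OS mirrors the map and its fovea", {
  pod <- phantom_params("inferior", severity = 0.5, noise_sd = 0,
                        fovea_offset_px = c(5, -3))
  pos <- pod; pos$laterality <- "OS"
  class(pos) <- class(pod)
  mod <- make_gcipl_map(pod, 3L, 64)
  mos <- make_gcipl_map(pos, 3L, 64)
  expect_identical(unclass(mod)[, 64:1], unclass(mos)[, ])
  expect_equal(attr(mos, "fovea")[1], 63 - attr(mod, "fovea")[1])
})

test_that("eye series severities follow the progression rule and label threshold", {
  p <- phantom_params("inferior", severity = 0.1)
  es <- make_eye_series(p, n_visits = 4, progression_rate = 0.15,
                        seed = 5L, img_px = 32)
  expect_equal(es$severities, c(0.1, 0.25, 0.40, 0.55))
  expect_identical(es$progression_label, "beyond_normal_range")
  expect_length(es$intervals_days, 3L)

  es0 <- make_eye_series(phantom_params("normal"), 3, 0, seed = 5L,
                         img_px = 32)
  expect_identical(es0$progression_label, "within_normal_range")
  expect_equal(es0$severities, rep(0, 3))
})

test_that("NAION edema series starts thick then thins below the template", {
  p <- phantom_params("superior", severity = 0.05, noise_sd = 0,
                      edema = TRUE)
  es <- make_eye_series(p, n_visits = 4, progression_rate = 0.25,
                        seed = 8L, img_px = 64)
  template <- make_gcipl_map(phantom_params("normal", noise_sd = 0),
                             1L, 64)
  ann <- sector_masks(annulus_geometry(64), attr(template, "fovea"))$annulus
  ref <- mean(template[ann])
  expect_gt(mean(es$maps[[1]][ann]), ref)     # transient thickening
  expect_lt(mean(es$maps[[4]][ann]), ref)     # later atrophy
})

test_that("poor-quality maps drop out a large region and are flagged", {
  m <- make_gcipl_map(phantom_params("normal", artifact = "poor_quality"),
                      2L, 64)
  expect_identical(attr(m, "qc"), "poor")
  expect_gte(mean(unclass(m) == 0), 0.15)
})

test_that("empty cohort is valid and cohorts are seed-deterministic", {
  sp <- cohort_spec(counts = c(normal = 0, glaucoma = 0, ON = 0, NAION = 0))
  empty <- make_cohort(sp, seed = 1L)
  expect_length(empty$series, 0L)
  expect_identical(nrow(empty$manifest), 0L)
  expect_named(empty$manifest,
               c("subject_id", "eye", "visit_idx", "interval_days",
                 "disease_label", "progression_label", "qc_label",
                 "fovea_x_px", "fovea_y_px", "path"))

  sp2 <- cohort_spec(counts = c(normal = 3, glaucoma = 3, ON = 0, NAION = 0),
                     n_visits = c(2, 3), img_px = 32)
  c1 <- make_cohort(sp2, seed = 11L)
  c2 <- make_cohort(sp2, seed = 11L)
  expect_identical(c1, c2)
})

test_that("class presets assign the expected angular patterns", {
  expect_named(class_preset("glaucoma")$patterns,
               c("inferior", "superior"))
  expect_identical(names(class_preset("ON")$patterns), "diffuse")
  expect_identical(names(class_preset("NAION")$patterns), "superior")
  expect_identical(names(class_preset("normal")$patterns), "normal")
})
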