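geom200 <- annulus_geometry(200)

test_that("sector masks partition the annulus for random fovea positions", {
  set.seed(101)
  for (i in 1:20) {
    fov <- runif(2, 85, 114)
    msk <- sector_masks(geom200, fov)
    stack <- msk$SN + msk$S + msk$ST + msk$IT + msk$I + msk$IN
    expect_true(all(stack[msk$annulus] == 1L))
    expect_true(all(stack[!msk$annulus] == 0L))
  }
})

test_that("centered fovea gives mirror-symmetric S and I masks", {
  msk <- sector_masks(geom200, c(99.5, 99.5))
  expect_identical(sum(msk$S), sum(msk$I))
  expect_identical(unname(msk$S[200:1, ]), unname(msk$I))
})

test_that("annulus pixel count matches the analytic ellipse-area formula", {
  msk <- sector_masks(geom200, c(99.5, 99.5))
  analytic <- pi * (2.4 * 2.0 - 0.6 * 0.5) / 0.03^2
  expect_lt(abs(sum(msk$annulus) - analytic) / analytic, 0.01)
})

test_that("fovea near the border flags a clipped annulus", {
  msk <- sector_masks(geom200, c(30, 99.5))
  expect_true(msk$clipped)
  expect_false(sector_masks(geom200, c(99.5, 99.5))$clipped)
  expect_error(sector_masks(geom200, c(-1, 50)), "inside the image")
})

test_that("constant maps give exact sector means and the weighted-mean identity holds", {
  m <- matrix(70, 200, 200)
  prof <- sector_means(m, fovea_px = c(99.5, 99.5))
  expect_identical(unname(prof$sector_means), rep(70, 6))
  expect_identical(prof$annulus_mean, 70)

  m2 <- make_gcipl_map(phantom_params("inferior", severity = 0.6), 4L)
  p2 <- sector_means(m2)
  expect_equal(p2$annulus_mean,
               sum(p2$sector_means * p2$pixel_counts) / sum(p2$pixel_counts),
               tolerance = 1e-12)
})

test_that("sector_means is linear in the map", {
  a <- make_gcipl_map(phantom_params("inferior", severity = 0.5), 1L, 64)
  b <- make_gcipl_map(phantom_params("superior", severity = 0.3), 2L, 64)
  fov <- c(31.5, 31.5)
  pa <- sector_means(unclass(a), fov)
  pb <- sector_means(unclass(b), fov)
  pc <- sector_means(2 * unclass(a) + 3 * unclass(b), fov)
  expect_equal(pc$sector_means, 2 * pa$sector_means + 3 * pb$sector_means,
               tolerance = 1e-10)
})

test_that("sector ratio of an inferior phantom matches a brute-force pixel loop", {
  m <- make_gcipl_map(phantom_params("inferior", severity = 0.5,
                                     noise_sd = 0), 1L)
  prof <- sector_means(m)
  wmean <- function(s) sum(prof$sector_means[s] * prof$pixel_counts[s]) /
    sum(prof$pixel_counts[s])
  r_pkg <- wmean(c("IT", "I", "IN")) / wmean(c("ST", "S", "SN"))
  # independent oracle: explicit loop over pixels using raw ellipse algebra
  fov <- attr(m, "fovea")
  sums <- counts <- c(inf = 0, sup = 0)
  for (col in 1:200) {
    x <- (col - 1 - fov[1]) * 0.03
    for (row in 1:200) {
      y <- (fov[2] - (row - 1)) * 0.03
      if ((x / 0.6)^2 + (y / 0.5)^2 >= 1 &&
          (x / 2.4)^2 + (y / 2.0)^2 <= 1) {
        h <- if (y < 0) "inf" else if (y > 0) "sup" else NA
        if (!is.na(h)) {
          sums[h] <- sums[h] + m[row, col]
          counts[h] <- counts[h] + 1
        }
      }
    }
  }
  # sector wedges split exactly at the horizontal meridian, so the
  # hemifield decomposition must agree
  r_loop <- (sums["inf"] / counts["inf"]) / (sums["sup"] / counts["sup"])
  expect_equal(unname(r_pkg), unname(r_loop), tolerance = 1e-9)
})

test_that("hemifield ratios are unit for constant maps and scale linearly", {
  m <- matrix(80, 200, 200)
  prof <- sector_means(m, c(99.5, 99.5))
  expect_equal(unname(hemifield_ratios(prof, 80)), c(1, 1),
               tolerance = 1e-12)
  prof_half <- sector_means(m * 0.5, c(99.5, 99.5))
  expect_equal(unname(hemifield_ratios(prof_half, 80)), c(0.5, 0.5),
               tolerance = 1e-12)
})

test_that("inferior thinning lowers r_inf monotonically with little r_sup change", {
  sev <- c(0, 0.25, 0.5, 0.75, 1)
  ratios <- t(vapply(sev, function(s) {
    m <- make_gcipl_map(phantom_params("inferior", severity = s,
                                       noise_sd = 0), 1L, 64)
    hemifield_ratios(sector_means(m), 80)
  }, numeric(2)))
  expect_true(all(diff(ratios[, "r_inf"]) < 0))
  expect_lt(max(abs(ratios[, "r_sup"] / ratios[1, "r_sup"] - 1)), 0.02)
})

test_that("empty sectors yield NA sentinels, never silent zeros", {
  # fovea close to the edge clips the temporal sectors at a small raster
  m <- matrix(70, 64, 64)
  prof <- sector_means(m, fovea_px = c(2, 31.5), geometry =
                         annulus_geometry(64))
  expect_true(prof$clipped)
  expect_true(all(is.na(prof$sector_means) |
                    prof$sector_means == 70))
})
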