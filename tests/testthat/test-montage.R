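small_model <- function() bvae_init(bvae_config(img_px = 12L, width = 6L,
                                                seed = 5L))

test_that("the default montage grid has 14 x 10 tiles and large steps keep endpoints", {
  model <- small_model()
  mm <- make_montage(model, c(-5, 8), c(-5, 4), step = 1)
  expect_length(mm$d1, 14L)
  expect_length(mm$d2, 10L)
  expect_identical(mm$d1, as.numeric(-5:8))
  mm2 <- make_montage(model, c(-5, 8), c(-5, 4), step = 13)
  expect_identical(mm2$d1, c(-5, 8))
})

test_that("every tile equals decode_display at its node and repeated calls are identical", {
  model <- small_model()
  mm <- make_montage(model, c(-2, 2), c(-1, 1), step = 1)
  set.seed(6)
  for (k in 1:10) {
    i <- sample(length(mm$d1), 1); j <- sample(length(mm$d2), 1)
    # batched and single-row BLAS products differ at machine precision
    expect_equal(mm$tiles[[i]][[j]],
                 decode_display(model, c(mm$d1[i], mm$d2[j])),
                 tolerance = 1e-10)
  }
  expect_identical(mm, make_montage(model, c(-2, 2), c(-1, 1), step = 1))
})

test_that("KDE contours translate with the points and cover the target mass", {
  set.seed(41)
  pts <- cbind(rnorm(500), rnorm(500))
  ct <- kde_contours(pts, levels = 0.5)
  shifted <- pts + matrix(rep(c(3, -2), each = 500), ncol = 2)
  ct2 <- kde_contours(shifted, levels = 0.5)
  p1 <- ct$polylines$p50[[1]]
  p2 <- ct2$polylines$p50[[1]]
  expect_equal(p1$x + 3, p2$x, tolerance = 1e-8)
  expect_equal(p1$y - 2, p2$y, tolerance = 1e-8)
})

test_that("degenerate point sets fall back to the bandwidth floor with a warning", {
  pts <- cbind(rep(1, 20), seq(0, 1, length.out = 20))
  expect_warning(ct <- kde_contours(pts, levels = 0.5), "bandwidth floor")
  expect_gte(min(ct$bandwidth), 1e-3)
})

test_that("trajectories keep visit order, annotate months, and degrade to points", {
  codes <- lapply(1:3, function(k)
    structure(list(d = c(k, 2 * k), b = rep(0, 8), d_logvar = rep(0, 2),
                   b_logvar = rep(0, 8), fovea_px = c(0, 0),
                   exclude_prob = 0), class = "latent_code"))
  tr <- plot_trajectory(codes, intervals_days = c(91L, 30L))
  expect_equal(tr$points$d1, 1:3)
  expect_identical(tr$segments$label[1], "3.0 months")
  # identical codes -> zero-length polyline
  same <- plot_trajectory(rbind(c(1, 1), c(1, 1)), 60L)
  expect_equal(same$segments$x0, same$segments$x1)
  single <- plot_trajectory(rbind(c(0.5, -0.5)))
  expect_identical(nrow(single$segments), 0L)
  expect_identical(nrow(single$points), 1L)
  expect_error(plot_trajectory(rbind(c(0, 0), c(1, 1)), integer(0)))
})

test_that("montage and overlays render to files", {
  model <- small_model()
  mm <- make_montage(model, c(-1, 1), c(-1, 1), step = 1)
  set.seed(2)
  ct <- kde_contours(cbind(rnorm(50), rnorm(50)))
  tr <- plot_trajectory(rbind(c(0, 0), c(1, -1)), 45L)
  png <- tempfile(fileext = ".png")
  plot(mm, file = png, contours = ct, trajectories = list(tr))
  expect_true(file.exists(png) && file.size(png) > 0)
  js <- tempfile(fileext = ".json")
  montage_overlays_json(js, contours = ct, trajectories = list(eye = tr))
  parsed <- jsonlite::read_json(js)
  expect_true(all(c("contours", "trajectories") %in% names(parsed)))
})
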