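# A tiny model is enough for the interface and gradient checks.
tiny_model <- function(img = 12L, width = 6L, seed = 3L) {
  bvae_init(bvae_config(img_px = img, width = width, seed = seed))
}

tiny_batch_maps <- function(img = 12L) {
  list(
    make_gcipl_map(phantom_params("inferior", severity = 0.5,
                                  fovea_offset_px = c(1, -1)), 1L, img),
    make_gcipl_map(phantom_params("normal", artifact = "poor_quality"),
                   2L, img),
    make_gcipl_map(phantom_params("superior", severity = 0.8,
                                  laterality = "OS"), 3L, img)
  )
}

test_that("encode returns the full latent contract for any valid map", {
  model <- tiny_model()
  cd <- encode(model, tiny_batch_maps()[[1]])
  expect_s3_class(cd, "latent_code")
  expect_length(cd$d, 2L)
  expect_length(cd$b, 8L)
  expect_length(cd$d_logvar, 2L)
  expect_length(cd$b_logvar, 8L)
  expect_true(all(cd$fovea_px >= 0 & cd$fovea_px < 12))
  expect_true(cd$exclude_prob >= 0 && cd$exclude_prob <= 1)
  expect_true(all(is.finite(unlist(cd[c("d", "b", "d_logvar",
                                        "b_logvar")]))))
})

test_that("encode rejects maps of the wrong raster size", {
  model <- tiny_model(img = 12L)
  expect_error(encode(model, matrix(70, 16, 16)), "12 x 12")
})

test_that("decode_display is deterministic and non-negative", {
  model <- tiny_model()
  a <- decode_display(model, c(0.3, -1.2))
  b <- decode_display(model, c(0.3, -1.2))
  expect_identical(a, b)
  expect_true(all(a >= 0))
  expect_identical(dim(a), c(10L, 10L))  # crop at 0.8 x raster
})

test_that("the additive identity y = y_D + y_B holds exactly for random codes", {
  model <- tiny_model()
  set.seed(9)
  for (i in 1:10) {
    cd <- structure(list(d = rnorm(2, sd = 3), b = rnorm(8),
                         d_logvar = rnorm(2), b_logvar = rnorm(8),
                         fovea_px = c(6, 6), exclude_prob = 0.1),
                    class = "latent_code")
    rp <- decode_full(model, cd)
    expect_identical(rp$y, rp$y_D + rp$y_B)
  }
})

test_that("encode-decode at posterior mean is deterministic", {
  model <- tiny_model()
  m <- tiny_batch_maps()[[1]]
  r1 <- decode_full(model, encode(model, m))
  r2 <- decode_full(model, encode(model, m))
  expect_identical(r1, r2)
})

test_that("KL divergence matches its closed form and a Monte-Carlo estimate", {
  expect_identical(kl_divergence(0, 0), 0)
  expect_equal(kl_divergence(1, 0), 0.5)
  expect_equal(kl_divergence(c(1, 1), c(0, 0)), 1)

  set.seed(20)
  for (i in 1:3) {
    mu <- rnorm(1); lv <- runif(1, -1.5, 1)
    n <- 1e6
    z <- rnorm(n, mu, exp(lv / 2))
    # log q(z) - log p(z) sampled under q
    ratio <- dnorm(z, mu, exp(lv / 2), log = TRUE) - dnorm(z, log = TRUE)
    mc <- mean(ratio); se <- sd(ratio) / sqrt(n)
    expect_lt(abs(kl_divergence(mu, lv) - mc), 3 * se)
  }
})

test_that("anatomical penalty is zero at the anchors and lays out the montage axes", {
  cfg <- bvae_config()
  expect_equal(unname(anatomical_penalty(
    c(anchor_map(0.9, cfg), anchor_map(1.1, cfg)), 0.9, 1.1, cfg)),
    c(0, 0))
  # anchor map is monotone increasing: thinner inferior region => lower d1
  rs <- seq(0.2, 1.2, by = 0.1)
  expect_true(all(diff(anchor_map(rs, cfg)) > 0))
  # configured constants: 50% thinning anchors at/below -3, normal in [1,4]
  expect_lte(anchor_map(0.5, cfg), -3)
  expect_true(anchor_map(1.0, cfg) >= 1 && anchor_map(1.0, cfg) <= 4)
  expect_true(anchor_map(78.68 / 80, cfg) >= 1 &&
                anchor_map(78.68 / 80, cfg) <= 4)
})

test_that("loss components are non-negative and total is linear in the weights", {
  model <- tiny_model()
  maps <- tiny_batch_maps()
  l <- compute_losses(model, maps)
  expect_true(all(l >= 0))
  comp <- l[setdiff(names(l), "total")]
  expect_equal(unname(l[["total"]]),
               sum(model$config$weights * comp), tolerance = 1e-12)

  m2 <- model
  m2$config$weights[["recon_full"]] <- 2 * m2$config$weights[["recon_full"]]
  l2 <- compute_losses(m2, maps)
  expect_equal(l2[["total"]] - l[["total"]],
               l[["recon_full"]] * model$config$weights[["recon_full"]],
               tolerance = 1e-12)
})

test_that("poor-quality samples contribute only the exclusion loss", {
  model <- tiny_model()
  poor <- list(make_gcipl_map(phantom_params("normal",
                                             artifact = "poor_quality"),
                              5L, 12L))
  l <- compute_losses(model, poor)
  for (nm in c("recon_display", "recon_full", "kl_d", "kl_b",
               "anat_d1", "anat_d2", "fovea"))
    expect_identical(unname(l[[nm]]), 0)
  expect_gt(l[["exclude"]], 0)
})

test_that("analytic gradients of the total loss match central finite differences", {
  model <- tiny_model(img = 10L, width = 5L, seed = 11L)
  maps <- tiny_batch_maps(img = 10L)
  cfg <- model$config
  X <- gclvae:::.as_batch(maps, cfg)
  batch <- gclvae:::.prepare_batch(maps, cfg)
  set.seed(33)
  eps_d <- matrix(rnorm(nrow(X) * 2), nrow(X))
  eps_b <- matrix(rnorm(nrow(X) * 8), nrow(X))
  fw <- gclvae:::.bvae_forward(model, X, eps_d, eps_b)
  # the booster target is a fixed input to the loss, frozen here
  batch <- gclvae:::.with_resid(batch, fw)
  grads <- gclvae:::.bvae_backward(model, fw, batch, X)
  loss_at <- function(net) {
    m2 <- model; m2$net <- net
    fw2 <- gclvae:::.bvae_forward(m2, X, eps_d, eps_b)
    gclvae:::.bvae_losses(fw2, batch, cfg)[["total"]]
  }
  h <- 1e-5
  worst <- 0
  for (comp in names(model$net)) {
    for (li in seq_along(model$net[[comp]])) {
      for (pn in intersect(names(model$net[[comp]][[li]]),
                           c("W", "b", "W1", "b1", "W2", "b2"))) {
        P <- model$net[[comp]][[li]][[pn]]
        for (i in seq_along(P)) {
          np <- model$net; np[[comp]][[li]][[pn]][i] <- P[i] + h
          nm <- model$net; nm[[comp]][[li]][[pn]][i] <- P[i] - h
          g_fd <- (loss_at(np) - loss_at(nm)) / (2 * h)
          g_an <- grads[[comp]][[li]][[pn]][i]
          denom <- max(abs(g_fd) + abs(g_an), 1e-4)
          worst <- max(worst, abs(g_fd - g_an) / denom)
        }
      }
    }
  }
  expect_lt(worst, 1e-4)
})
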