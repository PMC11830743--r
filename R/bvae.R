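#' @name bvae
#' @title Booster variational autoencoder for GCIPL thickness maps
#'
#' @description
#' The bVAE consists of an encoder `E`, a display decoder `D_D` and a booster
#' decoder `D_B`, co-trained without parameter sharing. `E` decomposes an
#' input map `x` into two display latents (d1, d2), eight booster latents
#' (b1-b8), a fovea estimate (f_x, f_y) and a poor-quality exclusion
#' probability (f_EXC). `D_D` reconstructs a fovea-centered crop `x_C` of the
#' input from the dLVs alone (`y_D`); `D_B` consumes all ten latents and adds
#' the residual fine detail (`y_B`), so the full reconstruction is
#' `y = y_D + y_B` exactly. During training the dLVs are regularized by a KL
#' divergence against the unit Gaussian and anchored anatomically: d1 to the
#' inferior-hemifield annulus thickness ratio and d2 to the superior ratio,
#' which lays the latent space out with inferior thinning to the upper left,
#' normal eyes to the upper right, diffuse thinning to the lower left and
#' superior thinning to the lower right.
NULL

#' Default bVAE configuration
#'
#' @param img_px Input raster size (square).
#' @param width Trunk width of encoder/decoders.
#' @param seed Seed controlling weight initialization and sampling.
#' @return A named list of architecture, normalization, anchor and loss
#'   weight settings.
#' @export
bvae_config <- function(img_px = 200L, width = 256L, seed = 1L) {
  img_px <- as.integer(img_px)
  list(
    img_px = img_px,
    crop_px = 2L * as.integer(round(0.4 * img_px)),  # 160 at 200 px
    width = as.integer(width),
    n_d = 2L, n_b = 8L,
    norm_scale = 150,          # um; thickness / 150, clipped to [0, 1.3]
    norm_clip = 1.3,
    anchor_scale = 10,         # t(r) = anchor_scale * (r - anchor_center)
    anchor_center = 0.8,
    reference_um = 80,
    logvar_cap = 5,            # soft bound: logvar = cap * tanh(z / cap)
    # kl_b must be well below the normalized-unit reconstruction gain the
    # boosters can deliver (~1e-3), or their posterior rationally collapses
    # to the prior and y_B degenerates to zero
    weights = c(recon_display = 1, recon_full = 1, kl_d = 1e-3, kl_b = 1e-4,
                anat_d1 = 0.5, anat_d2 = 0.5, fovea = 1, exclude = 0.1),
    seed = as.integer(seed)
  )
}

#' Initialize a bVAE model
#'
#' Builds the encoder trunk (dense + residual blocks), the six encoder heads
#' and the two decoders, with weights drawn from the seed in `config`.
#'
#' @param config A [bvae_config()].
#' @return A `bvae_model` list (layers plus config).
#' @export
bvae_init <- function(config = bvae_config()) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(config$seed, 101L))
  n_in <- config$img_px^2
  n_out <- config$crop_px^2
  w <- config$width
  model <- list(
    trunk = list(nn_dense(n_in, w, "tanh"), nn_res(w), nn_res(w)),
    head_d_mu  = list(nn_dense(w, config$n_d, "linear")),
    head_d_lv  = list(nn_dense(w, config$n_d, "linear")),
    head_b_mu  = list(nn_dense(w, config$n_b, "linear")),
    head_b_lv  = list(nn_dense(w, config$n_b, "linear")),
    # heads are filled in below; log-variance biases start negative so the
    # posteriors begin sharp and reparameterization noise cannot drown the
    # booster signal before the decoders learn to use it
    head_fovea = list(nn_dense(w, 32L, "tanh"), nn_dense(32L, 2L, "sigmoid")),
    head_exc   = list(nn_dense(w, 16L, "tanh"), nn_dense(16L, 1L, "sigmoid")),
    dec_d = list(nn_dense(config$n_d, w, "tanh"), nn_res(w),
                 nn_dense(w, n_out, "linear")),
    dec_b = list(nn_dense(config$n_d + config$n_b, w, "tanh"), nn_res(w),
                 nn_dense(w, n_out, "linear"))
  )
  model$head_d_lv[[1]]$b[] <- -2
  model$head_b_lv[[1]]$b[] <- -4
  # the booster latents live on a much smaller scale than the anchored
  # display latents (+-5); gain up both sides of the b pathway so its
  # gradient signal is not starved at initialization
  model$head_b_mu[[1]]$W <- model$head_b_mu[[1]]$W * 4
  model$dec_b[[1]]$W[config$n_d + seq_len(config$n_b), ] <-
    model$dec_b[[1]]$W[config$n_d + seq_len(config$n_b), ] * 4
  structure(list(net = model, config = config), class = "bvae_model")
}

#' @export
print.bvae_model <- function(x, ...) {
  cfg <- x$config
  np <- sum(unlist(tree_map(length, layers_params(unlist(x$net,
                                                         recursive = FALSE)))))
  cat(sprintf(
    "bVAE model: %d x %d input, crop %d, width %d, 2 dLV + 8 bLV, %d params\n",
    cfg$img_px, cfg$img_px, cfg$crop_px, cfg$width, np))
  invisible(x)
}

# normalization helpers -----------------------------------------------------

.norm_map <- function(x, cfg) pmin(pmax(x / cfg$norm_scale, 0), cfg$norm_clip)
.denorm_map <- function(z, cfg) pmax(z * cfg$norm_scale, 0)

# flatten a map matrix (or list of maps) into a batch row matrix
.as_batch <- function(maps, cfg) {
  if (is.matrix(maps) && !is.list(maps)) maps <- list(maps)
  n <- cfg$img_px
  bad <- vapply(maps, function(m) nrow(m) != n || ncol(m) != n, logical(1))
  if (any(bad))
    stop(sprintf("map raster must be %d x %d px for this model", n, n))
  X <- do.call(rbind, lapply(maps, function(m) as.numeric(unclass(m))))
  .norm_map(X, cfg)
}

.soft_logvar <- function(z, cap) cap * tanh(z / cap)

# full forward pass on a normalized batch; eps_* NULL means posterior mean
.bvae_forward <- function(model, X, eps_d = NULL, eps_b = NULL) {
  net <- model$net; cfg <- model$config
  tr <- nn_forward(net$trunk, X)
  H <- tr$out
  hd <- lapply(net[c("head_d_mu", "head_d_lv", "head_b_mu", "head_b_lv",
                     "head_fovea", "head_exc")],
               function(l) nn_forward(l, H))
  d_mu <- hd$head_d_mu$out
  b_mu <- hd$head_b_mu$out
  d_lv <- .soft_logvar(hd$head_d_lv$out, cfg$logvar_cap)
  b_lv <- .soft_logvar(hd$head_b_lv$out, cfg$logvar_cap)
  z_d <- if (is.null(eps_d)) d_mu else d_mu + exp(0.5 * d_lv) * eps_d
  z_b <- if (is.null(eps_b)) b_mu else b_mu + exp(0.5 * b_lv) * eps_b
  dd <- nn_forward(net$dec_d, z_d)
  db <- nn_forward(net$dec_b, cbind(z_d, z_b))
  list(trunk = tr, heads = hd, d_mu = d_mu, d_lv = d_lv, b_mu = b_mu,
       b_lv = b_lv, z_d = z_d, z_b = z_b, eps_d = eps_d, eps_b = eps_b,
       dec_d = dd, dec_b = db,
       y_D = dd$out, y_B = db$out, y = dd$out + db$out,
       fovea = hd$head_fovea$out, exc = hd$head_exc$out)
}

#' Encode thickness maps into latent codes
#'
#' Runs the encoder at the posterior mean (temperature 0). Maps must match
#' the model raster exactly; no silent resizing happens here (resizing
#' belongs to [read_thickness_map()]).
#'
#' @param model A trained [bvae_init()] model.
#' @param maps A single thickness map or a list of maps.
#' @return A `latent_code` for one map, or a list of codes.
#' @export
encode <- function(model, maps) {
  stopifnot(inherits(model, "bvae_model"))
  single <- is.matrix(maps) && !is.list(maps)
  X <- .as_batch(maps, model$config)
  fw <- .bvae_forward(model, X)
  n <- model$config$img_px
  codes <- lapply(seq_len(nrow(X)), function(i) {
    structure(list(
      d = as.numeric(fw$d_mu[i, ]), b = as.numeric(fw$b_mu[i, ]),
      d_logvar = as.numeric(fw$d_lv[i, ]), b_logvar = as.numeric(fw$b_lv[i, ]),
      fovea_px = as.numeric(fw$fovea[i, ]) * (n - 1),
      exclude_prob = as.numeric(fw$exc[i, 1])
    ), class = "latent_code")
  })
  if (single) codes[[1]] else codes
}

#' Encode a list of maps into a data frame of latent features
#'
#' One row per map with columns `d1, d2, b1..b8, f_x, f_y, f_exc`.
#' @inheritParams encode
#' @return A data.frame.
#' @export
encode_table <- function(model, maps) {
  codes <- encode(model, if (is.matrix(maps) && !is.list(maps))
    list(maps) else maps)
  df <- do.call(rbind, lapply(codes, function(cd)
    data.frame(t(c(d1 = cd$d[1], d2 = cd$d[2],
                   stats::setNames(cd$b, paste0("b", 1:8)),
                   f_x = cd$fovea_px[1], f_y = cd$fovea_px[2],
                   f_exc = cd$exclude_prob)))))
  rownames(df) <- NULL
  df
}

#' Decode a display-latent pair into a thickness map
#'
#' Deterministic: the display decoder maps (d1, d2) to a fovea-centered
#' thickness map in micrometres (non-negative after de-normalization).
#'
#' @param model A `bvae_model`.
#' @param d Numeric length-2 vector, or an n x 2 matrix of dLV pairs.
#' @return A crop-sized map matrix (or list of maps for matrix input).
#' @export
decode_display <- function(model, d) {
  stopifnot(inherits(model, "bvae_model"))
  single <- !is.matrix(d)
  D <- if (single) matrix(d, 1L) else d
  stopifnot(ncol(D) == 2L, all(is.finite(D)))
  out <- nn_forward(model$net$dec_d, D)$out
  cp <- model$config$crop_px
  maps <- lapply(seq_len(nrow(D)), function(i)
    matrix(.denorm_map(out[i, ], model$config), cp, cp))
  if (single) maps[[1]] else maps
}

#' Full reconstruction from a latent code
#'
#' Returns the display reconstruction `y_D`, the booster residual `y_B` and
#' the full reconstruction `y = y_D + y_B` (the identity holds exactly, in
#' normalized units; `y_D` and `y` are also returned de-normalized in um).
#'
#' @param model A `bvae_model`.
#' @param code A `latent_code` from [encode()].
#' @return A `recon_pair` list with `y_D`, `y_B`, `y` (normalized matrices)
#'   and `y_D_um`, `y_um` in micrometres.
#' @export
decode_full <- function(model, code) {
  stopifnot(inherits(model, "bvae_model"), inherits(code, "latent_code"))
  cfg <- model$config
  cp <- cfg$crop_px
  zd <- matrix(code$d, 1L)
  yD <- nn_forward(model$net$dec_d, zd)$out
  yB <- nn_forward(model$net$dec_b, cbind(zd, matrix(code$b, 1L)))$out
  y <- yD + yB
  structure(list(
    y_D = matrix(yD, cp, cp), y_B = matrix(yB, cp, cp), y = matrix(y, cp, cp),
    y_D_um = matrix(.denorm_map(yD, cfg), cp, cp),
    y_um = matrix(.denorm_map(y, cfg), cp, cp)
  ), class = "recon_pair")
}

#' Fovea-centered crop of a map
#'
#' Extracts the `crop_px` window centered on the fovea, replicating edge
#' pixels where the window is clipped by the raster.
#'
#' @param map Thickness map matrix.
#' @param fovea_px Fovea `(x, y)` 0-based pixels; defaults to the map
#'   attribute.
#' @param crop_px Output side length.
#' @return A `crop_px` x `crop_px` matrix.
#' @export
crop_map <- function(map, fovea_px = NULL, crop_px) {
  if (is.null(fovea_px)) fovea_px <- attr(map, "fovea")
  n <- nrow(map)
  half <- crop_px / 2
  rows <- round(fovea_px[2] - half + seq_len(crop_px))   # 1-based
  cols <- round(fovea_px[1] - half + seq_len(crop_px))
  rows <- pmin(pmax(rows, 1L), n)
  cols <- pmin(pmax(cols, 1L), n)
  unclass(map)[rows, cols, drop = FALSE]
}

#' Gaussian KL divergence against the standard normal
#'
#' Per dimension `0.5 * (mu^2 + exp(logvar) - 1 - logvar)`, summed over
#' dimensions (and rows, when matrices are given, returning one value per
#' row summed across columns).
#'
#' @param mu Mean vector or matrix (rows = samples).
#' @param logvar Log-variance, same shape.
#' @return Scalar (vector input) or per-row vector (matrix input).
#' @export
kl_divergence <- function(mu, logvar) {
  stopifnot(all(is.finite(mu)), all(is.finite(logvar)))
  k <- 0.5 * (mu^2 + exp(logvar) - 1 - logvar)
  if (is.matrix(k)) rowSums(k) else sum(k)
}

#' Anatomical anchor map for display latents
#'
#' Affine map `t(r) = scale * (r - center)` taking a hemifield thickness
#' ratio to its display-latent anchor. With the defaults (scale 10,
#' center 0.8, reference 80 um) a normal ratio near 1 anchors around +2 and
#' a 50%-thinned hemifield anchors at -3, spanning the montage range.
#'
#' @param r Hemifield thickness ratio(s).
#' @param config A [bvae_config()] (for the anchor constants).
#' @return Anchor value(s).
#' @export
anchor_map <- function(r, config = bvae_config()) {
  config$anchor_scale * (r - config$anchor_center)
}

#' Anatomical penalties on the display latents
#'
#' `anat_d1 = (d1 - t(r_inf))^2`, `anat_d2 = (d2 - t(r_sup))^2`: d1 is
#' anchored to the inferior-hemifield annulus thickness ratio, d2 to the
#' superior one. Zero exactly when d sits at its anchors.
#'
#' @param d Length-2 display latent vector.
#' @param r_inf,r_sup Hemifield thickness ratios (>= 0).
#' @param config A [bvae_config()].
#' @return Named vector `c(anat_d1, anat_d2)`.
#' @export
anatomical_penalty <- function(d, r_inf, r_sup, config = bvae_config()) {
  stopifnot(length(d) == 2L, r_inf >= 0, r_sup >= 0)
  c(anat_d1 = (d[1] - anchor_map(r_inf, config))^2,
    anat_d2 = (d[2] - anchor_map(r_sup, config))^2)
}

# loss computation on a forward pass ---------------------------------------
# batch: list with Xc (n x crop^2, normalized), fovea (n x 2 in [0,1]),
# qc (0 good / 1 poor), t_inf, t_sup (anchor targets). Poor-quality samples
# contribute only the exclusion loss.
.bvae_losses <- function(fw, batch, cfg) {
  w <- cfg$weights
  good <- as.numeric(batch$qc == 0)
  ng <- max(sum(good), 1)
  npx <- ncol(batch$Xc)

  pm <- function(per_sample) sum(per_sample * good) / ng  # mean over good
  recon_display <- pm(rowSums((fw$y_D - batch$Xc)^2) / npx)
  # boosting formulation: the booster regresses the display residual, which
  # enters the loss as a fixed target (batch$resid = x_C - y_D at the
  # current display weights). The value equals MSE(y, x_C) at those
  # weights; the display decoder receives no gradient from this term.
  recon_full    <- pm(rowSums((fw$y_B - batch$resid)^2) / npx)
  kl_d <- pm(kl_divergence(fw$d_mu, fw$d_lv))
  kl_b <- pm(kl_divergence(fw$b_mu, fw$b_lv))
  anat_d1 <- pm((fw$d_mu[, 1] - batch$t_inf)^2)
  anat_d2 <- pm((fw$d_mu[, 2] - batch$t_sup)^2)
  # squared pixel error normalized by image size: (err_px)^2 / img_px,
  # i.e. fractional coordinates scaled by img_px
  fovea <- pm(rowSums((fw$fovea - batch$fovea)^2)) * cfg$img_px
  p <- pmin(pmax(fw$exc[, 1], 1e-12), 1 - 1e-12)
  exclude <- -mean(batch$qc * log(p) + (1 - batch$qc) * log(1 - p))

  comp <- c(recon_display = recon_display, recon_full = recon_full,
            kl_d = kl_d, kl_b = kl_b, anat_d1 = anat_d1, anat_d2 = anat_d2,
            fovea = fovea, exclude = exclude)
  if (!all(is.finite(comp)))
    stop("non-finite loss component: ",
         paste(names(comp)[!is.finite(comp)], collapse = ", "))
  c(comp, total = sum(w * comp))
}

#' Compute the bVAE loss bundle for a batch of maps
#'
#' Reconstruction terms are mean squared error in normalized units between
#' `(y_D, x_C)` and `(y, x_C)`; the fovea loss is squared error in image-size
#' units; the exclusion loss is binary cross-entropy against the QC label.
#' Poor-quality samples contribute only the exclusion loss. The total is the
#' weighted sum with the config weight vector.
#'
#' @param model A `bvae_model`.
#' @param maps List of thickness maps (with `fovea` and `qc` attributes).
#' @param eps_d,eps_b Optional reparameterization noise matrices (posterior
#'   mean when NULL).
#' @return A named numeric `loss_bundle` with the eight components and
#'   `total`.
#' @export
compute_losses <- function(model, maps, eps_d = NULL, eps_b = NULL) {
  cfg <- model$config
  X <- .as_batch(maps, cfg)
  batch <- .prepare_batch(maps, cfg)
  fw <- .bvae_forward(model, X, eps_d, eps_b)
  batch <- .with_resid(batch, fw)
  structure(.bvae_losses(fw, batch, cfg), class = "loss_bundle")
}

# freeze the display residual as the booster regression target
.with_resid <- function(batch, fw) {
  batch$resid <- batch$Xc - fw$y_D
  batch
}

# build training targets from map attributes
.prepare_batch <- function(maps, cfg) {
  if (is.matrix(maps) && !is.list(maps)) maps <- list(maps)
  n <- cfg$img_px
  Xc <- do.call(rbind, lapply(maps, function(m)
    as.numeric(.norm_map(crop_map(m, crop_px = cfg$crop_px), cfg))))
  fov <- do.call(rbind, lapply(maps, function(m) attr(m, "fovea"))) / (n - 1)
  qc <- vapply(maps, function(m)
    as.numeric(identical(attr(m, "qc"), "poor")), numeric(1))
  anchors <- vapply(maps, function(m) {
    if (identical(attr(m, "qc"), "poor")) return(c(0, 0))
    pr <- sector_means(m)
    anchor_map(hemifield_ratios(pr, cfg$reference_um), cfg)
  }, numeric(2))
  list(Xc = Xc, fovea = fov, qc = qc,
       t_inf = anchors[1, ], t_sup = anchors[2, ])
}

# full backward pass: gradients of the total loss w.r.t. all parameters
.bvae_backward <- function(model, fw, batch, X) {
  cfg <- model$config
  w <- cfg$weights
  net <- model$net
  good <- as.numeric(batch$qc == 0)
  ng <- max(sum(good), 1)
  npx <- ncol(batch$Xc)
  nb <- nrow(X)

  dyB <- w[["recon_full"]] * 2 * (fw$y_B - batch$resid) *
    (good / (ng * npx))
  dyD <- w[["recon_display"]] * 2 * (fw$y_D - batch$Xc) *
    (good / (ng * npx))
  bw_db <- nn_backward(net$dec_b, fw$dec_b$caches, dyB)
  bw_dd <- nn_backward(net$dec_d, fw$dec_d$caches, dyD)
  dzd <- bw_dd$dX + bw_db$dX[, 1:2, drop = FALSE]
  dzb <- bw_db$dX[, 3:10, drop = FALSE]

  # reparameterization: z = mu + exp(lv/2) * eps
  d_mu_g <- dzd
  d_lv_g <- if (is.null(fw$eps_d)) 0 * dzd else
    dzd * fw$eps_d * 0.5 * exp(0.5 * fw$d_lv)
  b_mu_g <- dzb
  b_lv_g <- if (is.null(fw$eps_b)) 0 * dzb else
    dzb * fw$eps_b * 0.5 * exp(0.5 * fw$b_lv)

  gw <- good / ng
  d_mu_g <- d_mu_g + w[["kl_d"]] * fw$d_mu * gw
  d_lv_g <- d_lv_g + w[["kl_d"]] * 0.5 * (exp(fw$d_lv) - 1) * gw
  b_mu_g <- b_mu_g + w[["kl_b"]] * fw$b_mu * gw
  b_lv_g <- b_lv_g + w[["kl_b"]] * 0.5 * (exp(fw$b_lv) - 1) * gw

  d_mu_g[, 1] <- d_mu_g[, 1] +
    w[["anat_d1"]] * 2 * (fw$d_mu[, 1] - batch$t_inf) * gw
  d_mu_g[, 2] <- d_mu_g[, 2] +
    w[["anat_d2"]] * 2 * (fw$d_mu[, 2] - batch$t_sup) * gw

  dfov <- w[["fovea"]] * 2 * (fw$fovea - batch$fovea) * gw * cfg$img_px
  p <- pmin(pmax(fw$exc, 1e-12), 1 - 1e-12)
  # d BCE / d p ; the sigmoid derivative is applied inside nn_backward
  dexc <- -(batch$qc / p - (1 - batch$qc) / (1 - p)) *
    (w[["exclude"]] / nb)

  # soft logvar cap: lv = cap * tanh(z / cap) => dz = dlv * (1 - (lv/cap)^2)
  cap <- cfg$logvar_cap
  d_lv_raw <- d_lv_g * (1 - (fw$d_lv / cap)^2)
  b_lv_raw <- b_lv_g * (1 - (fw$b_lv / cap)^2)

  heads <- list(head_d_mu = d_mu_g, head_d_lv = d_lv_raw,
                head_b_mu = b_mu_g, head_b_lv = b_lv_raw,
                head_fovea = dfov, head_exc = dexc)
  dH <- 0
  grads <- list()
  for (nm in names(heads)) {
    bw <- nn_backward(net[[nm]], fw$heads[[nm]]$caches, heads[[nm]])
    grads[[nm]] <- bw$grads
    dH <- dH + bw$dX
  }
  bw_tr <- nn_backward(net$trunk, fw$trunk$caches, dH)
  grads$trunk <- bw_tr$grads
  grads$dec_d <- bw_dd$grads
  grads$dec_b <- bw_db$grads
  grads[names(net)]
}
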