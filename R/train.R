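#' Training configuration
#'
#' @param epochs_max Maximum number of epochs.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam learning rate.
#' @param patience Early-stopping patience: training stops after this many
#'   consecutive epochs without validation improvement (0 stops one epoch
#'   beyond the first non-improvement).
#' @param val_fraction Fraction of subjects held out for validation; the
#'   split is at the subject level, so no subject contributes maps to both
#'   sets.
#' @param burnin Warm-up epochs excluded from best-model selection and from
#'   the early-stopping count: during the first epochs the validation total
#'   is dominated by oscillating anchor terms and single-epoch dips are not
#'   trustworthy model-selection signals.
#' @param seed Integer seed controlling initialization, shuffling and
#'   reparameterization sampling.
#' @param weights Optional named loss-weight vector overriding the
#'   [bvae_config()] defaults.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs_max = 40L, batch_size = 32L,
                         learning_rate = 1e-3, patience = 8L,
                         val_fraction = 0.15, burnin = 0L, seed = 1L,
                         weights = NULL) {
  stopifnot(epochs_max >= 1, batch_size >= 1, learning_rate > 0,
            patience >= 0, burnin >= 0, val_fraction > 0, val_fraction < 1)
  structure(list(epochs_max = as.integer(epochs_max),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 patience = as.integer(patience),
                 val_fraction = val_fraction, burnin = as.integer(burnin),
                 seed = as.integer(seed),
                 weights = weights), class = "train_config")
}

# deterministic string hash for subject-level splitting (salted); the
# double-pass Lehmer scramble avalanches the final characters, which
# otherwise dominate sequential ids
subject_hash <- function(ids, salt = 20231L) {
  vapply(ids, function(s) {
    h <- as.numeric(salt) %% 9999991
    for (c in utf8ToInt(s)) h <- (h * 131 + c) %% 9999991
    h <- (h * 48271) %% 2147483647
    h <- (h * 48271) %% 2147483647
    h / 2147483647
  }, numeric(1))
}

# flatten a cohort (list of eye_series) into maps + subject ids
.cohort_maps <- function(cohort) {
  series <- if (!is.null(cohort$series)) cohort$series else cohort
  maps <- list(); sids <- character(0)
  for (nm in names(series)) {
    for (m in series[[nm]]$maps) {
      maps[[length(maps) + 1L]] <- m
      sids <- c(sids, nm)
    }
  }
  list(maps = maps, subject_id = sids)
}

#' Train a bVAE on a cohort
#'
#' Minibatch Adam training with reparameterized sampling, a subject-level
#' train/validation split, early stopping on the validation total loss and
#' restoration of the best-validation weights. A NaN loss aborts training
#' and retains the last finite checkpoint.
#'
#' @param cohort Output of [make_cohort()] (or a bare list of `eye_series`).
#' @param model_config A [bvae_config()]; its `img_px` must match the maps.
#' @param config A [train_config()].
#' @param verbose Print per-epoch losses.
#' @return A `bvae_checkpoint`: list with `model`, `history` (one row per
#'   epoch with every loss component for train and validation), `seed`,
#'   `best_epoch` and `diverged`.
#' @export
bvae_train <- function(cohort, model_config = bvae_config(),
                       config = train_config(), verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  if (!is.null(config$weights)) {
    stopifnot(all(names(config$weights) %in% names(model_config$weights)))
    model_config$weights[names(config$weights)] <- config$weights
  }
  model_config$seed <- config$seed
  fl <- .cohort_maps(cohort)
  if (!length(fl$maps)) stop("cohort is empty")
  cfg <- model_config

  # subject-level split
  hs <- subject_hash(unique(fl$subject_id))
  val_subj <- unique(fl$subject_id)[hs < config$val_fraction]
  is_val <- fl$subject_id %in% val_subj
  if (all(is_val) || !any(is_val)) {
    # tiny cohorts: fall back to a deterministic 1-subject holdout
    val_subj <- unique(fl$subject_id)[1]
    is_val <- fl$subject_id %in% val_subj
    if (all(is_val)) is_val <- seq_along(fl$maps) == 1L
  }

  X <- .as_batch(fl$maps, cfg)
  tg <- .prepare_batch(fl$maps, cfg)
  tr_idx <- which(!is_val); va_idx <- which(is_val)

  model <- bvae_init(cfg)
  params <- lapply(model$net, layers_params)
  opt <- adam_init(params)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(config$seed, 555L))

  sub_batch <- function(idx) list(
    Xc = tg$Xc[idx, , drop = FALSE], fovea = tg$fovea[idx, , drop = FALSE],
    qc = tg$qc[idx], t_inf = tg$t_inf[idx], t_sup = tg$t_sup[idx])

  eval_losses <- function() {
    # posterior-mean losses on the validation set, in chunks
    tot <- NULL; nacc <- 0
    for (ch in split(va_idx, ceiling(seq_along(va_idx) / 256))) {
      fw <- .bvae_forward(model, X[ch, , drop = FALSE])
      l <- .bvae_losses(fw, .with_resid(sub_batch(ch), fw), cfg)
      tot <- if (is.null(tot)) l * length(ch) else tot + l * length(ch)
      nacc <- nacc + length(ch)
    }
    tot / nacc
  }

  history <- list()
  best_val <- Inf; best_params <- params; best_epoch <- 0L
  streak <- 0L; diverged <- FALSE

  for (epoch in seq_len(config$epochs_max)) {
    # step decay keeps late epochs stable once the anchors are learned
    lr <- config$learning_rate * 0.5^floor((epoch - 1) / 12)
    # KL and sampling-temperature annealing over the first 10 epochs: the
    # latents first learn deterministically (autoencoder regime) so the
    # booster channel carries signal before prior pressure and sampling
    # noise can collapse its posterior
    ecfg <- cfg
    anneal <- min(1, epoch / 10)
    ecfg$weights[c("kl_d", "kl_b")] <- cfg$weights[c("kl_d", "kl_b")] * anneal
    temp <- min(1, (epoch - 1) / 10)
    ord <- sample(tr_idx)
    nb <- ceiling(length(ord) / config$batch_size)
    ep_loss <- NULL
    for (b in seq_len(nb)) {
      idx <- ord[((b - 1) * config$batch_size + 1):
                   min(b * config$batch_size, length(ord))]
      eps_d <- matrix(stats::rnorm(length(idx) * cfg$n_d), length(idx)) * temp
      eps_b <- matrix(stats::rnorm(length(idx) * cfg$n_b), length(idx)) * temp
      fw <- .bvae_forward(model, X[idx, , drop = FALSE], eps_d, eps_b)
      bt <- .with_resid(sub_batch(idx), fw)
      l <- tryCatch(.bvae_losses(fw, bt, ecfg),
                    error = function(e) NULL)
      if (is.null(l) || !is.finite(l[["total"]])) {
        diverged <- TRUE
        break
      }
      emodel <- model; emodel$config <- ecfg
      grads <- .bvae_backward(emodel, fw, bt, X[idx, , drop = FALSE])
      st <- adam_step(params, grads, opt, lr = lr)
      params <- st$params; opt <- st$state
      for (nm in names(model$net))
        model$net[[nm]] <- layers_set_params(model$net[[nm]], params[[nm]])
      ep_loss <- if (is.null(ep_loss)) l else ep_loss + l
    }
    if (diverged) break
    ep_loss <- ep_loss / nb
    vl <- eval_losses()
    history[[epoch]] <- c(epoch = epoch,
                          stats::setNames(ep_loss, paste0("train_",
                                                          names(ep_loss))),
                          stats::setNames(vl, paste0("val_", names(vl))))
    if (verbose)
      message(sprintf("epoch %2d  train %.5f  val %.5f", epoch,
                      ep_loss[["total"]], vl[["total"]]))
    if (epoch <= config$burnin) next
    if (vl[["total"]] < best_val - 1e-9) {
      best_val <- vl[["total"]]; best_params <- params
      best_epoch <- epoch; streak <- 0L
    } else {
      streak <- streak + 1L
      if (streak > config$patience) break
    }
  }

  if (best_epoch == 0L) {  # no epoch past burn-in: keep the final weights
    best_params <- params
    best_epoch <- length(history)
  }
  for (nm in names(model$net))
    model$net[[nm]] <- layers_set_params(model$net[[nm]], best_params[[nm]])
  structure(list(
    model = model,
    history = do.call(rbind.data.frame,
                      lapply(history, function(h) as.list(h))),
    seed = config$seed, best_epoch = best_epoch, best_val = best_val,
    val_subjects = val_subj, diverged = diverged
  ), class = "bvae_checkpoint")
}

#' @export
print.bvae_checkpoint <- function(x, ...) {
  cat(sprintf(
    "bVAE checkpoint: %d epochs (best %d, val %.5f)%s, seed %d\n",
    nrow(x$history), x$best_epoch, x$best_val,
    if (x$diverged) " [DIVERGED]" else "", x$seed))
  invisible(x)
}
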