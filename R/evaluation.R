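#' Image root-mean-square error
#'
#' @param a,b Thickness maps (same shape), micrometres.
#' @return RMSE in micrometres.
#' @export
image_rmse <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("maps must have the same shape")
  sqrt(mean((unclass(a) - unclass(b))^2))
}

# valid-mode separable filtering with a 1-D kernel along rows then columns
.filter_valid <- function(x, k) {
  r <- (length(k) - 1L) / 2L
  conv_cols <- function(m) {
    n <- nrow(m)
    out <- 0
    for (j in seq_along(k))
      out <- out + k[j] * m[j:(n - length(k) + j), , drop = FALSE]
    out
  }
  t(conv_cols(t(conv_cols(x))))
}

#' Structural similarity index between two thickness maps
#'
#' Mean local SSIM computed with an 11-pixel Gaussian window (sigma 1.5),
#' `K1 = 0.01`, `K2 = 0.03` and a fixed dynamic range of `L` micrometres so
#' that scores are comparable across eyes. 1 means identical images.
#'
#' @param a,b Same-shape maps in micrometres.
#' @param L Dynamic range (um), default 150.
#' @return SSIM in `[-1, 1]` (1 for identical maps).
#' @export
ssim_map <- function(a, b, L = 150) {
  if (!identical(dim(a), dim(b))) stop("maps must have the same shape")
  a <- unclass(a); b <- unclass(b)
  k <- exp(-((-5:5)^2) / (2 * 1.5^2)); k <- k / sum(k)
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  mu_a <- .filter_valid(a, k);  mu_b <- .filter_valid(b, k)
  s_aa <- .filter_valid(a * a, k) - mu_a^2
  s_bb <- .filter_valid(b * b, k) - mu_b^2
  s_ab <- .filter_valid(a * b, k) - mu_a * mu_b
  ss <- ((2 * mu_a * mu_b + C1) * (2 * s_ab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (s_aa + s_bb + C2))
  mean(ss)
}

#' Per-sector signed reconstruction differences over a cohort
#'
#' Signed difference is original minus reconstruction, aggregated per sector
#' and over the whole annulus. Profiles must come from the same eyes in the
#' same order (matched by the `id` column when present).
#'
#' @param x_profiles,recon_profiles Data frames from
#'   [sector_profile_table()].
#' @return Data frame with columns `region`, `mean_um`, `sd_um`.
#' @export
sector_signed_diff <- function(x_profiles, recon_profiles) {
  if (!is.null(x_profiles$id) && !is.null(recon_profiles$id) &&
      !identical(x_profiles$id, recon_profiles$id))
    stop("cohort keys do not match between original and reconstruction")
  regions <- c("annulus", "SN", "S", "ST", "IT", "I", "IN")
  do.call(rbind, lapply(regions, function(rg) {
    d <- x_profiles[[rg]] - recon_profiles[[rg]]
    data.frame(region = rg, mean_um = mean(d), sd_um = stats::sd(d))
  }))
}

#' Quality-control classification metrics
#'
#' Confusion-matrix rates for the exclusion head at a probability threshold;
#' "poor" is the positive class.
#'
#' @param exclude_probs Predicted exclusion probabilities.
#' @param qc_labels Binary truth (1/"poor" = poor quality).
#' @param threshold Decision threshold (default 0.5).
#' @return Named vector `accuracy`, `sensitivity`, `specificity`.
#' @export
qc_metrics <- function(exclude_probs, qc_labels, threshold = 0.5) {
  y <- if (is.character(qc_labels)) as.numeric(qc_labels == "poor")
       else as.numeric(qc_labels)
  stopifnot(all(y %in% c(0, 1)), length(y) == length(exclude_probs))
  pred <- as.numeric(exclude_probs >= threshold)
  c(accuracy = mean(pred == y),
    sensitivity = if (any(y == 1)) mean(pred[y == 1] == 1) else NA_real_,
    specificity = if (any(y == 0)) mean(pred[y == 0] == 0) else NA_real_)
}

#' Signed fovea-localization error statistics
#'
#' Estimated minus true fovea location, per axis, in pixel units. `scale`
#' rescales errors before aggregation (e.g. `200/64` to express errors from
#' a 64-px raster in native 0.03 mm pixels).
#'
#' @param estimates,truths n x 2 matrices of `(x, y)` pixel coordinates.
#' @param scale Multiplier applied to the errors.
#' @return Data frame with `axis`, `mean_px`, `sd_px`.
#' @export
fovea_error <- function(estimates, truths, scale = 1) {
  estimates <- as.matrix(estimates); truths <- as.matrix(truths)
  stopifnot(identical(dim(estimates), dim(truths)), ncol(estimates) == 2L)
  err <- (estimates - truths) * scale
  data.frame(axis = c("x", "y"),
             mean_px = colMeans(err),
             sd_px = apply(err, 2, stats::sd))
}
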