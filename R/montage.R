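#' Latent-space montage map
#'
#' Decodes a tile with the display decoder at every node of an inclusive
#' `(d1, d2)` grid. d1 runs along the x axis, d2 along the y axis, so the
#' montage lays inferior thinning to the upper left, normal/thickening to
#' the upper right, diffuse thinning to the lower left and superior thinning
#' to the lower right.
#'
#' @param model A trained `bvae_model`.
#' @param d1_range,d2_range Inclusive ranges (defaults match the printed
#'   montage, (-5,-5) to (8,4)).
#' @param step Grid step (> 0).
#' @return A `montage_map`: grid vectors `d1`, `d2`, a tile list indexed
#'   `[[i_d1]][[i_d2]]` (micrometre matrices), and empty contour/trajectory
#'   slots.
#' @export
make_montage <- function(model, d1_range = c(-5, 8), d2_range = c(-5, 4),
                         step = 1) {
  stopifnot(step > 0, all(is.finite(c(d1_range, d2_range))))
  d1 <- seq(d1_range[1], d1_range[2], by = step)
  if (d1[length(d1)] < d1_range[2]) d1 <- c(d1, d1_range[2])
  d2 <- seq(d2_range[1], d2_range[2], by = step)
  if (d2[length(d2)] < d2_range[2]) d2 <- c(d2, d2_range[2])
  grid <- as.matrix(expand.grid(d1 = d1, d2 = d2))
  tiles_flat <- decode_display(model, grid)
  tiles <- lapply(seq_along(d1), function(i)
    lapply(seq_along(d2), function(j)
      tiles_flat[[(j - 1) * length(d1) + i]]))
  structure(list(d1 = d1, d2 = d2, step = step, tiles = tiles,
                 contours = NULL, color_range_um = c(0, 120)),
            class = "montage_map")
}

#' @export
print.montage_map <- function(x, ...) {
  cat(sprintf("LS montage map: %d x %d tiles, d1 in [%g, %g], d2 in [%g, %g]\n",
              length(x$d1), length(x$d2), min(x$d1), max(x$d1),
              min(x$d2), max(x$d2)))
  invisible(x)
}

# product-Gaussian KDE evaluated at query points
.kde2_eval <- function(points, qx, qy, bw) {
  n <- nrow(points)
  dens <- numeric(length(qx))
  for (i in seq_len(n)) {
    dens <- dens + exp(-0.5 * (((qx - points[i, 1]) / bw[1])^2 +
                                 ((qy - points[i, 2]) / bw[2])^2))
  }
  dens / (n * 2 * pi * bw[1] * bw[2])
}

#' Scott's-rule bandwidth with a floor
#' @keywords internal
.kde_bandwidth <- function(points, floor_bw = 1e-3) {
  n <- nrow(points)
  bw <- apply(points, 2, stats::sd) * n^(-1 / 6)
  if (any(!is.finite(bw)) || any(bw < floor_bw)) {
    warning("degenerate point set: applying bandwidth floor")
    bw <- pmax(ifelse(is.finite(bw), bw, floor_bw), floor_bw)
  }
  bw
}

#' Kernel-density iso-proportion contours of a latent point cloud
#'
#' Density is a product-Gaussian kernel estimate with Scott's-rule bandwidth
#' (floored at 1e-3). A contour at iso-proportion level `p` is drawn at the
#' density threshold that encloses a fraction `p` of the points (the
#' threshold is the `(1 - p)` quantile of the density evaluated at the
#' points themselves), the convention used for smooth normative boundaries
#' in latent-space plots.
#'
#' @param points n x 2 matrix of (d1, d2) points, n >= 10.
#' @param levels Iso-proportion levels in (0, 1).
#' @param grid_n Evaluation grid resolution per axis.
#' @return A `kde_contours` list: `polylines` (list per level of data frames
#'   with `x`, `y`), `thresholds`, `bandwidth`, `levels`.
#' @export
kde_contours <- function(points, levels = c(0.25, 0.5, 0.75, 0.9),
                         grid_n = 120L) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2L, nrow(points) >= 10L,
            all(levels > 0 & levels < 1))
  bw <- .kde_bandwidth(points)
  pad <- 3 * bw
  gx <- seq(min(points[, 1]) - pad[1], max(points[, 1]) + pad[1],
            length.out = grid_n)
  gy <- seq(min(points[, 2]) - pad[2], max(points[, 2]) + pad[2],
            length.out = grid_n)
  gg <- expand.grid(x = gx, y = gy)
  dens_grid <- matrix(.kde2_eval(points, gg$x, gg$y, bw), grid_n, grid_n)
  dens_pts <- .kde2_eval(points, points[, 1], points[, 2], bw)
  thresholds <- stats::quantile(dens_pts, 1 - levels, names = FALSE)
  polylines <- lapply(seq_along(levels), function(i) {
    cl <- grDevices::contourLines(gx, gy, dens_grid, levels = thresholds[i])
    lapply(cl, function(c) data.frame(x = c$x, y = c$y))
  })
  names(polylines) <- paste0("p", levels * 100)
  structure(list(polylines = polylines, thresholds = thresholds,
                 bandwidth = bw, levels = levels),
            class = "kde_contours")
}

#' Fraction of points enclosed by a KDE iso-proportion contour
#'
#' Evaluates the KDE (same bandwidth convention as [kde_contours()]) built
#' from `points` at `query` locations and reports the fraction whose density
#' is at or above the contour threshold.
#'
#' @param contours A `kde_contours` object.
#' @param points The point cloud the contours were built from.
#' @param query Points to test (defaults to `points`).
#' @param level Which iso-proportion level to use.
#' @return Fraction in `[0, 1]`.
#' @export
kde_coverage <- function(contours, points, query = points, level = 0.5) {
  i <- match(level, contours$levels)
  if (is.na(i)) stop("level not present in contours")
  d <- .kde2_eval(as.matrix(points), query[, 1], query[, 2],
                  contours$bandwidth)
  mean(d >= contours$thresholds[i])
}

#' Longitudinal latent-space trajectory
#'
#' Orders the visit latent codes into a polyline in (d1, d2) and annotates
#' each segment with the inter-visit interval in months (days / 30.44).
#' A single visit yields a point marker with no segments.
#'
#' @param codes List of `latent_code`s (one per visit, in order), or an
#'   n x 2 matrix of dLV pairs.
#' @param intervals_days Integer vector, length one less than the number of
#'   visits.
#' @return An `ls_trajectory`: data frame `points` (visit, d1, d2) and data
#'   frame `segments` (from/to coordinates plus `months` and a label).
#' @export
plot_trajectory <- function(codes, intervals_days = integer(0)) {
  D <- if (is.matrix(codes)) codes else
    do.call(rbind, lapply(codes, function(cd) cd$d))
  nv <- nrow(D)
  stopifnot(nv >= 1, length(intervals_days) == max(nv - 1, 0))
  pts <- data.frame(visit = seq_len(nv) - 1L, d1 = D[, 1], d2 = D[, 2])
  segs <- if (nv >= 2) {
    months <- intervals_days / 30.44
    data.frame(x0 = D[-nv, 1], y0 = D[-nv, 2], x1 = D[-1, 1], y1 = D[-1, 2],
               months = months,
               label = sprintf("%.1f months", months))
  } else data.frame(x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
                    y1 = numeric(0), months = numeric(0),
                    label = character(0))
  structure(list(points = pts, segments = segs), class = "ls_trajectory")
}

#' Render a montage map (with optional contours and trajectories) to a file
#'
#' Tiles share a fixed thickness colour scale (0-120 um by default) so
#' patterns are comparable across the grid.
#'
#' @param x A `montage_map`.
#' @param file Output path (`.png` or `.svg`); when NULL, draws on the
#'   current device.
#' @param contours Optional `kde_contours` to overlay.
#' @param trajectories Optional list of `ls_trajectory` objects.
#' @param ... Unused.
#' @return Invisibly, the file path (or NULL).
#' @export
plot.montage_map <- function(x, file = NULL, contours = NULL,
                             trajectories = NULL, ...) {
  if (!is.null(file)) {
    if (grepl("\\.svg$", file)) grDevices::svg(file, width = 9, height = 7)
    else grDevices::png(file, width = 1200, height = 900)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  s <- x$step
  rng <- x$color_range_um
  pal <- grDevices::hcl.colors(64, "viridis")
  graphics::plot(NA, xlim = range(x$d1) + c(-s, s) / 2,
                 ylim = range(x$d2) + c(-s, s) / 2,
                 xlab = "d1", ylab = "d2", asp = NA)
  for (i in seq_along(x$d1)) for (j in seq_along(x$d2)) {
    tile <- x$tiles[[i]][[j]]
    idx <- pmin(pmax(1L, 1L + floor((tile - rng[1]) / diff(rng) * 63)), 64L)
    ras <- grDevices::as.raster(matrix(pal[idx], nrow(tile)))
    graphics::rasterImage(ras, x$d1[i] - s / 2, x$d2[j] - s / 2,
                          x$d1[i] + s / 2, x$d2[j] + s / 2,
                          interpolate = FALSE)
  }
  if (!is.null(contours))
    for (lv in contours$polylines) for (pl in lv)
      graphics::lines(pl$x, pl$y, col = "blue", lwd = 2)
  if (!is.null(trajectories)) for (tr in trajectories) {
    graphics::lines(tr$points$d1, tr$points$d2, col = "red", lwd = 2)
    graphics::points(tr$points$d1, tr$points$d2, col = "red", pch = 19)
    if (nrow(tr$segments))
      graphics::text((tr$segments$x0 + tr$segments$x1) / 2,
                     (tr$segments$y0 + tr$segments$y1) / 2,
                     tr$segments$label, cex = 0.7, col = "red")
  }
  invisible(file)
}

#' Machine-readable export of contours and trajectories
#'
#' @param file Output JSON path.
#' @param contours Optional `kde_contours`.
#' @param trajectories Optional named list of `ls_trajectory`.
#' @return The file path, invisibly.
#' @export
montage_overlays_json <- function(file, contours = NULL,
                                  trajectories = NULL) {
  obj <- list()
  if (!is.null(contours))
    obj$contours <- lapply(contours$polylines, function(lv)
      lapply(lv, function(pl) list(x = pl$x, y = pl$y)))
  if (!is.null(trajectories))
    obj$trajectories <- lapply(trajectories, function(tr)
      list(points = tr$points, segments = tr$segments))
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
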