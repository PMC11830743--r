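#' Elliptical annulus geometry for GCIPL sector analysis
#'
#' The Cirrus-equivalent macular GCIPL grid: an elliptical annulus centered on
#' the fovea with vertical inner/outer radii of 0.5/2.0 mm and horizontal
#' inner/outer radii of 0.6/2.4 mm, divided into six sectors (SN, S, ST, IT,
#' I, IN). Maps are square rasters covering 6 x 6 mm, so the pixel pitch is
#' `6 / img_px` mm (0.03 mm at the native 200 x 200 resolution).
#'
#' @param img_px Raster side length in pixels (square maps only).
#' @return An object of class `annulus_geometry`: a list with radii (mm),
#'   pixel pitch (mm/px), raster size and sector labels.
#' @export
annulus_geometry <- function(img_px = 200L) {
  stopifnot(is.numeric(img_px), length(img_px) == 1L, img_px >= 8)
  structure(list(
    v_inner = 0.5, v_outer = 2.0,
    h_inner = 0.6, h_outer = 2.4,
    px_pitch = 6 / img_px,
    img_px = as.integer(img_px),
    sector_labels = c("SN", "S", "ST", "IT", "I", "IN")
  ), class = "annulus_geometry")
}

#' Pixel-center offsets from the fovea, in millimetres
#'
#' Internal helper. Coordinates are 0-based `(x, y)` pixels with `y = 0` at
#' the superior edge. `dx` is positive toward the nasal side in the right-eye
#' (OD) frame (temporal on the left); `dy` is positive toward superior.
#' For OS maps the temporal axis is mirrored so that downstream sector
#' assignment is laterality-correct.
#'
#' @keywords internal
.fovea_offsets_mm <- function(geometry, fovea_px, laterality = "OD") {
  n <- geometry$img_px
  p <- geometry$px_pitch
  x <- (seq_len(n) - 1 - fovea_px[1]) * p           # columns, temporal -> nasal (OD)
  y <- (fovea_px[2] - (seq_len(n) - 1)) * p         # rows, + = superior
  # temporal axis points in +t direction: OD temporal is -x, OS temporal is +x
  tx <- if (identical(laterality, "OS")) x else -x
  list(
    tx = matrix(rep(tx, each = n), n, n),  # [row, col]
    dy = matrix(rep(y, times = n), n, n)
  )
}

#' Six sector masks plus the annulus mask
#'
#' Pixels belong to the annulus when they lie outside the inner ellipse and
#' inside the outer ellipse (center-of-pixel membership). Sector wedges are
#' 60 degrees of the *elliptically normalized* angle, i.e. the angle of the
#' coordinates scaled by `(1/h_outer, 1/v_outer)`, measured from the temporal
#' horizontal axis through superior. S and I are centered on the vertical
#' meridian (S spans 60-120 degrees, I its mirror).
#'
#' @param geometry An [annulus_geometry()].
#' @param fovea_px Numeric `(x, y)`, 0-based pixel coordinates of the fovea.
#' @param laterality `"OD"` or `"OS"`; OS flips nasal/temporal assignment.
#' @return A list with logical matrices `annulus` and one per sector label,
#'   plus `clipped` (TRUE when the outer ellipse extends past the raster).
#' @export
sector_masks <- function(geometry, fovea_px, laterality = "OD") {
  stopifnot(inherits(geometry, "annulus_geometry"),
            length(fovea_px) == 2L, all(is.finite(fovea_px)))
  n <- geometry$img_px
  if (any(fovea_px < 0) || any(fovea_px > n - 1))
    stop("fovea_px must lie inside the image")
  off <- .fovea_offsets_mm(geometry, fovea_px, laterality)
  tx <- off$tx; dy <- off$dy
  r_in  <- (tx / geometry$h_inner)^2 + (dy / geometry$v_inner)^2
  r_out <- (tx / geometry$h_outer)^2 + (dy / geometry$v_outer)^2
  annulus <- r_in >= 1 & r_out <= 1

  theta <- atan2(dy / geometry$v_outer, tx / geometry$h_outer)
  theta <- (theta %% (2 * pi)) / pi * 180  # [0, 360), 0 = temporal horizontal
  wedge <- pmin(floor(theta / 60), 5)      # 0..5 from temporal through superior
  sector_of <- c("ST", "S", "SN", "IN", "I", "IT")  # wedge 0..5

  masks <- list(annulus = annulus)
  for (i in 0:5) masks[[sector_of[i + 1L]]] <- annulus & wedge == i
  masks <- masks[c("annulus", geometry$sector_labels)]

  pitch_px <- geometry$px_pitch
  masks$clipped <-
    fovea_px[1] * pitch_px < geometry$h_outer ||
    (n - 1 - fovea_px[1]) * pitch_px < geometry$h_outer ||
    fovea_px[2] * pitch_px < geometry$v_outer ||
    (n - 1 - fovea_px[2]) * pitch_px < geometry$v_outer
  masks
}

#' Sector-wise mean thickness profile
#'
#' Arithmetic mean thickness (micrometres) over the whole annulus and each of
#' the six sectors. The annulus mean equals the pixel-count-weighted mean of
#' the sector means exactly. An empty (clipped-away) sector yields `NA`.
#'
#' @param map A thickness map matrix in micrometres ([thickness_map()] or a
#'   plain square matrix).
#' @param fovea_px Fovea `(x, y)` in 0-based pixels; defaults to the map's
#'   `fovea` attribute, or the raster centre.
#' @param laterality `"OD"` or `"OS"`; defaults to the map attribute.
#' @param geometry Optional [annulus_geometry()]; derived from the map size
#'   when missing.
#' @return A `sector_profile`: list with `annulus_mean`, named `sector_means`,
#'   `pixel_counts` and `clipped`.
#' @export
sector_means <- function(map, fovea_px = NULL, laterality = NULL,
                         geometry = NULL) {
  m <- unclass(map)
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (!all(is.finite(m))) stop("map must be finite")
  if (is.null(fovea_px)) fovea_px <- attr(map, "fovea")
  if (is.null(fovea_px)) fovea_px <- rep((nrow(m) - 1) / 2, 2L)
  if (is.null(laterality)) laterality <- attr(map, "laterality")
  if (is.null(laterality)) laterality <- "OD"
  if (is.null(geometry)) geometry <- annulus_geometry(nrow(m))
  msk <- sector_masks(geometry, fovea_px, laterality)
  labs <- geometry$sector_labels
  counts <- vapply(msk[labs], sum, integer(1))
  means <- vapply(labs, function(s) {
    if (counts[[s]] == 0L) NA_real_ else mean(m[msk[[s]]])
  }, numeric(1))
  structure(list(
    annulus_mean = if (sum(counts) == 0L) NA_real_ else mean(m[msk$annulus]),
    sector_means = means,
    pixel_counts = counts,
    clipped = msk$clipped
  ), class = "sector_profile")
}

#' @export
print.sector_profile <- function(x, ...) {
  cat("GCIPL annulus sector profile (um)\n")
  cat(sprintf("  annulus mean: %.2f%s\n", x$annulus_mean,
              if (isTRUE(x$clipped)) "  [clipped]" else ""))
  print(round(x$sector_means, 2))
  invisible(x)
}

#' Inferior and superior hemifield thickness ratios
#'
#' Pixel-weighted mean thickness of the inferior sectors (IT, I, IN) and the
#' superior sectors (ST, S, SN), each divided by a reference thickness. These
#' ratios anchor the anatomical penalties on the display latents d1 and d2.
#'
#' @param profile A `sector_profile` from [sector_means()].
#' @param reference_um Reference thickness in micrometres (default 80).
#' @return Named numeric vector `c(r_inf, r_sup)`.
#' @export
hemifield_ratios <- function(profile, reference_um = 80) {
  stopifnot(inherits(profile, "sector_profile"), reference_um > 0)
  wmean <- function(sectors) {
    w <- profile$pixel_counts[sectors]
    v <- profile$sector_means[sectors]
    if (sum(w) == 0L) return(NA_real_)
    sum(v * w, na.rm = TRUE) / sum(w[!is.na(v)])
  }
  c(r_inf = wmean(c("IT", "I", "IN")) / reference_um,
    r_sup = wmean(c("ST", "S", "SN")) / reference_um)
}

#' Sector profiles for a list of maps, as a data frame
#'
#' One row per map with columns `annulus`, the six sector means and
#' `clipped_flag`, suitable for CSV export.
#'
#' @param maps List of thickness maps.
#' @param ids Optional row identifiers.
#' @return A data.frame.
#' @export
sector_profile_table <- function(maps, ids = NULL) {
  profs <- lapply(maps, sector_means)
  df <- data.frame(
    id = if (is.null(ids)) seq_along(maps) else ids,
    annulus = vapply(profs, `[[`, numeric(1), "annulus_mean")
  )
  for (s in c("SN", "S", "ST", "IT", "I", "IN"))
    df[[s]] <- vapply(profs, function(p) p$sector_means[[s]], numeric(1))
  df$clipped_flag <- vapply(profs, function(p) isTRUE(p$clipped), logical(1))
  df
}
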