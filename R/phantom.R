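#' @name phantom
#' @title Synthetic GCIPL thickness-map phantoms
#'
#' @description
#' Seeded generator of synthetic macular GCIPL thickness maps with the
#' anatomy the encoder relies on: a perifoveal elliptical annulus of peak
#' thickness (the ganglion-cell ring 4-6 degrees from the fovea), optionally
#' thinned over the inferior hemifield (glaucoma-like), the superior
#' hemifield (NAION-like) or diffusely (optic-neuritis-like), with fovea
#' decentration, spatially correlated noise, epiretinal-membrane-like focal
#' thickening and poor-quality dropout artifacts, and progressive thinning
#' across visits.
#'
#' The thickness model at a pixel p is
#' `T(p) = floor + peak * g(rho(p)) * (1 - severity * w(theta(p))) + noise`,
#' where `(rho, theta)` are elliptical-polar coordinates about the fovea
#' (horizontal axis stretched by 1.2, matching the Cirrus annulus aspect),
#' `g` is a Gaussian ridge of the ring and `w` a raised-cosine hemifield
#' bump (identically 1 for diffuse thinning, 0 for normals).
NULL

# Calibration constants: the noise-free normal annulus mean is
# floor + peak * G where G is the annulus mean of the radial ridge g;
# hemifield bumps average exactly 1/2 over the annulus, so class-mean
# thickness is linear in mean severity. Constants solve those relations for
# the reference cohort means (normal 78.68, glaucoma 65.48, NAION 72.03,
# ON 71.29 um).
.phantom_calib <- list(
  base_floor   = 42,      # um
  ring_radius  = 1.25,    # mm, vertical-equivalent eccentricity of crest
  ring_width   = 0.45,    # mm
  annulus_peak = NA_real_, # set in .onLoad from G (see calib_annulus_peak)
  ellip        = 1.2,     # horizontal stretch (2.4/2.0)
  target_normal_mean = 78.68,
  severity_mean = c(glaucoma = 26.40 / 36.68, NAION = 13.30 / 36.68,
                    ON = 7.39 / 36.68),
  severity_k    = 5,      # Beta concentration for class severity draws
  floor_sd      = 4,      # um, between-eye variation
  peak_sd       = 6,      # um
  radius_sd     = 0.04,   # mm
  width_sd      = 0.02,   # mm
  normal_band_threshold = 0.2,  # final severity above this => beyond range
  edema_peak_factor = 1.3
)

#' Ridge attenuation integral of the normal phantom
#'
#' Mean of the radial ridge `g(rho)` over the elliptical annulus on the pixel
#' grid; used once to solve the annulus peak amplitude from the target normal
#' cohort mean. Exported because the calibration tests use it as an oracle.
#'
#' @param img_px Raster size.
#' @return Scalar in (0, 1).
#' @export
phantom_ridge_mean <- function(img_px = 200L) {
  geom <- annulus_geometry(img_px)
  c0 <- (img_px - 1) / 2
  off <- .fovea_offsets_mm(geom, c(c0, c0), "OD")
  rho <- sqrt((off$tx / .phantom_calib$ellip)^2 + off$dy^2)
  msk <- sector_masks(geom, c(c0, c0), "OD")$annulus
  g <- exp(-(rho - .phantom_calib$ring_radius)^2 /
             (2 * .phantom_calib$ring_width^2))
  mean(g[msk])
}

.calib_env <- new.env(parent = emptyenv())

# peak amplitude solving floor + peak * G = target normal mean (at 200 px)
.annulus_peak <- function() {
  if (is.null(.calib_env$peak)) {
    G <- phantom_ridge_mean(200L)
    .calib_env$peak <- (.phantom_calib$target_normal_mean -
                          .phantom_calib$base_floor) / G
  }
  .calib_env$peak
}

#' Phantom parameter set
#'
#' @param pattern_class One of `"normal"`, `"inferior"`, `"diffuse"`,
#'   `"superior"` - the angular thinning pattern.
#' @param severity Fraction of maximal GCIPL loss in the affected region,
#'   in `[0, 1]`.
#' @param base_floor Thickness far from the annulus (um).
#' @param annulus_peak Peak ring thickness above the floor (um). Default is
#'   the calibrated amplitude.
#' @param ring_radius_mm Vertical-equivalent eccentricity of the ring crest.
#' @param ring_width_mm Gaussian width of the ring.
#' @param fovea_offset_px Integer `(x, y)` offset of the fovea from the
#'   raster centre, in pixels.
#' @param noise_sd Pixel noise standard deviation (um) before smoothing.
#' @param artifact `"none"`, `"erm_focal_thickening"` or `"poor_quality"`.
#' @param laterality `"OD"` or `"OS"`; OS maps are mirrored horizontally.
#' @param edema Logical; transient annulus-peak inflation (disc-edema-like
#'   thickening) applied by [make_eye_series()] at visit 0.
#' @return A validated `phantom_params` list.
#' @export
phantom_params <- function(pattern_class = c("normal", "inferior", "diffuse",
                                             "superior"),
                           severity = 0,
                           base_floor = .phantom_calib$base_floor,
                           annulus_peak = .annulus_peak(),
                           ring_radius_mm = .phantom_calib$ring_radius,
                           ring_width_mm = .phantom_calib$ring_width,
                           fovea_offset_px = c(0L, 0L),
                           noise_sd = 2,
                           artifact = c("none", "erm_focal_thickening",
                                        "poor_quality"),
                           laterality = c("OD", "OS"),
                           edema = FALSE) {
  pattern_class <- match.arg(pattern_class)
  artifact <- match.arg(artifact)
  laterality <- match.arg(laterality)
  vals <- c(severity, base_floor, annulus_peak, ring_radius_mm,
            ring_width_mm, fovea_offset_px, noise_sd)
  if (!all(is.finite(vals))) stop("phantom parameters must be finite")
  if (severity < 0 || severity > 1) stop("severity must be in [0, 1]")
  if (ring_radius_mm <= 0 || ring_radius_mm > 3)
    stop("ring_radius_mm must be in (0, 3] mm")
  if (ring_width_mm <= 0) stop("ring_width_mm must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(
    pattern_class = pattern_class, severity = severity,
    base_floor = base_floor, annulus_peak = annulus_peak,
    ring_radius_mm = ring_radius_mm, ring_width_mm = ring_width_mm,
    fovea_offset_px = as.numeric(fovea_offset_px), noise_sd = noise_sd,
    artifact = artifact, laterality = laterality, edema = isTRUE(edema)
  ), class = "phantom_params")
}

# deterministic stream splitting; keeps derived seeds below 2^31
derive_seed <- function(seed, k) {
  s <- as.numeric(seed) %% 2147483647
  as.integer((s * 69069 + as.numeric(k) * 1234567 + 12345) %% 2147483647)
}

# raised-cosine hemifield bump: 1 inside the hemifield core, 20-degree
# cosine shoulders centered on the horizontal boundaries, 0 opposite.
# w_inferior + w_superior == 1 everywhere, so either bump averages exactly
# 1/2 over the annulus.
.angular_weight <- function(theta_deg, pattern_class) {
  if (pattern_class == "normal") return(0 * theta_deg)
  if (pattern_class == "diffuse") return(1 + 0 * theta_deg)
  center <- if (pattern_class == "inferior") 270 else 90
  d <- abs(((theta_deg - center + 180) %% 360) - 180)
  w <- numeric(length(d))
  w[d <= 80] <- 1
  ramp <- d > 80 & d < 100
  w[ramp] <- 0.5 * (1 + cos(pi * (d[ramp] - 80) / 20))
  dim(w) <- dim(theta_deg)
  w
}

# separable 1-px-sigma Gaussian smoothing with edge replication
.smooth1px <- function(m) {
  k <- exp(-(-3:3)^2 / 2); k <- k / sum(k)
  n <- nrow(m)
  idx <- pmin(pmax(outer(seq_len(n), -3:3, `+`), 1L), n)
  sm_cols <- function(x) {
    out <- 0 * x
    for (j in 1:7) out <- out + k[j] * x[idx[, j], , drop = FALSE]
    out
  }
  t(sm_cols(t(sm_cols(m))))
}

#' Render one synthetic GCIPL thickness map
#'
#' Deterministic in `(params, seed)`. The returned matrix is in micrometres,
#' `[row, col]` with row 1 the superior edge, and carries attributes
#' `fovea` (0-based `(x, y)` pixels), `qc` (`"good"`/`"poor"`),
#' `laterality` and `px_pitch` (mm).
#'
#' @param params A [phantom_params()].
#' @param seed Integer seed.
#' @param img_px Raster side length (default 200).
#' @return A `thickness_map` matrix.
#' @export
make_gcipl_map <- function(params, seed = 1L, img_px = 200L) {
  stopifnot(inherits(params, "phantom_params"))
  n <- as.integer(img_px)
  geom <- annulus_geometry(n)
  c0 <- (n - 1) / 2
  # render in the OD frame about the offset fovea; mirror at the end for OS
  fov <- c(c0 + params$fovea_offset_px[1], c0 + params$fovea_offset_px[2])
  off <- .fovea_offsets_mm(geom, fov, "OD")
  rho <- sqrt((off$tx / .phantom_calib$ellip)^2 + off$dy^2)
  theta <- atan2(off$dy / geom$v_outer, off$tx / geom$h_outer)
  theta <- (theta %% (2 * pi)) / pi * 180
  g <- exp(-(rho - params$ring_radius_mm)^2 / (2 * params$ring_width_mm^2))
  w <- .angular_weight(theta, params$pattern_class)
  thick <- params$base_floor + params$annulus_peak * g *
    (1 - params$severity * w)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, 0L))

  if (params$artifact == "erm_focal_thickening") {
    # +30 um Gaussian blob (sigma 0.5 mm) centered in the superior-temporal
    # quadrant at the ring eccentricity
    bx <- -1.25 * cos(pi / 6) * .phantom_calib$ellip   # temporal (OD: -x)
    by <- 1.25 * sin(pi / 6)
    x_mm <- -off$tx   # back to signed x in the OD frame
    d2 <- (x_mm - bx)^2 + (off$dy - by)^2
    thick <- thick + 30 * exp(-d2 / (2 * 0.5^2))
  }

  noise_sd <- params$noise_sd *
    if (params$artifact == "poor_quality") 2 else 1
  if (noise_sd > 0) {
    noise <- matrix(stats::rnorm(n * n, 0, noise_sd), n, n)
    thick <- thick + .smooth1px(noise)
  }

  qc <- "good"
  if (params$artifact == "poor_quality") {
    qc <- "poor"
    # random rectangular dropout covering >= 15% of pixels
    w_px <- ceiling(n * stats::runif(1, 0.40, 0.70))
    h_px <- ceiling(n * stats::runif(1, 0.40, 0.70))
    r0 <- sample.int(n - h_px + 1L, 1L)
    cst <- sample.int(n - w_px + 1L, 1L)
    thick[r0:(r0 + h_px - 1L), cst:(cst + w_px - 1L)] <- 0
  }

  thick <- pmax(thick, 0)
  fovea <- fov
  if (params$laterality == "OS") {
    thick <- thick[, n:1, drop = FALSE]
    fovea[1] <- (n - 1) - fovea[1]
  }
  structure(thick, class = c("thickness_map", "matrix"),
            fovea = fovea, qc = qc, laterality = params$laterality,
            px_pitch = geom$px_pitch, units = "um")
}

# save/restore the global RNG state so seeded generators do not clobber it
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.thickness_map <- function(x, ...) {
  cat(sprintf("GCIPL thickness map %d x %d px (%.0f x %.0f mm), %s, qc=%s\n",
              nrow(x), ncol(x), nrow(x) * attr(x, "px_pitch"),
              ncol(x) * attr(x, "px_pitch"),
              attr(x, "laterality"), attr(x, "qc")))
  cat(sprintf("  fovea (x,y) px: (%.1f, %.1f); range %.1f-%.1f um\n",
              attr(x, "fovea")[1], attr(x, "fovea")[2], min(x), max(x)))
  invisible(x)
}

#' Longitudinal series of maps for one eye
#'
#' Visit `k` (0-based) has `severity = min(1, severity0 + k * rate)`. The
#' progression label is `"beyond_normal_range"` when the final severity
#' exceeds the configured normal-band threshold (default 0.2). When
#' `initial$edema` is set (NAION-like series), visit 0 has its annulus peak
#' inflated, emulating transient thickening from optic disc edema before
#' atrophy sets in.
#'
#' @param initial [phantom_params()] at the first visit.
#' @param n_visits Number of visits (>= 1).
#' @param progression_rate Severity increase per visit (>= 0).
#' @param seed Integer seed.
#' @param img_px Raster size.
#' @param intervals_days Optional integer vector (length `n_visits - 1`);
#'   drawn uniformly from 60-400 days when missing.
#' @param disease_label One of `"normal"`, `"glaucoma"`, `"ON"`, `"NAION"`.
#' @param poor_quality_rate Per-visit probability that the scan is a
#'   poor-quality acquisition (dropout + doubled noise), independent of the
#'   eye's own artifact setting.
#' @return An `eye_series`: list of maps plus labels and intervals.
#' @export
make_eye_series <- function(initial, n_visits, progression_rate, seed = 1L,
                            img_px = 200L, intervals_days = NULL,
                            disease_label = "normal",
                            poor_quality_rate = 0) {
  stopifnot(inherits(initial, "phantom_params"), n_visits >= 1,
            progression_rate >= 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, 999L))
  if (is.null(intervals_days) && n_visits > 1)
    intervals_days <- sample(60:400, n_visits - 1L, replace = TRUE)
  poor <- stats::runif(n_visits) < poor_quality_rate
  severities <- pmin(1, initial$severity + (seq_len(n_visits) - 1) *
                          progression_rate)
  maps <- vector("list", n_visits)
  for (k in seq_len(n_visits)) {
    p <- initial
    p$severity <- severities[k]
    p$edema <- FALSE
    if (poor[k]) p$artifact <- "poor_quality"
    if (isTRUE(initial$edema) && k == 1L)
      p$annulus_peak <- p$annulus_peak * .phantom_calib$edema_peak_factor
    maps[[k]] <- make_gcipl_map(p, seed = derive_seed(seed, k), img_px)
  }
  label <- if (severities[n_visits] > .phantom_calib$normal_band_threshold)
    "beyond_normal_range" else "within_normal_range"
  structure(list(
    maps = maps,
    intervals_days = if (n_visits > 1) as.integer(intervals_days) else integer(0),
    severities = severities,
    progression_label = label,
    disease_label = disease_label,
    params = initial
  ), class = "eye_series")
}

#' Disease-class phantom presets
#'
#' Returns the parameter distribution a cohort draws from for one disease
#' class: the angular pattern (glaucoma inferior-dominant with a minority of
#' superior cases, ON diffuse, NAION superior-dominant), a Beta severity
#' distribution whose mean is calibrated to the class cohort thickness, and
#' artifact rates.
#'
#' @param class `"normal"`, `"glaucoma"`, `"ON"` or `"NAION"`.
#' @return A list of preset fields.
#' @export
class_preset <- function(class = c("normal", "glaucoma", "ON", "NAION")) {
  class <- match.arg(class)
  k <- .phantom_calib$severity_k
  mu <- switch(class, normal = 0,
               glaucoma = .phantom_calib$severity_mean[["glaucoma"]],
               ON = .phantom_calib$severity_mean[["ON"]],
               NAION = .phantom_calib$severity_mean[["NAION"]])
  list(
    class = class,
    patterns = switch(class,
      normal = c(normal = 1),
      glaucoma = c(inferior = 0.85, superior = 0.15),
      ON = c(diffuse = 1),
      NAION = c(superior = 1)),
    severity_shape = if (mu > 0) c(k * mu, k * (1 - mu)) else NULL,
    poor_quality_rate = 0.05,
    erm_rate = if (class == "glaucoma") 0.03 else 0.01,
    edema_rate = if (class == "NAION") 0.7 else 0
  )
}

# draw per-eye phantom parameters from a class preset; poor-quality scans
# are a per-visit event and are rolled by the series generator instead
.draw_eye_params <- function(preset, img_px, max_offset_px) {
  cls <- sample(names(preset$patterns), 1, prob = preset$patterns)
  sev <- if (is.null(preset$severity_shape)) 0 else
    stats::rbeta(1, preset$severity_shape[1], preset$severity_shape[2])
  art <- if (stats::runif(1) < preset$erm_rate) "erm_focal_thickening"
         else "none"
  phantom_params(
    pattern_class = cls, severity = sev,
    base_floor = .phantom_calib$base_floor +
      stats::rnorm(1, 0, .phantom_calib$floor_sd),
    annulus_peak = .annulus_peak() +
      stats::rnorm(1, 0, .phantom_calib$peak_sd),
    ring_radius_mm = .phantom_calib$ring_radius +
      stats::rnorm(1, 0, .phantom_calib$radius_sd),
    ring_width_mm = .phantom_calib$ring_width +
      stats::rnorm(1, 0, .phantom_calib$width_sd),
    fovea_offset_px = round(stats::runif(2, -max_offset_px, max_offset_px)),
    noise_sd = stats::runif(1, 1.5, 3),
    artifact = art,
    laterality = sample(c("OD", "OS"), 1),
    edema = stats::runif(1) < preset$edema_rate
  )
}

#' Cohort specification
#'
#' @param counts Named integer vector: eyes per class
#'   (`normal`, `glaucoma`, `ON`, `NAION`).
#' @param n_visits Integer range `c(min, max)` of visits per eye; `c(1, 1)`
#'   gives the cross-sectional calibration cohort.
#' @param img_px Raster size of the generated maps.
#' @param longitudinal Logical; when TRUE, baseline severity is mild and a
#'   progression rate is drawn per eye (about half of diseased eyes
#'   progress beyond the normal band), which is the regime the longitudinal
#'   classifier is trained on. When FALSE, severity is drawn from the
#'   class-calibrated distribution and eyes do not progress.
#' @param max_offset_px Largest fovea decentration in native pixels; default
#'   scales the 200-px value of 20 px to `img_px`.
#' @param severity_range Optional `c(lo, hi)`: draw disease severity
#'   uniformly from this range instead of the class-calibrated Beta
#'   distribution. Used for training cohorts that must cover the full
#'   severity axis evenly.
#' @param erm_rates Optional named list overriding the per-class epiretinal
#'   membrane artifact rate.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(counts = c(normal = 10, glaucoma = 10, ON = 10,
                                   NAION = 10),
                        n_visits = c(1, 1), img_px = 200L,
                        longitudinal = FALSE, max_offset_px = NULL,
                        severity_range = NULL, erm_rates = NULL) {
  stopifnot(all(counts >= 0), length(n_visits) == 2, n_visits[1] >= 1)
  if (is.null(max_offset_px)) max_offset_px <- round(20 * img_px / 200)
  structure(list(counts = counts, n_visits = as.integer(n_visits),
                 img_px = as.integer(img_px),
                 longitudinal = isTRUE(longitudinal),
                 max_offset_px = max_offset_px,
                 severity_range = severity_range,
                 erm_rates = erm_rates),
            class = "cohort_spec")
}

#' Generate a synthetic cohort of eye series
#'
#' Class-conditional pattern assignment (glaucoma inferior-dominant with a
#' minority superior, ON diffuse, NAION superior-dominant, normal near-zero
#' severity), reproducible under the seed. Returns the series plus a manifest
#' data frame with one row per map (columns `subject_id, eye, visit_idx,
#' interval_days, disease_label, progression_label, qc_label, fovea_x_px,
#' fovea_y_px, path`).
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return List with elements `series` (list of `eye_series`) and
#'   `manifest` (data.frame).
#' @export
make_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  classes <- names(spec$counts)[spec$counts > 0]
  series <- list()
  rows <- list()
  eye_idx <- 0L
  for (cl in classes) {
    preset <- class_preset(cl)
    if (!is.null(spec$erm_rates) && !is.null(spec$erm_rates[[cl]]))
      preset$erm_rate <- spec$erm_rates[[cl]]
    for (i in seq_len(spec$counts[[cl]])) {
      eye_idx <- eye_idx + 1L
      eseed <- derive_seed(seed, eye_idx)
      old <- .Random.seed_save()
      set.seed(eseed)
      nv <- if (spec$n_visits[1] == spec$n_visits[2]) spec$n_visits[1] else
        sample(spec$n_visits[1]:spec$n_visits[2], 1)
      par <- .draw_eye_params(preset, spec$img_px, spec$max_offset_px)
      if (spec$longitudinal && cl != "normal") {
        par$severity <- stats::runif(1, 0, 0.1)
        rate <- if (stats::runif(1) < 0.5) stats::runif(1, 0.08, 0.18)
                else stats::runif(1, 0, 0.015)
      } else {
        rate <- 0
        par$edema <- FALSE
        if (!is.null(spec$severity_range) && cl != "normal")
          par$severity <- stats::runif(1, spec$severity_range[1],
                                       spec$severity_range[2])
      }
      .Random.seed_restore(old)
      es <- make_eye_series(par, nv, rate, seed = eseed,
                            img_px = spec$img_px, disease_label = cl,
                            poor_quality_rate = preset$poor_quality_rate)
      sid <- sprintf("S%04d", eye_idx)
      series[[sid]] <- es
      for (k in seq_len(nv)) {
        mp <- es$maps[[k]]
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sid, eye = par$laterality, visit_idx = k - 1L,
          interval_days = if (k == 1L) 0L else es$intervals_days[k - 1L],
          disease_label = cl, progression_label = es$progression_label,
          qc_label = attr(mp, "qc"),
          fovea_x_px = attr(mp, "fovea")[1],
          fovea_y_px = attr(mp, "fovea")[2],
          path = NA_character_, stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(), eye = character(),
               visit_idx = integer(), interval_days = integer(),
               disease_label = character(), progression_label = character(),
               qc_label = character(), fovea_x_px = numeric(),
               fovea_y_px = numeric(), path = character(),
               stringsAsFactors = FALSE)
  list(series = series, manifest = manifest)
}

#' Cohort calibration summary
#'
#' Generates a cross-sectional cohort for one class and returns the mean over
#' quality-passing maps of the per-map mean of the six sector thicknesses -
#' the quantity the class calibration constants are solved against.
#'
#' @param class Disease class.
#' @param n Number of eyes.
#' @param seed Integer seed.
#' @param img_px Raster size (default native 200).
#' @return List with `mean_um`, `sd_um` and `n_good`.
#' @export
calibration_cohort_mean <- function(class, n = 500L, seed = 0L,
                                    img_px = 200L) {
  preset <- class_preset(class)
  vals <- numeric(0)
  for (i in seq_len(n)) {
    eseed <- derive_seed(seed, i + 7000L)
    old <- .Random.seed_save()
    set.seed(eseed)
    par <- .draw_eye_params(preset, img_px, round(20 * img_px / 200))
    if (stats::runif(1) < preset$poor_quality_rate)
      par$artifact <- "poor_quality"
    .Random.seed_restore(old)
    mp <- make_gcipl_map(par, seed = eseed, img_px = img_px)
    if (attr(mp, "qc") != "good") next
    prof <- sector_means(mp)
    vals <- c(vals, mean(prof$sector_means))
  }
  list(mean_um = mean(vals), sd_um = stats::sd(vals), n_good = length(vals))
}
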