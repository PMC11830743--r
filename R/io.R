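#' @name io
#' @title Map, manifest and checkpoint IO
#'
#' @description
#' Thickness maps travel as 16-bit single-channel TIFF (0.1 um per integer
#' unit), as R serialized array archives (`.rds`) or as headerless CSV
#' grids. Cohort manifests are CSV with one row per map. OS (left-eye) maps
#' are mirrored horizontally at load so downstream code is single-convention
#' (right-eye orientation). Pixel coordinates are 0-based with row 0 at the
#' superior edge.
NULL

.map_attrs <- function(m, fovea = NULL, qc = "good", laterality = "OD",
                       img_px = nrow(m)) {
  structure(m, class = c("thickness_map", "matrix"),
            fovea = if (is.null(fovea)) rep((img_px - 1) / 2, 2) else fovea,
            qc = qc, laterality = laterality, px_pitch = 6 / img_px,
            units = "um")
}

#' Write a thickness map to disk
#'
#' @param map Thickness map (micrometres).
#' @param path Output path; extension selects the dialect unless given.
#' @param dialect `"tiff16"` (0.1 um quantization), `"array-archive"`
#'   (`.rds`) or `"csv-grid"`.
#' @return `path`, invisibly.
#' @export
write_thickness_map <- function(map, path,
                                dialect = c("auto", "tiff16",
                                            "array-archive", "csv-grid")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") dialect <- .dialect_of(path)
  m <- unclass(map)
  switch(dialect,
    tiff16 = tiff::writeTIFF(pmin(round(m * 10), 65535) / 65535, path,
                             bits.per.sample = 16L),
    `array-archive` = saveRDS(map, path),
    `csv-grid` = utils::write.table(m, path, sep = ",", row.names = FALSE,
                                    col.names = FALSE))
  invisible(path)
}

.dialect_of <- function(path) {
  switch(tolower(tools::file_ext(path)),
         tif = , tiff = "tiff16",
         rds = "array-archive",
         csv = "csv-grid",
         stop("cannot infer map dialect from extension: ", path))
}

# bilinear resize of a matrix to n x n
.resize_bilinear <- function(m, n) {
  src <- nrow(m)
  pos <- (seq_len(n) - 0.5) * src / n - 0.5
  i0 <- pmin(pmax(floor(pos), 0), src - 1); i1 <- pmin(i0 + 1, src - 1)
  f <- pos - floor(pos)
  f[pos < 0] <- 0; f[pos > src - 1] <- 1
  rows <- m[i0 + 1, , drop = FALSE] * (1 - f) + m[i1 + 1, , drop = FALSE] * f
  t(t(rows[, i0 + 1, drop = FALSE]) * (1 - f) +
      t(rows[, i1 + 1, drop = FALSE]) * f)
}

# nearest-neighbour fill of non-finite pixels
.fill_nonfinite <- function(m) {
  bad <- which(!is.finite(m), arr.ind = TRUE)
  ok <- which(is.finite(m), arr.ind = TRUE)
  if (!nrow(ok)) stop("map contains no finite pixels")
  for (k in seq_len(nrow(bad))) {
    d2 <- (ok[, 1] - bad[k, 1])^2 + (ok[, 2] - bad[k, 2])^2
    m[bad[k, 1], bad[k, 2]] <- m[ok[which.min(d2), 1], ok[which.min(d2), 2]]
  }
  m
}

#' Read a thickness map
#'
#' Returns a micrometre-scaled square map, resized bilinearly to `img_px`
#' (with a note) when the stored raster differs. Non-finite pixels are
#' filled by nearest neighbour and the map is flagged (`flagged` attribute);
#' an all-NaN map is a hard error.
#'
#' @param path Input file.
#' @param dialect See [write_thickness_map()].
#' @param img_px Target raster (default 200).
#' @param fovea_px,qc,laterality Optional metadata (usually from the
#'   manifest); OS maps are mirrored to the right-eye frame at load, and the
#'   fovea x coordinate with them.
#' @return A `thickness_map`.
#' @export
read_thickness_map <- function(path, dialect = c("auto", "tiff16",
                                                 "array-archive", "csv-grid"),
                               img_px = 200L, fovea_px = NULL, qc = "good",
                               laterality = "OD") {
  dialect <- match.arg(dialect)
  if (dialect == "auto") dialect <- .dialect_of(path)
  if (!file.exists(path)) stop("no such file: ", path)
  m <- switch(dialect,
    tiff16 = tiff::readTIFF(path, as.is = TRUE) / 10,
    `array-archive` = unclass(readRDS(path)),
    `csv-grid` = as.matrix(utils::read.table(path, sep = ",",
                                             header = FALSE)))
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  if (!any(is.finite(m))) stop("all-NaN map: ", path)
  flagged <- !all(is.finite(m))
  if (flagged) m <- .fill_nonfinite(m)
  if (nrow(m) != img_px || ncol(m) != img_px) {
    message(sprintf("note: resizing %d x %d raster to %d x %d",
                    nrow(m), ncol(m), img_px, img_px))
    m <- .resize_bilinear(m, img_px)
    fovea_px <- NULL  # stored coordinates no longer apply
  }
  if (identical(laterality, "OS")) {
    m <- m[, ncol(m):1, drop = FALSE]
    if (!is.null(fovea_px)) fovea_px[1] <- (img_px - 1) - fovea_px[1]
  }
  out <- .map_attrs(m, fovea_px, qc, laterality, img_px)
  attr(out, "flagged") <- flagged
  out
}

#' Write a cohort to disk (maps + manifest)
#'
#' @param cohort Output of [make_cohort()].
#' @param dir Output directory (created).
#' @param dialect Map dialect (default tiff16).
#' @return Path of the manifest CSV.
#' @export
write_cohort <- function(cohort, dir, dialect = "tiff16") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- switch(dialect, tiff16 = "tif", `array-archive` = "rds",
                `csv-grid` = "csv")
  mf <- cohort$manifest
  row <- 0L
  for (nm in names(cohort$series)) {
    es <- cohort$series[[nm]]
    for (k in seq_along(es$maps)) {
      row <- row + 1L
      fn <- sprintf("%s_v%02d.%s", nm, k - 1L, ext)
      write_thickness_map(es$maps[[k]], file.path(dir, fn), dialect)
      mf$path[row] <- fn
    }
  }
  write_manifest(mf, file.path(dir, "manifest.csv"))
}

#' @rdname write_cohort
#' @param manifest Manifest data frame.
#' @param path CSV path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a manifest and its maps
#'
#' @param path Manifest CSV path.
#' @param img_px Target raster.
#' @return List with `manifest` and `maps` (in manifest row order, mirrored
#'   to the right-eye frame where the eye is OS).
#' @export
read_cohort <- function(path, img_px = 200L) {
  mf <- utils::read.csv(path, stringsAsFactors = FALSE)
  dir <- dirname(path)
  maps <- lapply(seq_len(nrow(mf)), function(i)
    read_thickness_map(file.path(dir, mf$path[i]), img_px = img_px,
                       fovea_px = c(mf$fovea_x_px[i], mf$fovea_y_px[i]),
                       qc = mf$qc_label[i], laterality = mf$eye[i]))
  list(manifest = mf, maps = maps)
}

#' Save / load a model checkpoint
#'
#' The checkpoint directory holds the weights (serialized array archive),
#' a YAML snapshot of the model configuration (including normalization and
#' anchor constants) and the training history as CSV.
#'
#' @param checkpoint A `bvae_checkpoint` from [bvae_train()].
#' @param dir Checkpoint directory.
#' @return `dir`, invisibly.
#' @export
save_checkpoint <- function(checkpoint, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(checkpoint$model$net, file.path(dir, "weights.rds"))
  cfg <- checkpoint$model$config
  cfg$weights <- as.list(cfg$weights)
  yaml::write_yaml(c(cfg, list(train_seed = checkpoint$seed,
                               best_epoch = checkpoint$best_epoch)),
                   file.path(dir, "config.yaml"))
  if (!is.null(checkpoint$history) && nrow(checkpoint$history))
    utils::write.csv(checkpoint$history, file.path(dir, "history.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  seed <- cfg$train_seed; best <- cfg$best_epoch
  cfg$train_seed <- NULL; cfg$best_epoch <- NULL
  cfg$weights <- unlist(cfg$weights)
  model <- structure(list(net = readRDS(file.path(dir, "weights.rds")),
                          config = cfg), class = "bvae_model")
  hist_path <- file.path(dir, "history.csv")
  structure(list(model = model,
                 history = if (file.exists(hist_path))
                   utils::read.csv(hist_path) else NULL,
                 seed = seed, best_epoch = best, diverged = FALSE),
            class = "bvae_checkpoint")
}
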