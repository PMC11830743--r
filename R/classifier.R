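#' Three-time-point latent feature assembly for one eye
#'
#' The first feature time point is the first usable visit, the third is the
#' last, and the second is the interior visit most equidistant from the
#' first and last (smallest `|gap to t1 - gap to t3|`, ties broken toward
#' the earlier visit). With the display latents alone the feature vector has
#' 6 values (d1, d2 at t1, t2, t3); adding the booster latents extends it to
#' 30.
#'
#' @param series An `eye_series` (for visit days and labels).
#' @param codes List of `latent_code`s, one per visit of the series.
#' @param use_blv Include booster latents.
#' @param usable Logical vector of usable visits (default: QC-passing maps).
#' @return A `feature_row` list (`features`, `label_binary`,
#'   `label_multiclass`, `visit_days_used`), or NULL (with a message) when
#'   fewer than 3 usable visits exist.
#' @export
assemble_features <- function(series, codes, use_blv = FALSE,
                              usable = NULL) {
  stopifnot(inherits(series, "eye_series"),
            length(codes) == length(series$maps))
  if (is.null(usable))
    usable <- vapply(series$maps, function(m)
      !identical(attr(m, "qc"), "poor"), logical(1))
  days <- cumsum(c(0, series$intervals_days))
  idx <- which(usable)
  if (length(idx) < 3L) {
    message("eye excluded: fewer than 3 usable visits")
    return(NULL)
  }
  i1 <- idx[1]; i3 <- idx[length(idx)]
  interior <- idx[idx != i1 & idx != i3]
  score <- abs((days[interior] - days[i1]) - (days[i3] - days[interior]))
  i2 <- interior[which.min(score)]     # which.min takes the earliest tie
  feat <- unlist(lapply(c(i1, i2, i3), function(i) {
    cd <- codes[[i]]
    v <- c(d1 = cd$d[1], d2 = cd$d[2])
    if (use_blv) v <- c(v, stats::setNames(cd$b, paste0("b", 1:8)))
    v
  }))
  names(feat) <- paste0(rep(c("t1_", "t2_", "t3_"),
                            each = length(feat) / 3), names(feat))
  structure(list(
    features = feat,
    label_binary = series$progression_label,
    label_multiclass = if (series$progression_label == "within_normal_range")
      "within_normal_range" else series$disease_label,
    visit_days_used = days[c(i1, i2, i3)]
  ), class = "feature_row")
}

#' Feature table for a cohort
#'
#' Encodes every visit of every eye and assembles one [assemble_features()]
#' row per eye with at least 3 usable visits.
#'
#' @param cohort Output of [make_cohort()].
#' @param model Trained `bvae_model`.
#' @param use_blv Include booster latents.
#' @return Data frame with `eye_id`, feature columns and both labels.
#' @export
build_feature_table <- function(cohort, model, use_blv = FALSE) {
  rows <- list()
  for (nm in names(cohort$series)) {
    es <- cohort$series[[nm]]
    codes <- encode(model, es$maps)
    fr <- suppressMessages(assemble_features(es, codes, use_blv))
    if (is.null(fr)) next
    rows[[nm]] <- data.frame(eye_id = nm, t(fr$features),
                             label_binary = fr$label_binary,
                             label_multiclass = fr$label_multiclass,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit a gradient-boosted-tree classifier on latent features
#'
#' XGBoost with a maximum tree depth of 15, step-size shrinkage (eta) of 0.3
#' and the `multi:softprob` objective (also for the binary task, as a
#' 2-class softprob), up to 200 boosting rounds with early stopping on an
#' internal validation fold split at the eye level.
#'
#' @param rows Feature table from [build_feature_table()] (or any data frame
#'   with feature columns and a label column).
#' @param mode `"binary"` (thinning beyond vs within normal range) or
#'   `"multiclass"` (within_normal_range / glaucoma / ON / NAION).
#' @param params Optional overrides for the xgboost parameter list.
#' @param nrounds Maximum boosting rounds.
#' @param val_fraction Eye-level fraction used for early stopping.
#' @param seed Seed for the validation fold.
#' @return A `gcl_classifier`: xgboost handle, class levels, feature names.
#' @export
fit_classifier <- function(rows, mode = c("binary", "multiclass"),
                           params = list(), nrounds = 200L,
                           val_fraction = 0.2, seed = 1L) {
  mode <- match.arg(mode)
  label_col <- if (mode == "binary") "label_binary" else "label_multiclass"
  feats <- grep("^t[123]_", names(rows), value = TRUE)
  classes <- sort(unique(rows[[label_col]]))
  if (length(classes) < 2L) stop("need at least 2 classes to fit")
  y <- match(rows[[label_col]], classes) - 1L
  X <- as.matrix(rows[feats])

  hv <- subject_hash(rows$eye_id, salt = 777L + seed)
  val <- hv < val_fraction
  if (!any(val) || all(val)) val <- seq_len(nrow(X)) %% 5L == 0L
  p <- utils::modifyList(list(
    objective = "multi:softprob", num_class = length(classes),
    max_depth = 15, eta = 0.3, nthread = 1), params)
  dtr <- xgboost::xgb.DMatrix(X[!val, , drop = FALSE], label = y[!val])
  dva <- xgboost::xgb.DMatrix(X[val, , drop = FALSE], label = y[val])
  fit <- xgboost::xgb.train(p, dtr, nrounds = nrounds,
                            evals = list(val = dva),
                            early_stopping_rounds = 10L, verbose = 0)
  structure(list(booster = fit, classes = classes, features = feats,
                 mode = mode), class = "gcl_classifier")
}

#' Per-class probabilities from a fitted classifier
#'
#' @param object A `gcl_classifier`.
#' @param rows Feature table.
#' @param ... Unused.
#' @return Matrix (rows x classes) of probabilities summing to 1.
#' @export
predict.gcl_classifier <- function(object, rows, ...) {
  X <- as.matrix(rows[object$features])
  pr <- predict(object$booster, xgboost::xgb.DMatrix(X))
  if (!is.matrix(pr))
    pr <- matrix(pr, ncol = length(object$classes), byrow = TRUE)
  colnames(pr) <- object$classes
  pr
}

#' Feature importances of a fitted classifier
#' @param object A `gcl_classifier`.
#' @return Data frame of gain importances.
#' @export
classifier_importance <- function(object) {
  as.data.frame(xgboost::xgb.importance(model = object$booster))
}

#' One-vs-rest ROC curves and AUCs for multiclass probabilities
#'
#' One ROC curve and AUC per class (class absent from the labels yields an
#' `NA` AUC sentinel). AUC is computed by the rank (Mann-Whitney) method and
#' is therefore invariant to monotone transforms of the scores.
#'
#' @param probabilities Matrix with one column per class (rows sum to 1).
#' @param labels True class labels (matching column names).
#' @return A `multiclass_roc` list: per-class `auc` and `curves`
#'   (data frames with `fpr`, `tpr`).
#' @export
multiclass_roc <- function(probabilities, labels) {
  stopifnot(is.matrix(probabilities), !is.null(colnames(probabilities)))
  if (max(abs(rowSums(probabilities) - 1)) > 1e-6)
    stop("probability rows must sum to 1")
  classes <- colnames(probabilities)
  aucs <- stats::setNames(rep(NA_real_, length(classes)), classes)
  curves <- stats::setNames(vector("list", length(classes)), classes)
  for (cl in classes) {
    y <- as.numeric(labels == cl)
    if (length(unique(y)) < 2L) next
    r <- pROC::roc(response = y, predictor = probabilities[, cl],
                   quiet = TRUE, direction = "<", levels = c(0, 1))
    aucs[cl] <- as.numeric(pROC::auc(r))
    curves[[cl]] <- data.frame(fpr = 1 - r$specificities,
                               tpr = r$sensitivities)
  }
  structure(list(auc = aucs, curves = curves), class = "multiclass_roc")
}

#' @export
print.multiclass_roc <- function(x, ...) {
  cat("One-vs-rest AUC:\n")
  print(round(x$auc, 3))
  invisible(x)
}
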