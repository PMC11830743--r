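fake_code <- function(d, b = rep(0, 8)) {
  structure(list(d = d, b = b, d_logvar = rep(0, 2), b_logvar = rep(0, 8),
                 fovea_px = c(100, 100), exclude_prob = 0),
            class = "latent_code")
}

fake_series <- function(n_visits, intervals, label = "beyond_normal_range",
                        disease = "glaucoma", img = 16L) {
  maps <- lapply(seq_len(n_visits), function(k)
    make_gcipl_map(phantom_params("normal"), k, img))
  structure(list(maps = maps, intervals_days = as.integer(intervals),
                 severities = rep(0, n_visits),
                 progression_label = label, disease_label = disease),
            class = "eye_series")
}

test_that("three-visit series uses the middle visit; ties break to the earlier visit", {
  s3 <- fake_series(3, c(100, 200))
  codes <- lapply(1:3, function(k) fake_code(c(k, -k)))
  fr <- assemble_features(s3, codes)
  expect_equal(unname(fr$features),
               c(1, -1, 2, -2, 3, -3))
  expect_equal(fr$visit_days_used, c(0, 100, 300))

  # visits at days 0, 100, 400, 500: both interior candidates score 300,
  # the earlier (day 100) wins
  s4 <- fake_series(4, c(100, 300, 100))
  codes4 <- lapply(1:4, function(k) fake_code(c(k, 0)))
  fr4 <- assemble_features(s4, codes4)
  expect_equal(fr4$visit_days_used, c(0, 100, 500))
  expect_equal(unname(fr4$features[3]), 2)  # t2 = second visit
})

test_that("booster latents toggle the feature length between 6 and 30", {
  s <- fake_series(3, c(90, 90))
  codes <- lapply(1:3, function(k) fake_code(c(0, 0), rep(k, 8)))
  expect_length(assemble_features(s, codes, use_blv = FALSE)$features, 6L)
  expect_length(assemble_features(s, codes, use_blv = TRUE)$features, 30L)
})

test_that("eyes with fewer than 3 usable visits are excluded with a message", {
  s <- fake_series(2, 90)
  codes <- lapply(1:2, function(k) fake_code(c(0, 0)))
  expect_message(out <- assemble_features(s, codes), "excluded")
  expect_null(out)

  # poor-quality visits do not count as usable
  s3 <- fake_series(3, c(90, 90))
  attr(s3$maps[[2]], "qc") <- "poor"
  codes3 <- lapply(1:3, function(k) fake_code(c(0, 0)))
  expect_message(out3 <- assemble_features(s3, codes3), "excluded")
  expect_null(out3)
})

test_that("the boosted-tree classifier separates Gaussian blobs and emits simplex probabilities", {
  set.seed(31)
  n <- 200
  rows <- data.frame(
    eye_id = sprintf("E%03d", 1:n),
    t1_d1 = c(rnorm(n / 2, -3), rnorm(n / 2, 3)),
    t1_d2 = rnorm(n),
    label_binary = rep(c("within_normal_range", "beyond_normal_range"),
                       each = n / 2),
    stringsAsFactors = FALSE)
  fit <- fit_classifier(rows, "binary")
  pr <- predict(fit, rows)
  expect_equal(unname(rowSums(pr)), rep(1, n), tolerance = 1e-6)
  acc <- mean(colnames(pr)[max.col(pr)] == rows$label_binary)
  expect_gte(acc, 0.99)
  imp <- classifier_importance(fit)
  expect_true("t1_d1" %in% imp$Feature)
  rows1 <- rows; rows1$label_binary <- "beyond_normal_range"
  expect_error(fit_classifier(rows1, "binary"), "2 classes")
})

test_that("one-vs-rest AUC is perfect for separable scores and null for random ones", {
  pr <- rbind(c(0.9, 0.1), c(0.8, 0.2), c(0.2, 0.8), c(0.1, 0.9))
  colnames(pr) <- c("a", "b")
  roc <- multiclass_roc(pr, c("a", "a", "b", "b"))
  expect_equal(unname(roc$auc), c(1, 1))

  set.seed(77)
  n <- 2000
  p1 <- runif(n)
  pr2 <- cbind(a = p1, b = 1 - p1)
  roc2 <- multiclass_roc(pr2, sample(c("a", "b"), n, replace = TRUE))
  expect_lt(abs(roc2$auc[["a"]] - 0.5), 0.03)
  expect_lt(abs(roc2$auc[["b"]] - 0.5), 0.03)
})

test_that("AUC equals the normalized Mann-Whitney statistic on an exhaustive toy", {
  scores <- c(0.1, 0.4, 0.35, 0.8, 0.65, 0.9)
  labels <- c("neg", "neg", "neg", "pos", "pos", "neg")
  pr <- cbind(pos = scores, neg = 1 - scores)
  roc <- multiclass_roc(pr, labels)
  # brute force over all (pos, neg) pairs
  pos <- scores[labels == "pos"]; neg <- scores[labels == "neg"]
  u <- 0
  for (p in pos) for (q in neg) u <- u + (p > q) + 0.5 * (p == q)
  expect_equal(unname(roc$auc["pos"]), u / (length(pos) * length(neg)))
})

test_that("a class absent from the labels yields an NA AUC sentinel", {
  pr <- cbind(a = c(0.7, 0.6), b = c(0.3, 0.4))
  roc <- multiclass_roc(pr, c("a", "a"))
  expect_true(is.na(roc$auc[["b"]]))
  expect_error(multiclass_roc(pr * 2, c("a", "a")), "sum to 1")
})
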