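# Hemoglobin grading, MLP fit/predict, and the evaluation suite.

test_that("hemoglobin grading matches the gradation table, boundaries included", {
  expect_equal(as.character(label_from_hb("male", 9.0)), "anemic")
  expect_equal(as.character(label_from_hb("female", 11.0)), "moderate")
  expect_equal(as.character(label_from_hb("male", 14.0)), "normal")

  # boundaries belong to the moderate band; anemic cut is sex-independent
  expect_equal(as.character(label_from_hb(c("male", "female"),
                                          c(10.5, 10.5))),
               c("moderate", "moderate"))
  expect_equal(as.character(label_from_hb("male", 13.5)), "moderate")
  expect_equal(as.character(label_from_hb("female", 12.0)), "moderate")
  expect_equal(as.character(label_from_hb("female", 12.0001)), "normal")
  expect_equal(as.character(label_from_hb("male", 13.5001)), "normal")
  expect_equal(as.character(label_from_hb(c("male", "female"),
                                          c(10.4999, 10.4999))),
               c("anemic", "anemic"))

  expect_error(label_from_hb("male", 0), "plausibility")
  expect_error(label_from_hb("female", 25), "plausibility")
  expect_error(label_from_hb("other", 12), "male")
})

test_that("hemoglobin grading is a total partition agreeing with the oracle", {
  grid <- seq(6, 18, by = 0.05)
  for (sex in c("male", "female")) {
    got <- as.character(label_from_hb(sex, grid))
    want <- vapply(grid, function(h) oracle_hb_label(sex, h), character(1))
    expect_identical(got, want)
    expect_true(all(got %in% hb_classes()))
  }
})

test_that("the MLP separates separable classes and is seed-deterministic", {
  df <- separable_features(n_per_class = 30, seed = 4)
  fit <- pallor_mlp(label ~ ., df, seed = 11)
  pred <- predict(fit, df)
  expect_gte(mean(pred == df$label), 0.99)

  fit2 <- pallor_mlp(label ~ ., df, seed = 11)
  expect_identical(fit$weights, fit2$weights)
  expect_identical(predict(fit, df, type = "prob"),
                   predict(fit2, df, type = "prob"))

  prob <- predict(fit, df, type = "prob")
  expect_true(all(prob >= 0))
  expect_equal(unname(rowSums(prob)), rep(1, nrow(df)), tolerance = 1e-6)
})

test_that("duplicating every training row does not change predictions", {
  df <- separable_features(n_per_class = 25, seed = 8)
  test <- separable_features(n_per_class = 10, seed = 9)
  fit1 <- pallor_mlp(label ~ ., df, seed = 3)
  fit2 <- pallor_mlp(label ~ ., rbind(df, df), seed = 3)
  expect_identical(predict(fit1, test), predict(fit2, test))
})

test_that("training refuses degenerate inputs", {
  df <- separable_features(n_per_class = 20, seed = 2)
  expect_error(pallor_mlp(label ~ ., df[df$label != "moderate", ],
                          hidden_units = 5), NA)
  miss <- df
  miss$label <- factor(miss$label, levels = hb_classes())
  miss <- miss[miss$label != "moderate", ]
  # factor with an empty level present in training data
  expect_error(pallor_mlp(as.matrix(miss[, 1:3]),
                          factor(miss$label, levels = hb_classes())),
               "absent")
  bad <- as.matrix(df[, 1:3])
  bad[1, 1] <- NA
  expect_error(pallor_mlp(bad, df$label), "finite")
})

test_that("confusion_matrix counts as defined", {
  cm <- confusion_matrix(c("anemic", "anemic", "moderate", "normal"),
                         c("anemic", "moderate", "moderate", "normal"))
  expect_equal(unname(cm["anemic", ]), c(1, 1, 0))
  expect_equal(sum(diag(cm)), 3)
  expect_equal(sum(cm), 4)

  same <- rep(hb_classes(), times = c(3, 4, 5))
  cm2 <- confusion_matrix(same, same)
  expect_equal(unname(diag(cm2)), c(3, 4, 5))
  expect_equal(sum(cm2) - sum(diag(cm2)), 0)

  expect_error(confusion_matrix(character(0), character(0)), "empty")
  expect_error(confusion_matrix(c("a", "b"), "a"), "differ")
})

test_that("classification metrics reproduce the one-vs-rest formulas", {
  perfect <- diag(c(10, 10, 10))
  rownames(perfect) <- colnames(perfect) <- hb_classes()
  rep0 <- classification_metrics(perfect)
  expect_equal(rep0$overall_accuracy, 1)
  expect_true(all(rep0$per_class$precision == 1))
  expect_true(all(rep0$per_class$sensitivity == 1))
  expect_true(all(rep0$per_class$specificity == 1))
  expect_true(all(rep0$per_class$f1 == 1))
  expect_true(all(rep0$per_class$fdr == 0))

  # binary-style counts TP=9 FN=1 FP=2 TN=8 folded into a 2x2 matrix
  cm <- matrix(c(9, 1, 2, 8), 2, byrow = TRUE,
               dimnames = list(c("pos", "neg"), c("pos", "neg")))
  r <- classification_metrics(cm)
  pos <- r$per_class[r$per_class$class == "pos", ]
  expect_equal(pos$sensitivity, 0.9)
  expect_equal(pos$specificity, 0.8)
  expect_equal(pos$precision, 9 / 11, tolerance = 1e-9)
  expect_equal(pos$f1, 2 * (9 / 11) * 0.9 / (9 / 11 + 0.9),
               tolerance = 1e-9)
  expect_equal(pos$ppv + pos$fdr, 1)

  never <- matrix(c(5, 0, 3, 4, 0, 2, 1, 0, 6), 3, byrow = TRUE,
                  dimnames = list(hb_classes(), hb_classes()))
  expect_warning(rn <- classification_metrics(never), "undefined")
  expect_true(is.nan(rn$per_class$ppv[2]))
  expect_true(is.nan(rn$per_class$fdr[2]))
})

test_that("metric identities hold on random confusion matrices", {
  set.seed(14)
  for (trial in 1:20) {
    cm <- matrix(rpois(9, 6), 3,
                 dimnames = list(hb_classes(), hb_classes()))
    if (sum(cm) == 0) next
    r <- suppressWarnings(classification_metrics(cm))
    expect_equal(r$overall_accuracy, sum(diag(cm)) / sum(cm))
    ok <- !is.nan(r$per_class$ppv)
    expect_equal(r$per_class$ppv[ok] + r$per_class$fdr[ok],
                 rep(1, sum(ok)), tolerance = 1e-12)
    # accuracy identity per class
    expect_equal(r$per_class$accuracy,
                 (r$per_class$tp + r$per_class$tn) / sum(cm))
  }
})

test_that("rank AUC equals trapezoidal integration and behaves at extremes", {
  truth <- rep(c("anemic", "normal"), each = 5)
  sep <- cbind(anemic = c(runif(5, 0.8, 1), runif(5, 0, 0.2)),
               normal = c(runif(5, 0, 0.2), runif(5, 0.8, 1)))
  auc <- roc_auc_ovr(truth, sep)
  expect_equal(unname(auc), c(1, 1))

  rev <- sep[, c(2, 1)]
  colnames(rev) <- colnames(sep)
  expect_equal(unname(roc_auc_ovr(truth, rev)), c(0, 0))

  set.seed(6)
  for (trial in 1:30) {
    n <- sample(4:20, 1)
    labs <- sample(c("anemic", "normal"), n, replace = TRUE)
    if (length(unique(labs)) < 2) next
    # coarse scores force ties
    sc <- matrix(sample(seq(0, 1, 0.25), 2 * n, replace = TRUE), ncol = 2,
                 dimnames = list(NULL, c("anemic", "normal")))
    got <- roc_auc_ovr(labs, sc)
    expect_equal(unname(got["anemic"]),
                 trapezoid_auc(labs == "anemic", sc[, "anemic"]),
                 tolerance = 1e-10)
    expect_equal(unname(got["normal"]),
                 trapezoid_auc(labs == "normal", sc[, "normal"]),
                 tolerance = 1e-10)
  }

  expect_error(roc_auc_ovr(rep("anemic", 4),
                           cbind(anemic = runif(4))), "degenerate")
})

test_that("rank AUC agrees with pROC on a random problem", {
  set.seed(23)
  labs <- sample(c("anemic", "normal"), 60, replace = TRUE)
  sc <- cbind(anemic = runif(60), normal = runif(60))
  got <- roc_auc_ovr(labs, sc)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = labs == "anemic", predictor = sc[, "anemic"],
    quiet = TRUE, direction = "<")))
  expect_equal(unname(got["anemic"]), ref, tolerance = 1e-10)
})

test_that("uniform random scores give AUC near one half", {
  set.seed(12)
  n <- 2000
  labs <- sample(hb_classes(), n, replace = TRUE)
  sc <- matrix(runif(3 * n), ncol = 3,
               dimnames = list(NULL, hb_classes()))
  auc <- roc_auc_ovr(labs, sc)
  expect_true(all(abs(auc - 0.5) < 0.05))
})

test_that("stratified 90/10 split reproduces the dataset arithmetic", {
  feats <- separable_features(n_per_class = 10, seed = 5)
  # synthetic table with the study's class counts
  counts <- c(anemic = 132, moderate = 169, normal = 310)
  set.seed(40)
  tab <- do.call(rbind, lapply(names(counts), function(cl) {
    idx <- sample(which(feats$label == cl), counts[cl], replace = TRUE)
    feats[idx, ]
  }))
  ev <- evaluate_split(tab, seed = 2, max_iter = 150)
  expect_equal(ev$split$n_train, 550)
  expect_equal(ev$split$n_test, 61)

  ev2 <- evaluate_split(tab, seed = 2, max_iter = 150)
  expect_identical(ev$split, ev2$split)
  expect_equal(ev$holdout$metrics$overall_accuracy,
               ev2$holdout$metrics$overall_accuracy)

  # resubstitution is at least nearly as good as held-out on separable data
  expect_gte(ev$resubstitution$metrics$overall_accuracy,
             ev$holdout$metrics$overall_accuracy - 0.05)

  expect_error(evaluate_split(feats[c(1, 11, 21), ]), "at least 2")
})

test_that("model artifacts round-trip through disk with a JSON sidecar", {
  df <- separable_features(n_per_class = 15, seed = 3)
  fit <- pallor_mlp(label ~ ., df, seed = 2, max_iter = 200)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(fit, path)
  expect_true(file.exists(paste0(path, ".json")))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(unlist(side$classes), fit$classes)
  back <- load_model(path)
  expect_identical(predict(back, df, type = "prob"),
                   predict(fit, df, type = "prob"))
})
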