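test_that("resampling plan enforces balanced folds", {
  p <- resampling_plan()
  expect_identical(p$per_class, 100L)
  expect_identical(p$n_sets, 50L)
  expect_identical(p$folds, 5L)
  expect_identical(p$repeats, 100L)
  expect_error(resampling_plan(per_class = 7L, folds = 5L), "divisible")
})

test_that("balanced subsets are balanced, deterministic and guarded", {
  set.seed(1)
  feats <- make_separable_features(10L)
  plan <- resampling_plan(per_class = 2L, n_sets = 3L, folds = 2L,
                          repeats = 1L, seed = 9L)
  ds <- balanced_subsets(feats, plan)
  expect_length(ds, 3L)
  for (d in ds) {
    expect_identical(nrow(d), 4L)
    expect_identical(sum(d$Class == "LoF"), 2L)
    expect_identical(sum(d$Class == "GoF"), 2L)
    # without replacement within a dataset
    expect_false(any(duplicated(rownames(d))))
  }
  ds2 <- balanced_subsets(feats, plan)
  expect_identical(ds, ds2)
  # deficit is reported, not padded
  expect_error(
    balanced_subsets(feats, resampling_plan(per_class = 15L, n_sets = 1L,
                                            folds = 5L, repeats = 1L)),
    "deficit 5")
})

test_that("one-hot encoding has one active column per nominal feature", {
  set.seed(2)
  feats <- make_separable_features(5L)
  x <- one_hot_encode(feats)
  vocab <- encoding_vocabulary(feats)
  expect_identical(ncol(x), sum(lengths(vocab)) + 1L)
  for (f in c("REF", "SUB", "TYPE", "SL", "PD")) {
    block <- x[, grep(paste0("^", f, "\\."), colnames(x)), drop = FALSE]
    expect_true(all(rowSums(block) == 1))
  }
  expect_identical(unname(x[, "SCORE"]), feats$SCORE)
  # records sharing all categories differ only in SCORE
  f2 <- feats[c(1, 1), ]
  f2$SCORE <- c(0.1, 0.9)
  x2 <- one_hot_encode(f2, vocab)
  expect_identical(x2[1, colnames(x2) != "SCORE"],
                   x2[2, colnames(x2) != "SCORE"])
  # missing alleles encode as the 'none' category
  f3 <- feats[1, ]; f3$REF <- NA; f3$SUB <- NA
  v3 <- encoding_vocabulary(rbind(feats, f3))
  expect_true("none" %in% v3$REF)
})

test_that("cross-validation bookkeeping: folds, sizes, determinism", {
  set.seed(3)
  feats <- make_separable_features(15L)
  plan <- resampling_plan(per_class = 10L, n_sets = 1L, folds = 5L,
                          repeats = 4L, seed = 5L)
  ds <- balanced_subsets(feats, plan)[[1]]
  res <- run_cv(ds, "logistic", plan)
  expect_identical(nrow(res), plan$repeats * plan$folds)
  # per-fold test counts: tp+fn = LoF test count, tn+fp = GoF test count
  expect_true(all(res$tp + res$fn == 2L))
  expect_true(all(res$tn + res$fp == 2L))
  res2 <- run_cv(ds, "logistic", plan)
  expect_identical(res, res2)
})

test_that("perfectly separable features are classified perfectly", {
  set.seed(4)
  feats <- make_separable_features(20L)
  plan <- resampling_plan(per_class = 10L, n_sets = 2L, folds = 5L,
                          repeats = 2L, seed = 7L)
  out <- run_experiment(feats, plan)
  expect_identical(nrow(out$aggregates), 3L)
  expect_equal(out$aggregates$accuracy, rep(1, 3))
  expect_equal(out$aggregates$auc, rep(1, 3))
  expect_identical(unique(out$aggregates$n_fold_results),
                   plan$n_sets * plan$repeats * plan$folds)
})

test_that("permuted labels give chance-level accuracy", {
  set.seed(6)
  feats <- make_separable_features(40L)
  feats$Class <- sample(feats$Class) # break any signal
  plan <- resampling_plan(per_class = 20L, n_sets = 2L, folds = 5L,
                          repeats = 50L, seed = 11L)
  out <- run_experiment(feats, plan, classifiers = "logistic")
  acc <- out$aggregates$accuracy
  expect_gt(acc, 0.40)
  expect_lt(acc, 0.60)
})

test_that("metric aggregation and rank AUC behave on known inputs", {
  one <- data.frame(dataset_index = 1L, repeat_index = 1L, fold_index = 1L,
                    classifier = "logistic", tp = 10, fn = 10, tn = 10,
                    fp = 10, auc = 0.5, stringsAsFactors = FALSE)
  m <- aggregate_metrics(one)
  expect_equal(m$accuracy, 0.5)
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$specificity, 0.5)
  expect_error(aggregate_metrics(one[0, ]), "no fold results")

  # perfect ordering -> AUC 1; ties count half
  expect_equal(lofgof:::.rank_auc(c(1, 2, 3, 4),
                                  c("GoF", "GoF", "LoF", "LoF")), 1)
  expect_equal(lofgof:::.rank_auc(c(1, 1, 1, 1),
                                  c("GoF", "GoF", "LoF", "LoF")), 0.5)
  # label-independent random scores stay near 0.5
  set.seed(8)
  aucs <- replicate(500, lofgof:::.rank_auc(rnorm(40),
                                            rep(c("LoF", "GoF"), 20)))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("balanced folds satisfy accuracy = (sensitivity+specificity)/2", {
  set.seed(10)
  feats <- make_separable_features(30L)
  feats$SCORE <- rnorm(nrow(feats), ifelse(feats$Class == "LoF", 0.5, -0.5))
  feats$SL <- sample(feats$SL)  # weaken so folds make mistakes
  plan <- resampling_plan(per_class = 10L, n_sets = 1L, folds = 5L,
                          repeats = 10L, seed = 13L)
  ds <- balanced_subsets(feats, plan)[[1]]
  res <- run_cv(ds, "logistic", plan)
  acc <- (res$tp + res$tn) / (res$tp + res$tn + res$fp + res$fn)
  sens <- res$tp / (res$tp + res$fn)
  spec <- res$tn / (res$tn + res$fp)
  expect_equal(acc, (sens + spec) / 2, tolerance = 1e-12)
})

test_that("logistic results are invariant to training-row order", {
  set.seed(12)
  n <- 60L
  feats <- data.frame(
    REF = sample(c("A", "C", "G", "T"), n, TRUE),
    SUB = sample(c("A", "C", "G", "T"), n, TRUE),
    TYPE = sample(c("missense", "nonsense"), n, TRUE),
    SCORE = rnorm(n), GRADE = NA_character_,
    SL = sample(c("Nucleus", "Cytoplasm"), n, TRUE),
    PD = sample(c("Kinase", "none"), n, TRUE),
    Class = sample(c("LoF", "GoF"), n, TRUE),
    stringsAsFactors = FALSE
  )
  x <- one_hot_encode(feats)
  y <- feats$Class
  perm <- sample(nrow(x))
  a <- lofgof:::.fit_predict("logistic", x, y, x[1:11, ], seed = 1L)
  b <- lofgof:::.fit_predict("logistic", x[perm, ], y[perm], x[1:11, ],
                             seed = 1L)
  expect_equal(a$score, b$score, tolerance = 1e-8)
  # but flipping the test labels does change the confusion counts
  yte <- y[1:11] # odd count, so accuracy cannot sit at 1/2
  flipped <- ifelse(yte == "LoF", "GoF", "LoF")
  expect_false(mean(a$pred == yte) == mean(a$pred == flipped))
})

test_that("svm and random forest expose usable decision scores", {
  set.seed(14)
  feats <- make_separable_features(20L)
  x <- one_hot_encode(feats)
  y <- feats$Class
  for (cl in c("svm", "random_forest")) {
    fp <- lofgof:::.fit_predict(cl, x, y, x, seed = 2L)
    expect_length(fp$score, nrow(x))
    # higher score must mean more LoF-like
    expect_gt(mean(fp$score[y == "LoF"]), mean(fp$score[y == "GoF"]))
    expect_equal(lofgof:::.rank_auc(fp$score, y), 1)
  }
})
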