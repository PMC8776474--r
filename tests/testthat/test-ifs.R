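test_that("stratified folds partition every sample exactly once", {
  lab <- factor(rep(c("negative", "positive"), each = 10))
  cv <- cv_config(n_folds = 10, seed = 3)
  fold <- m5Cselect:::make_folds(lab, cv)
  expect_equal(sort(unique(fold)), 1:10)
  expect_true(all(table(fold) == 2))               # 1 per class per fold
  expect_true(all(table(fold, lab) == 1))
  # n = n_folds with balanced classes: leave-one-out-like folds of size 1
  lab5 <- factor(rep(c("negative", "positive"), each = 5))
  fold5 <- m5Cselect:::make_folds(lab5, cv_config(n_folds = 10, seed = 1))
  expect_equal(as.vector(table(fold5)), rep(1L, 10))
})

test_that("fold construction rejects impossible configurations", {
  lab <- factor(rep(c("negative", "positive"), c(1, 19)))
  expect_error(m5Cselect:::make_folds(lab, cv_config(n_folds = 10)),
               "smallest class")
  lab2 <- factor(rep(c("negative", "positive"), c(3, 17)))
  expect_error(m5Cselect:::make_folds(lab2, cv_config(n_folds = 25)),
               "n_folds")
  # a small class is spread over folds, so every training fold sees it
  fold <- m5Cselect:::make_folds(lab2, cv_config(n_folds = 10, seed = 2))
  expect_gte(length(unique(fold[lab2 == "negative"])), 2L)
})

test_that("a label-identical feature is perfectly recovered by 1-NN", {
  lab <- rep(c("positive", "negative"), each = 10)
  x <- matrix(as.numeric(lab == "positive"), ncol = 1)
  fm <- toy_feature_matrix(x, lab)
  counts <- cross_validate(fm, spec = classifier_spec("knn", k = 1),
                           cv = cv_config(n_folds = 5, seed = 42))
  expect_equal(counts$FP, 0)
  expect_equal(counts$FN, 0)
  expect_equal(counts$TP + counts$TN, 20)
})

test_that("all four classifier families run and pool counts over every sample", {
  set.seed(8)
  n <- 40
  lab <- rep(c("positive", "negative"), each = n / 2)
  x <- cbind(rnorm(n, mean = ifelse(lab == "positive", 2, -2)), rnorm(n))
  fm <- toy_feature_matrix(x, lab)
  for (family in c("decision_tree", "knn", "random_forest", "svm")) {
    counts <- cross_validate(fm, spec = classifier_spec(family),
                             cv = cv_config(n_folds = 5, seed = 7))
    expect_equal(counts$TP + counts$TN + counts$FP + counts$FN, n)
    expect_gt(compute_metrics(counts)[["MCC"]], 0.5)  # trivially separable
  }
})

test_that("label-independent features give near-zero pooled MCC", {
  set.seed(21)
  mccs <- replicate(20, {
    n <- 200
    lab <- rep(c("positive", "negative"), each = n / 2)
    fm <- toy_feature_matrix(matrix(rnorm(n * 3), n, 3), lab)
    counts <- cross_validate(fm, spec = classifier_spec("knn"),
                             cv = cv_config(n_folds = 10, seed = 5))
    compute_metrics(counts)[["MCC"]]
  })
  expect_true(all(abs(mccs) < 0.3))
})

test_that("run_ifs emits one row per prefix and valid metric ranges", {
  set.seed(10)
  n <- 30
  lab <- rep(c("positive", "negative"), each = n / 2)
  x <- cbind(as.numeric(lab == "positive") + rnorm(n, sd = 0.05),
             matrix(rnorm(n * 4), n, 4))
  fm <- toy_feature_matrix(x, lab)
  r <- mrmr_rank(fm)
  res <- run_ifs(fm, r, classifier_spec("knn", k = 1),
                 cv_config(n_folds = 5, seed = 2))
  expect_equal(nrow(res), 5L)
  expect_equal(res$n_features, 1:5)
  expect_true(all(res$SN >= 0 & res$SN <= 1))
  expect_true(all(res$MCC >= -1 & res$MCC <= 1))
  # the near-perfect feature is ranked first: MCC ties break to smallest prefix
  expect_equal(res$MCC[1], 1)
  expect_equal(attr(res, "optimum_size"), 1L)
})

test_that("IFS is deterministic given the cv seed (random forest included)", {
  set.seed(12)
  n <- 30
  lab <- rep(c("positive", "negative"), each = n / 2)
  x <- matrix(rnorm(n * 4), n, 4)
  x[, 1] <- x[, 1] + ifelse(lab == "positive", 1.5, 0)
  fm <- toy_feature_matrix(x, lab)
  r <- mrmr_rank(fm)
  for (family in c("decision_tree", "knn", "svm", "random_forest")) {
    a <- run_ifs(fm, r, classifier_spec(family), cv_config(n_folds = 5, seed = 9))
    b <- run_ifs(fm, r, classifier_spec(family), cv_config(n_folds = 5, seed = 9))
    expect_identical(as.data.frame(a), as.data.frame(b))
  }
})

test_that("a constant feature ranked last leaves smaller prefixes untouched", {
  set.seed(14)
  n <- 24
  lab <- rep(c("positive", "negative"), each = n / 2)
  x <- matrix(rnorm(n * 3), n, 3)
  x[, 1] <- x[, 1] + ifelse(lab == "positive", 2, 0)
  fm3 <- toy_feature_matrix(x, lab)
  fm4 <- toy_feature_matrix(cbind(x, 1), lab)
  r3 <- mrmr_rank(fm3)
  r4 <- data.frame(feature = c(r3$feature, 4L))   # constant appended last
  res3 <- run_ifs(fm3, r3, classifier_spec("knn"), cv_config(n_folds = 4, seed = 1))
  res4 <- run_ifs(fm4, r4, classifier_spec("knn"), cv_config(n_folds = 4, seed = 1))
  expect_equal(as.data.frame(res3)[1:3, ], as.data.frame(res4)[1:3, ])
})

test_that("run_ifs validates the ranking and max_size", {
  lab <- rep(c("positive", "negative"), each = 5)
  fm <- toy_feature_matrix(matrix(rnorm(20), 10, 2), lab)
  bad <- data.frame(feature = c(1L, 3L))
  expect_error(run_ifs(fm, bad, classifier_spec("knn"), cv_config(n_folds = 2)),
               "validation")
  r <- mrmr_rank(fm)
  expect_error(run_ifs(fm, r, classifier_spec("knn"), cv_config(n_folds = 2),
                       max_size = 5), "max_size")
})

test_that("IFS TSV output mirrors the declared column order", {
  lab <- rep(c("positive", "negative"), each = 6)
  fm <- toy_feature_matrix(matrix(rnorm(24), 12, 2), lab)
  res <- run_ifs(fm, mrmr_rank(fm), classifier_spec("decision_tree"),
                 cv_config(n_folds = 3, seed = 1))
  path <- tempfile(); opt <- tempfile()
  write_ifs_table(res, path, optimum_path = opt)
  got <- read.delim(path)
  expect_equal(names(got), c("classifier", "n_features", "SN", "SP", "ACC",
                             "MCC", "precision", "F1"))
  expect_equal(nrow(read.delim(opt)), 1L)
})
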