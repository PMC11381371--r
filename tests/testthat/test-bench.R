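# Supervised-learning harness: splitting, oversampling, tuning,
# fitting, evaluation.

make_blobs <- function(n_pos = 20, n_neg = 40, sep = 3, p = 4, seed = 5) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_neg * p), ncol = p),
               matrix(rnorm(n_pos * p, mean = sep), ncol = p))
    d <- as.data.frame(x)
    d$class <- c(rep("none", n_neg), rep("severe_extreme", n_pos))
    d[sample(nrow(d)), ]
  })
}

test_that("train/test split is stratified, exhaustive and seed-reproducible", {
  d <- data.frame(x = 1:10, class = rep("a", 10))
  sp <- split_train_test(d, 0.7, seed = 3)
  expect_equal(nrow(sp$train), 7)
  expect_equal(nrow(sp$test), 3)
  expect_setequal(c(sp$train$x, sp$test$x), 1:10)

  sp2 <- split_train_test(d, 0.7, seed = 3)
  expect_identical(sp$train$x, sp2$train$x)

  # 80:20 class ratio in 100 rows: both partitions within one row of 80:20
  d2 <- data.frame(x = 1:100, class = rep(c("a", "b"), c(80, 20)))
  sp3 <- split_train_test(d2, 0.7, seed = 11)
  expect_equal(sum(sp3$train$class == "a"), 56)
  expect_equal(sum(sp3$train$class == "b"), 14)
  expect_equal(sum(sp3$test$class == "b"), 6)
})

test_that("oversampling balances counts by duplicating existing rows only", {
  d <- data.frame(x = 1:13, class = rep(c("A", "B"), c(10, 3)))
  b <- oversample_minority(d, seed = 7)
  expect_equal(as.vector(table(b$class)), c(10, 10))
  # every synthetic row is an exact copy of an original minority row
  expect_true(all(b$x[b$class == "B"] %in% d$x[d$class == "B"]))
  # already balanced -> unchanged
  d2 <- data.frame(x = 1:6, class = rep(c("A", "B"), 3))
  expect_identical(oversample_minority(d2, seed = 7), d2)
})

test_that("grids respect the stated hyperparameter ranges", {
  p <- 12
  g <- default_grid("elastic_linear", p)
  expect_true(all(g$alpha %in% c(0, 1)))
  expect_true(all(g$lambda >= 0.001 & g$lambda <= 1))
  expect_true(all(default_grid("knn", p)$k == 1:15))
  expect_true(all(default_grid("cart", p)$cp >= 0.001 &
                    default_grid("cart", p)$cp <= 0.1))
  expect_true(all(default_grid("random_forest", p)$mtry >= 1 &
                    default_grid("random_forest", p)$mtry <= p))
  ga <- default_grid("ann", p)
  expect_true(all(ga$size %in% c(0, 3:50)))
  gaf <- default_grid("ann", p, full_grid = TRUE)
  expect_gt(nrow(gaf), nrow(ga))
  expect_error(default_grid("boost", p), "unknown model family")
})

test_that("every family fits, scores in [0,1], and is seed-deterministic", {
  d <- make_blobs()
  sp <- split_train_test(d, 0.7, seed = 2)
  for (fam in bench_families()) {
    params <- default_params(fam, 4)
    s1 <- fit_predict(fam, params, sp$train, sp$test, seed = 9)
    s2 <- fit_predict(fam, params, sp$train, sp$test, seed = 9)
    expect_equal(s1, s2, info = fam)
    expect_true(all(s1 >= 0 & s1 <= 1), info = fam)
    expect_gt(auc_score(s1, sp$test$class), 0.9) # cleanly separable blobs
  }
})

test_that("degenerate fits are refused or give chance-level scores", {
  d <- make_blobs()
  single <- d[d$class == "none", ]
  expect_error(fit_predict("knn", list(k = 3), single, d), "single class")
  # constant features -> constant scores -> AUC 0.5
  dc <- d
  dc[, 1:4] <- 1
  s <- fit_predict("sda", list(diagonal = TRUE, lambda = 0.5), dc, dc)
  expect_equal(auc_score(s, dc$class), 0.5)
})

test_that("knn with k = 1 attains perfect training recall", {
  d <- make_blobs(sep = 1.2)
  s <- fit_predict("knn", list(k = 1), d, d)
  ev <- evaluate_scores(s, d$class)
  expect_equal(ev$recall, 1)
  expect_equal(ev$fn, 0)
})

test_that("evaluation metrics match hand-computed confusion and AUC values", {
  # TP=2 FP=1 FN=1 -> precision = recall = F1 = 2/3
  scores <- c(0.9, 0.8, 0.6, 0.3, 0.2)
  labels <- c("severe_extreme", "severe_extreme", "none", "severe_extreme",
              "none")
  ev <- evaluate_scores(scores, labels)
  expect_equal(ev$tp, 2); expect_equal(ev$fp, 1); expect_equal(ev$fn, 1)
  expect_equal(ev$precision, 2 / 3)
  expect_equal(ev$recall, 2 / 3)
  expect_equal(ev$f1, 2 / 3)
  # exhaustive pair enumeration: 3 of 4 pairs concordant
  expect_equal(auc_score(c(0.1, 0.4, 0.35, 0.8), c("a", "a", "b", "b"),
                         positive = "b"), 0.75)
  expect_equal(auc_score(c(0, 0, 1, 1), c("a", "a", "b", "b"),
                         positive = "b"), 1)
  # cross-check against an independent ROC implementation
  set.seed(17)
  sc <- runif(60); lab <- sample(c("a", "b"), 60, replace = TRUE)
  expect_equal(auc_score(sc, lab, positive = "b"),
               as.numeric(pROC::auc(pROC::roc(lab, sc, levels = c("a", "b"),
                                              direction = "<", quiet = TRUE))))
})

test_that("macro one-vs-rest AUC averages the per-class binary AUCs", {
  set.seed(29)
  lab <- sample(c("none", "mild_moderate", "severe_extreme"), 60,
                replace = TRUE)
  sc <- matrix(runif(180), ncol = 3,
               dimnames = list(NULL, c("none", "mild_moderate",
                                       "severe_extreme")))
  manual <- mean(vapply(colnames(sc), function(cl)
    auc_score(sc[, cl], ifelse(lab == cl, cl, "o"), positive = cl), 0))
  expect_equal(macro_auc_ovr(sc, lab), manual)
  # a perfect one-hot scorer reaches 1
  hot <- matrix(0, 60, 3, dimnames = dimnames(sc))
  hot[cbind(seq_len(60), match(lab, colnames(sc)))] <- 1
  expect_equal(macro_auc_ovr(hot, lab), 1)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(23)
  sc <- rnorm(50); lab <- rep(c("none", "severe_extreme"), 25)
  a0 <- auc_score(sc, lab)
  expect_equal(auc_score(plogis(3 * sc + 1), lab), a0)
  expect_equal(auc_score(rank(sc), lab), a0)
})

test_that("fold deviation is the relative spread of fold AUCs", {
  expect_equal(fold_deviation(c(0.7, 0.7, 0.7)), 0)
  expect_equal(fold_deviation(c(0.70, 0.70, 0.72)),
               100 * 0.02 / mean(c(0.70, 0.70, 0.72)))
  set.seed(2)
  expect_true(fold_deviation(runif(15, 0.5, 0.9)) >= 0)
})

test_that("tuning returns the single grid point, is deterministic, and finds
           small-k KNN on separable data", {
  d <- make_blobs(n_pos = 18, n_neg = 30, sep = 4)
  cfg <- pipeline_config(seed = 5)
  one <- tune_model("cart", d, cfg, grid = data.frame(cp = 0.05))
  expect_equal(one$best_params$cp, 0.05)

  t1 <- tune_model("knn", d, cfg, grid = data.frame(k = c(1, 3, 5)))
  t2 <- tune_model("knn", d, cfg, grid = data.frame(k = c(1, 3, 5)))
  expect_identical(t1$best_params, t2$best_params)
  expect_gt(t1$cv_auc, 0.95) # linearly separable -> CV AUC near 1
})

test_that("the full benchmark reports all families without leakage", {
  d <- make_blobs(n_pos = 15, n_neg = 35, sep = 2.5)
  cfg <- pipeline_config(seed = 4, cv_repeats = 2)
  out <- benchmark_models(d, cfg, families = c("sda", "cart"),
                          tune = TRUE)
  expect_equal(out$report$family, c("sda", "cart"))
  expect_true(all(out$report$auc >= 0 & out$report$auc <= 1))
  expect_true(out$leakage_ok)
  expect_equal(out$n_train + out$n_test, 50)
  # F1 is the harmonic mean of the reported precision and recall
  with(out$report[1, ], expect_equal(f1, 2 * precision * recall /
                                       (precision + recall)))
})
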