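# Supervised-learning harness: stratified split, minority oversampling,
# grid tuning via repeated cross-validation, six model families, and
# held-out AUC / precision / recall / F1 reporting.
#
# Model fits delegate to glmnet, rpart, randomForest, nnet and class::knn;
# the harness itself (fold assignment, per-fold oversampling, tie-breaking,
# seed substreams) is implemented here so its semantics are exact.

#' @name model_families
#' @title The six benchmarked model families
#' @description `bench_families()` returns the family tags:
#' elastic-net logistic regression (`elastic_linear`), shrinkage
#' discriminant analysis (`sda`), k-nearest neighbour (`knn`), CART
#' (`cart`), random forest (`random_forest`) and a single-hidden-layer
#' feed-forward network (`ann`).
#' @return Character vector of family tags.
#' @export
bench_families <- function() {
  c("elastic_linear", "sda", "knn", "cart", "random_forest", "ann")
}

#' Default tuning grid for a model family
#'
#' Grids cover the standard ranges: elastic net alpha in \{0, 1\} with
#' lambda in \[0.001, 1\]; SDA diagonal in \{TRUE, FALSE\} with shrinkage
#' lambda in \[0.001, 1\]; KNN k in 1..15; CART complexity in
#' \[0.001, 0.1\]; random-forest mtry in 1..p; ANN hidden layers \{0, 1\}
#' with a documented desk-scale neuron/decay subset (`full_grid = TRUE`
#' widens the ANN axes to neurons up to 50 and finer decay). Rows are
#' ordered simpler-first so tuning ties resolve toward the simpler model
#' (smaller k, larger complexity penalty, fewer neurons, stronger
#' shrinkage).
#'
#' @param family one of [bench_families()].
#' @param p number of predictors (bounds the random-forest grid).
#' @param full_grid widen the ANN grid to the full stated ranges.
#' @return data.frame of hyperparameter combinations, preference-ordered.
#' @export
default_grid <- function(family, p, full_grid = FALSE) {
  switch(family,
    elastic_linear = {
      g <- expand.grid(lambda = c(1, 0.1, 0.01, 0.001), alpha = c(0, 1))
      g[, c("alpha", "lambda")]
    },
    sda = expand.grid(lambda = c(1, 0.5, 0.1, 0.01, 0.001),
                      diagonal = c(TRUE, FALSE))[, c("diagonal", "lambda")],
    knn = data.frame(k = 1:15),
    cart = data.frame(cp = c(0.1, 0.05, 0.01, 0.005, 0.001)),
    random_forest = data.frame(mtry = unique(pmin(p, c(1, 2, 3, 5, 8, p)))),
    ann = {
      sizes <- if (full_grid) c(0, 3, 5, 10, 15, 25, 35, 50) else c(0, 3, 10, 25)
      decays <- if (full_grid) c(0.1, 0.01, 0.001, 1e-4, 1e-5) else
        c(0.1, 0.01, 1e-4)
      expand.grid(size = sizes, decay = decays)[, c("size", "decay")]
    },
    stop("unknown model family: ", family, call. = FALSE)
  )
}

#' Fixed default hyperparameters per family
#'
#' A single sensible grid point per family, used where tuning is not
#' wanted (e.g. permutation-null checks).
#'
#' @inheritParams default_grid
#' @return One-row data.frame of hyperparameters.
#' @export
default_params <- function(family, p) {
  switch(family,
    elastic_linear = data.frame(alpha = 0, lambda = 0.01),
    sda = data.frame(diagonal = TRUE, lambda = 0.1),
    knn = data.frame(k = 5),
    cart = data.frame(cp = 0.01),
    random_forest = data.frame(mtry = max(1, floor(sqrt(p)))),
    ann = data.frame(size = 3, decay = 0.01),
    stop("unknown model family: ", family, call. = FALSE)
  )
}

#' Stratified train/test split
#'
#' Disjoint, exhaustive, stratified by class and reproducible by seed:
#' each class contributes `round(fraction * n_class)` rows to the training
#' partition.
#'
#' @param data data.frame including `label_col`.
#' @param fraction training fraction.
#' @param seed integer seed.
#' @param label_col name of the class column.
#' @return list `train`, `test`.
#' @export
split_train_test <- function(data, fraction = 0.7, seed = 1L,
                             label_col = "class") {
  stopifnot(label_col %in% names(data))
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0,1)",
                                           call. = FALSE)
  idx_train <- integer(0)
  with_seed(seed, {
    for (cl in unique(data[[label_col]])) {
      rows <- which(data[[label_col]] == cl)
      n_tr <- round(fraction * length(rows))
      idx_train <- c(idx_train, sample(rows, n_tr))
    }
  })
  idx_train <- sort(idx_train)
  list(train = data[idx_train, , drop = FALSE],
       test = data[setdiff(seq_len(nrow(data)), idx_train), , drop = FALSE])
}

#' Random oversampling of minority classes
#'
#' Minority classes are resampled (duplication of existing rows, with
#' replacement) until every class count equals the majority count.
#' Intended for training data / training folds only.
#'
#' @inheritParams split_train_test
#' @return The balanced data.frame (original rows first, duplicates
#'   appended).
#' @export
oversample_minority <- function(data, seed = 1L, label_col = "class") {
  counts <- table(data[[label_col]])
  target <- max(counts)
  extra <- integer(0)
  with_seed(seed, {
    for (cl in names(counts)) {
      deficit <- target - counts[[cl]]
      if (deficit > 0) {
        rows <- which(data[[label_col]] == cl)
        extra <- c(extra, sample(rows, deficit, replace = TRUE))
      }
    }
  })
  rbind(data, data[extra, , drop = FALSE])
}

feature_matrix <- function(data, label_col) {
  num <- vapply(data, is.numeric, TRUE)
  num[label_col] <- FALSE
  num[names(num) == ".row_id"] <- FALSE
  as.matrix(data[, num, drop = FALSE])
}

encode_labels <- function(labels, positive) {
  factor(ifelse(labels == positive, "pos", "neg"), levels = c("neg", "pos"))
}

scale_by_train <- function(xtr, xte) {
  mu <- colMeans(xtr)
  sd <- apply(xtr, 2, stats::sd)
  sd[sd == 0 | is.na(sd)] <- 1
  list(train = sweep(sweep(xtr, 2, mu), 2, sd, "/"),
       test = sweep(sweep(xte, 2, mu), 2, sd, "/"))
}

# Regularized (shrinkage) discriminant analysis: pooled covariance shrunk
# toward its diagonal with intensity lambda; diagonal = TRUE uses the
# purely diagonal covariance.
sda_fit_predict <- function(xtr, ytr, xte, diagonal, lambda) {
  classes <- levels(ytr)
  mus <- lapply(classes, function(cl) colMeans(xtr[ytr == cl, , drop = FALSE]))
  ns <- vapply(classes, function(cl) sum(ytr == cl), 0)
  p <- ncol(xtr)
  pool <- matrix(0, p, p)
  for (i in seq_along(classes)) {
    xi <- xtr[ytr == classes[i], , drop = FALSE]
    if (nrow(xi) > 1) pool <- pool + (nrow(xi) - 1) * stats::cov(xi)
  }
  pool <- pool / max(1, sum(ns) - length(classes))
  sigma <- if (diagonal) diag(diag(pool), p) else
    (1 - lambda) * pool + lambda * diag(diag(pool), p)
  diag(sigma) <- diag(sigma) + 1e-8 * mean(diag(pool)) + 1e-12
  si <- solve(sigma)
  priors <- ns / sum(ns)
  disc <- vapply(seq_along(classes), function(i) {
    d <- sweep(xte, 2, mus[[i]])
    -0.5 * rowSums((d %*% si) * d) + log(priors[i])
  }, numeric(nrow(xte)))
  disc <- matrix(disc, nrow = nrow(xte))
  1 / (1 + exp(disc[, 1] - disc[, 2])) # P(pos); column 2 is "pos"
}

#' Fit one model family and score a test set
#'
#' Fits the family at the given hyperparameters on the training data and
#' returns continuous positive-class scores in \[0, 1\] for the test rows.
#' Deterministic given the seed. Refuses single-class training data.
#'
#' @param family one of [bench_families()].
#' @param params one-row data.frame / named list of hyperparameters (see
#'   [default_grid()]).
#' @param train,test data.frames with numeric features plus `label_col`
#'   (ignored if absent from `test`).
#' @param seed integer seed for stochastic fits (forest, network, knn
#'   tie-breaks).
#' @param label_col class column name.
#' @param positive positive class label (severe stress by convention).
#' @return Numeric vector of scores, one per test row.
#' @export
fit_predict <- function(family, params, train, test, seed = 1L,
                        label_col = "class", positive = "severe_extreme") {
  params <- as.list(params)
  ytr <- encode_labels(train[[label_col]], positive)
  if (length(unique(ytr)) < 2) {
    stop("training data contain a single class; cannot fit a classifier",
         call. = FALSE)
  }
  xtr <- feature_matrix(train, label_col)
  xte <- feature_matrix(test, label_col)[, colnames(xtr), drop = FALSE]
  with_seed(seed, {
    switch(family,
      elastic_linear = {
        fit <- glmnet::glmnet(xtr, ytr, family = "binomial",
                              alpha = params$alpha,
                              lambda = c(params$lambda * 2, params$lambda))
        as.numeric(stats::predict(fit, xte, s = params$lambda,
                                  type = "response"))
      },
      sda = {
        sc <- scale_by_train(xtr, xte)
        sda_fit_predict(sc$train, ytr, sc$test,
                        diagonal = isTRUE(params$diagonal),
                        lambda = params$lambda)
      },
      knn = {
        sc <- scale_by_train(xtr, xte)
        pred <- class::knn(sc$train, sc$test, ytr, k = params$k, prob = TRUE)
        pr <- attr(pred, "prob")
        ifelse(pred == "pos", pr, 1 - pr)
      },
      cart = {
        df <- data.frame(xtr, .y = ytr, check.names = FALSE)
        fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                            control = rpart::rpart.control(cp = params$cp,
                                                           xval = 0))
        stats::predict(fit, data.frame(xte, check.names = FALSE),
                       type = "prob")[, "pos"]
      },
      random_forest = {
        fit <- randomForest::randomForest(x = xtr, y = ytr,
                                          mtry = params$mtry, ntree = 300)
        stats::predict(fit, xte, type = "prob")[, "pos"]
      },
      ann = {
        sc <- scale_by_train(xtr, xte)
        df <- data.frame(sc$train, .y = ytr, check.names = FALSE)
        fit <- nnet::nnet(.y ~ ., data = df, size = params$size,
                          decay = params$decay, skip = params$size == 0,
                          maxit = 200, trace = FALSE, MaxNWts = 5000)
        as.numeric(stats::predict(fit, data.frame(sc$test, check.names = FALSE),
                                  type = "raw"))
      },
      stop("unknown model family: ", family, call. = FALSE)
    )
  })
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney rank statistic:
#' the probability that a random positive outranks a random negative, with
#' ties counted half.
#'
#' @param scores numeric classifier scores.
#' @param labels class labels.
#' @param positive positive class label.
#' @return AUC in \[0, 1\] (`NA` if a class is absent).
#' @export
auc_score <- function(scores, labels, positive = "severe_extreme") {
  pos <- labels == positive
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' Macro one-vs-rest AUC for multiclass scores
#'
#' For a matrix of per-class scores, averages the binary rank AUC of each
#' class against the rest. This is the convention used when a multiclass
#' outcome (e.g. the three-class severity scheme) is evaluated.
#'
#' @param scores numeric matrix, one column per class (named by class).
#' @param labels class labels.
#' @return Mean of the per-class one-vs-rest AUCs.
#' @export
macro_auc_ovr <- function(scores, labels) {
  stopifnot(is.matrix(scores), !is.null(colnames(scores)))
  per_class <- vapply(colnames(scores), function(cl) {
    auc_score(scores[, cl], ifelse(labels == cl, cl, "rest"), positive = cl)
  }, 0)
  mean(per_class, na.rm = TRUE)
}

#' Held-out evaluation metrics
#'
#' AUC (rank statistic) plus precision, recall and F1 at the stated
#' probability threshold, positive class = severe stress by convention.
#'
#' @param scores numeric scores in \[0, 1\].
#' @param labels class labels.
#' @param threshold classification threshold for the confusion matrix.
#' @param positive positive class label.
#' @return One-row data.frame `precision, recall, f1, auc, tp, fp, fn, tn`.
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5,
                            positive = "severe_extreme") {
  stopifnot(length(scores) == length(labels))
  pos <- labels == positive
  pred <- scores >= threshold
  tp <- sum(pred & pos); fp <- sum(pred & !pos)
  fn <- sum(!pred & pos); tn <- sum(!pred & !pos)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  data.frame(precision = precision, recall = recall, f1 = f1,
             auc = auc_score(scores, labels, positive),
             tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Fold-to-fold deviation
#'
#' Relative spread of fold AUCs, `100 * (max - min) / mean`, in percent.
#'
#' @param aucs numeric vector of per-fold AUCs.
#' @return Percentage spread (0 for identical folds).
#' @export
fold_deviation <- function(aucs) {
  aucs <- aucs[!is.na(aucs)]
  if (length(aucs) == 0 || mean(aucs) == 0) return(NA_real_)
  100 * (max(aucs) - min(aucs)) / mean(aucs)
}

stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      rows <- which(labels == cl)
      fold[rows] <- sample(rep_len(seq_len(k), length(rows)))
    }
  })
  fold
}

#' Grid-tune one model family by repeated cross-validation
#'
#' Every grid combination is evaluated by k-fold cross-validation repeated
#' r times (3 x 5 by default); minority oversampling is re-applied inside
#' each training fold so validation folds are never resampled. The best
#' combination maximizes mean CV AUC; ties resolve to the earlier
#' (simpler) grid row.
#'
#' @param family one of [bench_families()].
#' @param train training data.frame.
#' @param config a [pipeline_config()] (folds, repeats, master seed).
#' @param grid optional grid override (data.frame, preference-ordered).
#' @param label_col,positive as in [fit_predict()].
#' @return list `family, best_params, cv_auc, fold_aucs,
#'   fold_deviation_pct, cv_table`.
#' @export
tune_model <- function(family, train, config = pipeline_config(),
                       grid = NULL, label_col = "class",
                       positive = "severe_extreme") {
  if (is.null(grid)) {
    grid <- config$grids[[family]] %||%
      default_grid(family, ncol(feature_matrix(train, label_col)))
  }
  k <- config$cv_folds
  reps <- config$cv_repeats
  seed <- config$seed
  labels <- train[[label_col]]
  n_grid <- nrow(grid)
  auc_mat <- matrix(NA_real_, nrow = n_grid, ncol = k * reps)
  col <- 0L
  for (r in seq_len(reps)) {
    fold <- stratified_folds(labels, k, derive_seed(seed, paste0("folds", r)))
    for (f in seq_len(k)) {
      col <- col + 1L
      tr <- train[fold != f, , drop = FALSE]
      va <- train[fold == f, , drop = FALSE]
      tr_bal <- oversample_minority(
        tr, derive_seed(seed, paste0("over", r, "_", f)), label_col)
      for (gi in seq_len(n_grid)) {
        scores <- try(fit_predict(
          family, grid[gi, , drop = FALSE], tr_bal, va,
          seed = derive_seed(seed, paste(family, gi, r, f)),
          label_col = label_col, positive = positive), silent = TRUE)
        if (!inherits(scores, "try-error")) {
          auc_mat[gi, col] <- auc_score(scores, va[[label_col]], positive)
        }
      }
    }
  }
  mean_auc <- rowMeans(auc_mat, na.rm = TRUE)
  best <- which(mean_auc >= max(mean_auc, na.rm = TRUE) - 1e-12)[1L]
  fold_aucs <- auc_mat[best, ]
  list(
    family = family,
    best_params = grid[best, , drop = FALSE],
    cv_auc = mean_auc[best],
    fold_aucs = fold_aucs,
    fold_deviation_pct = fold_deviation(fold_aucs),
    cv_table = cbind(grid, mean_cv_auc = mean_auc)
  )
}

#' Benchmark the six model families
#'
#' Full harness: stratified 70/30 split, per-family grid tuning on the
#' training partition (oversampling inside each CV training fold), a final
#' fit on the oversampled training partition, and held-out evaluation. A
#' row-identity audit verifies that no held-out row was touched by
#' oversampling or tuning.
#'
#' @param data data.frame of numeric features plus a class column; rows
#'   with missing features or `excluded` class are dropped (counted).
#' @param config a [pipeline_config()].
#' @param families subset of [bench_families()].
#' @param tune grid-tune each family (`FALSE` uses [default_params()]).
#' @param label_col,positive as in [fit_predict()].
#' @return list with `report` (one row per family: precision, recall, F1,
#'   AUC, CV AUC, fold deviation), `details` (per-family tuning output),
#'   `leakage_ok`, `n_train`, `n_test`, `n_dropped`.
#' @export
benchmark_models <- function(data, config = pipeline_config(),
                             families = bench_families(), tune = TRUE,
                             label_col = "class",
                             positive = "severe_extreme") {
  keep <- stats::complete.cases(data) & data[[label_col]] != "excluded"
  n_dropped <- sum(!keep)
  data <- data[keep, , drop = FALSE]
  data$.row_id <- seq_len(nrow(data))
  sp <- split_train_test(data, config$split_fraction,
                         derive_seed(config$seed, "split"), label_col)
  train <- sp$train; test <- sp$test
  details <- list()
  rows <- list()
  for (family in families) {
    if (tune) {
      tuned <- tune_model(family, train, config, label_col = label_col,
                          positive = positive)
    } else {
      tuned <- list(family = family,
                    best_params = default_params(
                      family, ncol(feature_matrix(train, label_col))),
                    cv_auc = NA_real_, fold_aucs = NA_real_,
                    fold_deviation_pct = NA_real_)
    }
    train_bal <- oversample_minority(
      train, derive_seed(config$seed, paste0("over_final_", family)),
      label_col)
    scores <- fit_predict(family, tuned$best_params, train_bal, test,
                          seed = derive_seed(config$seed, paste0("fit_", family)),
                          label_col = label_col, positive = positive)
    ev <- evaluate_scores(scores, test[[label_col]], config$threshold,
                          positive)
    rows[[family]] <- data.frame(
      family = family,
      precision = ev$precision, recall = ev$recall, f1 = ev$f1,
      auc = ev$auc, cv_auc = tuned$cv_auc,
      fold_deviation_pct = tuned$fold_deviation_pct,
      params = paste(names(tuned$best_params),
                     unlist(lapply(tuned$best_params, format)),
                     sep = "=", collapse = ","),
      stringsAsFactors = FALSE
    )
    tuned$scores <- scores
    tuned$train_bal_row_ids <- train_bal$.row_id
    details[[family]] <- tuned
  }
  leakage_ok <- all(vapply(details, function(d)
    length(intersect(d$train_bal_row_ids, test$.row_id)) == 0, TRUE)) &&
    length(intersect(train$.row_id, test$.row_id)) == 0
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  list(report = report, details = details, leakage_ok = leakage_ok,
       n_train = nrow(train), n_test = nrow(test), n_dropped = n_dropped)
}
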