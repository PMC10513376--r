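test_that("balanced_bootstrap equalizes class counts", {
  y <- factor(rep(c("A", "B"), c(100, 10)))
  idx <- balanced_bootstrap(y, seed = 1)
  expect_length(idx, 20)
  expect_equal(as.vector(table(y[idx])), c(10, 10))

  y2 <- factor(rep(c("A", "B"), c(10, 10)))
  idx2 <- balanced_bootstrap(y2, seed = 2)
  expect_length(idx2, 20)
  expect_equal(as.vector(table(y2[idx2])), c(10, 10))

  y3 <- factor(rep(c("A", "B", "C"), c(50, 20, 5)))
  idx3 <- balanced_bootstrap(y3, seed = 3)
  expect_length(idx3, 15)
  expect_equal(as.vector(table(y3[idx3])), c(5, 5, 5))

  y4 <- factor(rep("A", 10), levels = c("A", "B"))
  expect_error(balanced_bootstrap(y4), "B")
})

make_separable <- function(n = 300, seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("A", "B"), length.out = n))
  X <- cbind(s1 = rnorm(n) + ifelse(y == "A", 3, -3),
             s2 = rnorm(n), s3 = runif(n))
  list(X = X, y = y)
}

test_that("brf_fit learns separable data and is seed-deterministic", {
  d <- make_separable()
  m <- brf_fit(d$X, d$y, forest_config(n_trees = 50, random_seed = 7))
  pred <- predict(m, d$X)
  expect_gte(mean(pred == d$y), 0.99)

  m2 <- brf_fit(d$X, d$y, forest_config(n_trees = 50, random_seed = 7))
  expect_identical(predict(m2, d$X), pred)
  expect_identical(m2$inbag, m$inbag)

  m3 <- brf_fit(d$X, d$y, forest_config(n_trees = 50, random_seed = 8))
  expect_false(identical(m3$inbag, m$inbag))

  expect_error(brf_fit(d$X, rep("A", nrow(d$X)), forest_config()),
               "single class")
})

test_that("every tree trains on exactly balanced classes (95:5 audit)", {
  set.seed(5)
  n <- 400
  y <- factor(rep(c("maj", "min"), c(380, 20)))
  X <- cbind(a = rnorm(n) + (y == "min"), b = rnorm(n))
  m <- brf_fit(X, y, forest_config(n_trees = 40, random_seed = 1))
  counts <- apply(m$inbag, 2L, function(idx) as.vector(table(y[idx])))
  expect_equal(dim(counts), c(2, 40))
  expect_true(all(counts == 20))         # m = minority count per class
})

test_that("predict returns consistent labels and probabilities", {
  d <- make_separable(n = 100, seed = 3)
  m <- brf_fit(d$X, d$y, forest_config(n_trees = 30, random_seed = 2))
  out <- predict(m, d$X, type = "both")
  expect_equal(rowSums(out$prob), rep(1, 100))
  expect_equal(colnames(out$prob), levels(d$y))
  # argmax consistency
  expect_equal(as.character(out$class),
               colnames(out$prob)[max.col(out$prob, ties.method = "first")])
  # when all trees agree the probability is exactly 1: with every feature
  # available at each split, each tree splits on the separating feature,
  # so far-out points are unanimous
  m_all <- brf_fit(d$X, d$y, forest_config(n_trees = 30, random_seed = 2,
                                           max_features_per_split = 3))
  far <- cbind(s1 = c(10, -10), s2 = 0, s3 = 0.5)
  pf <- predict(m_all, far, type = "prob")
  expect_equal(apply(pf, 1, max), c(1, 1))

  expect_error(predict(m, d$X[, c("s1", "s2")]), "s3")

  tau <- 0.9
  flagged <- flag_low_confidence(out$prob, tau)
  expect_equal(flagged, which(apply(out$prob, 1, max) < tau))
})

test_that("evaluate_predictions computes the reported metrics", {
  perfect <- evaluate_predictions(c("a", "b", "a"), c("a", "b", "a"))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1_macro, 1)
  expect_equal(perfect$gmean, 1)
  expect_equal(unname(diag(perfect$confusion_matrix)), c(1, 1))

  # recalls 1.0 and 0.25 -> gmean 0.5
  y_true <- rep(c("A", "B"), c(4, 4))
  y_pred <- c(rep("A", 4), "B", rep("A", 3))
  r <- evaluate_predictions(y_true, y_pred)
  expect_equal(unname(r$per_class_recall), c(1, 0.25))
  expect_equal(r$gmean, 0.5)

  # hand-computed 2x2 confusion table
  r2 <- evaluate_predictions(c("A", "A", "B", "B"), c("A", "B", "B", "B"))
  expect_equal(r2$accuracy, 0.75)
  expect_equal(unname(r2$per_class_recall), c(0.5, 1))
  expect_equal(r2$gmean, sqrt(0.5), tolerance = 1e-12)
  expect_equal(unname(r2$confusion_matrix["A", ]), c(0.5, 0.5))
  # f1: A: p=1, r=.5 -> 2/3; B: p=2/3, r=1 -> 0.8
  expect_equal(r2$f1_macro, mean(c(2 / 3, 0.8)))
  # accuracy equals trace of counts over n (internal consistency)
  expect_equal(r2$accuracy, sum(diag(r2$confusion_counts)) / r2$n)

  expect_error(evaluate_predictions(character(0), character(0)), "empty")
  expect_error(evaluate_predictions(c("a", "b"), "a"), "length")
})

test_that("grouped_kfold partitions experiments without leakage", {
  groups <- paste0("exp", 1:6)
  f <- grouped_kfold(groups, n_folds = 3, seed = 4)
  expect_setequal(names(f$fold), groups)
  expect_equal(as.vector(table(f$fold)), c(2, 2, 2))
  # every group in exactly one fold by construction; same seed, same split
  f2 <- grouped_kfold(groups, n_folds = 3, seed = 4)
  expect_identical(f2$fold, f$fold)
  expect_error(grouped_kfold(paste0("e", 1:2), n_folds = 3), "folds")
})

test_that("run_experiment rejects train/test experiment overlap", {
  ds <- random_track_dataset(n_tracks = 3, n_points = 8)
  expect_error(run_experiment(ds, ds, "binary"), "leakage")
})

test_that("models survive a plain-text save/load round trip", {
  d <- make_separable(n = 120, seed = 9)
  m <- brf_fit(d$X, d$y, forest_config(n_trees = 20, random_seed = 5))
  path <- withr::local_tempfile(fileext = ".json")
  save_brf_model(m, path)
  m2 <- load_brf_model(path)
  expect_identical(predict(m2, d$X), predict(m, d$X))
  expect_equal(predict(m2, d$X, type = "prob"),
               predict(m, d$X, type = "prob"))
  expect_equal(m2$selected_features, m$selected_features)
})
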