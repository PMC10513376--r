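# Balanced random forest classifier and evaluation machinery. Trees are
# grown in C++ (src/forest.cpp); the class-balanced bootstrap is drawn here
# so it can be audited from R.

#' Forest configuration
#'
#' @param n_trees number of trees (default 500).
#' @param max_features_per_split `"sqrt"` (default: floor(sqrt(p)) features
#'   examined at each split) or a positive integer.
#' @param min_node minimum samples in a leaf (default 1).
#' @param max_depth maximum tree depth, 0 = unlimited (default).
#' @param random_seed integer seed for bootstrap and split sampling.
#' @param class_scheme `"binary"` or `"three_class"` (informational tag).
#' @return an object of class `forest_config`.
#' @export
forest_config <- function(n_trees = 500L, max_features_per_split = "sqrt",
                          min_node = 1L, max_depth = 0L, random_seed = 1L,
                          class_scheme = c("binary", "three_class")) {
  n_trees <- as.integer(n_trees)
  if (is.na(n_trees) || n_trees < 1L) stop("`n_trees` must be >= 1")
  if (!identical(max_features_per_split, "sqrt")) {
    max_features_per_split <- as.integer(max_features_per_split)
    if (is.na(max_features_per_split) || max_features_per_split < 1L)
      stop("`max_features_per_split` must be \"sqrt\" or a positive integer")
  }
  structure(list(n_trees = n_trees,
                 max_features_per_split = max_features_per_split,
                 min_node = as.integer(min_node),
                 max_depth = as.integer(max_depth),
                 random_seed = as.integer(random_seed),
                 class_scheme = match.arg(class_scheme)),
            class = "forest_config")
}

#' Class-balanced bootstrap sample
#'
#' Draws, for every class, `m` indices with replacement from that class,
#' where `m` is the minority-class count; the returned sample therefore has
#' exactly equal class counts. This is the per-tree subsample of the
#' balanced random forest, which down-samples majority classes instead of
#' reweighting.
#'
#' @param y class labels (factor; every factor level must be present).
#' @param seed optional integer seed (set locally).
#' @return integer vector of sample indices, grouped by class.
#' @export
balanced_bootstrap <- function(y, seed = NULL) {
  if (!is.factor(y)) y <- factor(y)      # keep declared levels intact
  cnt <- tabulate(y, nlevels(y))
  if (nlevels(y) < 2L) stop("at least 2 classes are required")
  if (any(cnt == 0L))
    stop("class(es) absent from the data: ",
         paste(levels(y)[cnt == 0L], collapse = ", "))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  m <- min(cnt)
  unlist(lapply(levels(y), function(cl) {
    idx <- which(y == cl)
    idx[sample.int(length(idx), m, replace = TRUE)]
  }), use.names = FALSE)
}

#' Fit a balanced random forest
#'
#' Grows `n_trees` CART trees, each on an independent [balanced_bootstrap()]
#' sample, with `max_features_per_split` features examined at every split
#' (Gini impurity, histogram split search over up to 256 per-feature
#' quantile bins, grown to purity by default). The whole fit is
#' deterministic given `cfg$random_seed`.
#'
#' @param X numeric matrix (samples x features) with column names, already
#'   restricted to the selected features; no missing values.
#' @param y class labels (factor or character), >= 2 classes.
#' @param cfg a [forest_config()].
#' @return an object of class `brf_model`: the tree ensemble, the class
#'   levels, the expected feature names, the config, and the `inbag`
#'   matrix of per-tree bootstrap indices (for auditing).
#' @export
brf_fit <- function(X, y, cfg = forest_config()) {
  stopifnot(inherits(cfg, "forest_config"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (anyNA(X)) stop("missing feature values are not allowed")
  y <- droplevels(factor(y))
  if (nlevels(y) < 2L) stop("training labels contain a single class")
  if (length(y) != nrow(X)) stop("X and y lengths differ")
  m <- min(tabulate(y, nlevels(y)))
  s <- m * nlevels(y)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$random_seed)
  inbag <- vapply(seq_len(cfg$n_trees), function(t) balanced_bootstrap(y),
                  integer(s))
  inbag <- matrix(inbag, nrow = s)
  mtry <- if (identical(cfg$max_features_per_split, "sqrt")) {
    max(1L, floor(sqrt(ncol(X))))
  } else {
    min(cfg$max_features_per_split, ncol(X))
  }
  forest <- .brf_grow(X, as.integer(y) - 1L, inbag, nlevels(y), mtry,
                      max(1L, cfg$min_node), cfg$max_depth,
                      cfg$random_seed)
  structure(list(forest = forest, classes = levels(y),
                 selected_features = colnames(X), config = cfg,
                 inbag = inbag),
            class = "brf_model")
}

#' @export
print.brf_model <- function(x, ...) {
  cat(sprintf(
    "<brf_model: %d trees, %d features, classes: %s>\n",
    length(x$forest), length(x$selected_features),
    paste(x$classes, collapse = "/")))
  invisible(x)
}

#' Predict behaviors with a balanced random forest
#'
#' Majority vote over trees; the per-class probability is the fraction of
#' trees voting for that class, so probabilities sum to 1 and the predicted
#' label is always the probability argmax (first class level on exact vote
#' ties).
#'
#' @param object a [brf_fit()] model.
#' @param newdata numeric matrix or `feature_matrix` containing at least
#'   the model's selected features (by name).
#' @param type `"class"` (default) for labels, `"prob"` for the matrix of
#'   vote fractions, `"both"` for a list with both.
#' @param ... unused.
#' @return factor of labels, numeric matrix of probabilities, or both.
#' @export
predict.brf_model <- function(object, newdata,
                              type = c("class", "prob", "both"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "feature_matrix")) {
    newdata <- feature_block(newdata, object$selected_features)
  } else {
    newdata <- as.matrix(newdata)
    missing_cols <- setdiff(object$selected_features, colnames(newdata))
    if (length(missing_cols) > 0L)
      stop("missing feature column(s): ",
           paste(missing_cols, collapse = ", "))
    newdata <- newdata[, object$selected_features, drop = FALSE]
  }
  votes <- .brf_votes(object$forest, newdata, length(object$classes))
  prob <- votes / length(object$forest)
  colnames(prob) <- object$classes
  if (type == "prob") return(prob)
  cls <- factor(object$classes[max.col(prob, ties.method = "first")],
                levels = object$classes)
  if (type == "class") cls else list(class = cls, prob = prob)
}

#' Flag low-confidence predictions for manual review
#'
#' Returns the row indices whose maximum predicted-class probability is
#' below `tau`; misclassified samples tend to carry lower vote fractions,
#' so these are the candidates for human review.
#'
#' @param prob probability matrix from `predict(..., type = "prob")`.
#' @param tau probability threshold in (0, 1].
#' @return integer vector of row indices with max probability < `tau`.
#' @export
flag_low_confidence <- function(prob, tau) {
  stopifnot(is.numeric(tau), tau > 0, tau <= 1)
  which(apply(prob, 1L, max) < tau)
}

#' Evaluate predictions
#'
#' Computes accuracy (mean exact match), macro-averaged F1 (unweighted
#' mean of per-class F1, with F1 = 0 for a degenerate class), the geometric
#' mean of per-class recalls, per-class recall, and the confusion matrix
#' row-normalized by true class. Classes are those observed in `y_true`.
#'
#' @param y_true true labels.
#' @param y_pred predicted labels (same length).
#' @return an object of class `eval_report`.
#' @export
evaluate_predictions <- function(y_true, y_pred) {
  if (length(y_true) == 0L) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  lev <- union(levels(factor(y_true)), levels(factor(y_pred)))
  y_true <- factor(y_true, levels = lev)
  y_pred <- factor(y_pred, levels = lev)
  cm <- table(true = y_true, predicted = y_pred)
  observed <- rowSums(cm) > 0
  recall <- diag(cm) / rowSums(cm)
  precision <- diag(cm) / colSums(cm)
  f1 <- 2 * precision * recall / (precision + recall)
  f1[!is.finite(f1)] <- 0
  rec_obs <- recall[observed]
  report <- structure(list(
    accuracy = sum(diag(cm)) / sum(cm),
    f1_macro = mean(f1[observed]),
    gmean = prod(rec_obs)^(1 / length(rec_obs)),
    per_class_recall = recall,
    confusion_matrix = sweep(cm, 1L, pmax(rowSums(cm), 1L), "/"),
    confusion_counts = cm,
    n = length(y_true)), class = "eval_report")
  report
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report: n = %d, accuracy = %.3f, F1 = %.3f, G-mean = %.3f>\n",
    x$n, x$accuracy, x$f1_macro, x$gmean))
  cat("confusion matrix (row-normalized by true class):\n")
  print(round(x$confusion_matrix, 3))
  invisible(x)
}

#' Experiment-grouped cross-validation specification
#' @param n_folds number of folds (default 3).
#' @param group_key grouping column (default `"experiment_id"`).
#' @return an object of class `grouped_cv_spec`.
#' @export
grouped_cv_spec <- function(n_folds = 3L, group_key = "experiment_id") {
  n_folds <- as.integer(n_folds)
  if (is.na(n_folds) || n_folds < 2L) stop("`n_folds` must be >= 2")
  structure(list(n_folds = n_folds, group_key = group_key),
            class = "grouped_cv_spec")
}

#' Grouped k-fold assignment
#'
#' Assigns each group (experiment) to exactly one fold: groups are
#' shuffled with the seed and dealt round-robin, so fold sizes are balanced
#' by group count. Every sample inherits its group's fold, which is what
#' prevents leakage of an experiment across the train/validation boundary.
#'
#' @param groups character vector of group ids (one per sample) or the
#'   unique group ids.
#' @param n_folds number of folds.
#' @param seed integer seed for the shuffle.
#' @return list with `fold`: named integer vector mapping group id ->
#'   fold, and `n_folds`.
#' @export
grouped_kfold <- function(groups, n_folds = 3L, seed = 1L) {
  ug <- sort(unique(as.character(groups)))
  if (length(ug) < n_folds)
    stop("fewer groups (", length(ug), ") than folds (", n_folds, ")")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  shuffled <- sample(ug)
  # fold of the i-th shuffled group is ((i - 1) mod k) + 1
  fold <- setNames(((match(ug, shuffled) - 1L) %% n_folds) + 1L, ug)
  list(fold = fold, n_folds = as.integer(n_folds))
}

#' Run the full train/test experiment
#'
#' The end-to-end pipeline on raw track datasets: label mapping and short-
#' track filtering, 90-feature extraction, feature-count search by grouped
#' 3-fold cross-validation ([choose_feature_count()]), a final mRMR pass on
#' the full training data to fix the deployed feature list, balanced random
#' forest training, and evaluation on the held-out test experiments. Train
#' and test must not share experiment ids (leakage guard).
#'
#' @param train,test [track_dataset()] objects with per-timepoint labels.
#' @param scheme `"binary"` or `"three_class"`.
#' @param config a [pipeline_config()].
#' @return an object of class `synkin_run`: list with `model`, `curve`,
#'   `n_star`, `selected_features`, `report`, `predictions`, `scheme`,
#'   `seed`.
#' @export
run_experiment <- function(train, test, scheme = c("binary", "three_class"),
                           config = pipeline_config()) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(train, "track_dataset"),
            inherits(test, "track_dataset"))
  overlap <- intersect(unique(train$points$experiment_id),
                       unique(test$points$experiment_id))
  if (length(overlap) > 0L)
    stop("data leakage: experiment(s) present in both train and test: ",
         paste(overlap, collapse = ", "))
  prep <- function(ds) {
    ds <- map_labels(ds, scheme = if (scheme == "binary") "binary"
                     else "three_class")
    ds <- filter_short_tracks(ds, config$min_track_points)
    assemble_feature_matrix(ds, spec = config$window,
                            coast_threshold = config$coast_threshold)
  }
  fm_train <- prep(train)
  fm_test <- prep(test)
  if (anyNA(fm_train$label))
    stop("training data must be fully labeled")
  fcfg <- config$forest
  fcfg$class_scheme <- scheme
  fcfg$random_seed <- config$seed
  sel <- choose_feature_count(
    fm_train, grid_max = config$mrmr$grid_max,
    cv = config$cv, forest = fcfg, cv_n_trees = config$mrmr$cv_n_trees,
    mrmr_scheme = config$mrmr$scheme, delta = config$mrmr$delta,
    horizon = config$mrmr$horizon, rule = config$mrmr$rule,
    seed = config$seed)
  final_mrmr <- mrmr_select(fm_train, fm_train$label, n = sel$n_star,
                            scheme = config$mrmr$scheme)
  feats <- final_mrmr$ordered_features
  model <- brf_fit(feature_block(fm_train, feats), fm_train$label, fcfg)
  pred <- predict(model, feature_block(fm_test, feats), type = "both")
  report <- evaluate_predictions(fm_test$label, pred$class)
  structure(list(model = model, curve = sel$curve, n_star = sel$n_star,
                 selected_features = feats, mrmr = final_mrmr,
                 report = report, predictions = pred, scheme = scheme,
                 seed = config$seed),
            class = "synkin_run")
}

#' @export
print.synkin_run <- function(x, ...) {
  cat(sprintf("<synkin_run: %s scheme, %d features selected>\n",
              x$scheme, x$n_star))
  print(x$report)
  invisible(x)
}
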