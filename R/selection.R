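# mRMR feature selection: one-way ANOVA F-statistic for relevance, mean
# absolute Pearson correlation with the already-selected set for
# redundancy, combined greedily (quotient by default).

#' One-way ANOVA F-statistic of each feature across classes
#'
#' Relevance score for mRMR: for each feature column, the one-way ANOVA
#' F-statistic of the feature across the class labels. A feature constant
#' within every class (zero within-group variance) with zero between-group
#' variance returns 0; perfect separation returns `Inf`.
#'
#' @param X numeric matrix (samples x features) or a `feature_matrix`.
#' @param y class labels (factor or character): at least 2 classes, each
#'   with at least 2 samples.
#' @return named numeric vector of F-statistics.
#' @export
f_relevance <- function(X, y) {
  if (inherits(X, "feature_matrix")) X <- feature_block(X)
  y <- factor(y)
  y <- droplevels(y)
  k <- nlevels(y)
  if (k < 2L) stop("at least 2 classes are required")
  cnt <- tabulate(y, k)
  if (any(cnt < 2L))
    stop("every class needs >= 2 samples; offending class(es): ",
         paste(levels(y)[cnt < 2L], collapse = ", "))
  n <- nrow(X)
  gsum <- rowsum(X, y)                     # k x p group sums
  gmean <- gsum / cnt
  grand <- colSums(gsum) / n
  ssb <- colSums(cnt * (gmean - rep(grand, each = k))^2)
  sstot <- colSums(X^2) - n * grand^2
  ssw <- pmax(sstot - ssb, 0)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  f[ssb <= 0] <- 0                         # constant feature: guard 0/0
  names(f) <- colnames(X)
  f
}

#' Greedy mRMR feature selection
#'
#' Selects `n` features by the minimal-optimal mRMR strategy: the first
#' feature maximizes the F-statistic relevance; each subsequent feature
#' maximizes relevance penalized by redundancy, the mean absolute Pearson
#' correlation with the features already selected. The default combination
#' is the quotient F / mean|r| (`scheme = "quotient"`); the difference
#' F - mean|r| is available as an option. Ties are broken lexicographically
#' by feature name, so selection is deterministic; the greedy order is
#' nested (the first n selected are a prefix of the first n+1).
#'
#' @param X numeric matrix (samples x features) or a `feature_matrix` with
#'   column names.
#' @param y class labels.
#' @param n number of features to select (1 <= n <= ncol(X)).
#' @param scheme `"quotient"` (default) or `"difference"`.
#' @return an object of class `mrmr_result`: list with `ordered_features`,
#'   `relevance` (F of each selected feature, in selection order) and
#'   `score_at_selection` (greedy criterion value when each was added).
#' @export
mrmr_select <- function(X, y, n, scheme = c("quotient", "difference")) {
  scheme <- match.arg(scheme)
  if (inherits(X, "feature_matrix")) X <- feature_block(X)
  p <- ncol(X)
  n <- as.integer(n)
  if (is.na(n) || n < 1L || n > p)
    stop("`n` must be between 1 and the number of features (", p, ")")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(p))
  f <- f_relevance(X, y)
  nm <- colnames(X)
  selected <- integer(0)
  scores <- numeric(0)
  abscor_sum <- numeric(p)                 # running sum of |r| vs selected
  remaining <- seq_len(p)
  for (step in seq_len(n)) {
    if (step == 1L) {
      crit <- f[remaining]                 # redundancy of first feature: 0
    } else {
      red <- abscor_sum[remaining] / (step - 1L)
      crit <- if (scheme == "quotient") {
        f[remaining] / pmax(red, 1e-12)
      } else {
        f[remaining] - red
      }
    }
    ord <- order(-crit, nm[remaining])     # deterministic tie-break
    pick <- remaining[ord[1L]]
    selected <- c(selected, pick)
    scores <- c(scores, crit[ord[1L]])
    remaining <- setdiff(remaining, pick)
    if (length(remaining) > 0L) {
      r <- suppressWarnings(cor(X[, remaining, drop = FALSE], X[, pick]))
      r[is.na(r)] <- 0                     # zero-variance: no redundancy
      abscor_sum[remaining] <- abscor_sum[remaining] + abs(r)
    }
  }
  structure(list(ordered_features = nm[selected],
                 relevance = unname(f[selected]),
                 score_at_selection = unname(scores),
                 scheme = scheme),
            class = "mrmr_result")
}

#' @export
print.mrmr_result <- function(x, ...) {
  cat(sprintf("<mrmr_result: %d features (%s scheme)>\n",
              length(x$ordered_features), x$scheme))
  print(data.table(feature = x$ordered_features, F = x$relevance,
                   score = x$score_at_selection))
  invisible(x)
}

#' Stop rule on a cross-validation accuracy curve
#'
#' Given mean CV accuracy per feature count on the grid 3, 5, 7, ...,
#' returns the smallest grid point after which accuracy stops improving
#' meaningfully. Under the default `"per_increment"` reading, a point
#' qualifies when each of the next `horizon` increments raises mean
#' accuracy by less than `delta` (absolute); under `"cumulative"`, when no
#' grid point among the next `horizon` exceeds it by `delta` or more.
#' Comparisons carry a 1e-9 numerical tolerance so a gain of exactly
#' `delta` does not block on floating-point representation. If no point
#' qualifies the grid argmax is returned with a warning.
#'
#' @param mean_acc numeric vector of mean CV accuracies.
#' @param grid integer vector of feature counts (same length).
#' @param delta minimum meaningful accuracy gain (default 0.005, i.e. 0.5%).
#' @param horizon number of subsequent increments examined (default 5).
#' @param rule `"per_increment"` (default) or `"cumulative"`.
#' @return list with `n_star` (chosen feature count) and `fired` (logical:
#'   did the rule fire, or was the argmax fallback used).
#' @export
cv_stop_rule <- function(mean_acc, grid, delta = 0.005, horizon = 5L,
                         rule = c("per_increment", "cumulative")) {
  rule <- match.arg(rule)
  stopifnot(length(mean_acc) == length(grid), length(grid) >= 1L)
  m <- length(grid)
  tol <- 1e-9                            # gains exactly at delta don't block
  for (i in seq_len(m - horizon)) {
    idx <- seq.int(i + 1L, i + horizon)
    ok <- if (rule == "per_increment") {
      all(diff(mean_acc[seq.int(i, i + horizon)]) < delta + tol)
    } else {
      all(mean_acc[idx] - mean_acc[i] < delta + tol)
    }
    if (ok) return(list(n_star = grid[i], fired = TRUE))
  }
  warning("stop rule never fired; falling back to the grid argmax")
  list(n_star = grid[which.max(mean_acc)], fired = FALSE)
}

#' Choose the number of mRMR features by grouped cross-validation
#'
#' For feature counts 3, 5, 7, ... up to `grid_max`: within each of the
#' cross-validation folds (grouped by experiment so no experiment is in
#' both portions), mRMR is run once on the fold's training portion and the
#' balanced random forest is trained on each prefix of the selected order;
#' validation accuracy is averaged over folds into a CV curve. The chosen
#' count `n_star` is the first grid point satisfying [cv_stop_rule()]. The
#' search stops as soon as the rule can fire, so the returned curve may end
#' before `grid_max`.
#'
#' @param fm a labeled `feature_matrix` (training data).
#' @param grid_max largest feature count examined (>= 13 so the stop rule
#'   has its full horizon; default 21).
#' @param cv a [grouped_cv_spec()].
#' @param forest a [forest_config()] used for the fold models; `cv_n_trees`
#'   trees are grown per fold model.
#' @param cv_n_trees trees per fold model (default 50; fewer than the
#'   final model because only the ranking of feature counts matters here).
#' @param mrmr_scheme passed to [mrmr_select()].
#' @param delta,horizon,rule passed to [cv_stop_rule()].
#' @param seed integer seed controlling fold assignment and fold models.
#' @return list with `n_star`, `curve` (data.table: n, mean_acc, min_acc,
#'   max_acc), `fold_acc` (matrix folds x grid), `fired`.
#' @export
choose_feature_count <- function(fm, grid_max = 21L,
                                 cv = grouped_cv_spec(),
                                 forest = forest_config(),
                                 cv_n_trees = 50L,
                                 mrmr_scheme = "quotient",
                                 delta = 0.005, horizon = 5L,
                                 rule = "per_increment", seed = 1L) {
  grid_max <- as.integer(grid_max)
  if (grid_max < 13L)
    stop("`grid_max` must be >= 13 so the stop rule horizon exists")
  if (anyNA(fm$label)) stop("training feature matrix must be fully labeled")
  grid <- seq.int(3L, grid_max, by = 2L)
  folds <- grouped_kfold(fm$experiment_id, n_folds = cv$n_folds,
                         seed = seed)
  X <- feature_block(fm)
  yv <- factor(fm$label)
  fold_sel <- lapply(seq_len(cv$n_folds), function(k) {
    tr <- folds$fold[fm$experiment_id] != k
    mrmr_select(X[tr, , drop = FALSE], yv[tr], n = min(grid_max, ncol(X)),
                scheme = mrmr_scheme)$ordered_features
  })
  fold_acc <- matrix(NA_real_, nrow = cv$n_folds, ncol = length(grid),
                     dimnames = list(NULL, grid))
  decided <- NULL
  for (gi in seq_along(grid)) {
    ng <- grid[gi]
    for (k in seq_len(cv$n_folds)) {
      tr <- folds$fold[fm$experiment_id] != k
      feats <- fold_sel[[k]][seq_len(ng)]
      cfg <- forest
      cfg$n_trees <- as.integer(cv_n_trees)
      cfg$random_seed <- seed + 1000L * k + ng
      mdl <- brf_fit(X[tr, feats, drop = FALSE], yv[tr], cfg)
      pred <- predict(mdl, X[!tr, feats, drop = FALSE])
      fold_acc[k, gi] <- mean(pred == yv[!tr])
    }
    if (gi > horizon) {
      mean_acc <- colMeans(fold_acc[, seq_len(gi), drop = FALSE])
      res <- withCallingHandlers(
        cv_stop_rule(mean_acc, grid[seq_len(gi)], delta, horizon, rule),
        warning = function(w) invokeRestart("muffleWarning"))
      if (res$fired) { decided <- res; break }
    }
  }
  done <- which(!is.na(fold_acc[1L, ]))
  fold_acc <- fold_acc[, done, drop = FALSE]
  mean_acc <- colMeans(fold_acc)
  if (is.null(decided)) {
    decided <- cv_stop_rule(mean_acc, grid[done], delta, horizon, rule)
  }
  curve <- data.table(n = grid[done], mean_acc = mean_acc,
                      min_acc = apply(fold_acc, 2L, min),
                      max_acc = apply(fold_acc, 2L, max))
  list(n_star = decided$n_star, curve = curve, fold_acc = fold_acc,
       fired = decided$fired)
}
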