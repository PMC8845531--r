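# Outcome classification: four classifiers x optional PCA, 10-fold
# stratified cross-validation over the three nested feature sets.
#
# KNN is backed by FNN; logistic regression by stats::glm.  The environment
# provides no SVM or decision-tree package, so the SVM is a least-squares
# SVM (kernel ridge on +/-1 labels, RBF kernel with the median-distance
# scale heuristic) and the random forest is bagged CART trees (Gini,
# random feature subsets, out-of-the-box defaults, no tuning loop).

#' Resolve a nested feature set against signature columns
#'
#' @param feature_set one of `"sim_imaging_history"`, `"imaging_history"`,
#'   `"history"`.
#' @param columns available signature column names.
#' @param schema optional schema from [signature_schema()]; defaults to the
#'   full-battery layout.
#' @return character vector of selected columns (a subset chain:
#'   history < imaging_history < sim_imaging_history).
#' @export
feature_columns <- function(feature_set = c("sim_imaging_history",
                                            "imaging_history", "history"),
                            columns, schema = NULL) {
  feature_set <- match.arg(feature_set)
  schema <- schema %||% signature_schema()
  want <- switch(feature_set,
                 history = schema$history,
                 imaging_history = c(schema$imaging, schema$history),
                 sim_imaging_history = c(intersect(columns, schema$sim),
                                         schema$imaging, schema$history))
  out <- intersect(want, columns)
  if (length(out) == 0) stop("no matching feature columns")
  out
}

#' Empirical ROC curve and AUC
#'
#' Trapezoidal AUC over the empirical ROC, equal to the normalized
#' Mann-Whitney U statistic (ties counted half).
#'
#' @param scores numeric classifier scores (higher = positive).
#' @param labels 0/1 labels; both classes must be present.
#' @return list with `fpr`, `tpr`, `thresholds`, `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  # collapse ties on score
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tpr <- c(0, tp[last] / np)
  fpr <- c(0, fp[last] / nn)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, thresholds = c(Inf, s[last]), auc = auc)
}

# ---- internal classifier backends (train matrix already standardized) ---

fit_score <- function(classifier, xtr, ytr, xte, seed) {
  switch(classifier,
         knn = {
           k <- min(5, nrow(xtr))
           nn <- FNN::get.knnx(xtr, xte, k = k)$nn.index
           rowMeans(matrix(ytr[nn], nrow(xte), k))
         },
         svm = {
           yy <- ifelse(ytr == 1, 1, -1)
           d2 <- as.matrix(stats::dist(xtr))^2
           md <- median(d2[upper.tri(d2)])
           gamma <- if (is.finite(md) && md > 0) 1 / (2 * md) else 1
           Ktr <- exp(-gamma * d2)
           n <- nrow(xtr)
           alpha <- solve(Ktr + diag(n) / 10, yy)
           cross <- outer(rowSums(xte^2), rowSums(xtr^2), "+") -
             2 * xte %*% t(xtr)
           Kte <- exp(-gamma * cross)
           # map the decision value through a logistic link to a score
           plogis(as.vector(Kte %*% alpha))
         },
         rf = with_seed(seed, rf_score(xtr, ytr, xte)),
         logreg = {
           df <- as.data.frame(xtr); df$.y <- ytr
           fit <- suppressWarnings(glm(.y ~ ., data = df,
                                       family = binomial()))
           suppressWarnings(
             as.vector(predict(fit, newdata = as.data.frame(xte),
                               type = "response")))
         },
         stop("unknown classifier: ", classifier))
}

# ---- bagged CART (random forest) ---------------------------------------

tree_grow <- function(x, y, mtry, depth, min_node) {
  n <- length(y)
  p1 <- mean(y)
  if (depth <= 0 || n < min_node || p1 == 0 || p1 == 1)
    return(list(leaf = TRUE, prob = p1))
  feats <- sample.int(ncol(x), mtry)
  best <- NULL; bscore <- Inf
  for (f in feats) {
    o <- order(x[, f]); xv <- x[o, f]; yv <- y[o]
    cp <- cumsum(yv); tot <- cp[n]
    k <- which(diff(xv) > 0)
    if (!length(k)) next
    nl <- k; pl <- cp[k]; nr <- n - nl; pr <- tot - pl
    gini <- nl * (1 - (pl / nl)^2 - ((nl - pl) / nl)^2) +
      nr * (1 - (pr / nr)^2 - ((nr - pr) / nr)^2)
    j <- which.min(gini)
    if (gini[j] < bscore) {
      bscore <- gini[j]
      best <- list(f = f, thr = (xv[k[j]] + xv[k[j] + 1]) / 2)
    }
  }
  if (is.null(best)) return(list(leaf = TRUE, prob = p1))
  left <- x[, best$f] <= best$thr
  list(leaf = FALSE, f = best$f, thr = best$thr,
       l = tree_grow(x[left, , drop = FALSE], y[left], mtry,
                     depth - 1, min_node),
       r = tree_grow(x[!left, , drop = FALSE], y[!left], mtry,
                     depth - 1, min_node))
}

tree_prob <- function(node, x) {
  out <- numeric(nrow(x))
  rec <- function(nd, idx) {
    if (length(idx) == 0) return()
    if (nd$leaf) { out[idx] <<- nd$prob; return() }
    left <- x[idx, nd$f] <= nd$thr
    rec(nd$l, idx[left]); rec(nd$r, idx[!left])
  }
  rec(node, seq_len(nrow(x)))
  out
}

rf_score <- function(xtr, ytr, xte, n_trees = 100, depth = 10,
                     min_node = 2) {
  n <- nrow(xtr)
  mtry <- max(1, ceiling(sqrt(ncol(xtr))))
  acc <- numeric(nrow(xte))
  for (b in seq_len(n_trees)) {
    idx <- sample.int(n, n, replace = TRUE)
    tr <- tree_grow(xtr[idx, , drop = FALSE], ytr[idx], mtry, depth,
                    min_node)
    acc <- acc + tree_prob(tr, xte)
  }
  acc / n_trees
}

# ---- cross-validation ---------------------------------------------------

#' Stratified fold assignment
#' @param y 0/1 labels
#' @param folds fold count
#' @param seed integer seed
#' @return integer fold id per sample; every fold contains both classes
#'   whenever class counts allow it
#' @export
make_folds <- function(y, folds = 10, seed = 1) {
  y <- as.integer(y)
  ids <- integer(length(y))
  with_seed(child_seed(seed, "folds"), {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      ids[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
    }
  })
  ids
}

# train-fold transform: standardize, then optional PCA at >= 95% variance
fit_transform <- function(xtr, use_pca, var_keep = 0.95) {
  ctr <- colMeans(xtr)
  scl <- apply(xtr, 2, sd)
  scl[scl < 1e-12] <- 1
  xs <- sweep(sweep(xtr, 2, ctr), 2, scl, "/")
  rot <- NULL; ncomp <- ncol(xs)
  if (use_pca) {
    pc <- prcomp(xs, center = FALSE, scale. = FALSE)
    v <- pc$sdev^2
    cum <- cumsum(v) / sum(v)
    ncomp <- which(cum >= var_keep)[1]
    rot <- pc$rotation[, seq_len(ncomp), drop = FALSE]
    xs <- xs %*% rot
  }
  list(apply = function(x) {
    z <- sweep(sweep(x, 2, ctr), 2, scl, "/")
    if (!is.null(rot)) z <- z %*% rot
    z
  }, x = xs, ncomp = ncomp,
  checksum = digest::digest(list(ctr, scl, rot)))
}

#' Cross-validated evaluation of one classifier
#'
#' Within each training fold only: columns are standardized, PCA is
#' (optionally) fitted retaining the smallest component count reaching 95%
#' explained variance, and the classifier is fitted; the held-out fold is
#' transformed with the training-fold parameters and scored.  Recall and
#' precision refer to the recurrence-positive class at the 0.5 score
#' threshold.
#'
#' @param x numeric feature matrix (or data.frame).
#' @param y 0/1 labels.
#' @param classifier `"knn"`, `"svm"`, `"rf"` or `"logreg"`.
#' @param use_pca logical.
#' @param folds fold count (default 10).
#' @param seed integer seed (fold assignment + forest bootstrap).
#' @param fold_ids optional explicit fold assignment (overrides
#'   `folds`/`seed` stratification).
#' @return data.frame of per-fold `auc`, `accuracy`, `recall`,
#'   `precision`; attributes `transform_checksums` and `fold_ids`.
#' @export
fit_evaluate <- function(x, y, classifier = c("knn", "svm", "rf", "logreg"),
                         use_pca = FALSE, folds = 10, seed = 1,
                         fold_ids = NULL) {
  classifier <- match.arg(classifier)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.integer(y)
  if (anyNA(x) || anyNA(y)) stop("missing cells in features or labels")
  fold_ids <- fold_ids %||% make_folds(y, folds, seed)
  res <- list(); checksums <- character(0)
  for (f in sort(unique(fold_ids))) {
    te <- fold_ids == f
    if (length(unique(y[te])) < 2 || length(unique(y[!te])) < 2)
      stop("insufficient class balance: a fold contains one class only")
    tf <- fit_transform(x[!te, , drop = FALSE], use_pca)
    checksums <- c(checksums, tf$checksum)
    sc <- fit_score(classifier, tf$x, y[!te],
                    tf$apply(x[te, , drop = FALSE]),
                    seed = child_seed(seed, paste0("fold", f)))
    roc <- roc_curve(sc, y[te])
    pred <- as.integer(sc >= 0.5)
    tp <- sum(pred == 1 & y[te] == 1)
    res[[length(res) + 1]] <- data.frame(
      fold = f, auc = roc$auc,
      accuracy = mean(pred == y[te]),
      recall = if (sum(y[te] == 1) > 0) tp / sum(y[te] == 1) else NA_real_,
      precision = if (sum(pred == 1) > 0) tp / sum(pred == 1) else 0)
  }
  out <- do.call(rbind, res)
  attr(out, "transform_checksums") <- checksums
  attr(out, "fold_ids") <- fold_ids
  out
}

#' Compare all classifiers and select the best by ROC AUC
#'
#' Evaluates KNN, SVM, random forest and logistic regression, each with and
#' without PCA preprocessing, on identical stratified fold assignments, and
#' selects the combination with the largest mean ROC AUC (ties broken by
#' higher mean accuracy, then by the fixed order knn, svm, rf, logreg,
#' no-PCA first).
#'
#' @param x feature matrix.
#' @param y 0/1 labels.
#' @param folds,seed cross-validation controls.
#' @return object of class `classifier_report`: `grid` (per-combination
#'   mean/sd of AUC, accuracy, recall, precision), `selected` (row id),
#'   `fold_ids`, `per_fold` (list of per-fold tables).
#' @export
compare_and_select <- function(x, y, folds = 10, seed = 1) {
  fold_ids <- make_folds(as.integer(y), folds, seed)
  classifiers <- c("knn", "svm", "rf", "logreg")
  grid <- expand.grid(classifier = classifiers, pca = c(FALSE, TRUE),
                      stringsAsFactors = FALSE)
  per_fold <- vector("list", nrow(grid))
  stats <- lapply(seq_len(nrow(grid)), function(i) {
    r <- fit_evaluate(x, y, grid$classifier[i], use_pca = grid$pca[i],
                      seed = seed, fold_ids = fold_ids)
    per_fold[[i]] <<- r
    data.frame(auc = mean(r$auc), auc_sd = sd(r$auc),
               accuracy = mean(r$accuracy), accuracy_sd = sd(r$accuracy),
               recall = mean(r$recall, na.rm = TRUE),
               recall_sd = sd(r$recall, na.rm = TRUE),
               precision = mean(r$precision), precision_sd = sd(r$precision))
  })
  grid <- cbind(grid, do.call(rbind, stats))
  grid$model <- paste0(grid$classifier, ifelse(grid$pca, "+pca", ""))
  ord <- order(-grid$auc, -grid$accuracy, seq_len(nrow(grid)))
  selected <- ord[1]
  structure(list(grid = grid, selected = selected,
                 selected_model = grid$model[selected],
                 fold_ids = fold_ids, per_fold = per_fold),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("<classifier_report>\n")
  g <- x$grid[order(-x$grid$auc), c("model", "auc", "auc_sd", "accuracy")]
  print(g, row.names = FALSE, digits = 3)
  cat("selected:", x$selected_model, "\n")
  invisible(x)
}
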