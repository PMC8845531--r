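test_that("trapezoidal AUC equals the pair-counting oracle", {
  expect_equal(roc_curve(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
  expect_equal(roc_curve(c(0, 0, 1, 1), c(0, 0, 1, 1))$auc, 1)
  for (s in 1:20) {
    set.seed(s)
    n <- sample(6:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    sc <- round(runif(n), 2)   # rounding forces ties
    expect_equal(roc_curve(sc, y)$auc, oracle_auc(sc, y),
                 info = paste("case", s))
  }
  expect_error(roc_curve(runif(5), rep(1, 5)), "both classes")
})

test_that("random scores give AUC near one half at large n", {
  set.seed(2)
  y <- rbinom(10000, 1, 0.5)
  sc <- runif(10000)
  expect_lt(abs(roc_curve(sc, y)$auc - 0.5), 0.02)
})

test_that("PCA retains the minimal component count reaching 95% variance", {
  # orthogonal columns with exactly known sample variances 10, 2, 1, 0.5:
  # cumulative shares 74.1%, 88.9%, 96.3% -> 3 components
  set.seed(3)
  q <- qr.Q(qr(matrix(rnorm(400), 100, 4)))
  x <- sweep(q, 2, sqrt(99 * c(10, 2, 1, 0.5)), "*")
  pc <- prcomp(x, center = TRUE)
  tf <- afstress:::fit_transform(x, use_pca = TRUE)
  # fit_transform standardizes first: equal variances -> needs all 4
  expect_equal(tf$ncomp, 4)
  # on raw (unstandardized) scales the arithmetic is exact: check the rule
  v <- pc$sdev^2
  expect_equal(which(cumsum(v) / sum(v) >= 0.95)[1], 3)
  # three equal-weight directions -> all three retained
  q3 <- qr.Q(qr(matrix(rnorm(300), 100, 3)))
  x3 <- sweep(q3, 2, sqrt(99), "*")
  expect_equal(afstress:::fit_transform(x3, use_pca = TRUE)$ncomp, 3)
})

test_that("cross-validation is leak-free: test-fold labels cannot alter transforms", {
  set.seed(4)
  x <- matrix(rnorm(60 * 4), 60, 4)
  y <- rbinom(60, 1, 0.5)
  ids <- make_folds(y, folds = 5, seed = 9)
  r1 <- fit_evaluate(x, y, "logreg", use_pca = TRUE, fold_ids = ids)
  y2 <- y
  y2[ids == 1] <- sample(y[ids == 1])   # shuffle within test fold 1 only
  r2 <- fit_evaluate(x, y2, "logreg", use_pca = TRUE, fold_ids = ids)
  cs1 <- attr(r1, "transform_checksums")
  cs2 <- attr(r2, "transform_checksums")
  expect_identical(cs1[1], cs2[1])
})

test_that("all four classifiers separate a planted signal and stay null on noise", {
  set.seed(5)
  n <- 160
  x <- matrix(rnorm(n * 4), n, 4)
  y <- as.integer(x[, 1] + 0.15 * rnorm(n) > 0)
  for (cl in c("knn", "svm", "rf", "logreg")) {
    for (pca in c(FALSE, TRUE)) {
      r <- fit_evaluate(x, y, cl, use_pca = pca, seed = 6)
      expect_gt(mean(r$auc), 0.9,
                label = sprintf("%s pca=%s AUC", cl, pca))
    }
  }
  ynull <- sample(y)
  rn <- fit_evaluate(x, ynull, "logreg", seed = 7)
  expect_gt(mean(rn$auc), 0.35)
  expect_lt(mean(rn$auc), 0.65)
})

test_that("fold construction is stratified and degenerate folds error out", {
  y <- c(rep(1, 10), rep(0, 40))
  ids <- make_folds(y, folds = 5, seed = 1)
  for (f in 1:5) expect_true(all(c(0, 1) %in% y[ids == f]))
  set.seed(8)
  x <- matrix(rnorm(50 * 3), 50, 3)
  bad <- c(rep(1L, 10), rep(0L, 40))
  ids_bad <- rep(1:5, each = 10)     # fold 1 all-positive... fold 2+ all 0
  expect_error(fit_evaluate(x, bad, "logreg", fold_ids = ids_bad),
               "class balance")
})

test_that("compare_and_select is deterministic and falls back to tie-break order", {
  set.seed(9)
  x <- matrix(rnorm(80 * 3), 80, 3)
  y <- as.integer(x[, 1] > 0)
  a <- compare_and_select(x, y, seed = 10)
  b <- compare_and_select(x, y, seed = 10)
  expect_identical(a$grid, b$grid)
  expect_identical(a$selected_model, b$selected_model)
  # constant features: every AUC degenerates, selection = first in fixed order
  xc <- matrix(1, 40, 3) + 1e-9 * matrix(rnorm(120), 40, 3)
  yc <- rep(c(0L, 1L), 20)
  d <- compare_and_select(xc, yc, folds = 5, seed = 11)
  expect_lt(max(abs(d$grid$auc - 0.5)), 0.25)
  top <- d$grid[d$selected, ]
  best <- max(d$grid$auc)
  cand <- d$grid[d$grid$auc == best, ]
  expect_equal(top$model, cand$model[1])
})

test_that("signal confined to simulation columns yields the nested AUC ordering", {
  set.seed(12)
  n <- 500
  sc <- signature_schema()
  sim_sig <- rnorm(n)
  y <- as.integer(sim_sig + 0.6 * rnorm(n) > 0)
  cols <- c("s1_df", "s4_df", "total_area", "fibrosis_area", "age",
            "sex_male")
  x <- cbind(sim_sig + 0.2 * rnorm(n), rnorm(n), rnorm(n), rnorm(n),
             rnorm(n), rbinom(n, 1, 0.5))
  colnames(x) <- cols
  auc_for <- function(fset) {
    f <- feature_columns(fset, cols, sc)
    mean(fit_evaluate(x[, f, drop = FALSE], y, "logreg", seed = 13)$auc)
  }
  a_sim <- auc_for("sim_imaging_history")
  a_img <- auc_for("imaging_history")
  a_hist <- auc_for("history")
  expect_gt(a_sim, a_hist + 0.15)
  expect_gte(a_sim + 0.02, a_img)
  expect_gte(a_img + 0.05, a_hist - 0.05)
})
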