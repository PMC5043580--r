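test_that("lasso path is seeded, spans the grid, starts empty", {
  fm <- toy_features(100, p_noise = 10, seed = 2)
  path <- fit_lasso_path(fm, n_folds = 10, seed = 4)
  path2 <- fit_lasso_path(fm, n_folds = 10, seed = 4)
  expect_identical(path$cv_auc_mean, path2$cv_auc_mean)
  expect_identical(path$coefficients, path2$coefficients)
  expect_true(all(diff(path$lambdas) < 0))
  expect_equal(sum(path$coefficients[1, ] != 0), 0)
  expect_equal(length(path$cv_auc_mean), length(path$lambdas))
  expect_equal(length(path$cv_auc_se), length(path$lambdas))

  one_class <- fm; one_class$labels <- rep("positive", length(fm$labels))
  expect_error(fit_lasso_path(one_class, seed = 1), "two classes")
})

test_that("a perfectly separating feature dominates the 1-se model", {
  wins <- 0
  for (seed in 1:5) {
    fm <- toy_features(60, p_noise = 30, shift = 4, seed = seed)
    path <- fit_lasso_path(fm, n_folds = 10, seed = seed)
    m <- lasso_model(path, select_lambda_1se(path))
    top <- names(which.max(abs(m$active_features)))
    if (identical(top, "signal")) wins <- wins + 1
  }
  expect_gte(wins, 4)
})

test_that("all-noise features give near-random CV AUC", {
  set.seed(99)
  aucs <- sapply(1:5, function(seed) {
    fm <- toy_features(60, p_noise = 10, shift = 0, seed = seed + 50)
    path <- fit_lasso_path(fm, n_folds = 10, seed = seed)
    mean(path$cv_auc_mean)
  })
  expect_true(mean(aucs) > 0.4 && mean(aucs) < 0.6)
})

test_that("1-se rule picks the largest lambda within one standard error", {
  path <- fake_path(c(1, 0.5, 0.1),
                    rbind(0, 0.1, 0.2),
                    cv_auc_mean = c(0.60, 0.70, 0.72),
                    cv_auc_se = c(0.05, 0.03, 0.02),
                    motif_ids = "m")
  expect_equal(select_lambda_1se(path), 0.5)  # 0.70 >= 0.72 - 0.02

  flat <- fake_path(c(1, 0.5, 0.1), rbind(0, 0, 0),
                    cv_auc_mean = rep(0.7, 3), cv_auc_se = rep(0.01, 3),
                    motif_ids = "m")
  expect_equal(select_lambda_1se(flat), 1)

  sharp <- fake_path(c(1, 0.5, 0.1), rbind(0, 0, 0),
                     cv_auc_mean = c(0.6, 0.65, 0.72), cv_auc_se = rep(0, 3),
                     motif_ids = "m")
  expect_equal(select_lambda_1se(sharp), 0.1)
})

test_that("knowledge rule returns the largest lambda keeping the anchor", {
  coefs <- cbind(anchor = c(0, 0.2, 0.3), other = c(0.1, 0.2, 0.3))
  path <- fake_path(c(1, 0.5, 0.1), coefs, rep(0.7, 3), rep(0.01, 3))
  expect_equal(select_lambda_knowledge(path, "anchor"), 0.5)

  late <- fake_path(c(1, 0.5, 0.1), cbind(anchor = c(0, 0, 0.3)),
                    rep(0.7, 3), rep(0.01, 3))
  expect_equal(select_lambda_knowledge(late, "anchor"), 0.1)

  dead <- fake_path(c(1, 0.5, 0.1), cbind(anchor = c(0, 0, 0)),
                    rep(0.7, 3), rep(0.01, 3))
  expect_error(select_lambda_knowledge(dead, "anchor"), "anchor not informative")

  gappy <- fake_path(c(1, 0.5, 0.1), cbind(anchor = c(0.2, 0, 0.3)),
                     rep(0.7, 3), rep(0.01, 3))
  expect_warning(l <- select_lambda_knowledge(gappy, "anchor"),
                 "non-contiguously")
  expect_equal(l, 1)

  expect_error(select_lambda_knowledge(path, "missing_id"), "not in path")
})

test_that("knowledge rule anchor modes any/all behave as documented", {
  coefs <- cbind(a1 = c(0, 0.2, 0.3), a2 = c(0, 0, 0.1))
  path <- fake_path(c(1, 0.5, 0.1), coefs, rep(0.7, 3), rep(0.01, 3))
  expect_equal(select_lambda_knowledge(path, c("a1", "a2"), mode = "any"), 0.5)
  expect_equal(select_lambda_knowledge(path, c("a1", "a2"), mode = "all"), 0.1)
})

test_that("prediction aligns columns by motif id", {
  m <- fake_model(c(f1 = 1, f2 = -2, f3 = 0))
  x <- matrix(c(1, 0, 2, 1, 0, 1), nrow = 2,
              dimnames = list(NULL, c("f1", "f2", "f3")))
  base_scores <- predict(m, x)
  perm <- x[, c("f3", "f1", "f2")]
  expect_equal(predict(m, perm), base_scores)
  expect_error(predict(m, x[, c("f1", "f2"), drop = FALSE]), "f3")

  const <- fake_model(c(f1 = 0, f2 = 0, f3 = 0))
  expect_equal(predict(const, x), rep(0.5, 2))
})

test_that("confusion counting matches the worked example and a recount oracle", {
  cc <- confusion(c(0.9, 0.2), c("positive", "background"))
  expect_equal(unclass(cc)[c("tp", "fp", "tn", "fn")],
               list(tp = 1L, fp = 0L, tn = 1L, fn = 0L))
  all_pos <- confusion(c(0.9, 0.8), c("positive", "background"))
  expect_equal(all_pos$fn + all_pos$tn, 0L)

  set.seed(23)
  for (i in 1:200) {
    n <- sample(1:50, 1)
    scores <- runif(n)
    labels <- sample(c("positive", "background"), n, replace = TRUE)
    cutoff <- runif(1)
    cc <- confusion(scores, labels, cutoff)
    pred <- scores >= cutoff
    expect_equal(cc$tp, sum(pred & labels == "positive"))
    expect_equal(cc$fp, sum(pred & labels == "background"))
    expect_equal(cc$tn, sum(!pred & labels == "background"))
    expect_equal(cc$fn, sum(!pred & labels == "positive"))
    expect_equal(cc$tp + cc$fp + cc$tn + cc$fn, n)
  }
})

test_that("metric ratios match their definitions with NA sentinels", {
  expect_equal(sensitivity(list(tp = 3, fn = 1)), 0.75)
  expect_equal(specificity(list(tn = 7, fp = 3)), 0.7)
  c0 <- list(tp = 0, fp = 0, tn = 5, fn = 5)
  expect_true(is.na(ppv(c0)))
  expect_true(is.na(fdr(c0)))
  expect_true(is.na(sensitivity(list(tp = 0, fn = 0))))
  expect_true(is.na(specificity(list(tn = 0, fp = 0))))
})

test_that("ROC/AUC handles perfection, ties, and the 3/4-pair example", {
  roc1 <- roc_auc(c(0.9, 0.8, 0.2, 0.1),
                  c("positive", "positive", "background", "background"))
  expect_equal(roc1$auc, 1)
  roc_tie <- roc_auc(rep(0.5, 6), rep(c("positive", "background"), 3))
  expect_equal(roc_tie$auc, 0.5)
  roc34 <- roc_auc(c(0.9, 0.4, 0.6, 0.1),
                   c("positive", "positive", "background", "background"))
  expect_equal(roc34$auc, 0.75)
  expect_error(roc_auc(c(1, 2), c("positive", "positive")), "both classes")
})

test_that("ROC curve runs (0,0) to (1,1), monotone, trapezoid equals AUC", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(6:50, 1)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # forces ties
    labels <- sample(c("positive", "background"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    roc <- roc_auc(scores, labels)
    expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
    expect_equal(roc$fpr[length(roc$fpr)], 1)
    expect_equal(roc$tpr[length(roc$tpr)], 1)
    expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
    trap <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
    expect_equal(trap, roc$auc, tolerance = 1e-12)
  }
})

test_that("comparators separate signal, are seeded, and expose [0,1] scores", {
  fm <- toy_features(80, p_noise = 10, shift = 2.5, seed = 12)
  sp <- train_test_split(fm, 0.75, seed = 3)
  tr <- subset_rows(fm, sp$train); te <- subset_rows(fm, sp$test)
  comp <- fit_comparators(tr, n_folds = 5, n_trees = 200, seed = 8)
  expect_named(comp, c("linear_max_margin", "tree_ensemble"))
  for (m in comp) {
    sc <- predict(m, te)
    expect_true(all(sc >= 0 & sc <= 1))
    expect_gte(roc_auc(sc, te$labels)$auc, 0.9)
  }
  comp2 <- fit_comparators(tr, n_folds = 5, n_trees = 200, seed = 8)
  expect_identical(comp$linear_max_margin$hyperparams$C,
                   comp2$linear_max_margin$hyperparams$C)
  expect_identical(predict(comp$tree_ensemble, te),
                   predict(comp2$tree_ensemble, te))
})

test_that("comparators are near-random on permuted labels", {
  fm <- toy_features(60, p_noise = 8, shift = 2, seed = 5)
  set.seed(77)
  aucs <- replicate(3, {
    fmp <- fm; fmp$labels <- sample(fm$labels)
    sp <- train_test_split(fmp, 0.75, seed = 3)
    tr <- subset_rows(fmp, sp$train); te <- subset_rows(fmp, sp$test)
    comp <- fit_comparators(tr, n_folds = 5, n_trees = 150, seed = 8)
    c(roc_auc(predict(comp$linear_max_margin, te), te$labels)$auc,
      roc_auc(predict(comp$tree_ensemble, te), te$labels)$auc)
  })
  expect_true(all(rowMeans(aucs) > 0.3 & rowMeans(aucs) < 0.7))
})
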