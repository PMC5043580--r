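# Linear max-margin classifier (L2-regularized squared-hinge SVM) fit by
# BFGS on the convex primal. Self-contained because no SVM library is
# assumed; the linear kernel keeps the primal low-dimensional (p + 1).
.svm_fit_one <- function(x, y, C) {
  n <- nrow(x); p <- ncol(x)
  ys <- ifelse(y == 1, 1, -1)
  obj <- function(theta) {
    w <- theta[1:p]; b <- theta[p + 1]
    h <- pmax(0, 1 - ys * (x %*% w + b))
    0.5 * sum(w^2) + C * sum(h^2)
  }
  grad <- function(theta) {
    w <- theta[1:p]; b <- theta[p + 1]
    h <- pmax(0, 1 - ys * as.numeric(x %*% w + b))
    gw <- w - 2 * C * as.numeric(crossprod(x, ys * h))
    gb <- -2 * C * sum(ys * h)
    c(gw, gb)
  }
  fit <- optim(rep(0, p + 1), obj, grad, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-10))
  list(w = fit$par[1:p], b = fit$par[p + 1])
}

.standardize <- function(x, center = NULL, scale = NULL) {
  if (is.null(center)) {
    center <- colMeans(x)
    scale <- apply(x, 2, sd)
    scale[scale == 0] <- 1  # constant columns stay constant (coefficient 0)
  }
  list(x = sweep(sweep(x, 2, center), 2, scale, "/"), center = center, scale = scale)
}

.cv_folds <- function(n, n_folds, seed) {
  with_seed(seed, sample(rep(seq_len(n_folds), length.out = n)))
}

#' Comparator classifiers: linear max-margin and tree ensemble
#'
#' Fits the two reference comparators for the lasso model: a linear-kernel
#' max-margin classifier whose penalty `C` is chosen by cross-validated AUC
#' over a decade grid, and a random forest (default 500 trees, `sqrt(p)`
#' features per split, grown to purity). Both expose \[0, 1\] scores for ROC
#' analysis via [predict.fitted_model()].
#'
#' @param features A labeled `feature_matrix` or numeric matrix.
#' @param labels Class labels (taken from `features` when omitted).
#' @param c_grid Penalty grid for the max-margin classifier.
#' @param n_folds Cross-validation folds for choosing `C`.
#' @param n_trees,mtry Forest size and features per split (`NULL` = sqrt(p)).
#' @param seed Integer seed for folds and forest randomness.
#' @param positive_label Label treated as the positive class.
#' @return Named list of `fitted_model` objects:
#'   `linear_max_margin`, `tree_ensemble`.
#' @export
fit_comparators <- function(features, labels = NULL, c_grid = 10^(-5:0),
                            n_folds = 10, n_trees = 500, mtry = NULL,
                            seed = 1, positive_label = "positive") {
  d <- .as_xy(features, labels, positive_label)
  list(
    linear_max_margin = fit_linear_max_margin(d$x, d$y, c_grid, n_folds, seed),
    tree_ensemble = fit_tree_ensemble(d$x, d$y, n_trees, mtry, seed)
  )
}

fit_linear_max_margin <- function(x, y, c_grid = 10^(-5:0), n_folds = 10, seed = 1) {
  std <- .standardize(x)
  folds <- .cv_folds(nrow(x), n_folds, sub_seed(seed, 11L))
  cv_auc <- vapply(c_grid, function(C) {
    aucs <- vapply(seq_len(n_folds), function(k) {
      tr <- folds != k
      if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2) return(NA_real_)
      f <- .svm_fit_one(std$x[tr, , drop = FALSE], y[tr], C)
      dec <- as.numeric(std$x[!tr, , drop = FALSE] %*% f$w + f$b)
      roc_auc(dec, y[!tr], positive_label = 1)$auc
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))
  C <- c_grid[which.max(cv_auc)]  # first max -> smallest qualifying C
  f <- .svm_fit_one(std$x, y, C)
  dec <- as.numeric(std$x %*% f$w + f$b)
  platt <- .platt_scale(dec, y)
  w_named <- setNames(f$w, colnames(x))
  structure(list(
    kind = "linear_max_margin",
    hyperparams = list(C = C),
    w = f$w, b = f$b, center = std$center, scale = std$scale, platt = platt,
    cv_auc = setNames(cv_auc, c_grid),
    active_features = w_named[w_named != 0],
    motif_ids = colnames(x),
    seed = as.integer(seed)
  ), class = "fitted_model")
}

# Logistic mapping of decision values to [0,1]; falls back to a fixed slope
# when the classes are perfectly separated (glm would diverge).
.platt_scale <- function(dec, y) {
  if (min(dec[y == 1]) > max(dec[y == 0])) return(c(0, 4))
  fit <- suppressWarnings(glm(y ~ dec, family = binomial()))
  c(coef(fit)[1], max(coef(fit)[2], 1e-6))
}

fit_tree_ensemble <- function(x, y, n_trees = 500, mtry = NULL, seed = 1) {
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  forest <- with_seed(sub_seed(seed, 23L),
                      cpp_forest_fit(x, as.integer(y), as.integer(n_trees),
                                     as.integer(mtry), 1L))
  imp <- setNames(as.numeric(forest$importance), colnames(x))
  structure(list(
    kind = "tree_ensemble",
    hyperparams = list(n_trees = n_trees, mtry = mtry),
    forest = forest,
    active_features = sort(imp[imp > 0], decreasing = TRUE),
    motif_ids = colnames(x),
    seed = as.integer(seed)
  ), class = "fitted_model")
}
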