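.as_xy <- function(features, labels = NULL, positive_label = "positive") {
  if (is_feature_matrix(features)) {
    x <- features$values
    if (is.null(labels)) labels <- features$labels
  } else {
    x <- as.matrix(features)
  }
  if (is.null(labels) || any(is.na(labels))) stop("labels are required")
  if (length(unique(labels)) < 2) stop("need two classes to fit a classifier")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  list(x = x, y = as.integer(labels == positive_label), labels = labels)
}

#' L1-regularized logistic regression path with cross-validated AUC
#'
#' Fits a lasso logistic model over a descending penalty grid (default 100
#' log-spaced values from the smallest lambda that zeroes every coefficient
#' down to 0.001 of it) and records the 10-fold cross-validated AUC mean and
#' standard error at every lambda. Features are standardized internally by
#' the fitter; coefficients are reported on the original motifs/kb scale.
#'
#' @param features A labeled `feature_matrix` or numeric matrix.
#' @param labels Class labels (taken from `features` when omitted).
#' @param n_folds Cross-validation folds.
#' @param nlambda Grid size.
#' @param lambda_min_ratio Smallest grid lambda as a fraction of the largest.
#' @param seed Integer seed controlling fold assignment.
#' @param positive_label Label treated as the positive class.
#' @return A `lasso_path`: list with `lambdas` (descending), `coefficients`
#'   (`n_lambda x p`, original scale), `intercepts`, `cv_auc_mean`,
#'   `cv_auc_se`, `n_folds`, `seed`, `motif_ids`.
#' @export
fit_lasso_path <- function(features, labels = NULL, n_folds = 10,
                           nlambda = 100, lambda_min_ratio = 0.001,
                           seed = 1, positive_label = "positive") {
  d <- .as_xy(features, labels, positive_label)
  n <- nrow(d$x)
  if (n < n_folds) stop("fewer rows than folds")
  lmax <- glmnet::glmnet(d$x, d$y, family = "binomial", nlambda = 3,
                         standardize = TRUE)$lambda[1]
  # top of the grid sits just above the empirical lambda_max so the path
  # provably starts from the all-zero model
  grid <- exp(seq(log(lmax * 1.001), log(lmax * lambda_min_ratio),
                  length.out = nlambda))
  foldid <- with_seed(seed, sample(rep(seq_len(n_folds), length.out = n)))
  if (n < 10 * n_folds)
    stop("cross-validated AUC needs >= 10 observations per fold; have ",
         n, " rows for ", n_folds, " folds")
  cv <- glmnet::cv.glmnet(d$x, d$y, family = "binomial", lambda = grid,
                          type.measure = "auc", foldid = foldid,
                          standardize = TRUE, keep = FALSE)
  fit <- cv$glmnet.fit
  keep <- match(round(fit$lambda, 12), round(cv$lambda, 12))
  beta <- t(as.matrix(fit$beta))
  structure(list(
    lambdas = fit$lambda,
    coefficients = beta,
    intercepts = as.numeric(fit$a0),
    cv_auc_mean = cv$cvm[keep],
    cv_auc_se = cv$cvsd[keep],
    n_folds = n_folds,
    seed = as.integer(seed),
    motif_ids = colnames(d$x)
  ), class = "lasso_path")
}

#' @export
print.lasso_path <- function(x, ...) {
  cat(sprintf("Lasso path: %d lambdas in [%.4g, %.4g], %d features, %d-fold CV\n",
              length(x$lambdas), min(x$lambdas), max(x$lambdas),
              ncol(x$coefficients), x$n_folds))
  invisible(x)
}

n_active <- function(path, i) sum(path$coefficients[i, ] != 0)

#' One-standard-error penalty choice
#'
#' The largest lambda whose cross-validated AUC is within one standard error
#' (taken at the AUC maximum) of the maximum; ties resolve to the larger
#' lambda, i.e. the sparser model.
#'
#' @param path A [fit_lasso_path()] result.
#' @return The selected lambda.
#' @export
select_lambda_1se <- function(path) {
  stopifnot(inherits(path, "lasso_path"))
  best <- which.max(path$cv_auc_mean)
  bar <- path$cv_auc_mean[best] - path$cv_auc_se[best]
  path$lambdas[which(path$cv_auc_mean >= bar)[1]]  # lambdas descend
}

#' Knowledge-based (anchor-retention) penalty choice
#'
#' Compresses the model along the path and stops just before the anchor
#' motif(s) would be lost: returns the largest grid lambda at which the
#' anchor condition holds (`mode = "any"`: at least one anchor has a nonzero
#' coefficient; `"all"`: every anchor does). If the condition holds
#' non-contiguously along the path a warning is emitted and the largest
#' qualifying lambda is still returned.
#'
#' @param path A [fit_lasso_path()] result.
#' @param anchors Anchor motif id(s); must be columns of the path.
#' @param mode `"any"` or `"all"`.
#' @return The selected lambda.
#' @export
select_lambda_knowledge <- function(path, anchors, mode = c("any", "all")) {
  stopifnot(inherits(path, "lasso_path"))
  mode <- match.arg(mode)
  missing <- setdiff(anchors, path$motif_ids)
  if (length(missing))
    stop("anchor motif(s) not in path: ", paste(missing, collapse = ", "))
  nz <- path$coefficients[, anchors, drop = FALSE] != 0
  holds <- if (mode == "any") rowSums(nz) > 0 else rowSums(nz) == length(anchors)
  if (!any(holds)) stop("anchor not informative: condition never holds on the path")
  first <- which(holds)[1]
  if (any(!holds[seq(first, length(holds))]))
    warning("anchor condition holds non-contiguously along the path; ",
            "returning the largest qualifying lambda")
  path$lambdas[first]
}

#' Sparse model at a chosen penalty
#'
#' @param path A [fit_lasso_path()] result.
#' @param lambda A lambda on the path grid (nearest grid point is used).
#' @return A `fitted_model` of kind `"lasso"` whose `active_features` are
#'   exactly the nonzero-coefficient motifs at that lambda.
#' @export
lasso_model <- function(path, lambda) {
  stopifnot(inherits(path, "lasso_path"))
  i <- which.min(abs(path$lambdas - lambda))
  beta <- path$coefficients[i, ]
  structure(list(
    kind = "lasso",
    hyperparams = list(lambda = path$lambdas[i]),
    intercept = path$intercepts[i],
    coefficients = beta,
    active_features = beta[beta != 0],
    motif_ids = path$motif_ids,
    seed = path$seed
  ), class = "fitted_model")
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf("FittedModel (%s): %d active features; hyperparams: %s\n",
              x$kind, length(x$active_features),
              paste(names(x$hyperparams), signif(unlist(x$hyperparams), 4),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Predict class-probability scores
#'
#' Scores rows of a feature matrix with a fitted model. Columns are aligned
#' to the model's training motif ids by name, so column order is irrelevant;
#' a missing column is an error.
#'
#' @param object A `fitted_model`.
#' @param features A `feature_matrix` or numeric matrix with named columns.
#' @param ... Unused.
#' @return Numeric scores in \[0, 1\], one per row.
#' @export
predict.fitted_model <- function(object, features, ...) {
  x <- if (is_feature_matrix(features)) features$values else as.matrix(features)
  missing <- setdiff(object$motif_ids, colnames(x))
  if (length(missing))
    stop("feature column(s) missing: ", paste(head(missing, 5), collapse = ", "))
  x <- x[, object$motif_ids, drop = FALSE]
  switch(object$kind,
    lasso = as.numeric(plogis(object$intercept + x %*% object$coefficients)),
    linear_max_margin = {
      xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
      dec <- as.numeric(xs %*% object$w + object$b)
      as.numeric(plogis(object$platt[1] + object$platt[2] * dec))
    },
    tree_ensemble = as.numeric(cpp_forest_predict(object$forest, x)),
    stop("unknown model kind: ", object$kind))
}
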