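#' Featurizer context
#'
#' Bundles the motif library and scanning settings so different peak sets
#' are featurized identically (same columns, same threshold, same
#' background), as required when a model trained on one experiment scores
#' peaks from another.
#'
#' @param pwms List of [pwm()] objects.
#' @param background A [background_model()], or `NULL` to estimate from the
#'   sequences of each featurized set. When peak sets are to be *compared*
#'   (positives vs background, replicate vs replicate), always pass one
#'   shared model: near-threshold window scores are knife-edge sensitive to
#'   background frequencies, and per-set estimation can flip large numbers
#'   of borderline windows across the cutoff in one set but not the other,
#'   manufacturing spurious class differences.
#' @param threshold Scan threshold in bits.
#' @param pseudocount Per-cell PWM pseudocount.
#' @return A `featurizer` context.
#' @export
featurizer <- function(pwms, background = NULL, threshold = 6, pseudocount = 0) {
  structure(list(pwms = pwms, background = background, threshold = threshold,
                 pseudocount = pseudocount), class = "featurizer")
}

#' Featurize peaks into a normalized feature matrix
#'
#' @param peaks A [peak_set()].
#' @param genome Genome FASTA path, named character vector, or
#'   `DNAStringSet` (see [extract_sequences()]).
#' @param ftz A [featurizer()].
#' @param label Class label for the rows.
#' @return A normalized (motifs/kb) `feature_matrix`.
#' @export
featurize <- function(peaks, genome, ftz, label = NA_character_) {
  stopifnot(inherits(ftz, "featurizer"))
  seqs <- extract_sequences(peaks, genome)
  cm <- count_matrix(peaks, seqs, ftz$pwms, background = ftz$background,
                     threshold = ftz$threshold, pseudocount = ftz$pseudocount,
                     label = label)
  normalize_per_kb(cm)
}

#' Cross-prediction rate of a model on a foreign peak set
#'
#' Fraction of the peaks a trained classifier scores at or above the cutoff
#' — the model-based concordance measure that replaces raw coordinate
#' overlap when comparing replicate experiments.
#'
#' @param model A `fitted_model`.
#' @param peaks A [peak_set()] (e.g. the other replicate's peaks).
#' @param genome Genome for sequence extraction.
#' @param ftz The [featurizer()] the model was trained with.
#' @param cutoff Positive-prediction cutoff.
#' @return Proportion in \[0, 1\].
#' @export
cross_predict_rate <- function(model, peaks, genome, ftz, cutoff = 0.5) {
  if (length(peaks) == 0) stop("empty peak set")
  fm <- featurize(peaks, genome, ftz)
  mean(predict(model, fm) >= cutoff)
}

#' Positive-prediction rates over an overlap partition
#'
#' Applies one experiment's model to the unique/shared subsets (`A`, `B1`,
#' `B2`, `C`) of two replicate peak sets and reports per-subset positive
#' rates. Empty subsets get an `NA` rate.
#'
#' @param model A `fitted_model`.
#' @param partition An [partition_overlap()] result.
#' @param genome Genome for sequence extraction.
#' @param ftz The model's [featurizer()].
#' @param cutoff Positive-prediction cutoff.
#' @param trained_on Provenance tag recorded in the report.
#' @return A `concordance_report`: per-subset `n` and `rate`, plus cutoff
#'   and provenance.
#' @export
subset_prediction_rates <- function(model, partition, genome, ftz,
                                    cutoff = 0.5, trained_on = "set1") {
  stopifnot(inherits(partition, "overlap_partition"))
  subsets <- c("A", "B1", "B2", "C")
  rates <- lapply(subsets, function(s) {
    ps <- partition[[s]]
    if (length(ps) == 0) return(list(n = 0L, rate = NA_real_))
    fm <- featurize(ps, genome, ftz)
    list(n = length(ps), rate = mean(predict(model, fm) >= cutoff))
  })
  names(rates) <- subsets
  structure(list(subsets = rates, cutoff = cutoff, trained_on = trained_on),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("Concordance (model trained on %s, cutoff %.2f):\n",
              x$trained_on, x$cutoff))
  for (s in names(x$subsets))
    cat(sprintf("  %s: n=%d rate=%s\n", s, x$subsets[[s]]$n,
                format(x$subsets[[s]]$rate, digits = 4)))
  invisible(x)
}

#' Direct-contrast model between two experiments
#'
#' Labels peaks by experiment of origin (instead of peak versus background)
#' and reuses the standard split/fit machinery. Near-random held-out AUC
#' indicates the two experiments share motif grammar.
#'
#' @param peaks1,peaks2 [peak_set()] objects from the two experiments.
#' @param genome Genome for sequence extraction.
#' @param ftz A [featurizer()].
#' @param fraction Train proportion.
#' @param n_folds CV folds for the lasso path.
#' @param seed Integer seed.
#' @param anchors Optional anchor motif id(s); if supplied the
#'   knowledge-based rule selects the penalty, otherwise the 1-s.e. rule.
#' @return List with `model` (a `fitted_model`), `auc` (held-out test AUC)
#'   and `path`.
#' @export
direct_contrast_model <- function(peaks1, peaks2, genome, ftz,
                                  fraction = 0.75, n_folds = 10, seed = 1,
                                  anchors = NULL) {
  key1 <- paste(peaks1$intervals$chrom, peaks1$intervals$start, peaks1$intervals$end)
  key2 <- paste(peaks2$intervals$chrom, peaks2$intervals$start, peaks2$intervals$end)
  if (setequal(key1, key2))
    stop("the two experiments have identical peak sets; ",
         "direct contrast would duplicate every row across classes")
  fm1 <- featurize(peaks1, genome, ftz)
  fm2 <- featurize(peaks2, genome, ftz)
  fm1$labels <- rep("positive", length(fm1$labels))    # experiment 1 as "positive"
  fm2$labels <- rep("background", length(fm2$labels))
  stacked <- stack_labeled(fm1, fm2)
  split <- train_test_split(stacked, fraction, seed = sub_seed(seed, 31L))
  train <- subset_rows(stacked, split$train)
  test <- subset_rows(stacked, split$test)
  path <- fit_lasso_path(train, n_folds = n_folds, seed = sub_seed(seed, 32L))
  lambda <- if (is.null(anchors)) select_lambda_1se(path)
            else select_lambda_knowledge(path, anchors)
  model <- lasso_model(path, lambda)
  auc <- roc_auc(predict(model, test), test$labels)$auc
  list(model = model, auc = auc, path = path)
}

#' Active-feature overlap between two models
#'
#' @param m1,m2 `fitted_model` objects.
#' @return A `feature_overlap`: feature id sets, their intersection and the
#'   Jaccard index.
#' @export
model_feature_overlap <- function(m1, m2) {
  f1 <- names(m1$active_features); f2 <- names(m2$active_features)
  inter <- intersect(f1, f2)
  un <- union(f1, f2)
  structure(list(features_1 = f1, features_2 = f2, intersection = inter,
                 jaccard = if (length(un)) length(inter) / length(un) else NA_real_),
            class = "feature_overlap")
}

#' @export
print.feature_overlap <- function(x, ...) {
  cat(sprintf("Feature overlap: |f1|=%d |f2|=%d |intersection|=%d jaccard=%.3f\n",
              length(x$features_1), length(x$features_2),
              length(x$intersection), x$jaccard))
  invisible(x)
}
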