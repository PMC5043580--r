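# Shared synthetic-data machinery for the acceptance battery. Heavy per-seed
# computations run once and only small summaries are cached, so several
# acceptance criteria can share the same 10-seed protocol.

.acc_cache <- new.env(parent = emptyenv())

acc_background <- function() background_model(c(0.29, 0.21, 0.21, 0.29))

# One seed of the default strong-signal protocol: simulate, featurize,
# train replicate-1 vs background, select by both rules, evaluate held out,
# cross-predict replicate 2, score the overlap partition, fit the
# direct-contrast model. Returns a one-row data.frame of summaries.
acc_run_seed <- function(seed) {
  cfg <- synthetic_config(seed = seed)
  ds <- simulate_peaks(cfg)
  ftz <- featurizer(cfg$motifs$all, background = acc_background())
  fm_pos <- featurize(ds$rep1, ds$genome, ftz, label = "positive")
  fm_bg <- featurize(ds$background, ds$genome, ftz, label = "background")
  stacked <- stack_labeled(fm_pos, fm_bg)
  split <- train_test_split(stacked, 0.75, seed = sub_seed_t(seed, 1))
  train <- subset_rows(stacked, split$train)
  test <- subset_rows(stacked, split$test)
  path <- fit_lasso_path(train, n_folds = 10, seed = sub_seed_t(seed, 2))
  lambda_1se <- select_lambda_1se(path)
  lambda_k <- suppressWarnings(select_lambda_knowledge(path, "anchor_NKE"))
  model_k <- lasso_model(path, lambda_k)
  model_1se <- lasso_model(path, lambda_1se)
  active <- names(model_k$active_features)
  ev <- evaluate_scores(predict(model_k, test), test$labels)

  cross_rate <- cross_predict_rate(model_1se, ds$rep2, ds$genome, ftz)
  part <- partition_overlap(ds$rep1, ds$rep2)
  rates <- subset_prediction_rates(model_1se, part, ds$genome, ftz)
  dc <- direct_contrast_model(ds$rep1, ds$rep2, ds$genome, ftz,
                              seed = sub_seed_t(seed, 3))

  data.frame(
    seed = seed,
    auc_k = ev$auc,
    anchor_active = "anchor_NKE" %in% active,
    n_cof_active = sum(grepl("^cofactor_", active)),
    decoy_frac = sum(grepl("^decoy_", active)) / max(1, length(active)),
    n_active_k = length(model_k$active_features),
    n_active_1se = length(model_1se$active_features),
    lambda_k = lambda_k, lambda_1se = lambda_1se,
    cross_rate = cross_rate,
    rate_A = rates$subsets$A$rate, rate_B1 = rates$subsets$B1$rate,
    rate_B2 = rates$subsets$B2$rate, rate_C = rates$subsets$C$rate,
    nA = rates$subsets$A$n, nB1 = rates$subsets$B1$n,
    nB2 = rates$subsets$B2$n, nC = rates$subsets$C$n,
    n_rep1 = length(ds$rep1), n_rep2 = length(ds$rep2),
    direct_auc = dc$auc)
}

# test-local sub-seed helper (mirrors the package-internal convention)
sub_seed_t <- function(seed, k) (seed %% 100000L) * 131L + k * 17L + 5L

acceptance_battery <- function(seeds = 1:10) {
  key <- paste(seeds, collapse = ",")
  if (is.null(.acc_cache[[key]]))
    .acc_cache[[key]] <- do.call(rbind, lapply(seeds, acc_run_seed))
  .acc_cache[[key]]
}

# Labeled per-kb feature matrix for one seed (cached); used by the null
# calibration criterion and smaller unit checks.
acc_features <- function(seed = 1) {
  key <- paste0("fm", seed)
  if (is.null(.acc_cache[[key]])) {
    cfg <- synthetic_config(seed = seed)
    ds <- simulate_peaks(cfg)
    ftz <- featurizer(cfg$motifs$all, background = acc_background())
    .acc_cache[[key]] <- stack_labeled(
      featurize(ds$rep1, ds$genome, ftz, label = "positive"),
      featurize(ds$background, ds$genome, ftz, label = "background"))
  }
  .acc_cache[[key]]
}

# Small labeled matrix with one informative feature; cheap stand-in for a
# full simulation in classifier unit tests.
toy_features <- function(n_per_class = 60, p_noise = 15, shift = 1.5,
                         seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- matrix(rnorm(n * (p_noise + 1)), nrow = n)
  colnames(x) <- c("signal", paste0("noise", seq_len(p_noise)))
  labels <- rep(c("positive", "background"), each = n_per_class)
  x[labels == "positive", "signal"] <- x[labels == "positive", "signal"] + shift
  rownames(x) <- paste0("r", seq_len(n))
  structure(list(values = x, peak_ids = rownames(x),
                 motif_ids = colnames(x), labels = labels,
                 lengths = rep(1000, n), normalized = TRUE),
            class = "feature_matrix")
}
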