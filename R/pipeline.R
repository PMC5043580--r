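#' Pipeline run configuration
#'
#' @param peaks_bed Positive peaks (BED).
#' @param genome_fasta Genome sequence (FASTA).
#' @param pwm_file Motif library file (see [read_pwm_library()]).
#' @param allowed_bed Regions background peaks may occupy (BED).
#' @param anchor Anchor motif id(s); required for the knowledge rule.
#' @param pwm_format Motif library format (`"auto"` by extension).
#' @param threshold Scan threshold in bits.
#' @param split_fraction Train proportion.
#' @param n_folds Cross-validation folds.
#' @param selection `"1se"` or `"knowledge"`.
#' @param cutoff Positive-prediction cutoff for confusion metrics.
#' @param known_ppis Motif ids with known protein interactions (annotation
#'   only).
#' @param seed Integer seed (mandatory) for background placement, the
#'   train/test split and CV folds.
#' @param out_dir Output directory for reports.
#' @return A validated `run_config`.
#' @export
run_config <- function(peaks_bed, genome_fasta, pwm_file, allowed_bed,
                       anchor = NULL, pwm_format = "auto", threshold = 6,
                       split_fraction = 0.75, n_folds = 10,
                       selection = c("1se", "knowledge"), cutoff = 0.5,
                       known_ppis = character(0), seed, out_dir) {
  selection <- match.arg(selection)
  if (missing(seed)) stop("`seed` is mandatory")
  if (selection == "knowledge" && is.null(anchor))
    stop("knowledge-based selection requires an anchor motif id")
  for (f in c(peaks_bed, genome_fasta, pwm_file, allowed_bed))
    if (!file.exists(f)) stop("input file not found: ", f)
  structure(list(peaks_bed = peaks_bed, genome_fasta = genome_fasta,
                 pwm_file = pwm_file, allowed_bed = allowed_bed,
                 anchor = anchor, pwm_format = pwm_format,
                 threshold = threshold, split_fraction = split_fraction,
                 n_folds = n_folds, selection = selection, cutoff = cutoff,
                 known_ppis = known_ppis, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

#' Run the full classification pipeline
#'
#' Executes partition -> matched random background -> scan/normalize ->
#' train -> penalty selection -> evaluation -> co-occurrence -> candidate
#' ranking, writing every report to `config$out_dir`: `model.json`,
#' `roc.tsv`, `metrics.json`, `cv_path.tsv`, `cooccurrence.tsv`,
#' `anchor_exclusive.tsv` (when an anchor is given), `candidates.tsv`,
#' `background.bed` and `run_log.txt`. Reruns with the same config and seed
#' produce identical metrics and model JSON (numbers serialized at 12
#' significant digits).
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the fitted `model`, `path`, `metrics`,
#'   `candidates` and output `dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("motifgrammar %s | R %s",
                         as.character(utils::packageVersion("motifgrammar")),
                         paste(R.version$major, R.version$minor, sep = ".")),
                 sprintf("seed: %d", config$seed))
  log_cfg <- config[!(names(config) %in% "known_ppis")]
  log_lines <- c(log_lines, sprintf("%s: %s", names(log_cfg),
                                    vapply(log_cfg, function(v)
                                      paste(format(v), collapse = ","), character(1))))

  pwms <- .stage("load_motifs",
                 read_pwm_library(config$pwm_file, config$pwm_format))
  if (!is.null(config$anchor)) {
    ids <- vapply(pwms, `[[`, character(1), "id")
    missing <- setdiff(config$anchor, ids)
    if (length(missing))
      stop("stage 'load_motifs': anchor motif(s) not in library: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  peaks <- .stage("read_peaks", read_bed(config$peaks_bed, "positives"))
  allowed <- .stage("read_allowed", read_bed(config$allowed_bed, "allowed"))
  bg_peaks <- .stage("background",
                     generate_random_peaks(peaks, allowed,
                                           seed = sub_seed(config$seed, 1L)))
  write_bed(bg_peaks, file.path(config$out_dir, "background.bed"))

  genome <- .stage("genome", Biostrings::readDNAStringSet(config$genome_fasta))
  pos_seqs <- .stage("sequences", extract_sequences(peaks, genome))
  bg_seqs <- .stage("sequences", extract_sequences(bg_peaks, genome))
  background <- background_from_sequences(c(pos_seqs, bg_seqs))
  ftz <- featurizer(pwms, background = background, threshold = config$threshold)

  counts_pos <- .stage("scan", count_matrix(peaks, pos_seqs, pwms,
                                            background, config$threshold,
                                            label = "positive"))
  counts_bg <- .stage("scan", count_matrix(bg_peaks, bg_seqs, pwms,
                                           background, config$threshold,
                                           label = "background"))
  stacked <- .stage("normalize",
                    stack_labeled(normalize_per_kb(counts_pos),
                                  normalize_per_kb(counts_bg)))
  split <- .stage("split", train_test_split(stacked, config$split_fraction,
                                            seed = sub_seed(config$seed, 2L)))
  train <- subset_rows(stacked, split$train)
  test <- subset_rows(stacked, split$test)

  path <- .stage("train", fit_lasso_path(train, n_folds = config$n_folds,
                                         seed = sub_seed(config$seed, 3L)))
  lambda_1se <- select_lambda_1se(path)
  lambda <- .stage("select",
                   if (config$selection == "knowledge")
                     select_lambda_knowledge(path, config$anchor)
                   else lambda_1se)
  model <- lasso_model(path, lambda)

  metrics <- .stage("evaluate",
                    evaluate_scores(predict(model, test), test$labels,
                                    cutoff = config$cutoff))
  roc_df <- data.frame(threshold = metrics$roc$thresholds,
                       fpr = metrics$roc$fpr, tpr = metrics$roc$tpr)
  write_tsv(roc_df, file.path(config$out_dir, "roc.tsv"))
  write_tsv(data.frame(lambda = path$lambdas,
                       cv_auc_mean = path$cv_auc_mean,
                       cv_auc_se = path$cv_auc_se,
                       n_active = rowSums(path$coefficients != 0)),
            file.path(config$out_dir, "cv_path.tsv"))

  metrics_json <- round_sig(list(
    auc = metrics$auc, sensitivity = metrics$sensitivity,
    specificity = metrics$specificity, ppv = metrics$ppv, fdr = metrics$fdr,
    cutoff = config$cutoff,
    confusion = unclass(metrics$confusion),
    n_train = length(split$train), n_test = length(split$test)))
  jsonlite::write_json(metrics_json, file.path(config$out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  model_json <- round_sig(list(
    kind = model$kind, selection = config$selection,
    lambda = model$hyperparams$lambda, lambda_1se = lambda_1se,
    n_active = length(model$active_features),
    active_features = as.list(model$active_features),
    intercept = model$intercept, seed = config$seed))
  jsonlite::write_json(model_json, file.path(config$out_dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)

  cooc <- .stage("cooccur", {
    presence <- binarize(counts_pos)
    motifs <- union(names(model$active_features), config$anchor %||% character(0))
    if (length(motifs) >= 1) cooccurrence_matrix(presence, motifs) else NULL
  })
  if (!is.null(cooc)) {
    write_tsv(data.frame(motif_id = rownames(cooc$matrix), cooc$matrix,
                         check.names = FALSE),
              file.path(config$out_dir, "cooccurrence.tsv"))
  }
  candidates <- NULL
  if (!is.null(config$anchor)) {
    excl <- .stage("cooccur",
                   anchor_exclusive_fraction(binarize(counts_pos),
                                             config$anchor[1]))
    write_tsv(data.frame(motif_id = names(excl$fractions),
                         exclusive_fraction = as.numeric(excl$fractions)),
              file.path(config$out_dir, "anchor_exclusive.tsv"))
    candidates <- .stage("candidates",
                         rank_candidates(model, excl, config$known_ppis))
    write_tsv(candidates, file.path(config$out_dir, "candidates.tsv"))
  }

  log_lines <- c(log_lines,
                 sprintf("lambda_1se: %.6g | lambda_selected: %.6g (%s rule)",
                         lambda_1se, lambda, config$selection),
                 sprintf("active features: %d", length(model$active_features)),
                 sprintf("test AUC: %.4f | sensitivity: %.4f | specificity: %.4f | PPV: %.4f | FDR: %.4f",
                         metrics$auc, metrics$sensitivity, metrics$specificity,
                         metrics$ppv, metrics$fdr))
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))

  invisible(list(model = model, path = path, metrics = metrics,
                 candidates = candidates, featurizer = ftz,
                 background_peaks = bg_peaks, split = split,
                 dir = config$out_dir))
}
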