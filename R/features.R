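#' Motif-count feature matrix
#'
#' Builds the peaks x motifs table of raw hit counts (both strands) that,
#' after [normalize_per_kb()], becomes the motifs-per-kilobase feature
#' matrix used for classification.
#'
#' @param peaks A [peak_set()].
#' @param sequences Named character vector of peak sequences (names must
#'   cover every peak), e.g. from [extract_sequences()].
#' @param pwms List of [pwm()] objects with unique ids.
#' @param background A [background_model()]; `NULL` pools zero-order
#'   frequencies from `sequences`.
#' @param threshold Per-instance score cutoff in bits.
#' @param pseudocount Per-cell PWM pseudocount used during scoring.
#' @param label Class label attached to every row (`"positive"`,
#'   `"background"`, or `NA` to leave unlabeled).
#' @return A `feature_matrix`: list with `values` (numeric matrix),
#'   `peak_ids`, `motif_ids`, `labels`, `lengths` (bp) and `normalized` flag.
#' @export
count_matrix <- function(peaks, sequences, pwms, background = NULL,
                         threshold = 6, pseudocount = 0, label = NA_character_) {
  stopifnot(is_peak_set(peaks))
  if (is_pwm(pwms)) pwms <- list(pwms)
  motif_ids <- vapply(pwms, `[[`, character(1), "id")
  if (anyDuplicated(motif_ids)) stop("duplicate PWM ids")
  ids <- peaks$intervals$name
  missing <- setdiff(ids, names(sequences))
  if (length(missing)) stop("no sequence for peak '", missing[1], "'")
  seqs <- sequences[ids]
  if (is.null(background)) background <- background_from_sequences(seqs)
  codes <- lapply(seqs, encode_dna)
  mats <- lapply(pwms, .ll_matrices, background = background, pseudocount = pseudocount)
  values <- matrix(0L, nrow = length(ids), ncol = length(motif_ids),
                   dimnames = list(ids, motif_ids))
  for (j in seq_along(pwms)) {
    llf <- mats[[j]]$fwd; llr <- mats[[j]]$rev
    values[, j] <- vapply(codes, cpp_count_hits, integer(1),
                          ll = llf, llm = llr, threshold = threshold)
  }
  new_feature_matrix(values, labels = rep(label, length(ids)),
                     lengths = peak_lengths(peaks), normalized = FALSE)
}

new_feature_matrix <- function(values, labels, lengths, normalized) {
  structure(list(values = values,
                 peak_ids = rownames(values),
                 motif_ids = colnames(values),
                 labels = labels,
                 lengths = lengths,
                 normalized = normalized),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("FeatureMatrix: %d peaks x %d motifs (%s)%s\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "motifs/kb" else "raw counts",
              if (all(is.na(x$labels))) "" else
                paste0("; labels: ", paste(names(table(x$labels)),
                                           table(x$labels), collapse = ", "))))
  invisible(x)
}

is_feature_matrix <- function(x) inherits(x, "feature_matrix")

#' Normalize counts to motifs per kilobase
#'
#' @param matrix A raw-count `feature_matrix` from [count_matrix()].
#' @param lengths Per-peak lengths in bp (defaults to those recorded at
#'   counting time).
#' @return A `feature_matrix` with `normalized = TRUE`.
#' @export
normalize_per_kb <- function(matrix, lengths = matrix$lengths) {
  stopifnot(is_feature_matrix(matrix))
  if (matrix$normalized) stop("matrix is already normalized")
  if (is.null(lengths) || length(lengths) != nrow(matrix$values))
    stop("need one length per peak")
  if (any(lengths <= 0)) stop("peak lengths must be > 0")
  values <- matrix$values / (lengths / 1000)
  new_feature_matrix(values, matrix$labels, lengths, normalized = TRUE)
}

#' Stack positive and background matrices with class labels
#'
#' @param positive,background `feature_matrix` objects over identical motif
#'   columns (same ids, same order) and the same normalization state.
#' @return A labeled `feature_matrix` with rows `positive` then `background`.
#' @export
stack_labeled <- function(positive, background) {
  stopifnot(is_feature_matrix(positive), is_feature_matrix(background))
  if (nrow(background$values) == 0) stop("background matrix is empty; cannot train")
  if (nrow(positive$values) == 0) stop("positive matrix is empty; cannot train")
  if (!identical(positive$motif_ids, background$motif_ids))
    stop("motif columns differ between positive and background matrices")
  if (positive$normalized != background$normalized)
    stop("normalization state differs between matrices")
  values <- rbind(positive$values, background$values)
  rownames(values) <- make.unique(c(positive$peak_ids, background$peak_ids), sep = "_")
  new_feature_matrix(
    values,
    labels = rep(c("positive", "background"),
                 c(nrow(positive$values), nrow(background$values))),
    lengths = c(positive$lengths, background$lengths),
    normalized = positive$normalized)
}

#' Stratified train/test split
#'
#' Rows are split independently within each class so both partitions
#' preserve class proportions (within one row per class).
#'
#' @param matrix A labeled `feature_matrix`.
#' @param fraction Training proportion in (0, 1).
#' @param seed Integer seed; identical seeds give identical indices.
#' @return A `data_split`: list with sorted integer `train` and `test` row
#'   indices plus `fraction` and `seed`.
#' @export
train_test_split <- function(matrix, fraction = 0.75, seed) {
  stopifnot(is_feature_matrix(matrix))
  if (any(is.na(matrix$labels))) stop("matrix rows must be labeled")
  if (fraction <= 0 || fraction >= 1) stop("`fraction` must be in (0, 1)")
  classes <- split(seq_along(matrix$labels), matrix$labels)
  bad <- names(classes)[lengths(classes) < 4L]
  if (length(bad)) stop("class '", bad[1], "' has fewer than 4 rows")
  train <- with_seed(seed, {
    unlist(lapply(classes, function(idx) {
      n_train <- round(fraction * length(idx))
      if (n_train < 1L || n_train >= length(idx))
        stop("fraction ", fraction, " leaves an empty train or test set")
      sort(sample(idx, n_train))
    }), use.names = FALSE)
  })
  structure(list(train = sort(train),
                 test = setdiff(seq_along(matrix$labels), train),
                 fraction = fraction, seed = as.integer(seed)),
            class = "data_split")
}

#' Row-subset of a feature matrix
#'
#' @param matrix A `feature_matrix`.
#' @param idx Row indices.
#' @return A `feature_matrix` with the selected rows.
#' @export
subset_rows <- function(matrix, idx) {
  stopifnot(is_feature_matrix(matrix))
  new_feature_matrix(matrix$values[idx, , drop = FALSE],
                     matrix$labels[idx], matrix$lengths[idx],
                     matrix$normalized)
}

#' Write / read a feature matrix as TSV
#'
#' The TSV carries a `peak_id` column, a `label` column, a `length_bp`
#' column and one column per motif; [read_feature_matrix()] round-trips it.
#'
#' @param matrix A `feature_matrix`.
#' @param path Output file.
#' @return `path` (write) or a `feature_matrix` (read).
#' @export
write_feature_matrix <- function(matrix, path) {
  stopifnot(is_feature_matrix(matrix))
  df <- data.frame(peak_id = matrix$peak_ids, label = matrix$labels,
                   length_bp = matrix$lengths,
                   normalized = matrix$normalized,
                   matrix$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  meta <- c("peak_id", "label", "length_bp", "normalized")
  values <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  rownames(values) <- df$peak_id
  new_feature_matrix(values, labels = df$label, lengths = df$length_bp,
                     normalized = df$normalized[1])
}
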