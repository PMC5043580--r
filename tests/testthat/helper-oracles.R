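# Independent oracles and small random-object factories used across tests.

random_pwm <- function(width = sample(4:10, 1), id = "rnd") {
  m <- matrix(runif(width * 4, 0.01, 1), nrow = width)
  pwm(id, m / rowSums(m))
}

random_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

revcomp_str <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# Brute-force both-strand scanner: scores every window via the scalar
# log-likelihood function; minus-strand score is the score of the window's
# reverse complement.
oracle_scan <- function(p, sequence, background, threshold) {
  w <- p$width
  L <- nchar(sequence)
  out <- data.frame(motif_id = character(0), position = integer(0),
                    strand = character(0), score = numeric(0))
  if (L < w) return(out)
  rows <- list()
  for (i in 0:(L - w)) {
    win <- substr(sequence, i + 1, i + w)
    sf <- log_likelihood_score(p, win, background)
    sr <- log_likelihood_score(p, revcomp_str(win), background)
    if (is.finite(sf) && sf >= threshold)
      rows[[length(rows) + 1]] <- data.frame(motif_id = p$id, position = i,
                                             strand = "+", score = sf)
    if (is.finite(sr) && sr >= threshold)
      rows[[length(rows) + 1]] <- data.frame(motif_id = p$id, position = i,
                                             strand = "-", score = sr)
  }
  if (!length(rows)) return(out)
  hits <- do.call(rbind, rows)
  hits <- hits[order(hits$position, hits$strand), ]
  rownames(hits) <- NULL
  hits
}

# Pair-counting Mann-Whitney AUC (ties count one half).
oracle_auc <- function(scores, labels, positive_label = "positive") {
  pos <- scores[labels == positive_label]
  neg <- scores[labels != positive_label]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

random_peaks <- function(n, chroms = c("chr1", "chr2"), max_start = 5000,
                         max_len = 300, set_name = "rnd") {
  start <- sample.int(max_start, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  peak_set(sample(chroms, n, replace = TRUE), start, start + len,
           set_name = set_name)
}

fake_model <- function(coefs) {
  structure(list(kind = "lasso", hyperparams = list(lambda = 0.1),
                 intercept = 0, coefficients = coefs,
                 active_features = coefs[coefs != 0],
                 motif_ids = names(coefs)),
            class = "fitted_model")
}

fake_path <- function(lambdas, coefficients, cv_auc_mean, cv_auc_se,
                      motif_ids = colnames(coefficients)) {
  structure(list(lambdas = lambdas, coefficients = coefficients,
                 intercepts = rep(0, length(lambdas)),
                 cv_auc_mean = cv_auc_mean, cv_auc_se = cv_auc_se,
                 n_folds = 10, seed = 1L, motif_ids = motif_ids),
            class = "lasso_path")
}
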