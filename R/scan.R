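# log2 likelihood-ratio matrices for both strands.
# Minus-strand matrix: llm[j, b] = ll[w + 1 - j, comp(b)], i.e. the window is
# read as its reverse complement, so hit counts are invariant under
# reverse-complementing the scanned sequence.
.ll_matrices <- function(x, background, pseudocount) {
  probs <- adjust_probs(x$probs, pseudocount)
  bg <- as.numeric(background)
  ll <- log2(sweep(probs, 2, bg, "/"))
  llm <- ll[rev(seq_len(nrow(ll))), c(4L, 3L, 2L, 1L), drop = FALSE]
  list(fwd = ll, rev = llm)
}

#' Scan a sequence for motif hits
#'
#' Scores every window of `x$width` on both strands with the log2
#' likelihood-ratio score and reports windows at or above `threshold` (the
#' per-instance cutoff; default 6 bits). Windows containing non-ACGT bases
#' are skipped. By default all hits are kept, including overlapping ones;
#' `merge_overlaps = TRUE` greedily keeps the highest-scoring hit and drops
#' any hit of the same motif overlapping an already kept one.
#'
#' @param x A [pwm()].
#' @param sequence DNA string.
#' @param background A [background_model()]; `NULL` estimates zero-order
#'   frequencies from `sequence` itself via [background_from_sequences()].
#' @param threshold Minimum score in bits.
#' @param pseudocount Per-cell probability pseudocount (see
#'   [log_likelihood_score()]).
#' @param merge_overlaps Suppress overlapping hits of this motif.
#' @return `data.frame(motif_id, position, strand, score)`; `position` is the
#'   0-based offset of the window start on the forward sequence.
#' @export
scan_sequence <- function(x, sequence, background = NULL, threshold = 6,
                          pseudocount = 0, merge_overlaps = FALSE) {
  stopifnot(is_pwm(x))
  if (is.null(background)) background <- background_from_sequences(sequence)
  codes <- encode_dna(sequence)
  empty <- data.frame(motif_id = character(0), position = integer(0),
                      strand = character(0), score = numeric(0))
  if (length(codes) < x$width) return(empty)
  m <- .ll_matrices(x, background, pseudocount)
  sf <- cpp_window_scores(codes, m$fwd)
  sr <- cpp_window_scores(codes, m$rev)
  keep_f <- which(is.finite(sf) & sf >= threshold)
  keep_r <- which(is.finite(sr) & sr >= threshold)
  hits <- data.frame(
    motif_id = rep(x$id, length(keep_f) + length(keep_r)),
    position = c(keep_f, keep_r) - 1L,
    strand = rep(c("+", "-"), c(length(keep_f), length(keep_r))),
    score = c(sf[keep_f], sr[keep_r]),
    stringsAsFactors = FALSE)
  hits <- hits[order(hits$position, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  if (merge_overlaps && nrow(hits) > 1) hits <- .merge_hits(hits, x$width)
  hits
}

.merge_hits <- function(hits, width) {
  ord <- order(-hits$score, hits$position)
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) ||
        all(abs(hits$position[kept] - hits$position[i]) >= width))
      kept <- c(kept, i)
  }
  out <- hits[sort(kept), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count motif hits in a sequence (both strands)
#'
#' @inheritParams scan_sequence
#' @return Integer hit count.
#' @export
count_hits <- function(x, sequence, background, threshold = 6, pseudocount = 0) {
  stopifnot(is_pwm(x))
  codes <- encode_dna(sequence)
  if (length(codes) < x$width) return(0L)
  m <- .ll_matrices(x, background, pseudocount)
  cpp_count_hits(codes, m$fwd, m$rev, threshold)
}

#' Estimate a zero-order background from sequences
#'
#' Pools A/C/G/T counts over all sequences (non-ACGT bases ignored), adds a
#' pseudocount of 1 per base, and normalizes.
#'
#' @param sequences Character vector (or list) of DNA strings.
#' @return A [background_model()].
#' @export
background_from_sequences <- function(sequences) {
  sequences <- unlist(sequences, use.names = FALSE)
  codes <- unlist(lapply(sequences, encode_dna), use.names = FALSE)
  codes <- codes[codes <= 3L]
  if (!length(codes)) stop("no ACGT bases in input sequences")
  counts <- tabulate(codes + 1L, nbins = 4L) + 1
  background_model(counts / sum(counts))
}
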