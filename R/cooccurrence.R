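#' Binarize a raw-count feature matrix to motif presence
#'
#' Presence means at least `min_count` raw hits. Binarization acts on
#' counts, not per-kb values, so a normalized matrix is rejected.
#'
#' @param matrix A raw-count `feature_matrix`.
#' @param min_count Minimum hit count for presence.
#' @return Logical peaks x motifs matrix.
#' @export
binarize <- function(matrix, min_count = 1) {
  stopifnot(is_feature_matrix(matrix))
  if (matrix$normalized)
    stop("binarize() needs raw counts, not a per-kb normalized matrix")
  matrix$values >= min_count
}

#' Pairwise motif co-occurrence proportions
#'
#' Entry (i, j) is the fraction of all peaks containing both motifs; the
#' diagonal is each motif's prevalence (and can be well below 1). The matrix
#' is symmetric and every off-diagonal entry is bounded by the smaller of
#' the two prevalences.
#'
#' @param presence Logical peaks x motifs matrix from [binarize()].
#' @param motifs Optional motif id subset (e.g. a model's active features).
#' @return A `cooccurrence_matrix`: list with `matrix`, `motif_ids`,
#'   `n_peaks`.
#' @export
cooccurrence_matrix <- function(presence, motifs = colnames(presence)) {
  missing <- setdiff(motifs, colnames(presence))
  if (length(missing)) stop("motif(s) not in presence table: ",
                            paste(head(missing, 5), collapse = ", "))
  p <- presence[, motifs, drop = FALSE]
  n <- nrow(p)
  m <- crossprod(p * 1) / n
  structure(list(matrix = m, motif_ids = motifs, n_peaks = n),
            class = "cooccurrence_matrix")
}

#' @export
print.cooccurrence_matrix <- function(x, ...) {
  cat(sprintf("Co-occurrence over %d peaks, %d motifs\n",
              x$n_peaks, length(x$motif_ids)))
  print(round(x$matrix[seq_len(min(6, nrow(x$matrix))),
                       seq_len(min(6, ncol(x$matrix))), drop = FALSE], 3))
  invisible(x)
}

#' Anchor-exclusive motif fractions
#'
#' For each motif, the proportion of peaks containing it but not the anchor
#' motif — the signature of indirect (tethered) binding. With
#' `denominator = "all_peaks"` (default) this is the frequency-subtraction
#' form `freq(m) - freq(m AND anchor)`, so the anchor's own entry is zero by
#' construction; `"motif_peaks"` conditions on peaks containing the motif
#' (`|m AND !anchor| / |m|`).
#'
#' @param presence Logical peaks x motifs matrix from [binarize()].
#' @param anchor Anchor motif id (must be a column of `presence`).
#' @param denominator `"all_peaks"` or `"motif_peaks"`.
#' @return An `anchor_exclusive_report`: named fractions plus the anchor id
#'   and denominator convention.
#' @export
anchor_exclusive_fraction <- function(presence, anchor,
                                      denominator = c("all_peaks", "motif_peaks")) {
  denominator <- match.arg(denominator)
  if (!anchor %in% colnames(presence))
    stop("anchor motif '", anchor, "' not in presence table")
  n <- nrow(presence)
  has_anchor <- presence[, anchor]
  excl <- colSums(presence & !has_anchor)
  frac <- if (denominator == "all_peaks") excl / n
          else ifelse(colSums(presence) > 0, excl / colSums(presence), NA_real_)
  frac[anchor] <- 0
  structure(list(anchor = anchor, fractions = frac, denominator = denominator,
                 n_peaks = n), class = "anchor_exclusive_report")
}

#' @export
print.anchor_exclusive_report <- function(x, ...) {
  cat(sprintf("Anchor-exclusive fractions (anchor %s, denominator %s):\n",
              x$anchor, x$denominator))
  print(round(sort(x$fractions, decreasing = TRUE)[seq_len(min(8, length(x$fractions)))], 3))
  invisible(x)
}

#' Ranked candidate-interactor table
#'
#' Active non-anchor motifs of a fitted model, ranked by absolute
#' coefficient (or importance), annotated with their anchor-exclusive
#' fraction and a known/novel flag against a user-supplied list of known
#' protein-protein interactors.
#'
#' @param model A `fitted_model`.
#' @param exclusive An [anchor_exclusive_fraction()] report.
#' @param known_ppis Character vector of motif ids with known interactions.
#' @return `data.frame(motif_id, coefficient, exclusive_fraction, known_ppi)`
#'   sorted by decreasing `|coefficient|`.
#' @export
rank_candidates <- function(model, exclusive, known_ppis = character(0)) {
  stopifnot(inherits(exclusive, "anchor_exclusive_report"))
  feats <- model$active_features
  feats <- feats[names(feats) != exclusive$anchor]
  if (!length(feats))
    return(data.frame(motif_id = character(0), coefficient = numeric(0),
                      exclusive_fraction = numeric(0), known_ppi = logical(0)))
  ord <- order(-abs(feats))
  df <- data.frame(
    motif_id = names(feats)[ord],
    coefficient = as.numeric(feats)[ord],
    exclusive_fraction = as.numeric(exclusive$fractions[names(feats)[ord]]),
    known_ppi = names(feats)[ord] %in% known_ppis,
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}
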