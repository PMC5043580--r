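#' Position weight matrix
#'
#' Construct a PWM: a `width x 4` matrix of base probabilities over
#' (A, C, G, T), the unit of motif grammar used throughout the package.
#'
#' @param id Unique motif identifier.
#' @param probs Numeric `width x 4` matrix; rows must sum to 1 (within 1e-6)
#'   and entries must be non-negative. Columns are taken in A, C, G, T order.
#' @param name Display name (defaults to `id`).
#' @param source Provenance tag, one of `"jaspar"`, `"transfac"`, `"meme"`,
#'   `"denovo"`, `"synthetic"`.
#' @return An object of class `pwm` with fields `id`, `name`, `width`,
#'   `probs`, `source`.
#' @export
pwm <- function(id, probs, name = id, source = "synthetic") {
  source <- match.arg(source, c("jaspar", "transfac", "meme", "denovo", "synthetic"))
  probs <- as.matrix(probs)
  if (ncol(probs) != 4L) stop("`probs` must have 4 columns (A,C,G,T)")
  if (nrow(probs) < 1L) stop("`probs` must have width >= 1")
  if (any(!is.finite(probs)) || any(probs < 0))
    stop("PWM '", id, "': probabilities must be finite and non-negative")
  if (any(abs(rowSums(probs) - 1) > 1e-6))
    stop("PWM '", id, "': rows must sum to 1 within 1e-6")
  dimnames(probs) <- list(NULL, DNA_BASES)
  structure(
    list(id = as.character(id), name = as.character(name),
         width = nrow(probs), probs = probs, source = source),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM %s (%s, width %d, source %s)\n", x$id, x$name, x$width, x$source))
  print(round(x$probs, 3))
  invisible(x)
}

is_pwm <- function(x) inherits(x, "pwm")

#' Zero-order background base composition
#'
#' @param freqs Numeric vector of 4 strictly positive frequencies over
#'   (A, C, G, T); must sum to 1 within 1e-9.
#' @return An object of class `background_model`.
#' @export
background_model <- function(freqs = rep(0.25, 4)) {
  freqs <- as.numeric(freqs)
  if (length(freqs) != 4L) stop("background needs 4 frequencies (A,C,G,T)")
  if (any(freqs <= 0)) stop("background frequencies must be > 0")
  if (abs(sum(freqs) - 1) > 1e-9) stop("background frequencies must sum to 1 within 1e-9")
  structure(setNames(freqs, DNA_BASES), class = "background_model")
}

#' Reverse complement of a PWM
#'
#' Reverses the row (position) order and swaps the A/T and C/G columns.
#' Applying the operation twice returns the original matrix.
#'
#' @param x A [pwm()].
#' @return A `pwm` with id suffixed `"_rc"` unless it already carries it.
#' @export
reverse_complement <- function(x) {
  stopifnot(is_pwm(x))
  probs <- x$probs[rev(seq_len(x$width)), c("T", "G", "C", "A"), drop = FALSE]
  id <- if (endsWith(x$id, "_rc")) sub("_rc$", "", x$id) else paste0(x$id, "_rc")
  pwm(id, probs, name = x$name, source = x$source)
}

# Pseudocount-adjusted probabilities: add pc to each cell, renormalize rows.
adjust_probs <- function(probs, pseudocount) {
  if (pseudocount > 0) {
    probs <- probs + pseudocount
    probs <- probs / rowSums(probs)
  }
  probs
}

#' Log-likelihood score of one window
#'
#' Score of a DNA window of exactly the motif width:
#' `sum_i log2(p_i(b_i) / bg(b_i))` in bits, where the PWM probabilities are
#' optionally pseudocount-adjusted. Any non-ACGT base (e.g. N) yields
#' `-Inf`, so the window can never reach a finite threshold.
#'
#' @param x A [pwm()].
#' @param window DNA string of length `x$width` over A,C,G,T,N.
#' @param background A [background_model()].
#' @param pseudocount Probability added to every cell before row
#'   renormalization (0 keeps the matrix as loaded).
#' @return Score in bits (scalar; `-Inf` if the window contains non-ACGT).
#' @export
log_likelihood_score <- function(x, window, background = background_model(),
                                 pseudocount = 0) {
  stopifnot(is_pwm(x))
  codes <- encode_dna(window)
  if (length(codes) != x$width)
    stop("window length ", length(codes), " != PWM width ", x$width)
  if (any(codes > 3L)) return(-Inf)
  probs <- adjust_probs(x$probs, pseudocount)
  sum(log2(probs[cbind(seq_len(x$width), codes + 1L)] /
             as.numeric(background)[codes + 1L]))
}

#' Information content of a PWM
#'
#' `sum_i sum_b p_i(b) log2(p_i(b)/bg(b))` in bits, with `0 * log(0) = 0`.
#' Used for reporting only (e.g. flagging low-information motifs whose hits
#' are expected to be promiscuous).
#'
#' @inheritParams log_likelihood_score
#' @return Total information content in bits.
#' @export
information_content <- function(x, background = background_model()) {
  stopifnot(is_pwm(x))
  bg <- matrix(as.numeric(background), nrow = x$width, ncol = 4, byrow = TRUE)
  term <- x$probs * log2(x$probs / bg)
  term[x$probs == 0] <- 0
  sum(term)
}

#' Ungapped PWM similarity
#'
#' Maximum over all ungapped offsets, and over `b` versus its reverse
#' complement, of the mean column-wise Pearson correlation across the
#' overlapping columns. The minimum overlap considered is 4 columns (or the
#' full shorter width when that is below 4). Columns with zero variance
#' contribute a correlation of 0. The score is symmetric and lies in
#' \[-1, 1\]; a motif scores 1 against itself and its reverse complement.
#'
#' @param a,b [pwm()] objects.
#' @return Similarity score in \[-1, 1\].
#' @export
pwm_similarity <- function(a, b) {
  stopifnot(is_pwm(a), is_pwm(b))
  min_overlap <- min(4L, a$width, b$width)
  best <- -1
  for (mb in list(b$probs, reverse_complement(b)$probs)) {
    best <- max(best, .best_offset_similarity(a$probs, mb, min_overlap))
  }
  best
}

.col_cor <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) return(0)
  cor(x, y)
}

.best_offset_similarity <- function(ma, mb, min_overlap) {
  wa <- nrow(ma); wb <- nrow(mb)
  best <- -1
  for (off in seq(-(wb - 1L), wa - 1L)) {
    ia <- max(1L, off + 1L):min(wa, off + wb)
    ib <- ia - off
    if (length(ia) < min_overlap) next
    cc <- vapply(seq_along(ia),
                 function(k) .col_cor(ma[ia[k], ], mb[ib[k], ]), numeric(1))
    best <- max(best, mean(cc))
  }
  best
}
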