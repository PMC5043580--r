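#' Peak set of genomic intervals
#'
#' Intervals are 0-based, half-open (BED convention). Zero-length intervals
#' are rejected. Peaks without names get `chrom:start-end` identifiers;
#' duplicates are made unique.
#'
#' @param chrom Character vector of sequence names.
#' @param start,end Integer coordinates (0-based start, exclusive end).
#' @param name Optional peak names.
#' @param set_name Label for the whole set.
#' @return An object of class `peak_set`.
#' @export
peak_set <- function(chrom, start, end, name = NULL, set_name = "peaks") {
  start <- as.integer(start); end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end))) stop("non-integer coordinates")
  bad <- which(start < 0 | end <= start)
  if (length(bad))
    stop("invalid interval at row ", bad[1], ": start=", start[bad[1]],
         " end=", end[bad[1]], " (need 0 <= start < end)")
  if (is.null(name)) {
    name <- if (length(chrom)) paste0(chrom, ":", start, "-", end) else character(0)
  }
  name <- make.unique(as.character(name), sep = "_")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   name = name, stringsAsFactors = FALSE)
  structure(list(name = set_name, intervals = df), class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("PeakSet '%s': %d intervals on %d sequence(s)\n",
              x$name, nrow(x$intervals), length(unique(x$intervals$chrom))))
  print(head(x$intervals))
  invisible(x)
}

#' @export
length.peak_set <- function(x) nrow(x$intervals)

peak_lengths <- function(x) x$intervals$end - x$intervals$start

is_peak_set <- function(x) inherits(x, "peak_set")

as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$intervals$chrom,
    ranges = IRanges::IRanges(start = x$intervals$start + 1L, end = x$intervals$end),
    name = x$intervals$name)
}

subset_peaks <- function(x, idx, set_name = x$name) {
  df <- x$intervals[idx, , drop = FALSE]
  rownames(df) <- NULL
  structure(list(name = set_name, intervals = df), class = "peak_set")
}

#' Read a BED file into a peak set
#'
#' Accepts BED3/BED4+ (tab- or space-separated); `track`, `browser` and `#`
#' lines are skipped. Coordinates are kept 0-based half-open.
#'
#' @param path BED file.
#' @param set_name Label for the set (defaults to the file name).
#' @return A [peak_set()].
#' @export
read_bed <- function(path, set_name = basename(path)) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("no records in BED file: ", path)
  fields <- strsplit(lines, "[\t ]+")
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("line ", lineno[which(nf < 3)[1]], ": fewer than 3 BED columns")
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | end <= start)
  if (length(bad))
    stop("line ", lineno[bad[1]], ": invalid interval '", lines[bad[1]],
         "' (need integer 0 <= start < end)")
  name <- ifelse(nf >= 4, vapply(fields, function(f) f[min(4, length(f))], character(1)), NA)
  name <- ifelse(is.na(name) | name == ".", paste0(chrom, ":", start, "-", end), name)
  peak_set(chrom, start, end, name, set_name = set_name)
}

#' Write a peak set as BED4
#'
#' @param peaks A [peak_set()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  stopifnot(is_peak_set(peaks))
  df <- peaks$intervals[order(peaks$intervals$chrom, peaks$intervals$start), ]
  writeLines(sprintf("%s\t%d\t%d\t%s", df$chrom, df$start, df$end, df$name), path)
  invisible(path)
}

#' Extract peak sequences from a genome
#'
#' @param peaks A [peak_set()].
#' @param genome FASTA file path, a named character vector of chromosome
#'   sequences, or a `Biostrings::DNAStringSet`.
#' @return Named character vector (peak name -> uppercase DNA string).
#' @export
extract_sequences <- function(peaks, genome) {
  stopifnot(is_peak_set(peaks))
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), sub("\\s.*", "", names(genome)))
  }
  if (is.null(names(genome))) stop("genome sequences must be named by chromosome")
  df <- peaks$intervals
  chrom_len <- setNames(nchar(genome), names(genome))
  missing_chrom <- !(df$chrom %in% names(genome))
  if (any(missing_chrom))
    stop("peak '", df$name[which(missing_chrom)[1]], "': chromosome '",
         df$chrom[which(missing_chrom)[1]], "' not in genome")
  oob <- df$end > chrom_len[df$chrom]
  if (any(oob))
    stop("peak '", df$name[which(oob)[1]], "': interval [", df$start[which(oob)[1]],
         ",", df$end[which(oob)[1]], ") exceeds chromosome length ",
         chrom_len[df$chrom[which(oob)[1]]])
  seqs <- toupper(substring(genome[df$chrom], df$start + 1L, df$end))
  setNames(seqs, df$name)
}

#' Partition two peak sets by coordinate overlap
#'
#' Splits replicate experiments into the unique/shared subsets used for
#' concordance analysis: `A` (set1-only), `B1` (set1 peaks overlapping set2),
#' `B2` (set2 peaks overlapping set1) and `C` (set2-only). Overlap means at
#' least one shared base by default; `min_fraction` additionally requires
#' that fraction of the peak's own length to be shared.
#'
#' @param set1,set2 [peak_set()] objects.
#' @param min_fraction Minimum overlapping fraction of a peak's length
#'   (default 0 = any shared base).
#' @return An `overlap_partition`: list with peak sets `A`, `B1`, `B2`, `C`.
#' @export
partition_overlap <- function(set1, set2, min_fraction = 0) {
  stopifnot(is_peak_set(set1), is_peak_set(set2))
  g1 <- as_granges(set1); g2 <- as_granges(set2)
  # sets on entirely different chromosomes are a valid (empty) comparison;
  # silence the seqlevel-merge notice that case triggers
  ov <- suppressWarnings(GenomicRanges::findOverlaps(g1, g2))
  if (min_fraction > 0 && length(ov)) {
    inter <- GenomicRanges::pintersect(g1[S4Vectors::queryHits(ov)],
                                       g2[S4Vectors::subjectHits(ov)])
    wq <- GenomicRanges::width(g1[S4Vectors::queryHits(ov)])
    ws <- GenomicRanges::width(g2[S4Vectors::subjectHits(ov)])
    keep <- GenomicRanges::width(inter) >= pmin(wq, ws) * min_fraction
    ov <- ov[keep]
  }
  hit1 <- sort(unique(S4Vectors::queryHits(ov)))
  hit2 <- sort(unique(S4Vectors::subjectHits(ov)))
  structure(list(
    A = subset_peaks(set1, setdiff(seq_len(length(set1)), hit1), "A"),
    B1 = subset_peaks(set1, hit1, "B1"),
    B2 = subset_peaks(set2, hit2, "B2"),
    C = subset_peaks(set2, setdiff(seq_len(length(set2)), hit2), "C")
  ), class = "overlap_partition")
}

#' @export
print.overlap_partition <- function(x, ...) {
  cat(sprintf("OverlapPartition: A=%d B1=%d B2=%d C=%d\n",
              length(x$A), length(x$B1), length(x$B2), length(x$C)))
  invisible(x)
}

#' Matched random background peaks
#'
#' Draws a background set with exactly the template's length distribution
#' (a permutation of its lengths), wholly contained in `allowed` regions,
#' avoiding every `exclude` interval and mutually non-overlapping. Placement
#' is rejection sampling of (region, offset) uniform over feasible start
#' positions, with lengths placed in descending order.
#'
#' @param template [peak_set()] whose sizes and lengths are matched.
#' @param allowed [peak_set()] of regions the background may occupy (e.g.
#'   the promoter space an array design covers).
#' @param seed Integer seed; identical seeds give identical output.
#' @param exclude [peak_set()] of intervals the background must avoid
#'   (defaults to the template itself, preventing label leakage).
#' @param max_tries Placement attempts per interval before failing.
#' @param set_name Label for the output set.
#' @return A [peak_set()] of the same size as `template`.
#' @export
generate_random_peaks <- function(template, allowed, seed,
                                  exclude = template, max_tries = 1000,
                                  set_name = "background") {
  stopifnot(is_peak_set(template), is_peak_set(allowed))
  lens <- peak_lengths(template)
  with_seed(seed, place_random_intervals(lens, allowed, exclude = exclude,
                                         max_tries = max_tries,
                                         set_name = set_name))
}

# Core placement routine; consumes the current RNG stream.
place_random_intervals <- function(lengths, allowed, exclude = NULL,
                                   max_tries = 1000, set_name = "background") {
  adf <- allowed$intervals
  region_len <- adf$end - adf$start
  n <- length(lengths)
  ex_ch <- ex_s <- ex_e <- NULL
  if (!is.null(exclude) && length(exclude) > 0) {
    ex_ch <- exclude$intervals$chrom
    ex_s <- exclude$intervals$start
    ex_e <- exclude$intervals$end
  }
  p_ch <- character(n); p_s <- integer(n); p_e <- integer(n)
  n_placed <- 0L
  ord <- order(-lengths)
  out_ch <- character(n); out_s <- integer(n); out_e <- integer(n)
  for (i in ord) {
    len <- lengths[i]
    slots <- region_len - len + 1L
    feasible <- which(slots > 0L)
    if (!length(feasible))
      stop("no allowed region can hold an interval of length ", len)
    wts <- slots[feasible] / sum(slots[feasible])
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      r <- feasible[sample.int(length(feasible), 1L, prob = wts)]
      s <- adf$start[r] + sample.int(slots[r], 1L) - 1L
      e <- s + len
      ch <- adf$chrom[r]
      if (!is.null(ex_ch) && any(ex_ch == ch & ex_s < e & ex_e > s)) next
      if (n_placed > 0L) {
        k <- seq_len(n_placed)
        if (any(p_ch[k] == ch & p_s[k] < e & p_e[k] > s)) next
      }
      n_placed <- n_placed + 1L
      p_ch[n_placed] <- ch; p_s[n_placed] <- s; p_e[n_placed] <- e
      out_ch[i] <- ch; out_s[i] <- s; out_e[i] <- e
      ok <- TRUE
      break
    }
    if (!ok)
      stop("failed to place a background interval of length ", len,
           " after ", max_tries, " tries")
  }
  peak_set(out_ch, out_s, out_e,
           name = paste0(set_name, "_", seq_len(n)), set_name = set_name)
}

#' Fraction of set1 peaks overlapping set2
#'
#' @param set1,set2 [peak_set()] objects.
#' @return Proportion in \[0, 1\].
#' @export
overlap_fraction <- function(set1, set2) {
  part <- partition_overlap(set1, set2)
  length(part$B1) / length(set1)
}
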