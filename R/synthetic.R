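#' Synthetic sharply-defined PWM
#'
#' Builds a motif with a random consensus where the consensus base carries
#' probability `sharpness` at every position and the remainder is spread
#' evenly. Consumes the current RNG stream.
#'
#' @param id Motif id.
#' @param width Motif width.
#' @param sharpness Consensus base probability.
#' @return A [pwm()] with source `"synthetic"`.
#' @export
make_synthetic_pwm <- function(id, width = 8, sharpness = 0.94) {
  cons <- sample.int(4L, width, replace = TRUE)
  probs <- matrix((1 - sharpness) / 3, nrow = width, ncol = 4)
  probs[cbind(seq_len(width), cons)] <- sharpness
  pwm(id, probs, source = "synthetic")
}

#' Default synthetic motif library
#'
#' A fixed (seed-independent) library: one anchor motif, four cofactor
#' motifs and `n_decoys` decoys of widths 6-12 that are never planted.
#' Motifs are regenerated if any pair is too similar, so planted signals
#' stay attributable to their own motif. The anchor is deliberately shorter
#' and less sharp than the cofactors, emulating the short, low-information
#' binding element of a homeodomain factor: it is the weakest planted
#' feature, which is exactly the regime in which anchor-retention (rather
#' than purely statistical) model compression is meaningful.
#'
#' @param n_cofactors,n_decoys Library composition.
#' @param sharpness Consensus probability of decoy motifs.
#' @param anchor_width,anchor_sharpness Anchor motif geometry.
#' @param cofactor_width,cofactor_sharpness Cofactor motif geometry.
#' @return List with `anchor` (a [pwm()]), `cofactors`, `decoys` (lists of
#'   [pwm()]), and `all` (the concatenated library).
#' @export
default_synthetic_motifs <- function(n_cofactors = 4, n_decoys = 50,
                                     sharpness = 0.94, anchor_width = 6,
                                     anchor_sharpness = 0.85,
                                     cofactor_width = 12,
                                     cofactor_sharpness = 0.96) {
  key <- paste(n_cofactors, n_decoys, sharpness, anchor_width,
               anchor_sharpness, cofactor_width, cofactor_sharpness, sep = "|")
  cached <- .motif_cache[[key]]
  if (!is.null(cached)) return(cached)
  out <- with_seed(104729L, {
    planted <- list()
    # planted motifs must be mutually dissimilar and decoys dissimilar from
    # them, so recovered signal is attributable; decoy-decoy similarity is
    # harmless (decoys are never planted)
    add <- function(id, width, sh, record) {
      for (try in 1:50) {
        cand <- make_synthetic_pwm(id, width, sh)
        sims <- vapply(planted, pwm_similarity, numeric(1), b = cand)
        if (!length(sims) || max(sims) < 0.8) {
          if (record) planted[[length(planted) + 1L]] <<- cand
          return(cand)
        }
      }
      stop("could not generate a dissimilar motif for ", id)
    }
    anchor <- add("anchor_NKE", anchor_width, anchor_sharpness, TRUE)
    cofactors <- lapply(seq_len(n_cofactors), function(i)
      add(sprintf("cofactor_%02d", i), cofactor_width, cofactor_sharpness, TRUE))
    widths <- rep(6:12, length.out = n_decoys)
    decoys <- lapply(seq_len(n_decoys), function(i)
      add(sprintf("decoy_%02d", i), widths[i], sharpness, FALSE))
    list(anchor = anchor, cofactors = cofactors, decoys = decoys,
         all = c(list(anchor), cofactors, decoys))
  })
  .motif_cache[[key]] <- out
  out
}

.motif_cache <- new.env(parent = emptyenv())

#' Synthetic dataset configuration
#'
#' The stated world for testing: two replicate positive peak sets sharing a
#' planted motif grammar with a configurable coordinate-overlap fraction, an
#' indirect-binding subset of positives carrying cofactor motifs but no
#' anchor, and a matched background with small cofactor leakage. Defaults
#' are the strong-signal regime used throughout the test suite.
#'
#' @param n_pos Positives per replicate.
#' @param n_bg Background set size.
#' @param length_mean,length_sd Peak length distribution in bp (normal,
#'   truncated to `length_range`).
#' @param length_range Truncation bounds for peak lengths.
#' @param gc GC content of the zero-order genome.
#' @param anchor_prob Fraction of positives carrying the anchor motif
#'   (allocated exactly, always outside the indirect subset).
#' @param cofactor_prob Per-cofactor planting probability in positives.
#' @param leak_prob Per-cofactor planting probability in background peaks.
#' @param indirect_fraction Fraction of positives (exactly
#'   `ceiling(indirect_fraction * n_pos)` peaks) that carry at least one
#'   cofactor but never the anchor.
#' @param replicate_overlap Fraction of replicate-2 peaks reusing
#'   (jittered) replicate-1 coordinates.
#' @param shared_boost Multiplier (capped at probability 1) on anchor and
#'   cofactor planting probabilities in replicate-shared peaks, emulating
#'   reproducible peaks being higher-affinity sites.
#' @param motifs Motif library as from [default_synthetic_motifs()].
#' @param genome_length Genome size in bp (`NULL` = 8x total peak bp).
#' @param seed Integer seed governing every random choice.
#' @return A validated `synthetic_config`.
#' @export
synthetic_config <- function(n_pos = 500, n_bg = 500,
                             length_mean = 500, length_sd = 120,
                             length_range = c(100, 1200),
                             gc = 0.42,
                             anchor_prob = 0.6, cofactor_prob = 0.4,
                             leak_prob = 0.05, indirect_fraction = 0.15,
                             replicate_overlap = 0.55, shared_boost = 1.3,
                             motifs = default_synthetic_motifs(),
                             genome_length = NULL, seed = 1) {
  probs <- c(anchor_prob, cofactor_prob, leak_prob, indirect_fraction,
             replicate_overlap, gc)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (shared_boost < 0) stop("shared_boost must be >= 0")
  max_w <- max(vapply(motifs$all, `[[`, integer(1), "width"))
  if (length_range[1] < 2 * max_w)
    stop("minimum peak length must be >= 2x the widest motif (", 2 * max_w, " bp)")
  n_ind <- ceiling(indirect_fraction * n_pos)
  if (round(anchor_prob * n_pos) > n_pos - n_ind)
    stop("inconsistent config: anchor_prob ", anchor_prob,
         " and indirect_fraction ", indirect_fraction,
         " demand more direct peaks than exist")
  if (is.null(genome_length))
    genome_length <- max(1e6, 8 * (2 * n_pos + n_bg) * length_mean)
  structure(list(n_pos = n_pos, n_bg = n_bg, length_mean = length_mean,
                 length_sd = length_sd, length_range = length_range, gc = gc,
                 anchor_prob = anchor_prob, cofactor_prob = cofactor_prob,
                 leak_prob = leak_prob, indirect_fraction = indirect_fraction,
                 replicate_overlap = replicate_overlap,
                 shared_boost = shared_boost, motifs = motifs,
                 genome_length = as.integer(genome_length),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# iid genome as base codes 1..4; consumes the RNG stream.
.sim_genome_codes <- function(config) {
  p <- c((1 - config$gc) / 2, config$gc / 2, config$gc / 2, (1 - config$gc) / 2)
  sample.int(4L, config$genome_length, replace = TRUE, prob = p)
}

.codes_to_string <- function(codes) intToUtf8(c(65L, 67L, 71L, 84L)[codes])

# allowed regions tile the genome: 4 kb allowed, 1 kb gap
.allowed_regions <- function(genome_length) {
  starts <- seq(0L, genome_length - 4000L, by = 5000L)
  peak_set("chr1", starts, starts + 4000L, set_name = "allowed")
}

#' Simulate a zero-order genome and allowed regions
#'
#' @param config A [synthetic_config()].
#' @return List with `genome` (named character vector, one chromosome) and
#'   `allowed` (a [peak_set()] tiling the genome with gaps).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  codes <- with_seed(config$seed, .sim_genome_codes(config))
  list(genome = c(chr1 = .codes_to_string(codes)),
       allowed = .allowed_regions(config$genome_length))
}

#' Plant one motif instance into a sequence
#'
#' Replaces the `width`-long window at `position` (0-based) with a base
#' string sampled column-wise from the PWM (reverse-complemented for the
#' minus strand). Consumes the current RNG stream.
#'
#' @param sequence DNA string.
#' @param x A [pwm()].
#' @param position 0-based offset of the planted window.
#' @param strand `"+"` or `"-"`.
#' @return The modified sequence.
#' @export
plant_motif <- function(sequence, x, position, strand = "+") {
  stopifnot(is_pwm(x))
  if (position < 0 || position + x$width > nchar(sequence))
    stop("planting position ", position, " does not fit a width-", x$width,
         " motif in a ", nchar(sequence), " bp sequence")
  probs <- if (strand == "-") reverse_complement(x)$probs else x$probs
  inst <- paste(DNA_BASES[.sample_pwm_codes(probs)], collapse = "")
  paste0(substring(sequence, 1, position), inst,
         substring(sequence, position + x$width + 1, nchar(sequence)))
}

.sample_pwm_codes <- function(probs) {
  vapply(seq_len(nrow(probs)),
         function(k) sample.int(4L, 1L, prob = probs[k, ]), integer(1))
}

#' Simulate replicate peak sets with planted motif grammar
#'
#' Generates a genome, places replicate-1 positives, designates a
#' replicate-shared subset (reused by replicate 2 after jitter of up to 10%
#' of peak length) and an indirect subset (no anchor, at least one
#' cofactor), plants anchor/cofactor instances into the genome (decoys are
#' never planted), draws the remaining replicate-2 peaks fresh from the same
#' grammar, and places a matched background receiving cofactors only at the
#' leak probability. Fully deterministic given `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_dataset`: list with `genome`, `allowed`, `rep1`,
#'   `rep2`, `background` ([peak_set()]s), `truth` (data.frame of plantings:
#'   set, peak_id, motif_id, offset, gstart, strand), `peak_info`
#'   (per-positive flags: shared, indirect, has_anchor) and `config`.
#' @export
simulate_peaks <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, .simulate_peaks_impl(config))
}

.rtrunc_lengths <- function(n, config) {
  out <- integer(0)
  while (length(out) < n) {
    x <- round(rnorm(n, config$length_mean, config$length_sd))
    out <- c(out, x[x >= config$length_range[1] & x <= config$length_range[2]])
  }
  out[seq_len(n)]
}

.simulate_peaks_impl <- function(config) {
  codes <- .sim_genome_codes(config)
  allowed <- .allowed_regions(config$genome_length)
  mot <- config$motifs
  anchor_probs <- mot$anchor$probs
  cof_probs <- lapply(mot$cofactors, `[[`, "probs")
  n_cof <- length(cof_probs)

  cap <- 4L * (2L * config$n_pos * (1L + n_cof) + config$n_bg * n_cof) + 64L
  t_set <- t_peak <- t_motif <- t_strand <- character(cap)
  t_off <- t_g <- occ_s <- occ_e <- integer(cap)
  inst_codes <- vector("list", cap)
  n_plant <- 0L
  plant <- function(set, peak_id, motif_id, probs, pstart, pend) {
    w <- nrow(probs)
    for (try in 1:100) {
      off <- sample.int(pend - pstart - w + 1L, 1L) - 1L
      g <- pstart + off
      if (n_plant > 0L) {
        k <- seq_len(n_plant)
        if (any(occ_s[k] < g + w & occ_e[k] > g)) next
      }
      strand <- if (runif(1) < 0.5) "+" else "-"
      pl <- if (strand == "-") probs[rev(seq_len(w)), c(4L, 3L, 2L, 1L), drop = FALSE]
            else probs
      n_plant <<- n_plant + 1L
      inst_codes[[n_plant]] <<- .sample_pwm_codes(pl)
      occ_s[n_plant] <<- g; occ_e[n_plant] <<- g + w
      t_set[n_plant] <<- set; t_peak[n_plant] <<- peak_id
      t_motif[n_plant] <<- motif_id; t_strand[n_plant] <<- strand
      t_off[n_plant] <<- off; t_g[n_plant] <<- g
      return(invisible(TRUE))
    }
    stop("could not place a motif instance without collision in peak ", peak_id)
  }

  # grammar assignment for a block of positives; returns flags
  assign_grammar <- function(set, ps, shared_flag, boost) {
    n <- length(ps)
    if (n == 0) return(NULL)
    p_anchor <- min(1, config$anchor_prob * boost)
    p_cof <- min(1, config$cofactor_prob * boost)
    n_ind <- ceiling(config$indirect_fraction * n)
    n_anchor <- round(p_anchor * n)
    if (n_anchor > n - n_ind)
      stop("inconsistent config: anchor and indirect demands exceed ", n, " peaks")
    ind <- sample.int(n, n_ind)
    anchor_carriers <- sample(setdiff(seq_len(n), ind), n_anchor)
    df <- ps$intervals
    has_cof <- matrix(FALSE, n, n_cof)
    for (i in seq_len(n)) {
      if (i %in% anchor_carriers)
        plant(set, df$name[i], mot$anchor$id, anchor_probs, df$start[i], df$end[i])
      draws <- runif(n_cof) < p_cof
      if (i %in% ind && !any(draws)) draws[sample.int(n_cof, 1L)] <- TRUE
      for (j in which(draws))
        plant(set, df$name[i], mot$cofactors[[j]]$id, cof_probs[[j]],
              df$start[i], df$end[i])
      has_cof[i, ] <- draws
    }
    data.frame(set = set, peak_id = df$name,
               shared = shared_flag, indirect = seq_len(n) %in% ind,
               has_anchor = seq_len(n) %in% anchor_carriers,
               stringsAsFactors = FALSE)
  }

  # replicate 1
  rep1 <- place_random_intervals(.rtrunc_lengths(config$n_pos, config), allowed,
                                 set_name = "rep1")
  n_shared <- round(config$replicate_overlap * config$n_pos)
  shared_idx <- sort(sample.int(config$n_pos, n_shared))
  shared_flag1 <- seq_len(config$n_pos) %in% shared_idx
  info1 <- rbind(
    assign_grammar("rep1", subset_peaks(rep1, which(shared_flag1)), TRUE,
                   config$shared_boost),
    assign_grammar("rep1", subset_peaks(rep1, which(!shared_flag1)), FALSE, 1))

  # replicate 2: jittered reuse of shared rep1 coordinates + fresh peaks
  df1 <- rep1$intervals[shared_idx, , drop = FALSE]
  lens <- df1$end - df1$start
  jit <- vapply(lens, function(L) {
    m <- as.integer(floor(0.1 * L))
    if (m == 0L) 0L else sample.int(2L * m + 1L, 1L) - m - 1L
  }, integer(1))
  s2 <- pmax(0L, pmin(df1$start + jit, config$genome_length - lens))
  shared2 <- peak_set(df1$chrom, s2, s2 + lens,
                      name = paste0("rep2_shared_", seq_along(s2)),
                      set_name = "rep2")
  n_fresh <- config$n_pos - n_shared
  fresh2 <- place_random_intervals(
    .rtrunc_lengths(n_fresh, config), allowed,
    exclude = peak_set(c(rep1$intervals$chrom, shared2$intervals$chrom),
                       c(rep1$intervals$start, shared2$intervals$start),
                       c(rep1$intervals$end, shared2$intervals$end)),
    set_name = "rep2_fresh")
  info2 <- assign_grammar("rep2", fresh2, FALSE, 1)
  rep2 <- peak_set(c(shared2$intervals$chrom, fresh2$intervals$chrom),
                   c(shared2$intervals$start, fresh2$intervals$start),
                   c(shared2$intervals$end, fresh2$intervals$end),
                   name = c(shared2$intervals$name, fresh2$intervals$name),
                   set_name = "rep2")

  # background: cofactor leakage only, avoiding every positive interval
  all_pos <- peak_set(c(rep1$intervals$chrom, rep2$intervals$chrom),
                      c(rep1$intervals$start, rep2$intervals$start),
                      c(rep1$intervals$end, rep2$intervals$end))
  bg <- place_random_intervals(.rtrunc_lengths(config$n_bg, config), allowed,
                               exclude = all_pos, set_name = "background")
  dfb <- bg$intervals
  for (i in seq_len(config$n_bg)) {
    for (j in which(runif(n_cof) < config$leak_prob))
      plant("background", dfb$name[i], mot$cofactors[[j]]$id, cof_probs[[j]],
            dfb$start[i], dfb$end[i])
  }

  # apply all plantings to the genome in one in-place pass
  for (k in seq_len(n_plant)) {
    w <- length(inst_codes[[k]])
    codes[(t_g[k] + 1L):(t_g[k] + w)] <- inst_codes[[k]]
  }
  idx <- seq_len(n_plant)
  truth <- data.frame(set = t_set[idx], peak_id = t_peak[idx],
                      motif_id = t_motif[idx], offset = t_off[idx],
                      gstart = t_g[idx], strand = t_strand[idx],
                      stringsAsFactors = FALSE)

  # rep2 shared peaks inherit rep1 plantings that fall wholly inside them
  t1 <- truth[truth$set == "rep1", , drop = FALSE]
  all_ids <- vapply(mot$all, `[[`, character(1), "id")
  all_w <- vapply(mot$all, `[[`, integer(1), "width")
  t1w <- all_w[match(t1$motif_id, all_ids)]
  inherited <- lapply(seq_along(s2), function(k) {
    inside <- t1$gstart >= s2[k] & (t1$gstart + t1w) <= (s2[k] + lens[k])
    if (!any(inside)) return(NULL)
    data.frame(set = "rep2", peak_id = shared2$intervals$name[k],
               motif_id = t1$motif_id[inside],
               offset = t1$gstart[inside] - s2[k],
               gstart = t1$gstart[inside], strand = t1$strand[inside],
               stringsAsFactors = FALSE)
  })
  truth <- rbind(truth, do.call(rbind, inherited))
  rownames(truth) <- NULL

  shared_info2 <- data.frame(set = "rep2", peak_id = shared2$intervals$name,
                             shared = TRUE, indirect = NA, has_anchor = NA,
                             stringsAsFactors = FALSE)
  structure(list(
    genome = c(chr1 = .codes_to_string(codes)),
    allowed = allowed,
    rep1 = rep1, rep2 = rep2, background = bg,
    truth = truth,
    peak_info = rbind(info1, shared_info2, info2),
    config = config
  ), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic dataset: %d + %d positives, %d background, %d plantings, genome %.2f Mb\n",
    length(x$rep1), length(x$rep2), length(x$background), nrow(x$truth),
    nchar(x$genome[[1]]) / 1e6))
  invisible(x)
}

#' Write a synthetic dataset to standard files
#'
#' Emits FASTA (genome), BED (replicates, background, allowed regions), a
#' truth TSV of plantings and the configuration as JSON.
#'
#' @param dataset A [simulate_peaks()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- Biostrings::DNAStringSet(dataset$genome)
  Biostrings::writeXStringSet(seqs, file.path(dir, "genome.fa"))
  write_bed(dataset$rep1, file.path(dir, "rep1.bed"))
  write_bed(dataset$rep2, file.path(dir, "rep2.bed"))
  write_bed(dataset$background, file.path(dir, "background.bed"))
  write_bed(dataset$allowed, file.path(dir, "allowed.bed"))
  write_tsv(dataset$truth, file.path(dir, "truth.tsv"))
  cfg <- dataset$config
  cfg$motifs <- vapply(cfg$motifs$all, `[[`, character(1), "id")
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
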