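test_that("simulated genome matches requested GC and is seed-deterministic", {
  cfg <- synthetic_config(n_pos = 10, n_bg = 10, genome_length = 1e6, seed = 3)
  g <- simulate_genome(cfg)
  base_tab <- table(strsplit(g$genome[["chr1"]], "")[[1]])
  gc <- sum(base_tab[c("C", "G")]) / sum(base_tab)
  expect_lt(abs(gc - 0.42), 0.02)
  expect_identical(simulate_genome(cfg)$genome, g$genome)
  expect_true(all(g$allowed$intervals$end <= 1e6))

  at_only <- synthetic_config(n_pos = 10, n_bg = 10, gc = 0,
                              genome_length = 1e5, seed = 3)
  expect_false(grepl("[GC]", simulate_genome(at_only)$genome[["chr1"]]))
})

test_that("planted instances are found by the scanner with their own score", {
  onehot <- pwm("cons", rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0)))
  set.seed(5)
  s <- plant_motif(strrep("T", 10), onehot, position = 4)
  expect_equal(s, "TTTTACGTTT")
  s_rc <- plant_motif(strrep("T", 10), onehot, position = 4, strand = "-")
  expect_equal(substr(s_rc, 5, 7), "CGT")  # reverse complement of ACG
  expect_error(plant_motif(strrep("T", 10), onehot, position = 8), "fit")

  u <- background_model()
  p <- random_pwm(6, id = "pl")
  for (i in 1:10) {
    seq0 <- random_dna(60)
    planted <- plant_motif(seq0, p, position = 20)
    inst <- substr(planted, 21, 26)
    sc <- log_likelihood_score(p, inst, u)
    hits <- scan_sequence(p, planted, u, threshold = sc - 1e-9)
    k <- which(hits$position == 20 & hits$strand == "+")
    expect_length(k, 1)
    expect_equal(hits$score[k], sc)
  }
})

test_that("replicate overlap, anchor allocation, and indirect subset are exact", {
  cfg <- synthetic_config(n_pos = 200, n_bg = 100, anchor_prob = 0.8,
                          indirect_fraction = 0.2, shared_boost = 1, seed = 11)
  ds <- simulate_peaks(cfg)

  # measured coordinate overlap within +-0.05 of the 0.55 target
  expect_lt(abs(overlap_fraction(ds$rep1, ds$rep2) - 0.55), 0.05)

  info1 <- ds$peak_info[ds$peak_info$set == "rep1", ]
  expect_equal(nrow(info1), 200)
  # with anchor_prob + indirect_fraction = 1, exactly ceil(0.2 * n) peaks
  # lack the anchor, and they are exactly the indirect subset
  expect_equal(sum(!info1$has_anchor), ceiling(0.2 * 200))
  expect_equal(sum(info1$indirect), ceiling(0.2 * 200))
  expect_true(all(info1$indirect == !info1$has_anchor))

  # indirect peaks never carry an anchor planting but do carry a cofactor
  t1 <- ds$truth[ds$truth$set == "rep1", ]
  for (pk in info1$peak_id[info1$indirect]) {
    mot <- t1$motif_id[t1$peak_id == pk]
    expect_false("anchor_NKE" %in% mot)
    expect_gte(sum(grepl("^cofactor_", mot)), 1)
  }
  # anchor carriers have exactly one anchor planting
  anchor_counts <- table(t1$peak_id[t1$motif_id == "anchor_NKE"])
  expect_true(all(anchor_counts == 1))
  expect_equal(sum(info1$has_anchor), length(anchor_counts))

  # decoys are never planted
  expect_false(any(grepl("^decoy_", ds$truth$motif_id)))

  # plantings fit inside their peaks
  all_peaks <- rbind(ds$rep1$intervals, ds$rep2$intervals, ds$background$intervals)
  key <- setNames(seq_len(nrow(all_peaks)), all_peaks$name)
  set.seed(12)
  for (i in sample(nrow(ds$truth), 50)) {
    row <- ds$truth[i, ]
    pk <- all_peaks[key[[row$peak_id]], ]
    expect_gte(row$gstart, pk$start)
    expect_lte(row$gstart + 1, pk$end)
    expect_equal(row$offset, row$gstart - pk$start)
  }
})

test_that("inconsistent anchor/indirect demands are rejected", {
  expect_error(synthetic_config(anchor_prob = 1, indirect_fraction = 1),
               "inconsistent")
  expect_error(synthetic_config(anchor_prob = 0.95, indirect_fraction = 0.15),
               "inconsistent")
  expect_error(synthetic_config(gc = 1.5), "\\[0, 1\\]")
})

test_that("truth-recorded plantings are recoverable by the scanner", {
  cfg <- synthetic_config(n_pos = 60, n_bg = 30, seed = 19)
  ds <- simulate_peaks(cfg)
  u <- acc_background()
  lib <- setNames(cfg$motifs$all,
                  vapply(cfg$motifs$all, `[[`, character(1), "id"))
  seqs <- c(extract_sequences(ds$rep1, ds$genome),
            extract_sequences(ds$rep2, ds$genome),
            extract_sequences(ds$background, ds$genome))
  set.seed(20)
  rows <- sample(nrow(ds$truth), 40)
  for (i in rows) {
    row <- ds$truth[i, ]
    p <- lib[[row$motif_id]]
    s <- seqs[[row$peak_id]]
    inst <- substr(s, row$offset + 1, row$offset + p$width)
    inst_score <- if (row$strand == "+") log_likelihood_score(p, inst, u)
                  else log_likelihood_score(p, revcomp_str(inst), u)
    hits <- scan_sequence(p, s, u, threshold = inst_score - 1e-9)
    expect_true(any(hits$position == row$offset & hits$strand == row$strand))
  }
})

test_that("unplanted decoys show no enrichment in positives", {
  cfg <- synthetic_config(n_pos = 150, n_bg = 150, seed = 29)
  ds <- simulate_peaks(cfg)
  ftz <- featurizer(cfg$motifs$decoys, background = acc_background())
  fm_pos <- featurize(ds$rep1, ds$genome, ftz)
  fm_bg <- featurize(ds$background, ds$genome, ftz)
  rate_pos <- mean(fm_pos$values)
  rate_bg <- mean(fm_bg$values)
  expect_lt(abs(rate_pos - rate_bg), 0.2 * max(rate_pos, rate_bg, 0.1))
})

test_that("the full dataset is reproducible from its seed and exports cleanly", {
  cfg <- synthetic_config(n_pos = 30, n_bg = 20, seed = 31)
  ds <- simulate_peaks(cfg)
  ds2 <- simulate_peaks(cfg)
  expect_identical(ds$genome, ds2$genome)
  expect_identical(ds$truth, ds2$truth)
  expect_identical(ds$rep1$intervals, ds2$rep1$intervals)

  dir <- withr::local_tempdir()
  write_synthetic_dataset(ds, dir)
  expect_true(all(file.exists(file.path(dir,
    c("genome.fa", "rep1.bed", "rep2.bed", "background.bed", "allowed.bed",
      "truth.tsv", "config.json")))))
  back <- read_bed(file.path(dir, "rep1.bed"))
  expect_equal(length(back), 30)
  fa <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  expect_equal(as.character(fa[[1]]), unname(ds$genome["chr1"]))
})
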