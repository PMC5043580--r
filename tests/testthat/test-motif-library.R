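test_that("JASPAR PFM counts are normalized to probabilities", {
  f <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(">M1 toy",
               "A [ 4 0 ]",
               "C [ 0 4 ]",
               "G [ 0 0 ]",
               "T [ 0 0 ]"), f)
  lib <- read_pwm_library(f, pseudocount = 0)
  expect_length(lib, 1)
  expect_equal(lib[[1]]$width, 2)
  expect_equal(unname(lib[[1]]$probs),
               rbind(c(1, 0, 0, 0), c(0, 1, 0, 0)))
  # plain 4-row dialect without base letters / brackets
  f2 <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(">M2", "4 0", "0 4", "0 0", "0 0"), f2)
  expect_equal(unname(read_pwm_library(f2, pseudocount = 0)[[1]]$probs),
               rbind(c(1, 0, 0, 0), c(0, 1, 0, 0)))
})

test_that("TRANSFAC blocks parse and degenerate rows are rejected", {
  f <- withr::local_tempfile(fileext = ".transfac")
  writeLines(c("AC M0001", "XX", "ID toyTF", "XX",
               "P0 A C G T",
               "01 4 0 0 0 A",
               "02 0 4 0 0 C",
               "03 1 1 1 1 N",
               "XX", "//"), f)
  lib <- read_pwm_library(f, pseudocount = 0)
  expect_equal(lib[[1]]$width, 3)
  expect_equal(lib[[1]]$id, "M0001")
  expect_equal(unname(lib[[1]]$probs[3, ]), rep(0.25, 4))

  f0 <- withr::local_tempfile(fileext = ".transfac")
  writeLines(c("AC M0002", "P0 A C G T", "01 0 0 0 0 N", "//"), f0)
  expect_error(read_pwm_library(f0, pseudocount = 0), "all-zero")
  expect_silent(read_pwm_library(f0, pseudocount = 1e-4))
})

test_that("MEME minimal format round-trips through write_meme", {
  pwms <- list(pwm("m1", rbind(c(0.7, 0.1, 0.1, 0.1), c(0.25, 0.25, 0.25, 0.25))),
               pwm("m2", rbind(c(0, 0, 0, 1))))
  f <- withr::local_tempfile(fileext = ".meme")
  write_meme(pwms, f)
  back <- read_pwm_library(f, pseudocount = 0)
  expect_equal(vapply(back, `[[`, character(1), "id"), c("m1", "m2"))
  expect_equal(unname(back[[1]]$probs), unname(pwms[[1]]$probs), tolerance = 1e-5)
  expect_equal(back[[2]]$width, 1)
})

test_that("malformed motif records raise parse errors naming the record", {
  f <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(">BAD1", "A [ 1 x ]", "C [ 0 1 ]", "G [ 0 0 ]", "T [ 0 0 ]"), f)
  expect_error(read_pwm_library(f), "BAD1")
  fneg <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(">NEG", "A [ -1 2 ]", "C [ 1 0 ]", "G [ 1 0 ]", "T [ 1 0 ]"), fneg)
  expect_error(read_pwm_library(fneg), "negative")
  fdup <- withr::local_tempfile(fileext = ".pfm")
  writeLines(rep(c(">D1", "1 1", "1 1", "1 1", "1 1"), 2), fdup)
  expect_error(read_pwm_library(fdup), "duplicate")
})

test_that("reverse_complement swaps bases, reverses positions, involutes", {
  a <- pwm("a", rbind(c(1, 0, 0, 0)))
  expect_equal(unname(reverse_complement(a)$probs), rbind(c(0, 0, 0, 1)))
  ac <- pwm("ac", rbind(c(1, 0, 0, 0), c(0, 1, 0, 0)))
  rc <- reverse_complement(ac)
  expect_equal(unname(rc$probs), rbind(c(0, 0, 1, 0), c(0, 0, 0, 1)))  # GT
  set.seed(42)
  for (i in 1:100) {
    p <- random_pwm()
    expect_equal(reverse_complement(reverse_complement(p))$probs, p$probs)
  }
})

test_that("log-likelihood window scoring matches hand arithmetic", {
  u <- background_model()
  unif <- pwm("u", matrix(0.25, nrow = 3, ncol = 4))
  expect_equal(log_likelihood_score(unif, "ACG", u), 0)
  p7 <- pwm("p7", matrix(c(0.7, 0.1, 0.1, 0.1), nrow = 2, ncol = 4,
                         byrow = TRUE))
  expect_equal(log_likelihood_score(p7, "AA", u), 2 * log2(0.7 / 0.25))
  expect_identical(log_likelihood_score(p7, "AN", u), -Inf)
  expect_error(log_likelihood_score(p7, "AAA", u), "width")
})

test_that("information content: uniform 0, one-hot 2 bits, hand value", {
  u <- background_model()
  expect_equal(information_content(pwm("u", matrix(0.25, 2, 4)), u), 0)
  expect_equal(information_content(pwm("h", rbind(c(1, 0, 0, 0))), u), 2)
  col <- pwm("c", matrix(c(0.7, 0.1, 0.1, 0.1), 1, 4))
  expect_equal(information_content(col, u),
               0.7 * log2(2.8) + 3 * 0.1 * log2(0.4))
})

test_that("PWM similarity: self and reverse complement score 1, one-hot -1/3", {
  set.seed(7)
  p <- random_pwm(8)
  expect_equal(pwm_similarity(p, p), 1)
  expect_equal(pwm_similarity(p, reverse_complement(p)), 1)
  aaaa <- pwm("A4", matrix(rep(c(1, 0, 0, 0), each = 4), 4, 4))
  cccc <- pwm("C4", matrix(rep(c(0, 1, 0, 0), each = 4), 4, 4))
  expect_equal(pwm_similarity(aaaa, cccc), -1 / 3)
  for (i in 1:50) {
    a <- random_pwm(sample(4:9, 1)); b <- random_pwm(sample(4:9, 1))
    s <- pwm_similarity(a, b)
    expect_equal(s, pwm_similarity(b, a))
    expect_true(s >= -1 && s <= 1)
  }
})

test_that("scan_sequence reports every above-threshold window on both strands", {
  u <- background_model()
  p7 <- pwm("p7", matrix(c(0.7, 0.1, 0.1, 0.1), nrow = 2, ncol = 4,
                         byrow = TRUE))
  polyA <- strrep("A", 20)
  hits <- scan_sequence(p7, polyA, u, threshold = 2)
  expect_equal(nrow(hits), 19)
  expect_true(all(hits$strand == "+"))
  expect_equal(hits$position, 0:18)
  expect_equal(hits$score, rep(2 * log2(0.7 / 0.25), 19))
  expect_equal(nrow(scan_sequence(p7, "", u, 2)), 0)
  expect_equal(nrow(scan_sequence(p7, polyA, u, threshold = 3)), 0)
  # N voids its windows
  hits_n <- scan_sequence(p7, "AANAA", u, threshold = 2)
  expect_equal(hits_n$position, c(0, 3))
})

test_that("scanner agrees exactly with the brute-force oracle", {
  set.seed(11)
  for (i in 1:20) {
    p <- random_pwm(sample(3:8, 1))
    s <- random_dna(sample(30:150, 1))
    bg <- background_model(prop.table(runif(4, 0.5, 1)))
    thr <- runif(1, -2, 4)
    got <- scan_sequence(p, s, bg, thr)
    want <- oracle_scan(p, s, bg, thr)
    expect_equal(got$position, want$position)
    expect_equal(got$strand, want$strand)
    expect_equal(got$score, want$score, tolerance = 1e-9)
  }
})

test_that("hit count is invariant under reverse-complementing the sequence", {
  set.seed(13)
  for (i in 1:20) {
    p <- random_pwm(sample(3:7, 1))
    s <- random_dna(80)
    bg <- background_model(prop.table(runif(4, 0.5, 1)))
    expect_equal(nrow(scan_sequence(p, s, bg, 1)),
                 nrow(scan_sequence(p, revcomp_str(s), bg, 1)))
    expect_equal(count_hits(p, s, bg, 1), count_hits(p, revcomp_str(s), bg, 1))
  }
})

test_that("merge_overlaps keeps the best hit among overlapping ones", {
  u <- background_model()
  pA <- pwm("pA", matrix(c(0.97, 0.01, 0.01, 0.01), nrow = 3, ncol = 4,
                         byrow = TRUE))
  hits <- scan_sequence(pA, strrep("A", 10), u, threshold = 2)
  merged <- scan_sequence(pA, strrep("A", 10), u, threshold = 2,
                          merge_overlaps = TRUE)
  expect_equal(nrow(hits), 8)
  expect_equal(nrow(merged), 3)  # width-3 windows at >= 3 bp spacing
  expect_true(all(diff(sort(merged$position)) >= 3))
})

test_that("probability rows sum to 1 after read/normalize/reverse-complement", {
  f <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(">M1", "3 1", "5 0", "2 7", "1 1"), f)
  lib <- read_pwm_library(f)
  expect_true(all(abs(rowSums(lib[[1]]$probs) - 1) < 1e-6))
  expect_true(all(abs(rowSums(reverse_complement(lib[[1]])$probs) - 1) < 1e-6))
})
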