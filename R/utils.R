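DNA_BASES <- c("A", "C", "G", "T")

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derived sub-seed, kept below 2^31.
sub_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(k) * 7L + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Byte -> base code lookup: A=0, C=1, G=2, T=3, anything else 4.
.code_lookup <- local({
  lk <- rep.int(4L, 256L)
  lk[utf8ToInt("A") + 1L] <- 0L
  lk[utf8ToInt("C") + 1L] <- 1L
  lk[utf8ToInt("G") + 1L] <- 2L
  lk[utf8ToInt("T") + 1L] <- 3L
  lk[utf8ToInt("a") + 1L] <- 0L
  lk[utf8ToInt("c") + 1L] <- 1L
  lk[utf8ToInt("g") + 1L] <- 2L
  lk[utf8ToInt("t") + 1L] <- 3L
  lk
})

encode_dna <- function(sequence) {
  if (!nzchar(sequence)) return(integer(0))
  .code_lookup[utf8ToInt(sequence) + 1L]
}

reverse_complement_string <- function(sequence) {
  chartr("ACGTacgt", "TGCAtgca", paste(rev(strsplit(sequence, "")[[1]]), collapse = ""))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

round_sig <- function(x, digits = 12L) {
  if (is.list(x)) return(lapply(x, round_sig, digits = digits))
  if (is.double(x)) return(signif(x, digits))
  x
}
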