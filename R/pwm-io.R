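#' Read a PWM library from a standard motif file
#'
#' Supports MEME minimal (letter-probability matrix blocks), JASPAR PFM
#' (`>` header plus four base rows of counts, with or without `A [ ... ]`
#' bracket syntax) and TRANSFAC (`PO`/`P0` blocks with numbered position
#' rows). Count (or probability) rows are normalized to probabilities after
#' adding `pseudocount` to every cell, so matrices with literal zeros never
#' produce `-Inf` log-likelihood terms downstream.
#'
#' @param path Motif file.
#' @param format One of `"auto"` (by extension: `.meme`/`.txt` MEME,
#'   `.pfm`/`.jaspar` JASPAR, `.transfac`/`.dat` TRANSFAC), `"meme"`,
#'   `"jaspar_pfm"`, `"transfac"`.
#' @param pseudocount Added to each matrix cell before row normalization.
#' @return List of [pwm()] objects with unique ids.
#' @export
read_pwm_library <- function(path, format = "auto", pseudocount = 1e-4) {
  if (!file.exists(path)) stop("motif file not found: ", path)
  format <- match.arg(format, c("auto", "meme", "jaspar_pfm", "transfac"))
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- switch(ext,
      meme = "meme", txt = "meme",
      pfm = "jaspar_pfm", jaspar = "jaspar_pfm",
      transfac = "transfac", dat = "transfac",
      stop("cannot auto-detect motif format from extension '.", ext,
           "'; pass `format` explicitly"))
  }
  lines <- readLines(path, warn = FALSE)
  pwms <- switch(format,
    meme = .parse_meme(lines, pseudocount),
    jaspar_pfm = .parse_jaspar(lines, pseudocount),
    transfac = .parse_transfac(lines, pseudocount))
  ids <- vapply(pwms, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate motif id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  pwms
}

# counts (rows = positions) -> pwm, with pseudocount normalization
.counts_to_pwm <- function(id, counts, name, source, pseudocount) {
  if (any(!is.finite(counts)))
    stop("motif '", id, "': non-numeric or non-finite matrix entry")
  if (any(counts < 0)) stop("motif '", id, "': negative counts")
  rs <- rowSums(counts)
  if (pseudocount <= 0 && any(rs == 0))
    stop("motif '", id, "': position with all-zero counts and no pseudocount")
  probs <- (counts + pseudocount) / (rs + 4 * pseudocount)
  pwm(id, probs, name = name, source = source)
}

.num_fields <- function(line) {
  x <- strsplit(trimws(line), "\\s+")[[1]]
  suppressWarnings(as.numeric(x))
}

.parse_meme <- function(lines, pseudocount) {
  motif_at <- grep("^MOTIF\\b", lines)
  if (!length(motif_at)) stop("no MOTIF records found (is this MEME minimal format?)")
  lapply(motif_at, function(i) {
    hdr <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    id <- hdr[2]
    name <- if (length(hdr) >= 3) hdr[3] else id
    j <- i + 1L
    while (j <= length(lines) && !grepl("^letter-probability matrix", lines[j])) {
      if (grepl("^MOTIF\\b", lines[j]))
        stop("motif '", id, "': missing letter-probability matrix")
      j <- j + 1L
    }
    if (j > length(lines)) stop("motif '", id, "': missing letter-probability matrix")
    w <- suppressWarnings(as.integer(sub(".*w= *([0-9]+).*", "\\1", lines[j])))
    rows <- list()
    k <- j + 1L
    while (k <= length(lines) && length(rows) < (if (is.na(w)) Inf else w)) {
      v <- .num_fields(lines[k])
      if (length(v) != 4 || any(is.na(v))) break
      rows[[length(rows) + 1L]] <- v
      k <- k + 1L
    }
    if (!is.na(w) && length(rows) != w)
      stop("motif '", id, "': expected ", w, " matrix rows, found ", length(rows))
    if (!length(rows)) stop("motif '", id, "': empty probability matrix")
    .counts_to_pwm(id, do.call(rbind, rows), name, "meme", pseudocount)
  })
}

.parse_jaspar <- function(lines, pseudocount) {
  lines <- lines[nzchar(trimws(lines))]
  hdr_at <- grep("^>", lines)
  if (!length(hdr_at)) stop("no '>' headers found (is this JASPAR PFM format?)")
  bounds <- c(hdr_at, length(lines) + 1L)
  lapply(seq_along(hdr_at), function(m) {
    i <- hdr_at[m]
    hdr <- strsplit(sub("^>\\s*", "", lines[i]), "\\s+")[[1]]
    id <- hdr[1]
    name <- if (length(hdr) >= 2) hdr[2] else id
    body <- lines[seq(i + 1L, length.out = bounds[m + 1L] - i - 1L)]
    if (length(body) < 4) stop("motif '", id, "': expected 4 base rows, found ", length(body))
    body <- body[1:4]
    letters <- toupper(sub("^\\s*([ACGTacgt]).*", "\\1", body))
    has_letters <- all(letters %in% DNA_BASES)
    rows <- lapply(body, function(ln) {
      ln <- gsub("^\\s*[ACGTacgt]?\\s*\\[?", "", ln)
      ln <- gsub("\\]", "", ln)
      v <- .num_fields(ln)
      if (any(is.na(v)) || !length(v)) stop("motif '", id, "': non-numeric matrix row")
      v
    })
    if (length(unique(lengths(rows))) != 1)
      stop("motif '", id, "': base rows have differing widths")
    counts <- do.call(rbind, rows)  # 4 x width, rows in file order
    if (has_letters) counts <- counts[match(DNA_BASES, letters), , drop = FALSE]
    .counts_to_pwm(id, t(counts), name, "jaspar", pseudocount)
  })
}

.parse_transfac <- function(lines, pseudocount) {
  po_at <- grep("^P[O0]\\b", lines)
  if (!length(po_at)) stop("no PO/P0 blocks found (is this TRANSFAC format?)")
  lapply(po_at, function(i) {
    # identifiers from the nearest preceding AC/ID lines
    before <- lines[seq_len(i - 1L)]
    ac <- grep("^AC\\s+", before, value = TRUE)
    idl <- grep("^ID\\s+", before, value = TRUE)
    id <- if (length(ac)) sub("^AC\\s+", "", ac[length(ac)])
          else if (length(idl)) sub("^ID\\s+", "", idl[length(idl)])
          else paste0("transfac_", i)
    name <- if (length(idl)) sub("^ID\\s+", "", idl[length(idl)]) else id
    rows <- list()
    k <- i + 1L
    while (k <= length(lines) && grepl("^[0-9]+\\s", lines[k])) {
      v <- .num_fields(lines[k])
      if (length(v) < 5 || any(is.na(v[2:5])))
        stop("motif '", id, "': malformed TRANSFAC position line: ", lines[k])
      rows[[length(rows) + 1L]] <- v[2:5]
      k <- k + 1L
    }
    if (!length(rows)) stop("motif '", id, "': PO block with no position rows")
    .counts_to_pwm(trimws(id), do.call(rbind, rows), trimws(name), "transfac", pseudocount)
  })
}

#' Write PWMs in MEME minimal format
#'
#' @param pwms List of [pwm()] objects.
#' @param path Output file.
#' @param background Optional [background_model()] recorded in the header.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwms, path, background = background_model()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", ""), con)
  writeLines(sprintf("Background letter frequencies\nA %.5f C %.5f G %.5f T %.5f\n",
                     background[1], background[2], background[3], background[4]), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s %s", p$id, p$name), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       p$width), con)
    writeLines(apply(p$probs, 1, function(r) paste(sprintf("%.6f", r), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}
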