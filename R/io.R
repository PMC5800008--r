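# File formats: six-letter FASTA, BED methylation positions, tab-separated
# query tables, record pools and plain-text affinity models.

#' Read and write methylation-aware FASTA
#'
#' FASTA is read through Biostrings as a BStringSet so that the lowercase
#' m/g letters survive; sequences are validated against the fragment-mode
#' grammar unless `validate = FALSE`.
#'
#' @param path File path.
#' @param validate Check the CpG grammar (default TRUE).
#' @return Named character vector of sequences.
#' @export
readMethylFasta <- function(path, validate = TRUE) {
  if (!file.exists(path))
    .stopf("no such file: %s", path, class = "methylShapeFileError")
  set <- Biostrings::readBStringSet(path)
  seqs <- stats::setNames(as.character(set), names(set))
  if (validate) .assertValid(seqs, "fragment", "FASTA sequence")
  seqs
}

#' @rdname readMethylFasta
#' @param seqs Named character vector of sequences.
#' @export
writeMethylFasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read methylation positions from a BED file
#'
#' Standard BED dialect: 0-based, half-open intervals.  Each interval must
#' have width 2 and cover a CpG dinucleotide of the named sequence; the
#' returned positions are 1-based indices of the C.
#'
#' @param path BED file path.
#' @param seqs Optional named sequences used to check that each interval
#'   covers a CpG.
#' @return data.frame with columns `name` and `pos` (1-based C position).
#' @export
readMethylationBed <- function(path, seqs = NULL) {
  if (!file.exists(path))
    .stopf("no such file: %s", path, class = "methylShapeFileError")
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0L)
    return(data.frame(name = character(0), pos = integer(0)))
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) == 0L)
    return(data.frame(name = character(0), pos = integer(0)))
  w <- GenomicRanges::width(gr)
  if (any(w != 2L))
    .stopf("BED interval(s) must have width 2 (cover a CpG); got width %s",
           paste(unique(w[w != 2L]), collapse = ","),
           class = "methylShapeFormatError")
  out <- data.frame(name = as.character(GenomicRanges::seqnames(gr)),
                    pos = GenomicRanges::start(gr))
  if (!is.null(seqs)) {
    for (i in seq_len(nrow(out))) {
      s <- seqs[[out$name[i]]]
      if (is.null(s))
        .stopf("BED names sequence %s absent from FASTA", out$name[i],
               class = "methylShapeFormatError")
      if (substring(s, out$pos[i], out$pos[i] + 1L) != "CG")
        .stopf("BED interval at %s:%d does not cover a CpG",
               out$name[i], out$pos[i], class = "methylShapeFormatError")
    }
  }
  out
}

.TABLE_COLS <- c("key", "MGW", "ProT", "Roll23", "Roll34", "HelT23",
                 "HelT34", "n")

#' Serialize and read pentamer query tables
#'
#' Tab-separated text: a header line followed by one row per canonical key
#' (key, MGW, ProT, Roll23, Roll34, HelT23, HelT34, n).  Values are written
#' with fixed decimal precision (default 2, the style of published shape
#' tables); missing values as NA.  `readQueryTable()` rejects malformed
#' rows and non-canonical keys with the offending line number.
#'
#' @param table A [QueryTable].
#' @param path Output path.
#' @param digits Decimal places to serialize.
#' @return `readQueryTable()` returns a [QueryTable].
#' @export
writeQueryTable <- function(table, path, digits = 2L) {
  stopifnot(is(table, "QueryTable"))
  e <- table@entries
  fmt <- function(x) ifelse(is.na(x), "NA", formatC(x, format = "f",
                                                    digits = digits))
  lines <- c(paste(.TABLE_COLS, collapse = "\t"),
             paste(e$key, fmt(e$mgw), fmt(e$prot), fmt(e$roll23),
                   fmt(e$roll34), fmt(e$helt23), fmt(e$helt34), e$n,
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeQueryTable
#' @export
readQueryTable <- function(path) {
  if (!file.exists(path))
    .stopf("no such file: %s", path, class = "methylShapeFileError")
  lines <- readLines(path)
  if (!length(lines) || !identical(strsplit(lines[1L], "\t")[[1L]],
                                   .TABLE_COLS))
    .stopf("line 1: bad or missing header", class = "methylShapeFormatError")
  body <- lines[-1L]
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != length(.TABLE_COLS)))
    .stopf("line %d: expected %d fields, found %d",
           which(nf != length(.TABLE_COLS))[1L] + 1L, length(.TABLE_COLS),
           nf[nf != length(.TABLE_COLS)][1L],
           class = "methylShapeFormatError")
  m <- matrix(unlist(parts), ncol = length(.TABLE_COLS), byrow = TRUE)
  keys <- m[, 1L]
  okkey <- isValidMethylSeq(keys, "window") & nchar(keys) == 5L
  if (!all(okkey))
    .stopf("line %d: invalid key %s", which(!okkey)[1L] + 1L,
           keys[!okkey][1L], class = "methylShapeFormatError")
  ck <- canonicalKey(keys)
  if (any(ck$flipped))
    .stopf("line %d: non-canonical key %s", which(ck$flipped)[1L] + 1L,
           keys[ck$flipped][1L], class = "methylShapeFormatError")
  num <- function(j) suppressWarnings(as.numeric(m[, j]))
  vals <- lapply(2L:7L, num)
  bad <- Reduce(`|`, lapply(seq_along(vals),
                            function(j) is.na(vals[[j]]) & m[, j + 1L] != "NA"))
  if (any(bad))
    .stopf("line %d: non-numeric value", which(bad)[1L] + 1L,
           class = "methylShapeFormatError")
  entries <- data.frame(key = keys, mgw = vals[[1L]], prot = vals[[2L]],
                        roll23 = vals[[3L]], roll34 = vals[[4L]],
                        helt23 = vals[[5L]], helt34 = vals[[6L]],
                        n = as.integer(m[, 8L]))
  methods::new("QueryTable", entries = entries,
               metadata = list(source = path))
}

#' Serialize and read shape-record pools
#'
#' Tab-separated text, one row per record: fragment id, sequence, then
#' semicolon-joined per-position MGW and ProT lists (N values) and per-step
#' Roll and HelT lists (N-1 values); undefined entries as NA.  Reading is
#' gzip-transparent.
#'
#' @param pool A [ShapeRecordPool].
#' @param path File path (a `.gz` suffix is honoured on read and write).
#' @param digits Decimal places to serialize (default 4).
#' @return `readRecordPool()` returns a [ShapeRecordPool].
#' @export
writeRecordPool <- function(pool, path, digits = 4L) {
  stopifnot(is(pool, "ShapeRecordPool"))
  join <- function(x) paste(ifelse(is.na(x), "NA",
                                   formatC(x, format = "f", digits = digits)),
                            collapse = ";")
  bo <- .bpOffsets(pool); so <- .stepOffsets(pool)
  rows <- vapply(seq_along(pool@id), function(i) {
    n <- pool@len[i]
    paste(pool@id[i], pool@seq[i],
          join(pool@mgw[bo[i] + seq_len(n)]),
          join(pool@prot[bo[i] + seq_len(n)]),
          join(pool@roll[so[i] + seq_len(n - 1L)]),
          join(pool@helt[so[i] + seq_len(n - 1L)]),
          sep = "\t")
  }, "")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c("id\tseq\tMGW\tProT\tRoll\tHelT", rows), con)
  invisible(path)
}

#' @rdname writeRecordPool
#' @export
readRecordPool <- function(path) {
  if (!file.exists(path))
    .stopf("no such file: %s", path, class = "methylShapeFileError")
  lines <- readLines(path)  # file() under readLines is gzip-transparent
  if (!length(lines) || !identical(lines[1L], "id\tseq\tMGW\tProT\tRoll\tHelT"))
    .stopf("line 1: bad or missing header", class = "methylShapeFormatError")
  parts <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 6L))
    .stopf("line %d: expected 6 fields", which(nf != 6L)[1L] + 1L,
           class = "methylShapeFormatError")
  m <- matrix(unlist(parts), ncol = 6L, byrow = TRUE)
  splitNum <- function(x) lapply(strsplit(x, ";", fixed = TRUE),
                                 function(v) suppressWarnings(as.numeric(v)))
  mgw <- splitNum(m[, 3L]); prot <- splitNum(m[, 4L])
  roll <- splitNum(m[, 5L]); helt <- splitNum(m[, 6L])
  n <- nchar(m[, 2L])
  bad <- which(lengths(mgw) != n | lengths(prot) != n |
                 lengths(roll) != n - 1L | lengths(helt) != n - 1L)
  if (length(bad))
    .stopf("line %d: feature list length mismatch", bad[1L] + 1L,
           class = "methylShapeFormatError")
  ShapeRecordPool(id = m[, 1L], seq = m[, 2L], mgw = mgw, prot = prot,
                  roll = roll, helt = helt,
                  metadata = list(source = path))
}

#' Serialize and read affinity models
#'
#' Plain-text key=value format: header keys (`lambda1`, `lambda2`,
#' `intercept`, `layout`, `dropped`) followed by one `w.<feature>=<value>`
#' line per layout entry.
#'
#' @param model An [AffinityModel].
#' @param path File path.
#' @return `readAffinityModel()` returns an [AffinityModel].
#' @export
writeAffinityModel <- function(model, path) {
  stopifnot(is(model, "AffinityModel"))
  w <- stats::setNames(rep(0, length(model@layout)), model@layout)
  w[names(model@weights)] <- model@weights
  lines <- c(sprintf("lambda1=%.10g", model@lambda1),
             sprintf("lambda2=%.10g", model@lambda2),
             sprintf("intercept=%.10g", model@intercept),
             sprintf("layout=%s", paste(model@layout, collapse = ",")),
             sprintf("dropped=%s", paste(model@dropped, collapse = ",")),
             sprintf("w.%s=%.10g", names(w), w))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeAffinityModel
#' @export
readAffinityModel <- function(path) {
  if (!file.exists(path))
    .stopf("no such file: %s", path, class = "methylShapeFileError")
  lines <- readLines(path)
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  get1 <- function(k) {
    i <- match(k, keys)
    if (is.na(i)) .stopf("missing field %s", k,
                         class = "methylShapeFormatError")
    vals[i]
  }
  layout <- strsplit(get1("layout"), ",", fixed = TRUE)[[1L]]
  droppedStr <- get1("dropped")
  dropped <- if (nzchar(droppedStr))
    strsplit(droppedStr, ",", fixed = TRUE)[[1L]] else character(0)
  wIdx <- grepl("^w\\.", keys)
  w <- stats::setNames(as.numeric(vals[wIdx]), sub("^w\\.", "", keys[wIdx]))
  methods::new("AffinityModel",
               weights = w[layout[layout %in% names(w)]],
               intercept = as.numeric(get1("intercept")),
               lambda1 = as.numeric(get1("lambda1")),
               lambda2 = as.numeric(get1("lambda2")),
               layout = layout, dropped = dropped,
               metadata = list(source = path))
}
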