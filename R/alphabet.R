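# Expanded-alphabet sequence model for CpG-methylated DNA.
#
# Sequences are strings over {A, C, G, T, m, g}: "m" is 5-methylcytosine and
# "g" the guanine base-paired with an "m" on the opposite strand.  Because
# mammalian CpG methylation is symmetric (both cytosines of the CpG are
# methylated; partial methylation is not modelled), "m" and "g" are not
# independent letters: they occur only as the dinucleotide unit "mg".  Two
# grammar modes exist:
#
#  * fragment mode -- full sequences: every "m" is immediately followed by
#    "g" and every "g" immediately preceded by "m";
#  * window mode -- k-mer windows cut from a valid fragment: additionally a
#    trailing "m" (its "g" lies beyond the window) and a leading "g" (its
#    "m" lies before the window) are allowed.

.METHYL_LETTERS <- c("A", "C", "G", "T", "m", "g")

# Fixed total order used for canonicalization: A < C < G < T < g < m.
# This order is load-bearing: serialized tables key on the canonical form,
# so it must be stable across platforms and locales.  Comparison is done on
# a digit transliteration, which is locale-independent.
.rankKey <- function(x) chartr("ACGTgm", "123456", x)

#' Complement bases of the methylation-aware alphabet
#'
#' Watson-Crick complement extended to the expanded alphabet:
#' A<->T, C<->G and m<->g ("g" is by definition the base paired with
#' 5-methylcytosine, so the complement of "m" is "g" and vice versa).
#'
#' @param base Character vector of single letters in `A,C,G,T,m,g`.
#' @return Character vector of complemented letters.
#' @examples
#' methylComplement(c("A", "m", "g"))
#' @export
methylComplement <- function(base) {
  if (!is.character(base))
    .stopf("base letters must be character", class = "methylShapeAlphabetError")
  bad <- !(base %in% .METHYL_LETTERS)
  if (any(bad))
    .stopf("unknown symbol(s): %s", paste(unique(base[bad]), collapse = ", "),
           class = "methylShapeAlphabetError")
  chartr("ACGTmg", "TGCAgm", base)
}

#' Reverse complement of methylation-aware sequences
#'
#' Vectorized over input strings.  Validity is preserved in both grammar
#' modes: a leading "g" maps to a trailing "m" and vice versa.
#'
#' @param x Character vector of sequences over `A,C,G,T,m,g`.
#' @return Character vector of reverse complements.
#' @examples
#' methylRevComp(c("ACGTA", "AAmgT", "mg"))
#' @export
methylRevComp <- function(x) {
  bad <- grepl("[^ACGTmg]", x)
  if (any(bad))
    .stopf("invalid letters in sequence(s): %s",
           paste(utils::head(x[bad], 3L), collapse = ", "),
           class = "methylShapeAlphabetError")
  comp <- chartr("ACGTmg", "TGCAgm", x)
  vapply(.splitChars(comp), function(ch) paste(rev(ch), collapse = ""), "")
}

#' Validate a sequence against the CpG-methylation grammar
#'
#' Diagnostic validation: rather than failing, every grammar violation is
#' reported with its position.  In `"fragment"` mode each "m" must be
#' followed by "g" and each "g" preceded by "m"; `"window"` mode further
#' permits a trailing "m" and a leading "g" (their partners lie outside the
#' window).
#'
#' @param seq Single sequence string.
#' @param mode `"fragment"` or `"window"`.
#' @return A data.frame with columns `pos`, `letter`, `problem`
#'   (zero rows when the sequence is valid).
#' @examples
#' validateMethylSeq("AAmgT", "fragment")       # ok: zero rows
#' validateMethylSeq("gmgAm", "fragment")       # leading g, trailing m
#' validateMethylSeq("gmgAm", "window")         # ok
#' @export
validateMethylSeq <- function(seq, mode = c("fragment", "window")) {
  mode <- match.arg(mode)
  stopifnot(is.character(seq), length(seq) == 1L)
  ch <- .splitChars(seq)[[1L]]
  n <- length(ch)
  out <- list()
  add <- function(pos, letter, problem)
    out[[length(out) + 1L]] <<- data.frame(pos = pos, letter = letter,
                                           problem = problem)
  bad <- which(!(ch %in% .METHYL_LETTERS))
  for (i in bad) add(i, ch[i], "letter outside {A,C,G,T,m,g}")
  for (i in which(ch == "m")) {
    if (i == n) {
      if (mode == "fragment") add(i, "m", "m at final position lacks its g")
    } else if (ch[i + 1L] != "g") add(i, "m", "m not followed by g")
  }
  for (i in which(ch == "g")) {
    if (i == 1L) {
      if (mode == "fragment") add(i, "g", "g at first position lacks its m")
    } else if (ch[i - 1L] != "m") add(i, "g", "g not preceded by m")
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(pos = integer(0), letter = character(0),
                  problem = character(0))
}

#' @rdname validateMethylSeq
#' @param x Character vector of sequences.
#' @return `isValidMethylSeq`: logical vector.
#' @export
isValidMethylSeq <- function(x, mode = c("fragment", "window")) {
  mode <- match.arg(mode)
  vapply(x, function(s) nrow(validateMethylSeq(s, mode)) == 0L, NA,
         USE.NAMES = FALSE)
}

.assertValid <- function(x, mode, what = "sequence") {
  ok <- isValidMethylSeq(x, mode)
  if (!all(ok))
    .stopf("invalid %s (%s mode): %s", what, mode,
           paste(utils::head(x[!ok], 3L), collapse = ", "),
           class = "methylShapeAlphabetError")
  invisible(x)
}

#' Methylate CpG dinucleotides of a standard DNA sequence
#'
#' Replaces targeted CpG steps by "mg".  Methylation is always symmetric:
#' a single call marks both strands via the paired letters.
#'
#' @param seq Standard DNA string over `A,C,G,T`.
#' @param positions Integer vector of 1-based positions of the C of each
#'   CpG to methylate, or `"all_cpg"` (default) for every CG dinucleotide.
#' @return Fragment-valid methylation-aware sequence.
#' @examples
#' methylateSeq("AACGT")                 # "AAmgT"
#' methylateSeq("ACGCGT")                # "AmgmgT"
#' methylateSeq("TACGTACGT", positions = 3)
#' @export
methylateSeq <- function(seq, positions = "all_cpg") {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (grepl("[^ACGT]", seq))
    .stopf("methylateSeq expects a standard DNA sequence over {A,C,G,T}",
           class = "methylShapeAlphabetError")
  if (identical(positions, "all_cpg")) {
    positions <- .fixedMatches(seq, "CG")
  } else {
    positions <- as.integer(positions)
  }
  if (!length(positions)) return(seq)
  ch <- .splitChars(seq)[[1L]]
  for (i in positions) {
    if (i < 1L || i + 1L > length(ch) || ch[i] != "C" || ch[i + 1L] != "G")
      .stopf("position %d does not carry a CpG dinucleotide", i,
             class = "methylShapeMethylationError")
    ch[i] <- "m"; ch[i + 1L] <- "g"
  }
  paste(ch, collapse = "")
}

#' @rdname methylateSeq
#' @description `demethylateSeq()` strips methylation marks (m -> C, g -> G),
#'   recovering the underlying standard sequence.
#' @export
demethylateSeq <- function(seq) chartr("mg", "CG", seq)

#' Canonical (strand-independent) form of a k-mer
#'
#' The canonical key of `p` is the lexicographic minimum of `p` and its
#' reverse complement under the fixed letter order A < C < G < T < g < m.
#' Query tables are keyed on canonical pentamers, so a sequence and its
#' reverse complement always resolve to the same table entry.
#'
#' @param p Character vector of window-valid k-mers.
#' @param validate Check window-mode validity (default TRUE).
#' @return data.frame with columns `key` (canonical form) and `flipped`
#'   (TRUE when the reverse complement was chosen).
#' @examples
#' canonicalKey(c("TTTTT", "AmgTT"))
#' @export
canonicalKey <- function(p, validate = TRUE) {
  if (validate) .assertValid(p, "window", "k-mer")
  rc <- methylRevComp(p)
  flipped <- .rankKey(rc) < .rankKey(p)
  data.frame(key = ifelse(flipped, rc, p), flipped = flipped)
}

# All window-valid strings of length k over the expanded alphabet,
# enumerated by brute force and filtered by the grammar.  Cached.
.windowValidKmers <- function(k) {
  slot <- paste0("wv", k)
  if (!is.null(.msCache[[slot]])) return(.msCache[[slot]])
  grids <- rep(list(.METHYL_LETTERS), k)
  all <- do.call(paste0, expand.grid(grids, stringsAsFactors = FALSE,
                                     KEEP.OUT.ATTRS = FALSE))
  mat <- matrix(unlist(.splitChars(all)), ncol = k, byrow = TRUE)
  ok <- rep(TRUE, length(all))
  for (i in seq_len(k)) {
    isM <- mat[, i] == "m"
    isG <- mat[, i] == "g"
    if (i < k) ok <- ok & !(isM & mat[, i + 1L] != "g")
    if (i > 1L) ok <- ok & !(isG & mat[, i - 1L] != "m")
  }
  res <- all[ok]
  .msCache[[slot]] <- res
  res
}

# Canonicalization lookup for all window-valid k-mers: named vectors
# key[kmer], flipped[kmer].  Cached per k.
.canonMap <- function(k) {
  slot <- paste0("canon", k)
  if (!is.null(.msCache[[slot]])) return(.msCache[[slot]])
  wv <- .windowValidKmers(k)
  ck <- canonicalKey(wv, validate = FALSE)
  m <- list(key = stats::setNames(ck$key, wv),
            flipped = stats::setNames(ck$flipped, wv))
  .msCache[[slot]] <- m
  m
}

#' Enumerate canonical pentamers of the methylation-aware universe
#'
#' Exhaustively enumerates window-valid pentamers and deduplicates them
#' under reverse complementation.  The unmethylated universe holds 512
#' canonical pentamers; introducing the m/g letters adds 475 new canonical
#' pentamers (950 window-valid strings before deduplication), for a total
#' table universe of 987 keys.
#'
#' @param kind `"unmethylated"`, `"methylated_new"` (contains at least one
#'   of m/g) or `"all"`.
#' @return Sorted character vector of canonical pentamer keys.
#' @examples
#' length(enumeratePentamers("unmethylated"))   # 512
#' length(enumeratePentamers("methylated_new")) # 475
#' @export
enumeratePentamers <- function(kind = c("all", "unmethylated",
                                        "methylated_new")) {
  kind <- match.arg(kind)
  wv <- .windowValidKmers(5L)
  keys <- unique(.canonMap(5L)$key[wv])
  meth <- grepl("[mg]", keys)
  sel <- switch(kind, all = keys, unmethylated = keys[!meth],
                methylated_new = keys[meth])
  sel[order(.rankKey(sel))]
}

#' Count CpG steps of a pentamer
#'
#' Counts occurrences of the CG and mg dinucleotides.  Used e.g. to select
#' the 116 canonical pentamers carrying exactly one CpG step, on which the
#' methylation effect-size analysis operates.
#'
#' @param p Character vector of window-valid k-mers.
#' @return Integer vector of CpG/mpg step counts.
#' @examples
#' countCpGSteps(c("ACGTA", "CGCGA", "AAmgT"))
#' @export
countCpGSteps <- function(p) {
  .assertValid(p, "window", "k-mer")
  vapply(p, function(s)
    length(.fixedMatches(s, "CG")) + length(.fixedMatches(s, "mg")),
    0L, USE.NAMES = FALSE)
}
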