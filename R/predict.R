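# Sliding-window shape prediction and methylation-induced shape change.

#' Predict a shape profile for a sequence
#'
#' Slides a pentamer window over the sequence: the shape features at
#' position i are looked up from the table using the pentamer
#' N(i-2)..N(i+2), so a sequence of length N yields N - 4 defined MGW/ProT
#' positions (3..N-2).  Step features are assembled from the two pentamer
#' windows that cover a step: the step between bp s and s+1 receives the
#' roll34/helt34 slot of the window centred at s and the roll23/helt23
#' slot of the window centred at s+1.  Under the default `"average"`
#' policy the two contributions are averaged; the two boundary steps (2
#' and N-2) have a single available contribution, which is used as is.
#' `"five_prime"`/`"three_prime"` keep only the upstream/downstream
#' window's slot where both exist.
#'
#' @param seq Fragment-valid methylation-aware sequence, length >= 5.
#' @param table A [QueryTable] covering the queried pentamers.
#' @param stepPolicy Step assembly policy (see Details).
#' @param missing Missing-key policy passed to [queryShape()].
#' @return A [ShapeProfile].
#' @export
shapeProfile <- function(seq, table,
                         stepPolicy = c("average", "five_prime",
                                        "three_prime"),
                         missing = c("na", "error")) {
  stepPolicy <- match.arg(stepPolicy)
  missing <- match.arg(missing)
  stopifnot(is.character(seq), length(seq) == 1L)
  n <- nchar(seq)
  if (n < 5L)
    .stopf("sequence shorter than 5 bp", class = "methylShapeInputError")
  .assertValid(seq, "fragment")

  centers <- 3:(n - 2L)
  pent <- substring(seq, centers - 2L, centers + 2L)
  q <- queryShape(table, pent, missing = missing)

  mgw <- rep(NA_real_, n); prot <- rep(NA_real_, n)
  mgw[centers] <- q$mgw
  prot[centers] <- q$prot

  roll <- rep(NA_real_, n - 1L); helt <- rep(NA_real_, n - 1L)
  # value34[c] / value23[c]: slot of the window centred at c
  v34 <- rep(NA_real_, n); v23 <- rep(NA_real_, n)
  h34 <- rep(NA_real_, n); h23 <- rep(NA_real_, n)
  v34[centers] <- q$roll34; v23[centers] <- q$roll23
  h34[centers] <- q$helt34; h23[centers] <- q$helt23
  steps <- 2:(n - 2L)
  combine <- function(up, down) {
    both <- cbind(up, down)
    switch(stepPolicy,
           average = rowMeans(both, na.rm = TRUE),
           five_prime = ifelse(is.na(up), down, up),
           three_prime = ifelse(is.na(down), up, down))
  }
  roll[steps] <- combine(v34[steps], v23[steps + 1L])
  helt[steps] <- combine(h34[steps], h23[steps + 1L])
  roll[is.nan(roll)] <- NA_real_
  helt[is.nan(helt)] <- NA_real_

  methods::new("ShapeProfile", seq = seq, mgw = mgw, prot = prot,
               roll = roll, helt = helt, kind = "shape")
}

#' Methylation-induced shape change (delta-shape)
#'
#' Computes `profile(methylated) - profile(unmethylated)` elementwise.  The
#' methylated sequence is profiled against the methylation-aware table
#' (mPQT) and the unmethylated sequence against the unmethylated table
#' (PQT); NA propagates.  An empty methylation specification yields an
#' identically zero profile (defined entries 0, boundaries NA).
#'
#' @param seq Standard DNA sequence over `A,C,G,T`.
#' @param methylation Integer positions of CpG cytosines to methylate,
#'   `"all_cpg"`, or `NULL`/empty for no methylation.
#' @param pqt Unmethylated [QueryTable].
#' @param mpqt Methylation-aware [QueryTable].
#' @param ... Passed on to [shapeProfile()] (step policy, missing-key
#'   policy).
#' @return A [ShapeProfile] of kind `"delta"`.
#' @export
deltaShape <- function(seq, methylation = "all_cpg", pqt, mpqt, ...) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (identical(methylation, "all_cpg"))
    methylation <- .fixedMatches(seq, "CG")
  n <- nchar(seq)
  if (is.null(methylation) || !length(methylation)) {
    zero <- function(len, lo, hi) {
      v <- rep(NA_real_, len); v[lo:hi] <- 0; v
    }
    return(methods::new("ShapeProfile", seq = seq,
                        mgw = zero(n, 3L, n - 2L),
                        prot = zero(n, 3L, n - 2L),
                        roll = zero(n - 1L, 2L, n - 2L),
                        helt = zero(n - 1L, 2L, n - 2L),
                        kind = "delta"))
  }
  mseq <- methylateSeq(seq, methylation)
  pm <- shapeProfile(mseq, mpqt, ...)
  pu <- shapeProfile(seq, pqt, ...)
  methods::new("ShapeProfile", seq = mseq,
               mgw = pm@mgw - pu@mgw, prot = pm@prot - pu@prot,
               roll = pm@roll - pu@roll, helt = pm@helt - pu@helt,
               kind = "delta")
}

#' Context-matched methylation effect on minor groove width
#'
#' When a CpG has only one bp inside the pentamer window of the queried
#' position (its C at window position 5, or its g at window position 1),
#' the methylated pentamer implies the identity of a sixth base beyond the
#' window (an "m" at position 5 guarantees a following g), while the
#' unmethylated pentamer implies nothing.  The plain PQT reference then
#' averages over contexts the mPQT value never saw, confounding the
#' methylation estimate.  Here the unmethylated reference is taken from a
#' CpG-context table instead -- the hexamer-ending-in-CG table when one
#' window boundary touches a CpG, the CG-flank heptamer table when both
#' do -- so both terms of the difference share the implied context.  When
#' the full CpG lies inside the window there is no confound and the result
#' equals the plain delta-shape MGW.
#'
#' @param seq Standard DNA sequence over `A,C,G,T`.
#' @param at Query position (1-based) whose MGW is evaluated.
#' @param methylation Integer positions of CpG cytosines to methylate.
#' @param pqt,mpqt Pentamer tables.
#' @param hexTable Hexamer [ContextTable] (`NNNNCG`).
#' @param heptTable Heptamer [ContextTable] (`CGNNNCG`); only needed for
#'   doubly-flanked windows.
#' @return One-row data.frame: `pos`, `delta_mgw`, `mgw_meth`,
#'   `mgw_unmeth`, `context_kmer`, `context_kind`.
#' @export
contextMatchedDeltaMGW <- function(seq, at, methylation, pqt, mpqt,
                                   hexTable = NULL, heptTable = NULL) {
  stopifnot(is.character(seq), length(seq) == 1L)
  n <- nchar(seq)
  if (at < 3L || at > n - 2L)
    .stopf("query position %d has no full pentamer window", at,
           class = "methylShapeInputError")
  mseq <- methylateSeq(seq, methylation)
  pentM <- substring(mseq, at - 2L, at + 2L)
  pentU <- substring(seq, at - 2L, at + 2L)
  mgwMeth <- queryShape(mpqt, pentM)$mgw

  chM <- .splitChars(pentM)[[1L]]
  trailingM <- chM[5L] == "m"
  leadingG <- chM[1L] == "g"

  if (!trailingM && !leadingG) {
    # full CpG (if any) inside the window: no confound, plain reference
    mgwUn <- queryShape(pqt, pentU)$mgw
    kmer <- pentU; kind <- "pentamer"
  } else if (trailingM && leadingG) {
    if (is.null(heptTable))
      .stopf("heptamer context table required for CpG at both window flanks")
    if (at - 3L < 1L || at + 3L > n)
      .stopf("sequence too short for heptamer context at position %d", at,
             class = "methylShapeInputError")
    kmer <- substring(seq, at - 3L, at + 3L)
    mgwUn <- queryContext(heptTable, kmer, 4L, "MGW")
    kind <- "heptamer"
  } else {
    if (is.null(hexTable))
      .stopf("hexamer context table required for CpG at a window flank")
    if (trailingM) {
      if (at + 3L > n)
        .stopf("sequence too short for hexamer context at position %d", at,
               class = "methylShapeInputError")
      kmer <- substring(seq, at - 2L, at + 3L)   # ends with CG
      pos <- 3L
    } else {
      if (at - 3L < 1L)
        .stopf("sequence too short for hexamer context at position %d", at,
               class = "methylShapeInputError")
      kmer <- substring(seq, at - 3L, at + 2L)   # starts with CG
      pos <- 4L
    }
    mgwUn <- queryContext(hexTable, kmer, pos, "MGW")
    kind <- "hexamer"
  }
  data.frame(pos = at, delta_mgw = mgwMeth - mgwUn,
             mgw_meth = mgwMeth, mgw_unmeth = mgwUn,
             context_kmer = kmer, context_kind = kind)
}

#' Methylation-induced MGW change at the AY positions of a Pbx-Hox site
#'
#' Evaluates the context-matched delta-MGW at the two adenines flanking
#' the central spacer of a 12-bp Pbx-Hox binding site (pattern
#' `NTGAYNNAYNNN`; positions 4 and 8), for a single methylated CpG at the
#' given offset.  Minor groove narrowing at these positions is associated
#' with enhanced binding, so a methylation-induced widening predicts
#' suppressed binding.
#'
#' @param site 12-mer matching `NTGAYNNAYNNN`.
#' @param methPos 1-based position of the methylated CpG's cytosine.
#' @param pqt,mpqt,hexTable,heptTable Tables as in
#'   [contextMatchedDeltaMGW()].
#' @return data.frame with one row per AY position: `position`,
#'   `offset_class`, `delta_mgw`, `context_kmer`, `context_kind`.
#' @export
pbxHoxDeltaMGW <- function(site, methPos, pqt, mpqt,
                           hexTable = NULL, heptTable = NULL) {
  offset <- classifyCpGOffset(site, methPos)
  out <- lapply(c(4L, 8L), function(at) {
    r <- contextMatchedDeltaMGW(site, at, methPos, pqt, mpqt,
                                hexTable, heptTable)
    data.frame(position = at, offset_class = offset,
               delta_mgw = r$delta_mgw, context_kmer = r$context_kmer,
               context_kind = r$context_kind)
  })
  do.call(rbind, out)
}
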