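# Mining shape-record pools into pentamer query tables, and querying them.

#' Mine pentamer occurrences from a shape-record pool
#'
#' Slides a 5-bp window over every record and emits one occurrence per
#' window under the window's canonical key.  A window centred at position c
#' contributes MGW and ProT from the central bp (position c), Roll and HelT
#' from the window's steps 2-3 (fragment step c-1) and 3-4 (fragment step
#' c).  Only windows whose central bp lies at least `2 + margin` positions
#' from each fragment end are mined (centres in `[3 + margin, N - 2 -
#' margin]`); the default 1-bp margin keeps terminal positions, which in
#' simulated trajectories are affected by end fraying, out of the tables.
#' When the canonical form is the reverse complement of the observed
#' window, the two step slots are swapped (MGW and ProT are strand
#' symmetric at the central bp and unchanged).
#'
#' @param pool A ShapeRecordPool.
#' @param margin Non-negative integer, extra exclusion beyond the
#'   geometric minimum of 2 bp.
#' @return data.frame with columns `record`, `center`, `pentamer`, `key`,
#'   `flipped`, `mgw`, `prot`, `roll23`, `roll34`, `helt23`, `helt34`;
#'   one row per mined window.  A fragment of length N yields
#'   `N - 4 - 2*margin` windows.
#' @export
mineOccurrences <- function(pool, margin = 1L) {
  stopifnot(is(pool, "ShapeRecordPool"), margin >= 0L)
  margin <- as.integer(margin)
  nwin <- pmax(0L, pool@len - 4L - 2L * margin)
  if (sum(nwin) == 0L)
    return(data.frame(record = character(0), center = integer(0),
                      pentamer = character(0), key = character(0),
                      flipped = logical(0), mgw = numeric(0),
                      prot = numeric(0), roll23 = numeric(0),
                      roll34 = numeric(0), helt23 = numeric(0),
                      helt34 = numeric(0)))
  rec <- rep(seq_along(pool@len), nwin)
  centers <- sequence(nwin, from = 3L + margin)
  pent <- substring(pool@seq[rec], centers - 2L, centers + 2L)

  bo <- .bpOffsets(pool)[rec]
  so <- .stepOffsets(pool)[rec]
  mgw <- pool@mgw[bo + centers]
  prot <- pool@prot[bo + centers]
  r23 <- pool@roll[so + centers - 1L]
  r34 <- pool@roll[so + centers]
  h23 <- pool@helt[so + centers - 1L]
  h34 <- pool@helt[so + centers]

  cm <- .canonMap(5L)
  key <- unname(cm$key[pent])
  if (anyNA(key))
    .stopf("window(s) not valid in window mode: %s",
           paste(utils::head(unique(pent[is.na(key)]), 3L), collapse = ", "))
  flip <- unname(cm$flipped[pent])

  data.frame(record = pool@id[rec], center = centers, pentamer = pent,
             key = key, flipped = flip, mgw = mgw, prot = prot,
             roll23 = ifelse(flip, r34, r23),
             roll34 = ifelse(flip, r23, r34),
             helt23 = ifelse(flip, h34, h23),
             helt34 = ifelse(flip, h23, h34))
}

.resolveUniverse <- function(universe) {
  if (is.character(universe) && length(universe) == 1L &&
      universe %in% c("all", "unmethylated", "methylated_new"))
    enumeratePentamers(universe)
  else {
    ck <- canonicalKey(universe)
    if (any(ck$flipped)) .stopf("universe keys must be canonical")
    universe
  }
}

#' Build a pentamer query table from a shape-record pool
#'
#' Each table entry is the arithmetic mean of each of the six feature slots
#' over all mined occurrences of the canonical key; all occurrences in the
#' pool are weighted equally (not averaged per fragment first).  Keys with
#' fewer than `minOccurrences` occurrences are flagged missing.
#'
#' @param pool A ShapeRecordPool.
#' @param universe Keyword (`"all"`, `"unmethylated"`, `"methylated_new"`)
#'   or explicit character vector of canonical keys the table must cover.
#' @param margin Mining margin, see [mineOccurrences()].
#' @param minOccurrences Minimum occurrence count per key (default 1).
#' @param missing `"error"` (default) fails on an incomplete universe,
#'   `"na"` stores missing keys with NA values and their (sub-threshold)
#'   count.
#' @return A [QueryTable].
#' @export
buildQueryTable <- function(pool, universe = "all", margin = 1L,
                            minOccurrences = 1L,
                            missing = c("error", "na")) {
  missing <- match.arg(missing)
  if (length(pool) == 0L) .stopf("empty pool")
  universe <- .resolveUniverse(universe)
  if (!length(universe)) .stopf("empty universe")
  occ <- mineOccurrences(pool, margin)
  if (!nrow(occ)) .stopf("pool contributes zero occurrences")

  g <- factor(occ$key, levels = sort(unique(occ$key)))
  vals <- as.matrix(occ[, c("mgw", "prot", "roll23", "roll34",
                            "helt23", "helt34")])
  sums <- rowsum(vals, g)
  cnt <- as.integer(tabulate(g, nbins = nlevels(g)))
  means <- sums / cnt

  idx <- match(universe, levels(g))
  n <- ifelse(is.na(idx), 0L, cnt[idx])
  entries <- data.frame(key = universe,
                        mgw = means[idx, "mgw"], prot = means[idx, "prot"],
                        roll23 = means[idx, "roll23"],
                        roll34 = means[idx, "roll34"],
                        helt23 = means[idx, "helt23"],
                        helt34 = means[idx, "helt34"],
                        n = n, row.names = NULL)
  low <- entries$n < minOccurrences
  if (any(low)) {
    if (missing == "error")
      .stopf("%d universe key(s) below %d occurrences (e.g. %s)",
             sum(low), minOccurrences,
             paste(utils::head(entries$key[low], 3L), collapse = ", "),
             class = "methylShapeMissingKeyError")
    entries[low, c("mgw", "prot", "roll23", "roll34", "helt23", "helt34")] <-
      NA_real_
  }
  methods::new("QueryTable", entries = entries,
               metadata = list(pool_id = pool@metadata$pool_id,
                               margin = margin,
                               min_occurrences = minOccurrences,
                               n_records = length(pool),
                               n_occurrences = nrow(occ)))
}

#' Query a pentamer table
#'
#' Looks up window-valid pentamers under their canonical form.  When the
#' canonical form is the reverse complement of the query, the step-feature
#' pairs (roll23, roll34) and (helt23, helt34) are swapped before being
#' returned, so values are always expressed in the orientation of the
#' query; MGW and ProT are unchanged.
#'
#' @param table A [QueryTable].
#' @param pentamer Character vector of window-valid pentamers.
#' @param missing `"na"` (default) returns NA values for keys absent from
#'   the table; `"error"` fails.
#' @return data.frame with one row per query: `pentamer`, `key`, `flipped`,
#'   the six feature slots and `n`.
#' @export
queryShape <- function(table, pentamer, missing = c("na", "error")) {
  missing <- match.arg(missing)
  stopifnot(is(table, "QueryTable"))
  cm <- .canonMap(5L)
  key <- unname(cm$key[pentamer])
  if (anyNA(key))
    .stopf("invalid pentamer(s): %s",
           paste(utils::head(unique(pentamer[is.na(key)]), 3L),
                 collapse = ", "),
           class = "methylShapeAlphabetError")
  flip <- unname(cm$flipped[pentamer])
  e <- table@entries
  idx <- match(key, e$key)
  # keys flagged missing at build time (NA values) count as absent
  absent <- is.na(idx) | is.na(e$mgw[idx])
  if (missing == "error" && any(absent))
    .stopf("key(s) missing from table: %s",
           paste(utils::head(unique(key[absent]), 3L), collapse = ", "),
           class = "methylShapeMissingKeyError")
  pick <- function(col) e[[col]][idx]
  data.frame(pentamer = pentamer, key = key, flipped = flip,
             mgw = pick("mgw"), prot = pick("prot"),
             roll23 = ifelse(flip, pick("roll34"), pick("roll23")),
             roll34 = ifelse(flip, pick("roll23"), pick("roll34")),
             helt23 = ifelse(flip, pick("helt34"), pick("helt23")),
             helt34 = ifelse(flip, pick("helt23"), pick("helt34")),
             n = pick("n"), row.names = NULL)
}

# Expand a pattern containing N wildcards into all concrete sequences.
.expandWildcard <- function(pattern) {
  ch <- .splitChars(pattern)[[1L]]
  opts <- lapply(ch, function(x) if (x == "N") c("A", "C", "G", "T") else x)
  do.call(paste0, expand.grid(opts, stringsAsFactors = FALSE,
                              KEEP.OUT.ATTRS = FALSE))
}

#' Query a pentamer table with N wildcards
#'
#' Returns the unweighted mean of [queryShape()] over all concrete
#' expansions of the pattern (N expands to A, C, G, T).  Used to pad k-mer
#' featurization with unknown flanking context.
#'
#' @param table A [QueryTable].
#' @param pattern Character vector of length-5 patterns over
#'   `A,C,G,T,m,g,N`; every concrete expansion must be window-valid.
#' @param missing Missing-key policy passed to [queryShape()].
#' @return data.frame with one row per pattern: `pattern` plus the six
#'   averaged feature slots.
#' @export
queryWildcard <- function(table, pattern, missing = c("na", "error")) {
  missing <- match.arg(missing)
  expansions <- lapply(pattern, .expandWildcard)
  all <- unlist(expansions, use.names = FALSE)
  ok <- isValidMethylSeq(all, "window")
  if (!all(ok))
    .stopf("pattern expansion(s) not window-valid: %s",
           paste(utils::head(all[!ok], 3L), collapse = ", "),
           class = "methylShapeAlphabetError")
  q <- queryShape(table, all, missing = missing)
  g <- rep(seq_along(pattern), lengths(expansions))
  vals <- as.matrix(q[, c("mgw", "prot", "roll23", "roll34",
                          "helt23", "helt34")])
  means <- rowsum(vals, g) / as.vector(table(g))
  data.frame(pattern = pattern, means, row.names = NULL)
}

# ---- CpG-context k-mer tables ------------------------------------------

.contextPatternKeys <- function(kind) {
  four <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")),
                                          if (kind == "hexamer") 4L else 3L),
                                      stringsAsFactors = FALSE,
                                      KEEP.OUT.ATTRS = FALSE))
  if (kind == "hexamer") paste0(four, "CG") else paste0("CG", four, "CG")
}

#' Build a CpG-context k-mer table from an unmethylated pool
#'
#' Compiles per-position MGW (and ProT) means for all hexamers ending with
#' CpG (`NNNNCG`) or all heptamers with CpG flanks (`CGNNNCG`).  These
#' tables capture the dependency of shape on the base following a pentamer
#' window, which the pentamer tables miss: a methylated pentamer ending in
#' "m" implies a G at the next position, so its unmethylated reference must
#' be conditioned on that same context.  Keys are stored in pattern
#' orientation; windows matching on the opposite strand contribute with
#' positions reversed, and a window matching in both orientations
#' contributes to both keys.
#'
#' @param pool ShapeRecordPool of unmethylated records.
#' @param kind `"hexamer"` or `"heptamer"`.
#' @param margin Per-position exclusion margin as in [mineOccurrences()]:
#'   only fragment positions in `[3 + margin, N - 2 - margin]` contribute.
#' @return A [ContextTable].
#' @export
buildContextTable <- function(pool, kind = c("hexamer", "heptamer"),
                              margin = 1L) {
  kind <- match.arg(kind)
  stopifnot(is(pool, "ShapeRecordPool"))
  if (any(grepl("[mg]", pool@seq)))
    .stopf("context tables are built from unmethylated records only")
  k <- if (kind == "hexamer") 6L else 7L
  keys <- .contextPatternKeys(kind)

  nwin <- pmax(0L, pool@len - k + 1L)
  rec <- rep(seq_along(pool@len), nwin)
  starts <- sequence(nwin, from = 1L)
  win <- substring(pool@seq[rec], starts, starts + k - 1L)
  rcwin <- methylRevComp(unique(win))
  rcmap <- stats::setNames(rcwin, unique(win))

  fwd <- !is.na(match(win, keys))
  rev <- !is.na(match(unname(rcmap[win]), keys))

  sumM <- matrix(0, nrow = length(keys), ncol = k,
                 dimnames = list(keys, NULL))
  sumP <- sumM
  cnt <- matrix(0L, nrow = length(keys), ncol = k,
                dimnames = list(keys, NULL))
  bo <- .bpOffsets(pool)[rec]
  lo <- 3L + margin
  hi <- pool@len[rec] - 2L - margin

  accumulate <- function(sel, reversed) {
    if (!any(sel)) return()
    kidx <- match(if (reversed) unname(rcmap[win[sel]]) else win[sel], keys)
    for (p in seq_len(k)) {
      fragpos <- starts[sel] + p - 1L
      okpos <- fragpos >= lo & fragpos <= hi[sel]
      if (!any(okpos)) next
      col <- if (reversed) k + 1L - p else p
      v <- pool@mgw[bo[sel][okpos] + fragpos[okpos]]
      w <- pool@prot[bo[sel][okpos] + fragpos[okpos]]
      ki <- kidx[okpos]
      def <- !is.na(v)
      if (any(def)) {
        sM <- rowsum(v[def], ki[def])
        sP <- rowsum(w[def], ki[def])
        rows <- as.integer(rownames(sM))
        sumM[rows, col] <<- sumM[rows, col] + sM[, 1L]
        sumP[rows, col] <<- sumP[rows, col] + sP[, 1L]
        cnt[rows, col] <<- cnt[rows, col] + as.vector(table(ki[def]))
      }
    }
  }
  accumulate(fwd, reversed = FALSE)
  accumulate(rev, reversed = TRUE)

  mgw <- sumM / cnt; mgw[cnt == 0L] <- NA_real_
  prot <- sumP / cnt; prot[cnt == 0L] <- NA_real_
  methods::new("ContextTable", kind = kind, k = k,
               mgw = mgw, prot = prot, n = cnt,
               metadata = list(margin = margin, n_records = length(pool)))
}

#' Query a context table at a named position
#'
#' The k-mer may be given in either orientation; opposite-strand queries
#' are mapped onto the pattern-oriented key with the position reversed.
#'
#' @param ctable A [ContextTable].
#' @param kmer k-mer (standard alphabet) matching the context pattern in
#'   one orientation.
#' @param position 1-based position within `kmer` to read.
#' @param feature `"MGW"` or `"ProT"`.
#' @param missing `"na"` or `"error"`.
#' @return Numeric value (mean over context-matching occurrences).
#' @export
queryContext <- function(ctable, kmer, position,
                         feature = c("MGW", "ProT"),
                         missing = c("na", "error")) {
  feature <- match.arg(feature)
  missing <- match.arg(missing)
  stopifnot(is(ctable, "ContextTable"), nchar(kmer) == ctable@k)
  mat <- if (feature == "MGW") ctable@mgw else ctable@prot
  keys <- rownames(mat)
  if (kmer %in% keys) {
    v <- mat[kmer, position]
  } else {
    rc <- methylRevComp(kmer)
    if (!(rc %in% keys))
      .stopf("k-mer %s matches the %s context pattern in neither orientation",
             kmer, ctable@kind, class = "methylShapeMissingKeyError")
    v <- mat[rc, ctable@k + 1L - position]
  }
  if (is.na(v) && missing == "error")
    .stopf("no occurrence recorded for %s position %d", kmer, position,
           class = "methylShapeMissingKeyError")
  unname(v)
}
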