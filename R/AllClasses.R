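# S4 containers.
#
# ShapeRecordPool stores per-fragment, per-position shape feature values in
# a flattened (CompressedList-like) layout: one concatenated numeric vector
# per feature plus per-record offsets, which keeps mining vectorized.

#' ShapeRecordPool: pool of per-fragment shape records
#'
#' Each record carries a fragment-valid methylation-aware sequence of length
#' N, per-base-pair MGW (Angstrom) and ProT (degrees) values (length N,
#' undefined termini allowed as NA) and per-step Roll and HelT values
#' (degrees, length N-1; step k sits between bp k and k+1).  Values are
#' stored concatenated across records.
#'
#' @slot id character, record identifiers.
#' @slot seq character, fragment sequences.
#' @slot len integer, fragment lengths.
#' @slot mgw,prot numeric, concatenated per-bp values (sum(len) entries).
#' @slot roll,helt numeric, concatenated per-step values (sum(len-1)).
#' @slot metadata list of provenance information.
#' @export
setClass("ShapeRecordPool",
         representation(id = "character", seq = "character", len = "integer",
                        mgw = "numeric", prot = "numeric",
                        roll = "numeric", helt = "numeric",
                        metadata = "list"),
         prototype(metadata = list()))

setValidity("ShapeRecordPool", function(object) {
  n <- length(object@id)
  if (length(object@seq) != n || length(object@len) != n)
    return("id, seq and len must have equal length")
  if (any(object@len != nchar(object@seq)))
    return("len must equal nchar(seq)")
  if (length(object@mgw) != sum(object@len) ||
      length(object@prot) != sum(object@len))
    return("mgw/prot must hold sum(len) values")
  if (length(object@roll) != sum(object@len - 1L) ||
      length(object@helt) != sum(object@len - 1L))
    return("roll/helt must hold sum(len - 1) values")
  if (any(object@len < 5L))
    return("records must be at least 5 bp long")
  ok <- isValidMethylSeq(object@seq, "fragment")
  if (!all(ok))
    return(sprintf("invalid fragment sequence(s): %s",
                   paste(utils::head(object@seq[!ok], 3L), collapse = ", ")))
  TRUE
})

#' QueryTable: canonical pentamer query table
#'
#' Maps each canonical pentamer key to six mean shape feature values (MGW
#' and ProT at the central bp; Roll and HelT at pentamer steps 2-3 and 3-4)
#' plus the number of pooled occurrences.  The unmethylated table (PQT)
#' covers 512 keys; the methylation-aware table (mPQT) covers 987.
#'
#' @slot entries data.frame with columns key, mgw, prot, roll23, roll34,
#'   helt23, helt34, n.
#' @slot metadata list (pool id, mining margin, build options).
#' @export
setClass("QueryTable",
         representation(entries = "data.frame", metadata = "list"),
         prototype(metadata = list()))

setValidity("QueryTable", function(object) {
  e <- object@entries
  need <- c("key", "mgw", "prot", "roll23", "roll34", "helt23", "helt34", "n")
  if (!all(need %in% names(e)))
    return(paste("entries must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(e$key)) return("duplicate keys")
  ck <- canonicalKey(e$key)
  if (any(ck$flipped)) return("non-canonical key(s) present")
  vals <- as.matrix(e[, c("mgw", "prot", "roll23", "roll34",
                          "helt23", "helt34")])
  # a row is either fully populated or flagged missing (all NA)
  bad <- !stats::complete.cases(vals) & rowSums(!is.na(vals)) > 0L
  if (any(bad))
    return("entries must be fully populated or flagged missing (all NA)")
  TRUE
})

#' ContextTable: CpG-context k-mer table
#'
#' Per-position MGW and ProT means for k-mers matching a CpG context
#' pattern: hexamers ending in CG (`NNNNCG`, 256 keys) or heptamers with CG
#' at both flanks (`CGNNNCG`, 64 keys).  Keys are kept in pattern
#' orientation; occurrences from the opposite strand are mapped in with
#' positions reversed.  These tables supply the context-matched
#' unmethylated reference when a CpG has only one bp inside a pentamer
#' window.
#'
#' @slot kind `"hexamer"` or `"heptamer"`.
#' @slot k k-mer width (6 or 7).
#' @slot mgw,prot numeric matrices (keys x positions) of means.
#' @slot n integer matrix of per-position occurrence counts.
#' @slot metadata list.
#' @export
setClass("ContextTable",
         representation(kind = "character", k = "integer",
                        mgw = "matrix", prot = "matrix", n = "matrix",
                        metadata = "list"),
         prototype(metadata = list()))

setValidity("ContextTable", function(object) {
  if (!object@kind %in% c("hexamer", "heptamer")) return("unknown kind")
  k <- if (object@kind == "hexamer") 6L else 7L
  if (object@k != k) return("k inconsistent with kind")
  keys <- rownames(object@mgw)
  if (is.null(keys)) return("mgw must have keys as rownames")
  pat <- if (k == 6L) "^[ACGT]{4}CG$" else "^CG[ACGT]{3}CG$"
  if (!all(grepl(pat, keys)))
    return("key(s) do not match the declared context pattern")
  if (ncol(object@mgw) != k) return("mgw must have k columns")
  TRUE
})

#' ShapeProfile: per-position shape feature vectors
#'
#' Result of sliding-window prediction for one sequence.  Per-bp features
#' (mgw, prot) have length N with entries defined exactly at positions
#' 3..N-2; per-step features (roll, helt) have length N-1 with entries
#' defined at steps 2..N-2.  Undefined boundary entries are NA so that
#' indices align with input coordinates.  `kind` is `"shape"` for plain
#' profiles and `"delta"` for methylated-minus-unmethylated differences.
#'
#' @slot seq character, the profiled sequence.
#' @slot mgw,prot numeric length N.
#' @slot roll,helt numeric length N-1.
#' @slot kind `"shape"` or `"delta"`.
#' @export
setClass("ShapeProfile",
         representation(seq = "character", mgw = "numeric", prot = "numeric",
                        roll = "numeric", helt = "numeric", kind = "character"),
         prototype(kind = "shape"))

setValidity("ShapeProfile", function(object) {
  n <- nchar(object@seq)
  if (length(object@mgw) != n || length(object@prot) != n)
    return("mgw/prot must have one entry per bp")
  if (length(object@roll) != n - 1L || length(object@helt) != n - 1L)
    return("roll/helt must have one entry per step")
  if (!object@kind %in% c("shape", "delta")) return("unknown kind")
  TRUE
})

#' AffinityModel: linear shape-to-affinity model
#'
#' Affine model ddG/RT ~ intercept + W . features fitted by elastic-net
#' regression (penalty l1*||w||_1 + l2*||w||_2^2 on internally standardized
#' features; coefficients are reported on the original feature scale).
#' Because the model is linear, methylation-induced energy shifts are
#' predicted directly from delta-shape features as W . delta (no
#' intercept).  The feature layout is stored with the model to prevent
#' silent mismatches.
#'
#' @slot weights named numeric, coefficients on the original feature scale.
#' @slot intercept numeric(1).
#' @slot lambda1,lambda2 numeric(1), L1 and L2 penalties.
#' @slot layout character, feature names in model order.
#' @slot dropped character, zero-variance features removed before fitting.
#' @slot metadata list (standardization constants, convergence info).
#' @export
setClass("AffinityModel",
         representation(weights = "numeric", intercept = "numeric",
                        lambda1 = "numeric", lambda2 = "numeric",
                        layout = "character", dropped = "character",
                        metadata = "list"),
         prototype(dropped = character(0), metadata = list()))

setValidity("AffinityModel", function(object) {
  if (!all(names(object@weights) %in% object@layout))
    return("weights must be named by layout entries")
  if (length(object@intercept) != 1L) return("intercept must be scalar")
  TRUE
})

#' TruthModel: planted ground truth for synthetic shape records
#'
#' Statistical stand-in for the mined all-atom simulation output.  Base
#' feature values are drawn once (seeded) per canonical unmethylated
#' pentamer (MGW, ProT) and canonical tetramer (Roll, HelT); methylation
#' effects are applied deterministically on top: a Roll shift at mg steps,
#' a ProT shift at methylated central bp, a HelT shift for off-centre mg
#' steps, and a small context-dependent MGW term.  Step features are
#' defined at tetramer resolution (roll23 of a pentamer is the step truth
#' of its first four letters, roll34 of its last four), which makes pools
#' internally consistent: at zero noise a mined table reproduces the truth
#' exactly.
#'
#' @slot pentamer data.frame: key, mgw, prot for every canonical pentamer.
#' @slot step data.frame: key (canonical tetramer), roll, helt.
#' @slot params list of effect sizes, noise sigma, pos6 interaction, seed.
#' @export
setClass("TruthModel",
         representation(pentamer = "data.frame", step = "data.frame",
                        params = "list"))

setMethod("show", "ShapeRecordPool", function(object) {
  cat(sprintf("ShapeRecordPool with %d records (lengths %d-%d bp)\n",
              length(object@id),
              if (length(object@len)) min(object@len) else 0L,
              if (length(object@len)) max(object@len) else 0L))
  if (length(object@id))
    cat("  first record:", object@id[1L], object@seq[1L], "\n")
})

setMethod("length", "ShapeRecordPool", function(x) length(x@id))

setMethod("show", "QueryTable", function(object) {
  e <- object@entries
  cat(sprintf("QueryTable with %d canonical pentamer keys (%d missing)\n",
              nrow(e), sum(e$n == 0L | is.na(e$mgw))))
  if (!is.null(object@metadata$margin))
    cat("  mining margin:", object@metadata$margin, "bp\n")
})

setMethod("show", "ContextTable", function(object) {
  cat(sprintf("ContextTable (%s, k = %d) with %d keys\n",
              object@kind, object@k, nrow(object@mgw)))
})

setMethod("show", "ShapeProfile", function(object) {
  cat(sprintf("%s for %s (%d bp)\n",
              if (object@kind == "delta") "DeltaProfile (methylated - unmethylated)"
              else "ShapeProfile",
              object@seq, nchar(object@seq)))
  df <- as.data.frame(object)
  print(utils::head(df, 8L))
  if (nrow(df) > 8L) cat("  ...\n")
})

setMethod("show", "AffinityModel", function(object) {
  nz <- sum(object@weights != 0)
  cat(sprintf("AffinityModel: %d features (%d nonzero), lambda1 = %g, lambda2 = %g\n",
              length(object@layout), nz, object@lambda1, object@lambda2))
  cat(sprintf("  intercept: %.4f\n", object@intercept))
})

setMethod("show", "TruthModel", function(object) {
  p <- object@params
  cat(sprintf("TruthModel (seed %s): %d pentamer keys, %d step keys\n",
              as.character(p$seed), nrow(object@pentamer), nrow(object@step)))
  cat(sprintf("  effects: Roll %+g deg (mg step), ProT %+g deg (methyl bp), HelT %+g deg, MGW %+g A\n",
              p$rollShift, p$protShift, p$heltShift, p$mgwShift))
  cat(sprintf("  occurrence noise sigma = %g, pos6 interaction = %g\n",
              p$sigma, p$pos6Effect))
})

#' @export
#' @method as.data.frame ShapeProfile
as.data.frame.ShapeProfile <- function(x, ...) {
  n <- nchar(x@seq)
  data.frame(pos = seq_len(n),
             base = .splitChars(x@seq)[[1L]],
             mgw = x@mgw, prot = x@prot,
             roll = c(x@roll, NA_real_), helt = c(x@helt, NA_real_))
}
setMethod("as.data.frame", "ShapeProfile",
          function(x, ...) as.data.frame.ShapeProfile(x, ...))

#' @export
#' @method as.data.frame QueryTable
as.data.frame.QueryTable <- function(x, ...) x@entries
setMethod("as.data.frame", "QueryTable",
          function(x, ...) as.data.frame.QueryTable(x, ...))

#' Accessors
#'
#' `tableKeys()` returns the canonical keys of a QueryTable;
#' `featureValues()` extracts one feature vector from a ShapeProfile.
#'
#' @param x A QueryTable or ShapeProfile.
#' @param feature One of `"MGW"`, `"ProT"`, `"Roll"`, `"HelT"`.
#' @rdname accessors
#' @export
tableKeys <- function(x) {
  stopifnot(is(x, "QueryTable"))
  x@entries$key
}

#' @rdname accessors
#' @export
featureValues <- function(x, feature = c("MGW", "ProT", "Roll", "HelT")) {
  stopifnot(is(x, "ShapeProfile"))
  switch(match.arg(feature),
         MGW = x@mgw, ProT = x@prot, Roll = x@roll, HelT = x@helt)
}

# Constructor for ShapeRecordPool from per-record lists.
#' Build a ShapeRecordPool from per-record vectors
#'
#' @param id,seq character vectors (one entry per record).
#' @param mgw,prot lists of numeric vectors, one per record, length N.
#' @param roll,helt lists of numeric vectors, one per record, length N-1.
#' @param metadata list.
#' @return A ShapeRecordPool.
#' @export
ShapeRecordPool <- function(id, seq, mgw, prot, roll, helt,
                            metadata = list()) {
  methods::new("ShapeRecordPool",
               id = as.character(id), seq = as.character(seq),
               len = nchar(seq),
               mgw = as.numeric(unlist(mgw, use.names = FALSE)),
               prot = as.numeric(unlist(prot, use.names = FALSE)),
               roll = as.numeric(unlist(roll, use.names = FALSE)),
               helt = as.numeric(unlist(helt, use.names = FALSE)),
               metadata = metadata)
}

# Per-record start offsets into the flattened value vectors.
.bpOffsets <- function(pool) c(0L, cumsum(pool@len))[seq_along(pool@len)]
.stepOffsets <- function(pool) c(0L, cumsum(pool@len - 1L))[seq_along(pool@len)]

#' Extract one record of a pool as a list
#'
#' @param pool A ShapeRecordPool.
#' @param i Record index or id.
#' @return list(id, seq, mgw, prot, roll, helt).
#' @export
poolRecord <- function(pool, i) {
  if (is.character(i)) i <- match(i, pool@id)
  stopifnot(!is.na(i), i >= 1L, i <= length(pool))
  n <- pool@len[i]
  bo <- .bpOffsets(pool)[i]; so <- .stepOffsets(pool)[i]
  list(id = pool@id[i], seq = pool@seq[i],
       mgw = pool@mgw[bo + seq_len(n)], prot = pool@prot[bo + seq_len(n)],
       roll = pool@roll[so + seq_len(n - 1L)],
       helt = pool@helt[so + seq_len(n - 1L)])
}
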