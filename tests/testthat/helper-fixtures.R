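# Shared fixtures, built lazily and cached for the whole run.

.fx <- new.env()

# Planted truth, full-universe designs and a zero-noise pool/table.
fxTruth <- function() {
  if (is.null(.fx$truth)) .fx$truth <- truthModel(seed = 101)
  .fx$truth
}
fxDesigns <- function() {
  if (is.null(.fx$designs)) .fx$designs <- designPool("all", coverage = 1)
  .fx$designs
}
fxPool0 <- function() {
  if (is.null(.fx$pool0))
    .fx$pool0 <- simulateRecords(fxTruth(), fxDesigns(), nOcc = 1,
                                 sigma = 0, seed = 7)
  .fx$pool0
}
fxTable0 <- function() {
  if (is.null(.fx$table0)) .fx$table0 <- buildQueryTable(fxPool0(), "all")
  .fx$table0
}

# A table in which every key holds the same FeatureTuple.
uniformTable <- function(mgw = 5, prot = -7, roll = 2, helt = 34) {
  keys <- enumeratePentamers("all")
  methods::new("QueryTable",
               entries = data.frame(key = keys, mgw = mgw, prot = prot,
                                    roll23 = roll, roll34 = roll,
                                    helt23 = helt, helt34 = helt, n = 1L))
}

# Random fragment-valid methylation-aware sequences: random ACGT backbone
# with each CpG methylated with probability 1/2.
randomMethylSeqs <- function(n, minLen = 8L, maxLen = 30L, seed = 1L) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    len <- sample(minLen:maxLen, 1L)
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    cg <- gregexpr("CG", s, fixed = TRUE)[[1L]]
    cg <- cg[cg > 0]
    if (length(cg)) {
      pick <- cg[stats::runif(length(cg)) < 0.5]
      if (length(pick)) s <- methylateSeq(s, pick)
    }
    s
  }, "")
}

# Independent reverse-complement oracle: explicit per-letter loop, coded
# differently from the package's chartr-based implementation.
oracleRevComp <- function(s) {
  pairs <- list(A = "T", T = "A", C = "G", G = "C", m = "g", g = "m")
  ch <- strsplit(s, "")[[1]]
  paste(vapply(rev(ch), function(x) pairs[[x]], ""), collapse = "")
}

# One single-window record (5 bp): profile arrays aligned so the central
# window carries the given feature tuple.
singleWindowRecord <- function(seq5, mgw, prot, roll23, roll34, helt23,
                               helt34) {
  list(seq = seq5,
       mgw = c(NA, NA, mgw, NA, NA),
       prot = c(NA, NA, prot, NA, NA),
       roll = c(NA, roll23, roll34, NA),
       helt = c(NA, helt23, helt34, NA))
}

poolFromRecords <- function(recs, ids = sprintf("r%02d", seq_along(recs))) {
  ShapeRecordPool(id = ids,
                  seq = vapply(recs, `[[`, "", "seq"),
                  mgw = lapply(recs, `[[`, "mgw"),
                  prot = lapply(recs, `[[`, "prot"),
                  roll = lapply(recs, `[[`, "roll"),
                  helt = lapply(recs, `[[`, "helt"))
}
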