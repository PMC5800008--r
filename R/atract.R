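# Methylation effect on the minor groove width of A-tracts.
#
# A-tracts (runs of >= 3 A/T bp without a TpA step) have intrinsically
# narrow minor grooves; an adjacent methylated CpG can amplify or relax
# that narrowing depending on the A/T composition.  The analysis compares
# paired methylated/unmethylated MGW samples at the central nucleotide of
# each tract context with one-sided tests (alternative: methylation
# narrows the groove).

.ATRACT_3BP <- c("AAACG", "AATCG", "ATTCG", "TTTCG")
.ATRACT_4BP <- c("AAAACG", "AAATCG", "AATTCG", "ATTTCG", "TTTTCG")

#' A-tract contexts of the 3-bp and 4-bp series
#'
#' The 3-bp series runs from AAACG to TTTCG, the 4-bp series from AAAAC to
#' TTTTC (given with their following G), exchanging one A/T to T/A at a
#' time from the 3' end.  MGW is measured at the central nucleotide of the
#' tract: position 2 of the 5-mer context (its pentamer window borrows one
#' bp of left flank and implies the g beyond the window), position 3 of
#' the 6-mer context (its pentamer window lies fully inside).
#'
#' @param series `"3bp"` or `"4bp"`.
#' @return data.frame with columns `context` and `measure_at` (1-based
#'   position within the context).
#' @export
atractContexts <- function(series = c("3bp", "4bp")) {
  series <- match.arg(series)
  if (series == "3bp")
    data.frame(context = .ATRACT_3BP, measure_at = 2L)
  else
    data.frame(context = .ATRACT_4BP, measure_at = 3L)
}

# One-sided paired test for minor groove narrowing upon methylation.
# All-zero paired differences carry no evidence for narrowing: P = 1.
.atractTest <- function(meth, unmeth, method = c("wilcoxon", "ttest")) {
  method <- match.arg(method)
  stopifnot(length(meth) == length(unmeth))
  if (length(meth) < 2L)
    .stopf("fewer than 2 paired samples", class = "methylShapeInputError")
  d <- meth - unmeth
  if (all(d == 0)) return(1)
  p <- if (method == "wilcoxon") {
    suppressWarnings(stats::wilcox.test(meth, unmeth, paired = TRUE,
                                        alternative = "less")$p.value)
  } else {
    tryCatch(stats::t.test(meth, unmeth, paired = TRUE,
                           alternative = "less")$p.value,
             error = function(e) 1)
  }
  unname(p)
}

.pStars <- function(p) {
  ifelse(p <= 0.001, "***",
         ifelse(p <= 0.01, "**",
                ifelse(p <= 0.05, "*", "")))
}

#' A-tract minor groove width analysis
#'
#' Summarizes paired methylated/unmethylated MGW samples per A-tract
#' context and computes a one-sided P value with minor groove narrowing
#' upon methylation as the alternative hypothesis.  Defaults follow the
#' analysis design: Wilcoxon signed-rank for the 3-bp series, paired t for
#' the 4-bp series.  Significance stars: `*` for 0.01 < P <= 0.05, `**`
#' for 0.001 < P <= 0.01 (`***` below that).
#'
#' @param pairs data.frame with columns `context`, `mgw_meth`,
#'   `mgw_unmeth` (one row per paired sample), e.g. from
#'   [simulateAtractPairs()].
#' @param method `"auto"` (by series), `"wilcoxon"` or `"ttest"`.
#' @param series Used by `"auto"` to pick the default test.
#' @return data.frame per context: `context`, `n`, `median_meth`,
#'   `median_unmeth`, `mean_delta`, `p_value`, `stars`, `method`.
#' @export
atractAnalysis <- function(pairs, method = c("auto", "wilcoxon", "ttest"),
                           series = c("3bp", "4bp")) {
  method <- match.arg(method)
  series <- match.arg(series)
  stopifnot(all(c("context", "mgw_meth", "mgw_unmeth") %in% names(pairs)))
  if (method == "auto")
    method <- if (series == "3bp") "wilcoxon" else "ttest"
  out <- lapply(split(pairs, pairs$context), function(g) {
    p <- .atractTest(g$mgw_meth, g$mgw_unmeth, method)
    data.frame(context = g$context[1L], n = nrow(g),
               median_meth = stats::median(g$mgw_meth),
               median_unmeth = stats::median(g$mgw_unmeth),
               mean_delta = mean(g$mgw_meth - g$mgw_unmeth),
               p_value = p, stars = .pStars(p), method = method)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(match(res$context, unique(pairs$context))), , drop = FALSE]
}
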