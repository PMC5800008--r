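# Sliding-window profiles, delta-shape and context-matched MGW.

test_that("profiles define N-4 bp values and N-3 step values", {
  tab <- fxTable0()
  p5 <- shapeProfile("AACGT", tab)
  expect_equal(sum(!is.na(featureValues(p5, "MGW"))), 1L)
  expect_equal(which(!is.na(featureValues(p5, "MGW"))), 3L)
  for (s in randomMethylSeqs(20, minLen = 5, maxLen = 40, seed = 8)) {
    p <- shapeProfile(s, tab)
    n <- nchar(s)
    expect_equal(sum(!is.na(featureValues(p, "MGW"))), n - 4L)
    expect_equal(which(!is.na(featureValues(p, "ProT"))), 3:(n - 2L))
    expect_equal(which(!is.na(featureValues(p, "Roll"))), 2:(n - 2L))
    expect_equal(which(!is.na(featureValues(p, "HelT"))), 2:(n - 2L))
  }
  expect_error(shapeProfile("ACGT", tab), class = "methylShapeInputError")
})

test_that("a uniform table yields a constant profile", {
  tab <- uniformTable(mgw = 5.5, prot = -8, roll = 2.5, helt = 34.5)
  p <- shapeProfile("ACGTTACGGA", tab)
  expect_equal(unique(stats::na.omit(featureValues(p, "MGW"))), 5.5)
  expect_equal(unique(stats::na.omit(featureValues(p, "Roll"))), 2.5)
  expect_equal(unique(stats::na.omit(featureValues(p, "HelT"))), 34.5)
})

test_that("interior steps average the two covering windows", {
  tab <- fxTable0()
  s <- "ACGTTGCA"
  p <- shapeProfile(s, tab)
  # hand-computed two-term average for step 4 (between bp 4 and 5):
  # roll34 of the window centred at 4 plus roll23 of the window centred
  # at 5, halved
  q4 <- queryShape(tab, substr(s, 2, 6))
  q5 <- queryShape(tab, substr(s, 3, 7))
  expect_equal(featureValues(p, "Roll")[4], (q4$roll34 + q5$roll23) / 2)
  expect_equal(featureValues(p, "HelT")[4], (q4$helt34 + q5$helt23) / 2)
  # boundary steps use the single available contribution
  q3 <- queryShape(tab, substr(s, 1, 5))
  expect_equal(featureValues(p, "Roll")[2], q3$roll23)
  q6 <- queryShape(tab, substr(s, 4, 8))
  expect_equal(featureValues(p, "Roll")[6], q6$roll34)
  # alternative step policies keep a single window's slot
  p5p <- shapeProfile(s, tab, stepPolicy = "five_prime")
  expect_equal(featureValues(p5p, "Roll")[4], q4$roll34)
})

test_that("profiles are strand symmetric", {
  tab <- fxTable0()
  for (s in randomMethylSeqs(100, minLen = 6, maxLen = 25, seed = 21)) {
    p <- shapeProfile(s, tab)
    pr <- shapeProfile(methylRevComp(s), tab)
    expect_equal(featureValues(pr, "MGW"), rev(featureValues(p, "MGW")))
    expect_equal(featureValues(pr, "ProT"), rev(featureValues(p, "ProT")))
    expect_equal(featureValues(pr, "Roll"), rev(featureValues(p, "Roll")))
    expect_equal(featureValues(pr, "HelT"), rev(featureValues(p, "HelT")))
  }
})

test_that("delta-shape is zero without methylation or table differences", {
  tab <- fxTable0()
  d0 <- deltaShape("AACGTACGT", NULL, tab, tab)
  expect_equal(stats::na.omit(featureValues(d0, "MGW")),
               rep(0, 5), ignore_attr = TRUE)
  # when both tables agree on every queried key the delta vanishes even
  # with methylation present
  u <- uniformTable()
  dsame <- deltaShape("AACGTACGT", "all_cpg", u, u)
  for (f in c("MGW", "ProT", "Roll", "HelT"))
    expect_equal(stats::na.omit(featureValues(dsame, f)),
                 rep(0, length(stats::na.omit(featureValues(dsame, f)))),
                 ignore_attr = TRUE)
  dAA <- deltaShape("AAATAAA", "all_cpg", tab, tab)   # no CpG present
  expect_equal(stats::na.omit(featureValues(dAA, "Roll")),
               rep(0, 4), ignore_attr = TRUE)
})

test_that("delta-shape recovers the planted methylation effects", {
  truth <- fxTruth()
  tab <- fxTable0()
  pqt <- truthTable(truth, "unmethylated")
  d <- deltaShape("TACGTT", "all_cpg", pqt, tab)
  # the mg step sits at step 3; planted Roll shift is +6 degrees
  expect_equal(featureValues(d, "Roll")[3], 6, tolerance = 1e-10)
  # ProT drops by 5 degrees at both methylated base pairs
  expect_equal(featureValues(d, "ProT")[3:4], c(-5, -5),
               tolerance = 1e-10)
  # single-window case: delta equals the table difference exactly
  d5 <- deltaShape("AACGT", "all_cpg", pqt, tab)
  diff5 <- queryShape(tab, "AAmgT")$mgw - queryShape(pqt, "AACGT")$mgw
  expect_equal(featureValues(d5, "MGW")[3], diff5)
})

test_that("context-matched MGW removes the sixth-position confound", {
  # planted downstream interaction: records gain +0.4 A when the base
  # three positions past a window centre is G (and mirrored on the other
  # strand), which the pentamer tables cannot see
  tr <- truthModel(seed = 11, mgwShift = -0.3, mgwContextSd = 0,
                   pos6Effect = 0.4)
  flanks <- c("AGTC", "CATG", "GACT", "TCAG")
  rcf <- methylRevComp(flanks)
  hexes <- paste0(
    do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), 4),
                                stringsAsFactors = FALSE)), "CG")
  dHex <- data.frame(id = sprintf("h%04d", seq_len(4L * length(hexes))),
                     seq = paste0(rep(flanks, length(hexes)),
                                  rep(hexes, each = 4L),
                                  rep(rcf, length(hexes))))
  ctxHex <- buildContextTable(simulateRecords(tr, dHex, 1, sigma = 0,
                                              seed = 2), "hexamer")
  dM <- data.frame(id = paste0("m", 1:4),
                   seq = paste0(flanks, "TGATmg", rcf))
  mpqt <- buildQueryTable(simulateRecords(tr, dM, 1, sigma = 0, seed = 3),
                          universe = canonicalKey("TGATm")$key,
                          missing = "na")
  pqt <- buildQueryTable(simulateRecords(tr, designPool("unmethylated"),
                                         1, sigma = 0, seed = 4),
                         "unmethylated")

  site <- "ATGATCGATAAA"
  r <- contextMatchedDeltaMGW(site, at = 4, methylation = 6, pqt, mpqt,
                              hexTable = ctxHex)
  expect_equal(r$context_kind, "hexamer")
  expect_equal(r$context_kmer, "TGATCG")
  planted <- -0.3
  plainErr <- queryShape(mpqt, "TGATm")$mgw -
    queryShape(pqt, "TGATC")$mgw - planted
  expect_lt(abs(r$delta_mgw - planted), 0.1)
  expect_gt(abs(plainErr), 0.25)
  expect_gt(abs(plainErr), 3 * abs(r$delta_mgw - planted))
})

test_that("full-CpG windows fall back to the plain pentamer reference", {
  truth <- fxTruth()
  tab <- fxTable0()
  pqt <- truthTable(truth, "unmethylated")
  site <- "ATGATTAACGAA"        # CpG at 9/10, fully inside the A8 window
  r <- contextMatchedDeltaMGW(site, at = 8, methylation = 9, pqt, tab)
  expect_equal(r$context_kind, "pentamer")
  d <- deltaShape(site, 9, pqt, tab)
  expect_equal(r$delta_mgw, featureValues(d, "MGW")[8])
})

test_that("Pbx-Hox offsets map onto the expected context k-mers", {
  truth <- fxTruth()
  tab <- fxTable0()
  pqt <- truthTable(truth, "unmethylated")
  dHex <- data.frame(id = sprintf("h%04d", seq_len(256L)),
                     seq = paste0("AGTC",
                                  paste0(do.call(paste0,
                                    expand.grid(rep(list(c("A", "C", "G",
                                                           "T")), 4),
                                                stringsAsFactors = FALSE)),
                                    "CG"),
                                  "GACT"))
  ctxHex <- buildContextTable(simulateRecords(truth, dHex, 1, sigma = 0,
                                              seed = 5), "hexamer")
  # offset 6/7: the A4 window ends one bp into the CpG
  r67 <- pbxHoxDeltaMGW("ATGATCGATAAA", 6, pqt, tab, hexTable = ctxHex)
  expect_equal(r67$offset_class, c("6/7", "6/7"))
  expect_equal(r67$context_kmer[1], "TGATCG")
  expect_equal(r67$context_kind[1], "hexamer")
  # offset 10/11: the A8 window ends one bp into the CpG; both AY
  # positions see a hexamer context ending in CG
  r1011 <- pbxHoxDeltaMGW("ATGATTAATCGA", 10, pqt, tab, hexTable = ctxHex)
  expect_equal(r1011$offset_class, c("10/11", "10/11"))
  expect_equal(r1011$context_kmer[2], "TAATCG")
  expect_equal(r1011$context_kind[2], "hexamer")
  # the CpG does not touch the A4 window at this offset
  expect_equal(r1011$context_kind[1], "pentamer")
})

test_that("A-tract tests detect planted narrowing and reject widening", {
  # identical paired samples: no evidence for narrowing
  same <- data.frame(context = "AAAACG", mgw_meth = rep(5, 10),
                     mgw_unmeth = rep(5, 10))
  for (m in c("wilcoxon", "ttest"))
    expect_equal(atractAnalysis(same, method = m)$p_value, 1)

  narrow <- truthModel(seed = 31, mgwShift = -0.5, mgwContextSd = 0)
  for (series in c("3bp", "4bp")) {
    pairs <- simulateAtractPairs(narrow, series, nPairs = 20,
                                 sigma = 0.1, seed = 13)
    res <- atractAnalysis(pairs, series = series)
    expect_equal(nrow(res), nrow(atractContexts(series)))
    expect_true(all(res$p_value <= 0.01))
    expect_true(all(res$stars != ""))
  }
  widen <- truthModel(seed = 31, mgwShift = +0.5, mgwContextSd = 0)
  pairsW <- simulateAtractPairs(widen, "4bp", nPairs = 20, sigma = 0.1,
                                seed = 14)
  resW <- atractAnalysis(pairsW, series = "4bp")
  expect_true(all(resW$p_value >= 0.95))
  expect_error(atractAnalysis(data.frame(context = "AAAACG", mgw_meth = 1,
                                         mgw_unmeth = 2)),
               class = "methylShapeInputError")
})
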