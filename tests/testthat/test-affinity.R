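# Cleavage energies, elastic-net fitting and the Pbx-Hox comparator.

test_that("count filtering applies the threshold per variant", {
  tab <- data.frame(kmer = c("AAAAAA", "AAAAAC", "AAAAAG"),
                    variant = "unmethylated", count = c(24L, 25L, 26L))
  kept <- filterHexamers(tab, 25L)
  expect_equal(kept$count, c(25L, 26L))
  expect_equal(filterHexamers(tab, 0L)$count, tab$count)
  expect_warning(empty <- filterHexamers(tab, 100L), "below")
  expect_equal(nrow(empty), 0L)
})

test_that("count-to-energy conversion has the expected closed forms", {
  t0 <- data.frame(kmer = c("AAAAAA", "CCCCCC", "GGGGGG"),
                   variant = "unmethylated", count = c(10, 10, 10))
  expect_equal(countsToEnergy(t0)$energy, c(0, 0, 0))
  # counts (a, a, e * m) whose mean is m: the third energy is exactly -1
  m <- 20 / (3 - exp(1))
  t1 <- data.frame(kmer = c("AAAAAA", "CCCCCC", "GGGGGG"),
                   variant = "unmethylated",
                   count = c(10, 10, exp(1) * m))
  en <- countsToEnergy(t1)
  expect_equal(en$energy[en$kmer == "GGGGGG"], -1)
  # scale invariance
  t2 <- t1; t2$count <- t1$count * 2
  expect_equal(countsToEnergy(t2)$energy, en$energy)
  # named reference hexamer sets the zero
  enRef <- countsToEnergy(t1, reference = "AAAAAA")
  expect_equal(enRef$energy[enRef$kmer == "AAAAAA"], 0)
  expect_error(countsToEnergy(data.frame(kmer = "AAAAAA",
                                         variant = "unmethylated",
                                         count = 0)),
               class = "methylShapeInputError")
})

test_that("k-mer featurization has the fixed layout and wildcard padding", {
  tab <- fxTable0()
  X <- featurizeKmers(c("AACGTT", "AAmgTT"), tab)
  expect_equal(dim(X), c(2L, 22L))   # 6 MGW + 6 ProT + 5 Roll + 5 HelT
  expect_equal(colnames(X), featureLayout(6L))
  expect_false(anyNA(X))
  # wildcard-padded entries equal brute-force averages over all flanks:
  # MGW_1 of hexamer h averages the windows ab + h[1..3] over all 16 ab
  h <- "AACGTT"
  flanks <- expand.grid(a = c("A", "C", "G", "T"), b = c("A", "C", "G", "T"),
                        stringsAsFactors = FALSE)
  pents <- paste0(flanks$a, flanks$b, substr(h, 1, 3))
  expect_equal(unname(X[h, "MGW_1"]), mean(queryShape(tab, pents)$mgw))
  # step entries combine the two covering padded windows
  q3 <- queryShape(tab, substr(h, 1, 5))
  q4 <- queryShape(tab, substr(h, 2, 6))
  expect_equal(unname(X[h, "Roll_3"]), (q3$roll34 + q4$roll23) / 2)
})

test_that("elastic net at zero penalty matches the normal equations", {
  set.seed(2)
  X <- matrix(rnorm(200 * 10), 200)
  colnames(X) <- paste0("f", 1:10)
  y <- drop(X %*% rnorm(10)) + rnorm(200, 0, 0.1)
  m <- fitAffinityModel(X, y, 0, 0)
  b <- qr.solve(cbind(1, X), y)
  expect_lt(max(abs(c(m@intercept, m@weights[colnames(X)]) - b)) /
              max(abs(b)), 1e-8)
})

test_that("elastic net limits and degeneracies behave", {
  set.seed(3)
  X <- matrix(rnorm(50 * 4), 50)
  colnames(X) <- paste0("f", 1:4)
  y <- rnorm(50)
  big <- fitAffinityModel(X, y, 1e6, 0)
  expect_true(all(big@weights == 0))
  expect_equal(big@intercept, mean(y))
  Xz <- cbind(X, f5 = 0)
  expect_warning(mz <- fitAffinityModel(Xz, y, 0.1, 0.1), "zero-variance")
  expect_equal(mz@dropped, "f5")
  expect_length(predictAffinity(mz, Xz), 50L)
})

test_that("elastic net agrees with an independent solver", {
  # glmnet minimizes RSS/(2n) + lambda (alpha ||w||1 + (1-alpha)/2 ||w||2^2);
  # on pre-standardized features our objective divided by 2n matches it with
  # lambda = (l1 + 2 l2) / (2n), alpha = l1 / (l1 + 2 l2)
  set.seed(4)
  n <- 150L
  X <- matrix(rnorm(n * 6), n)
  X <- scale(X)   # sample-sd scale: internal standardization is identity
  colnames(X) <- paste0("f", 1:6)
  y <- drop(X %*% c(1.5, -1, 0.5, 0, 0, 0)) + rnorm(n, 0, 0.3)
  l1 <- 8; l2 <- 4
  mine <- fitAffinityModel(X, y, l1, l2)
  lam <- (l1 + 2 * l2) / (2 * n)
  alp <- l1 / (l1 + 2 * l2)
  g <- glmnet::glmnet(X, y, alpha = alp, lambda = lam,
                      standardize = FALSE, thresh = 1e-14)
  gw <- as.numeric(g$beta)
  # both solve the same convex problem up to standardization details
  expect_equal(unname(mine@weights[colnames(X)]), gw, tolerance = 0.02)
  expect_equal(sign(mine@weights[colnames(X)]), sign(gw),
               ignore_attr = TRUE)
})

test_that("planted linear truth is recovered at low noise", {
  set.seed(6)
  X <- matrix(rnorm(200 * 8), 200)
  colnames(X) <- paste0("f", 1:8)
  wStar <- c(2, -1.5, 1, -0.5, 0, 0, 0, 0)
  y <- drop(X %*% wStar) + rnorm(200, 0, 0.05)
  m <- fitAffinityModel(X, y, 0.01, 0.01)
  w <- unname(m@weights[colnames(X)])
  nz <- wStar != 0
  expect_equal(sign(w[nz]), sign(wStar[nz]))
  expect_lt(sqrt(sum((w - wStar)^2)) / sqrt(sum(wStar^2)), 0.1)
})

test_that("delta predictions are linear and sign-consistent", {
  w <- stats::setNames(c(-0.2, 0.05), c("Roll_3", "MGW_2"))
  model <- methods::new("AffinityModel", weights = w, intercept = 1.3,
                        lambda1 = 0, lambda2 = 0, layout = names(w))
  zero <- stats::setNames(c(0, 0), names(w))
  expect_equal(predictDddG(model, zero), 0)
  # negative Roll weight at the CpG step times a positive Roll increase:
  # binding enhanced (negative energy shift)
  dRoll <- stats::setNames(c(6, 0), names(w))
  expect_lt(predictDddG(model, dRoll), 0)
  # linearity: delta prediction equals the difference of predictions
  set.seed(8)
  f1 <- stats::setNames(rnorm(2), names(w))
  f2 <- stats::setNames(rnorm(2), names(w))
  expect_equal(unname(predictDddG(model, f1 - f2)),
               unname(predictAffinity(model, rbind(f1)) -
                        predictAffinity(model, rbind(f2))),
               tolerance = 1e-12)
  expect_error(predictDddG(model, stats::setNames(1, "MGW_9")),
               class = "methylShapeLayoutError")
})

test_that("cross-validation returns a penalty grid and best pair", {
  set.seed(9)
  X <- matrix(rnorm(60 * 4), 60)
  colnames(X) <- paste0("f", 1:4)
  y <- drop(X %*% c(1, -1, 0, 0)) + rnorm(60, 0, 0.2)
  cv <- cvAffinityModel(X, y, lambda1Grid = c(0, 0.1),
                        lambda2Grid = c(0, 0.1), k = 3, seed = 5)
  expect_equal(nrow(cv$grid), 4L)
  expect_true(cv$best$lambda1 %in% c(0, 0.1))
})

test_that("CpG offsets classify per the site pattern", {
  expect_equal(classifyCpGOffset("ATGATCGATAAA", 6), "6/7")
  expect_equal(classifyCpGOffset("ATGATTAACGAA", 9), "9/10")
  expect_equal(classifyCpGOffset("ATGATTAATCGA", 10), "10/11")
  expect_equal(classifyCpGOffset("ATGATTAATACG", 11), "other")
  expect_equal(classifyCpGOffset("ATGATCGATAAA"), "none")
  expect_error(classifyCpGOffset("AAAATCGATAAA", 6),
               class = "methylShapePatternError")
  expect_error(classifyCpGOffset("ATGATCGATAAA", 5),
               class = "methylShapeMethylationError")
})

test_that("methylation effects on binding follow the log-ratio form", {
  rec <- data.frame(site = c("ATGATCGATAAA", "ATGATTAACGAA"),
                    meth_pos = c(6L, 9L),
                    affinity_unmeth = c(1, 0.2),
                    affinity_meth = c(1, 2))
  eff <- methylationEffect(rec)
  expect_equal(eff$pairs$dddG[1], 0)
  expect_equal(eff$pairs$dddG[2], -log(10))    # 10-fold gain
  expect_equal(eff$pairs$offset_class, c("6/7", "9/10"))
  expect_error(methylationEffect(transform(rec, affinity_meth = 0)),
               class = "methylShapeInputError")
  # planted cohort: group medians recover the planted signs
  sim <- simulateBindingRecords(nPerClass = 30, noiseSd = 0.2, seed = 17)
  by <- methylationEffect(sim)$byOffset
  planted <- c("6/7" = 1.5, "9/10" = -2.3, "10/11" = 1.0, "other" = 0.2)
  expect_equal(sign(by$median_dddG[match(names(planted),
                                         by$offset_class)]),
               sign(unname(planted)))
})

test_that("affinity models round-trip through the key=value format", {
  set.seed(10)
  X <- matrix(rnorm(40 * 5), 40)
  colnames(X) <- featureLayout(6)[1:5]
  y <- rnorm(40)
  m <- fitAffinityModel(X, y, 0.05, 0.02)
  path <- withr::local_tempfile(fileext = ".txt")
  writeAffinityModel(m, path)
  back <- readAffinityModel(path)
  expect_equal(back@weights, m@weights, tolerance = 1e-9)
  expect_equal(back@intercept, m@intercept, tolerance = 1e-9)
  expect_equal(back@layout, m@layout)
  expect_equal(predictAffinity(back, X), predictAffinity(m, X),
               tolerance = 1e-8)
})
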