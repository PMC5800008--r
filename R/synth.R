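# Synthetic-data generation with planted ground truth.
#
# Stands in for the mined all-atom trajectory output: a seeded TruthModel
# assigns base shape values to canonical sequence contexts, applies
# methylation effects deterministically, and record simulation adds i.i.d.
# Gaussian occurrence noise.  Step features (Roll, HelT) are defined at
# tetramer resolution -- the step between bp s and s+1 depends on the
# tetramer s-1..s+2 -- so the two pentamer windows covering a step always
# agree and a zero-noise pool reproduces the planted table exactly.

.DEFAULT_FLANKS <- c("AGTC", "CATG", "GACT", "TCAG")

#' Create a planted truth model
#'
#' Base values are drawn once (seeded) per canonical unmethylated pentamer
#' (MGW ~ N(5.1, 0.3) Angstrom, ProT ~ N(-7, 3) degrees) and canonical
#' unmethylated tetramer (Roll ~ N(1, 2.5) degrees, HelT ~ N(34.3, 1.2)
#' degrees), spanning the ranges typical of B-DNA shape tables.
#' Methylation effects are added deterministically on top of the
#' demethylated base value:
#' \itemize{
#'   \item `rollShift` (default +6 deg) at mg steps (the methylated step
#'     itself);
#'   \item `protShift` (default -5 deg) when the central bp of a pentamer
#'     is m or g;
#'   \item `heltShift` (default -2 deg) when an mg step sits off-centre in
#'     the step's tetramer context (the CpG at pentamer position 1 or 3);
#'   \item `mgwShift` (default -0.1 Angstrom) plus a seeded per-key
#'     context jitter of sd `mgwContextSd` for any pentamer carrying
#'     methylation marks (MGW changes are subtle and context dependent).
#' }
#' `pos6Effect` (default 0) adds, at record-simulation time, an MGW
#' dependency on the base three positions downstream of a window centre
#' (and its strand mirror) -- the weak sixth-position dependency that
#' pentamer tables cannot capture and that the CpG-context tables are
#' designed to remove.
#'
#' @param seed Integer seed; the model is fully reproducible from it.
#' @param rollShift,protShift,heltShift,mgwShift Methylation effect sizes.
#' @param mgwContextSd Sd of the per-key MGW context jitter.
#' @param pos6Effect MGW interaction with the sixth position (Angstrom).
#' @param sigma Default occurrence noise sd used by [simulateRecords()].
#' @return A [TruthModel].
#' @export
truthModel <- function(seed = 1L, rollShift = 6, protShift = -5,
                       heltShift = -2, mgwShift = -0.1,
                       mgwContextSd = 0.1, pos6Effect = 0, sigma = 0.5) {
  pentKeys <- enumeratePentamers("all")
  tetAll <- .windowValidKmers(4L)
  tetKeys <- unique(.canonMap(4L)$key[tetAll])
  tetKeys <- tetKeys[order(.rankKey(tetKeys))]

  unmethPent <- pentKeys[!grepl("[mg]", pentKeys)]
  unmethTet <- tetKeys[!grepl("[mg]", tetKeys)]
  methPent <- pentKeys[grepl("[mg]", pentKeys)]

  draws <- .withSeed(seed, list(
    mgw = stats::rnorm(length(unmethPent), 5.1, 0.3),
    prot = stats::rnorm(length(unmethPent), -7, 3),
    roll = stats::rnorm(length(unmethTet), 1, 2.5),
    helt = stats::rnorm(length(unmethTet), 34.3, 1.2),
    jitter = stats::rnorm(length(methPent), 0, mgwContextSd)))

  baseMGW <- stats::setNames(draws$mgw, unmethPent)
  baseProT <- stats::setNames(draws$prot, unmethPent)
  baseRoll <- stats::setNames(draws$roll, unmethTet)
  baseHelT <- stats::setNames(draws$helt, unmethTet)
  jitter <- stats::setNames(draws$jitter, methPent)

  demethKey <- function(keys, k) {
    d <- demethylateSeq(keys)
    unname(.canonMap(k)$key[d])
  }
  pd <- demethKey(pentKeys, 5L)
  isMeth <- grepl("[mg]", pentKeys)
  central <- substring(pentKeys, 3L, 3L)
  pent <- data.frame(
    key = pentKeys,
    mgw = unname(baseMGW[pd]) + mgwShift * isMeth +
      ifelse(isMeth, unname(jitter[pentKeys]), 0),
    prot = unname(baseProT[pd]) + protShift * (central %in% c("m", "g")))

  td <- demethKey(tetKeys, 4L)
  centerMg <- substring(tetKeys, 2L, 3L) == "mg"
  offMg <- substring(tetKeys, 1L, 2L) == "mg" |
    substring(tetKeys, 3L, 4L) == "mg"
  step <- data.frame(
    key = tetKeys,
    roll = unname(baseRoll[td]) + rollShift * centerMg,
    helt = unname(baseHelT[td]) + heltShift * offMg)

  methods::new("TruthModel", pentamer = pent, step = step,
               params = list(seed = seed, rollShift = rollShift,
                             protShift = protShift, heltShift = heltShift,
                             mgwShift = mgwShift,
                             mgwContextSd = mgwContextSd,
                             pos6Effect = pos6Effect, sigma = sigma))
}

# Truth lookups for arbitrary window-valid k-mers (canonicalized).
.truthPent <- function(truth, pentamers) {
  keys <- unname(.canonMap(5L)$key[pentamers])
  if (anyNA(keys)) .stopf("truth lookup: invalid pentamer",
                          class = "methylShapeMissingKeyError")
  i <- match(keys, truth@pentamer$key)
  if (anyNA(i)) .stopf("truth model lacks key(s)",
                       class = "methylShapeMissingKeyError")
  list(mgw = truth@pentamer$mgw[i], prot = truth@pentamer$prot[i])
}

.truthStep <- function(truth, tetramers) {
  keys <- unname(.canonMap(4L)$key[tetramers])
  if (anyNA(keys)) .stopf("truth lookup: invalid tetramer",
                          class = "methylShapeMissingKeyError")
  i <- match(keys, truth@step$key)
  if (anyNA(i)) .stopf("truth model lacks step key(s)",
                       class = "methylShapeMissingKeyError")
  list(roll = truth@step$roll[i], helt = truth@step$helt[i])
}

#' Materialize the planted truth as a query table
#'
#' Returns the exact table a zero-noise, zero-pos6 pool reproduces:
#' MGW/ProT per canonical pentamer, Roll/HelT slots from the step truth of
#' the pentamer's first and last four letters.  Used as the recovery
#' reference in parameter-recovery analyses.
#'
#' @param truth A [TruthModel].
#' @param universe Universe keyword or canonical key vector (default
#'   `"all"`).
#' @return A [QueryTable] (occurrence counts set to 1).
#' @export
truthTable <- function(truth, universe = "all") {
  keys <- .resolveUniverse(universe)
  p <- .truthPent(truth, keys)
  s1 <- .truthStep(truth, substring(keys, 1L, 4L))
  s2 <- .truthStep(truth, substring(keys, 2L, 5L))
  methods::new("QueryTable",
               entries = data.frame(key = keys, mgw = p$mgw, prot = p$prot,
                                    roll23 = s1$roll, roll34 = s2$roll,
                                    helt23 = s1$helt, helt34 = s2$helt,
                                    n = 1L),
               metadata = list(source = "truth",
                               seed = truth@params$seed))
}

#' Design a fragment pool covering a pentamer universe
#'
#' Greedy cover: canonical pentamers are visited in lexicographic order
#' and, while a pentamer's minable occurrence count is below `coverage`, a
#' fragment is added whose core is that pentamer completed to
#' fragment-mode validity (a leading g gains its m, a trailing m its g;
#' cores are 5-7 bp) flanked by 4 bp on each side, the right flank being
#' the reverse complement of the left.  Flanks rotate through `flankSet`,
#' so repeated coverage of one core uses different flanking contexts.
#' Occurrences contributed incidentally by flank-core junctions count
#' toward coverage.  Deterministic for a fixed universe and flank set.
#'
#' @param universe Universe keyword or canonical key vector.
#' @param coverage Minimum minable occurrences per universe key.
#' @param flankSet Character vector of 4-bp flanks over `A,C,G,T`.
#' @param margin Mining margin used to count minable windows.
#' @return data.frame of fragment designs: `id`, `core_key`, `core`,
#'   `flank`, `seq`.
#' @export
designPool <- function(universe = "all", coverage = 1L,
                       flankSet = .DEFAULT_FLANKS, margin = 1L) {
  stopifnot(coverage >= 1L, length(flankSet) >= 1L)
  if (any(grepl("[^ACGT]", flankSet)) || any(nchar(flankSet) != 4L))
    .stopf("flanks must be 4 bp over {A,C,G,T}")
  keys <- .resolveUniverse(universe)
  keys <- keys[order(.rankKey(keys))]
  counts <- stats::setNames(integer(length(keys)), keys)
  cm <- .canonMap(5L)
  rcFlank <- methylRevComp(flankSet)

  completeCore <- function(key) {
    core <- key
    if (startsWith(core, "g")) core <- paste0("m", core)
    if (endsWith(core, "m")) core <- paste0(core, "g")
    core
  }

  ids <- character(0); coreKeys <- character(0); cores <- character(0)
  flanks <- character(0); seqs <- character(0)
  fi <- 0L
  for (key in keys) {
    core <- completeCore(key)
    while (counts[[key]] < coverage) {
      fi <- fi + 1L
      fl <- flankSet[((fi - 1L) %% length(flankSet)) + 1L]
      seq <- paste0(fl, core, rcFlank[((fi - 1L) %% length(flankSet)) + 1L])
      n <- nchar(seq)
      centers <- (3L + margin):(n - 2L - margin)
      wkeys <- unname(cm$key[substring(seq, centers - 2L, centers + 2L)])
      hit <- wkeys[wkeys %in% keys]
      if (!key %in% hit)
        .stopf("internal: designed fragment misses its own core key %s", key)
      tb <- table(hit)
      counts[names(tb)] <- counts[names(tb)] + as.integer(tb)
      ids <- c(ids, sprintf("frag%05d", fi))
      coreKeys <- c(coreKeys, key); cores <- c(cores, core)
      flanks <- c(flanks, fl); seqs <- c(seqs, seq)
    }
  }
  data.frame(id = ids, core_key = coreKeys, core = cores, flank = flanks,
             seq = seqs)
}

.sigmaOf <- function(sigma, feature) {
  if (length(sigma) == 1L && is.null(names(sigma))) return(sigma)
  if (!feature %in% names(sigma)) .stopf("sigma lacks entry for %s", feature)
  unname(sigma[[feature]])
}

#' Simulate shape records from a truth model
#'
#' For every design, the noiseless feature arrays are assembled from the
#' truth (MGW/ProT per position from the pentamer centred there, Roll/HelT
#' per step from the step's tetramer context; the two boundary positions
#' and steps on each side are undefined), the pos6 MGW interaction is
#' added where configured, and `nOcc` replicate records are drawn with
#' i.i.d. Gaussian noise of sd `sigma` at every defined entry.  Identical
#' seeds produce byte-identical pools.
#'
#' @param truth A [TruthModel].
#' @param designs data.frame with columns `id` and `seq` (e.g. from
#'   [designPool()]).
#' @param nOcc Replicate records per design.
#' @param sigma Noise sd; scalar or named vector (`mgw`, `prot`, `roll`,
#'   `helt`).  Defaults to the truth model's sigma.
#' @param seed RNG seed for the noise.
#' @return A [ShapeRecordPool].
#' @export
simulateRecords <- function(truth, designs, nOcc = 1L, sigma = NULL,
                            seed = 1L) {
  stopifnot(is(truth, "TruthModel"),
            all(c("id", "seq") %in% names(designs)))
  if (is.null(sigma)) sigma <- truth@params$sigma
  nOcc <- as.integer(nOcc)
  pos6 <- truth@params$pos6Effect

  nd <- nrow(designs)
  lens <- nchar(designs$seq)
  baseM <- vector("list", nd); baseP <- vector("list", nd)
  baseR <- vector("list", nd); baseH <- vector("list", nd)
  for (i in seq_len(nd)) {
    s <- designs$seq[i]; n <- lens[i]
    centers <- 3:(n - 2L)
    tp <- .truthPent(truth, substring(s, centers - 2L, centers + 2L))
    mg <- rep(NA_real_, n); pr <- rep(NA_real_, n)
    mg[centers] <- tp$mgw
    pr[centers] <- tp$prot
    if (pos6 != 0) {
      ch <- .splitChars(s)[[1L]]
      dn <- ifelse(centers + 3L <= n, ch[pmin(centers + 3L, n)], "")
      up <- ifelse(centers - 3L >= 1L, ch[pmax(centers - 3L, 1L)], "")
      mg[centers] <- mg[centers] + pos6 * ((dn %in% c("G", "g")) +
                                             (up %in% c("C", "m")))
    }
    steps <- 2:(n - 2L)
    ts <- .truthStep(truth, substring(s, steps - 1L, steps + 2L))
    ro <- rep(NA_real_, n - 1L); he <- rep(NA_real_, n - 1L)
    ro[steps] <- ts$roll
    he[steps] <- ts$helt
    baseM[[i]] <- mg; baseP[[i]] <- pr; baseR[[i]] <- ro; baseH[[i]] <- he
  }
  flatM <- unlist(baseM); flatP <- unlist(baseP)
  flatR <- unlist(baseR); flatH <- unlist(baseH)

  # replicate-major ordering: all designs for rep 1, then rep 2, ...
  repM <- rep(flatM, nOcc); repP <- rep(flatP, nOcc)
  repR <- rep(flatR, nOcc); repH <- rep(flatH, nOcc)
  .withSeed(seed, {
    addNoise <- function(v, feat) {
      s <- .sigmaOf(sigma, feat)
      if (s > 0) {
        ok <- !is.na(v)
        v[ok] <- v[ok] + stats::rnorm(sum(ok), 0, s)
      }
      v
    }
    repM <- addNoise(repM, "mgw"); repP <- addNoise(repP, "prot")
    repR <- addNoise(repR, "roll"); repH <- addNoise(repH, "helt")
  })
  ids <- paste0(rep(designs$id, times = nOcc), ".r",
                rep(seq_len(nOcc), each = nd))
  methods::new("ShapeRecordPool",
               id = ids, seq = rep(designs$seq, nOcc),
               len = rep(lens, nOcc),
               mgw = repM, prot = repP, roll = repR, helt = repH,
               metadata = list(pool_id = sprintf("synth-seed%s", seed),
                               sigma = sigma, n_occ = nOcc,
                               truth_seed = truth@params$seed))
}

#' Simulate a DNase-style cleavage-count table from a planted model
#'
#' Hexamer energies are computed from the planted weight vector as
#' `E = X w` (shape features from the supplied table, no intercept) and
#' counts drawn multinomially with probabilities proportional to
#' `exp(-E)`, separately for the unmethylated hexamer set and for the
#' methylated variants of every CpG-containing hexamer (features of the
#' mg-substituted sequence).
#'
#' @param weights Named numeric in [featureLayout()] order (zero entries
#'   may be omitted), or an [AffinityModel] whose weights are used.
#' @param table Methylation-aware [QueryTable] used for featurization.
#' @param hexamers Unmethylated hexamer set (default: all 4096).
#' @param depth Total count depth per variant class.
#' @param seed RNG seed.
#' @return Cleavage table data.frame: `kmer` (parent hexamer), `variant`,
#'   `cpg_offset` (position of the first CpG; NA for unmethylated rows),
#'   `count`.
#' @export
simulateCleavage <- function(weights, table, hexamers = NULL,
                             depth = 2e6, seed = 1L) {
  if (is(weights, "AffinityModel")) weights <- weights@weights
  if (is.null(hexamers)) {
    hexamers <- do.call(paste0,
                        expand.grid(rep(list(c("A", "C", "G", "T")), 6L),
                                    stringsAsFactors = FALSE,
                                    KEEP.OUT.ATTRS = FALSE))
  }
  energyOf <- function(kmers) {
    X <- featurizeKmers(kmers, table, missing = "error")
    drop(X[, names(weights), drop = FALSE] %*% weights)
  }
  eu <- energyOf(hexamers)
  if (any(!is.finite(eu))) .stopf("non-finite planted energies")
  hasCpG <- grepl("CG", hexamers, fixed = TRUE)
  hm <- vapply(hexamers[hasCpG], methylateSeq, "", USE.NAMES = FALSE)
  em <- energyOf(hm)
  offs <- vapply(hexamers[hasCpG],
                 function(h) .fixedMatches(h, "CG")[1L], 0L,
                 USE.NAMES = FALSE)
  .withSeed(seed, {
    cu <- stats::rmultinom(1L, depth, exp(-eu))[, 1L]
    cm <- stats::rmultinom(1L, depth, exp(-em))[, 1L]
  })
  rbind(data.frame(kmer = hexamers, variant = "unmethylated",
                   cpg_offset = NA_integer_, count = cu),
        data.frame(kmer = hexamers[hasCpG], variant = "methylated",
                   cpg_offset = offs, count = cm))
}

#' Simulate paired Pbx-Hox binding records with planted offset effects
#'
#' Generates 12-bp sites matching `NTGAYNNAYNNN` with a single CpG at
#' offset 6/7, 9/10, 10/11 or at position 11/12 (classified `"other"`),
#' and paired relative affinities such that the log affinity ratio equals
#' the planted per-offset effect plus Gaussian noise:
#' `affinity_meth = affinity_unmeth * exp(-(effect + noise))`.
#'
#' @param effects Named numeric of planted dddG/RT per offset class.
#' @param nPerClass Pairs per offset class.
#' @param noiseSd Sd of the log-scale noise.
#' @param seed RNG seed.
#' @return data.frame: `site`, `meth_pos`, `offset_class`,
#'   `affinity_unmeth`, `affinity_meth`, `true_effect`.
#' @export
simulateBindingRecords <- function(effects = c("6/7" = 1.5, "9/10" = -2.3,
                                               "10/11" = 1.0,
                                               "other" = 0.2),
                                   nPerClass = 25L, noiseSd = 0.1,
                                   seed = 1L) {
  methPosOf <- c("6/7" = 6L, "9/10" = 9L, "10/11" = 10L, "other" = 11L)
  stopifnot(all(names(effects) %in% names(methPosOf)))
  .withSeed(seed, {
    out <- lapply(names(effects), function(cls) {
      mp <- methPosOf[[cls]]
      sites <- vapply(seq_len(nPerClass), function(i) {
        ch <- c(sample(c("A", "C", "G", "T"), 1L), "T", "G", "A",
                sample(c("C", "T"), 1L),
                sample(c("A", "C", "G", "T"), 1L),
                sample(c("A", "C", "G", "T"), 1L), "A",
                sample(c("C", "T"), 1L),
                sample(c("A", "C", "G", "T"), 1L),
                sample(c("A", "C", "G", "T"), 1L),
                sample(c("A", "C", "G", "T"), 1L))
        ch[mp] <- "C"; ch[mp + 1L] <- "G"
        if (mp == 9L) ch[9L] <- "C"    # position 9 must stay a pyrimidine
        paste(ch, collapse = "")
      }, "")
      au <- exp(stats::rnorm(nPerClass, 0, 0.5))
      am <- au * exp(-(effects[[cls]] + stats::rnorm(nPerClass, 0, noiseSd)))
      data.frame(site = sites, meth_pos = mp, offset_class = cls,
                 affinity_unmeth = au, affinity_meth = am,
                 true_effect = effects[[cls]])
    })
    do.call(rbind, out)
  })
}

#' Simulate paired A-tract MGW samples
#'
#' For each A-tract context of the chosen series, draws `nPairs` random
#' 4-bp flanks, embeds the unmethylated and CpG-methylated context between
#' the flank and its reverse complement, simulates one noisy record per
#' fragment, and reads the MGW at the central nucleotide of the tract.
#' Pairing is by fragment context: the methylated and unmethylated member
#' of a pair share the same flank, so the paired difference isolates the
#' methylation effect.
#'
#' @param truth A [TruthModel] (set its `mgwShift` to plant narrowing or
#'   widening).
#' @param series `"3bp"` or `"4bp"`.
#' @param nPairs Pairs per context.
#' @param sigma Occurrence noise sd for the simulated records.
#' @param seed RNG seed.
#' @return data.frame: `context`, `pair`, `flank`, `mgw_unmeth`,
#'   `mgw_meth`.
#' @export
simulateAtractPairs <- function(truth, series = c("3bp", "4bp"),
                                nPairs = 20L, sigma = 0.1, seed = 1L) {
  series <- match.arg(series)
  ctx <- atractContexts(series)
  flanks <- .withSeed(seed, vapply(seq_len(nPairs), function(i)
    paste(sample(c("A", "C", "G", "T"), 4L, replace = TRUE),
          collapse = ""), ""))
  out <- lapply(seq_len(nrow(ctx)), function(ci) {
    co <- ctx$context[ci]
    com <- methylateSeq(co, "all_cpg")
    designs <- data.frame(
      id = c(paste0(co, ".u", seq_len(nPairs)),
             paste0(co, ".m", seq_len(nPairs))),
      seq = c(paste0(flanks, co, methylRevComp(flanks)),
              paste0(flanks, com, methylRevComp(flanks))))
    pool <- simulateRecords(truth, designs, nOcc = 1L, sigma = sigma,
                            seed = seed + ci)
    at <- 4L + ctx$measure_at[ci]
    bo <- .bpOffsets(pool)
    vals <- pool@mgw[bo + at]
    data.frame(context = co, pair = seq_len(nPairs), flank = flanks,
               mgw_unmeth = vals[seq_len(nPairs)],
               mgw_meth = vals[nPairs + seq_len(nPairs)])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
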