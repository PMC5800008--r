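# Shape-to-affinity modeling: DNase I hexamer energies, elastic-net
# regression on shape features, and the Pbx-Hox methylation-effect
# comparator.

#' Filter a cleavage table by minimum count
#'
#' Hexamers observed fewer than `minCount` times carry unreliable energy
#' estimates and are removed (default threshold 25 absolute phosphate
#' cleavage counts).  The filter is applied independently per methylation
#' variant.
#'
#' @param table data.frame with columns `kmer`, `variant`
#'   (`"unmethylated"`/`"methylated"`), `count` and optionally
#'   `cpg_offset`.
#' @param minCount Minimum retained count (default 25).
#' @return Filtered data.frame (warning if empty).
#' @export
filterHexamers <- function(table, minCount = 25L) {
  stopifnot(all(c("kmer", "variant", "count") %in% names(table)))
  if (any(table$count < 0)) .stopf("negative counts")
  out <- table[table$count >= minCount, , drop = FALSE]
  if (!nrow(out)) warning("all rows below the count threshold")
  rownames(out) <- NULL
  out
}

#' Convert cleavage counts to relative binding free energies
#'
#' ddG/RT(h) = -ln(c_h / c_ref), computed independently per methylation
#' variant.  The reference is the mean retained count by default
#' (`"median"` or a named reference hexamer are alternatives); energies
#' are invariant under global rescaling of the counts.
#'
#' @param table Filtered cleavage table (see [filterHexamers()]).
#' @param reference `"mean"`, `"median"`, or a hexamer string whose count
#'   defines the zero of the scale.
#' @return data.frame with columns `kmer`, `variant`, `energy` (and
#'   `cpg_offset` if present in the input).
#' @export
countsToEnergy <- function(table, reference = "mean") {
  stopifnot(all(c("kmer", "variant", "count") %in% names(table)))
  if (any(table$count <= 0))
    .stopf("counts must be positive after filtering",
           class = "methylShapeInputError")
  refOf <- function(counts, kmers) {
    if (identical(reference, "mean")) mean(counts)
    else if (identical(reference, "median")) stats::median(counts)
    else {
      i <- match(reference, kmers)
      if (is.na(i)) .stopf("reference hexamer %s not in table", reference)
      counts[i]
    }
  }
  out <- lapply(split(table, table$variant), function(g) {
    g$energy <- -log(g$count / refOf(g$count, g$kmer))
    g
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  keep <- intersect(c("kmer", "variant", "cpg_offset", "energy"), names(res))
  res[, keep, drop = FALSE]
}

#' Feature layout for k-mer shape featurization
#'
#' @param k k-mer width.
#' @return Character vector of feature names, `MGW_1..MGW_k`,
#'   `ProT_1..ProT_k`, `Roll_1..Roll_(k-1)`, `HelT_1..HelT_(k-1)`
#'   (4k - 2 entries; 22 for a hexamer).
#' @export
featureLayout <- function(k = 6L) {
  c(paste0("MGW_", seq_len(k)), paste0("ProT_", seq_len(k)),
    paste0("Roll_", seq_len(k - 1L)), paste0("HelT_", seq_len(k - 1L)))
}

#' Featurize k-mers with wildcard-padded shape values
#'
#' Pads each k-mer with two N wildcards on either side so that every
#' internal position and step receives a pentamer-window value (the
#' wildcard query averages over all concrete flanks).  Step values combine
#' the two covering windows as in [shapeProfile()] (both always available
#' thanks to the padding).  The resulting vector is ordered per
#' [featureLayout()]; models store this layout so featurization and
#' prediction cannot silently disagree.
#'
#' @param kmers Character vector of fragment-valid k-mers over
#'   `A,C,G,T,m,g`, all the same width.
#' @param table A [QueryTable] covering the queried pentamers (use the
#'   methylation-aware table when k-mers carry m/g).
#' @param missing Missing-key policy.
#' @return Numeric matrix, one row per k-mer, columns per
#'   [featureLayout()].
#' @export
featurizeKmers <- function(kmers, table, missing = c("na", "error")) {
  missing <- match.arg(missing)
  k <- unique(nchar(kmers))
  if (length(k) != 1L) .stopf("k-mers must share one width")
  .assertValid(kmers, "fragment", "k-mer")
  padded <- paste0("NN", kmers, "NN")

  # window centred at k-mer position i <-> padded substring [i, i+4]
  patByPos <- vapply(seq_len(k), function(i)
    substring(padded, i, i + 4L), character(length(kmers)))
  patByPos <- matrix(patByPos, nrow = length(kmers))
  pats <- unique(as.vector(patByPos))
  qw <- queryWildcard(table, pats, missing = missing)
  look <- function(col) {
    v <- stats::setNames(qw[[col]], qw$pattern)
    matrix(unname(v[as.vector(patByPos)]), nrow = length(kmers))
  }
  mgw <- look("mgw"); prot <- look("prot")
  r23 <- look("roll23"); r34 <- look("roll34")
  h23 <- look("helt23"); h34 <- look("helt34")

  steps <- seq_len(k - 1L)
  roll <- (r34[, steps, drop = FALSE] + r23[, steps + 1L, drop = FALSE]) / 2
  helt <- (h34[, steps, drop = FALSE] + h23[, steps + 1L, drop = FALSE]) / 2

  X <- cbind(mgw, prot, roll, helt)
  dimnames(X) <- list(kmers, featureLayout(k))
  X
}

.softThreshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

#' Fit a linear shape-to-affinity model by elastic-net regression
#'
#' Minimizes `||y - Xw - b||^2 + lambda1 ||w||_1 + lambda2 ||w||_2^2` by
#' cyclic coordinate descent on internally standardized features (mean 0,
#' unit variance); coefficients are reported back on the original feature
#' scale.  The fit is deterministic for fixed inputs: features are visited
#' in layout order and iteration stops when no coefficient moves by more
#' than `tol`.  With both penalties zero the solution is ordinary least
#' squares.  Single-feature-class submodels (Roll-only etc.) are obtained
#' by subsetting the design columns before fitting.
#'
#' @param X Numeric design matrix with named columns (see
#'   [featurizeKmers()]).
#' @param y Numeric response (ddG/RT), `length(y) == nrow(X)`.
#' @param lambda1,lambda2 L1 and L2 penalties (defaults 0.01).
#' @param tol Convergence tolerance on coefficient updates (default 1e-8).
#' @param maxIter Maximum coordinate-descent sweeps.
#' @return An [AffinityModel].
#' @export
fitAffinityModel <- function(X, y, lambda1 = 0.01, lambda2 = 0.01,
                             tol = 1e-8, maxIter = 100000L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (nrow(X) != length(y) || nrow(X) < 2L)
    .stopf("need nrow(X) == length(y) >= 2", class = "methylShapeInputError")
  layout <- colnames(X)
  sds <- apply(X, 2L, stats::sd)
  dropped <- layout[sds == 0 | is.na(sds)]
  if (length(dropped))
    warning(sprintf("dropping zero-variance feature(s): %s",
                    paste(dropped, collapse = ", ")))
  keep <- setdiff(layout, dropped)
  Xk <- X[, keep, drop = FALSE]
  xm <- colMeans(Xk)
  xs <- apply(Xk, 2L, stats::sd)
  Z <- sweep(sweep(Xk, 2L, xm), 2L, xs, "/")
  ym <- mean(y)
  r <- y - ym                      # residual with w = 0
  p <- ncol(Z)
  w <- numeric(p)
  zz <- colSums(Z^2)
  iter <- 0L
  if (p > 0L) repeat {
    iter <- iter + 1L
    delta <- 0
    for (j in seq_len(p)) {
      zj <- Z[, j]
      rho <- sum(zj * r) + zz[j] * w[j]
      wj <- .softThreshold(rho, lambda1 / 2) / (zz[j] + lambda2)
      if (wj != w[j]) {
        r <- r - zj * (wj - w[j])
        delta <- max(delta, abs(wj - w[j]))
        w[j] <- wj
      }
    }
    if (delta <= tol || iter >= maxIter) break
  }
  wOrig <- stats::setNames(w / xs, keep)
  intercept <- ym - sum(wOrig * xm)
  methods::new("AffinityModel", weights = wOrig, intercept = intercept,
               lambda1 = lambda1, lambda2 = lambda2,
               layout = layout, dropped = dropped,
               metadata = list(iterations = iter, tol = tol,
                               standardization = list(mean = xm, sd = xs),
                               y_mean = ym))
}

#' Cross-validate elastic-net penalties
#'
#' Seeded k-fold cross-validation over a penalty grid; returns the grid of
#' mean squared errors and the best pair.
#'
#' @param X,y Design and response as in [fitAffinityModel()].
#' @param lambda1Grid,lambda2Grid Candidate penalties.
#' @param k Number of folds (default 5).
#' @param seed RNG seed for the fold assignment.
#' @return list(grid = data.frame(lambda1, lambda2, mse), best =
#'   list(lambda1, lambda2)).
#' @export
cvAffinityModel <- function(X, y, lambda1Grid = c(0, 0.01, 0.1, 1),
                            lambda2Grid = c(0, 0.01, 0.1, 1),
                            k = 5L, seed = 1L) {
  X <- as.matrix(X)
  folds <- .withSeed(seed, sample(rep_len(seq_len(k), nrow(X))))
  grid <- expand.grid(lambda1 = lambda1Grid, lambda2 = lambda2Grid)
  grid$mse <- vapply(seq_len(nrow(grid)), function(i) {
    errs <- vapply(seq_len(k), function(f) {
      tr <- folds != f
      m <- suppressWarnings(
        fitAffinityModel(X[tr, , drop = FALSE], y[tr],
                         grid$lambda1[i], grid$lambda2[i]))
      mean((y[!tr] - predictAffinity(m, X[!tr, , drop = FALSE]))^2)
    }, 0)
    mean(errs)
  }, 0)
  best <- grid[which.min(grid$mse), ]
  list(grid = grid,
       best = list(lambda1 = best$lambda1, lambda2 = best$lambda2))
}

#' Predict affinities and methylation-induced energy shifts
#'
#' `predictAffinity()` evaluates the affine model `intercept + X w`.
#' `predictDddG()` exploits the model's linearity: the methylation-induced
#' energy shift dddG/RT is `W . delta-features` with no intercept, so
#' delta-shape vectors are used directly as input.
#'
#' @param model An [AffinityModel].
#' @param X Feature matrix in the model layout (extra columns ignored by
#'   name; missing non-dropped columns are an error).
#' @return Numeric vector of predictions.
#' @export
predictAffinity <- function(model, X) {
  X <- as.matrix(X)
  drop(model@intercept + .alignFeatures(model, X) %*% model@weights)
}

#' @rdname predictAffinity
#' @param deltaX Matrix (or vector) of delta-features in the model layout.
#' @export
predictDddG <- function(model, deltaX) {
  if (is.null(dim(deltaX))) {
    deltaX <- matrix(deltaX, nrow = 1L,
                     dimnames = list(NULL, names(deltaX)))
  }
  drop(.alignFeatures(model, as.matrix(deltaX)) %*% model@weights)
}

.alignFeatures <- function(model, X) {
  need <- names(model@weights)
  if (is.null(colnames(X))) {
    if (ncol(X) == length(model@layout)) {
      colnames(X) <- model@layout
    } else if (ncol(X) != length(need)) {
      .stopf("feature layout mismatch: expected %d columns, got %d",
             length(model@layout), ncol(X),
             class = "methylShapeLayoutError")
    } else colnames(X) <- need
  }
  miss <- setdiff(need, colnames(X))
  if (length(miss))
    .stopf("feature layout mismatch: missing %s",
           paste(utils::head(miss, 3L), collapse = ", "),
           class = "methylShapeLayoutError")
  X[, need, drop = FALSE]
}

#' Classify the CpG offset of a methylated Pbx-Hox site
#'
#' Pbx-Hox heterodimers bind 12-bp sites matching `NTGAYNNAYNNN` (Y = C or
#' T).  Methylation of a CpG at offset 6/7 (`NTGAYCGAYNNN`) or 10/11
#' (`NTGAYNNAYCGN`) suppresses binding, whereas a CpG at offset 9/10
#' (`NTGAYNNACGNN`) enhances it.
#'
#' @param site 12-mer over `A,C,G,T` matching the pattern.
#' @param methPos 1-based position of the methylated cytosine, or
#'   `NULL`/empty for an unmethylated site.
#' @return One of `"6/7"`, `"9/10"`, `"10/11"`, `"other"`, `"none"`.
#' @export
classifyCpGOffset <- function(site, methPos = NULL) {
  stopifnot(is.character(site), length(site) == 1L)
  if (!grepl("^[ACGT]TGA[CT][ACGT]{2}A[CT][ACGT]{3}$", site))
    .stopf("site %s does not match NTGAYNNAYNNN", site,
           class = "methylShapePatternError")
  if (is.null(methPos) || !length(methPos)) return("none")
  if (length(methPos) != 1L)
    .stopf("exactly one methylated CpG expected",
           class = "methylShapeInputError")
  methPos <- as.integer(methPos)
  if (substring(site, methPos, methPos + 1L) != "CG")
    .stopf("position %d of %s is not a CpG", methPos, site,
           class = "methylShapeMethylationError")
  switch(as.character(methPos), "6" = "6/7", "9" = "9/10", "10" = "10/11",
         "other")
}

#' Methylation effect on binding free energy from paired affinities
#'
#' For each site measured with and without methylation, the effect on
#' binding free energy is `dddG/RT = -ln(affinity_meth /
#' affinity_unmeth)`: positive values mean suppressed, negative enhanced
#' binding (a 10-fold affinity gain gives -ln 10 = -2.303).  Pairs are
#' grouped by CpG offset class within the Pbx-Hox site pattern.
#'
#' @param records data.frame with columns `site` (12-mer), `meth_pos`
#'   (1-based C position, NA for unmethylated pairs excluded),
#'   `affinity_meth`, `affinity_unmeth` (both positive).
#' @return list with `pairs` (per-pair dddG and offset class) and
#'   `byOffset` (n and median dddG per offset class).
#' @export
methylationEffect <- function(records) {
  need <- c("site", "meth_pos", "affinity_meth", "affinity_unmeth")
  stopifnot(all(need %in% names(records)))
  if (any(records$affinity_meth <= 0 | records$affinity_unmeth <= 0))
    .stopf("affinities must be positive", class = "methylShapeInputError")
  pairs <- records
  pairs$dddG <- -log(pairs$affinity_meth / pairs$affinity_unmeth)
  pairs$offset_class <- vapply(seq_len(nrow(pairs)), function(i)
    classifyCpGOffset(pairs$site[i], pairs$meth_pos[i]), "")
  byOffset <- do.call(rbind, lapply(split(pairs, pairs$offset_class),
                                    function(g)
    data.frame(offset_class = g$offset_class[1L], n = nrow(g),
               median_dddG = stats::median(g$dddG))))
  rownames(byOffset) <- NULL
  list(pairs = pairs, byOffset = byOffset)
}
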