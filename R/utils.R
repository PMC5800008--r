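# Internal helpers shared across modules.

.msCache <- new.env(parent = emptyenv())

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv(), inherits = FALSE) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

.stopf <- function(fmt, ..., class = "methylShapeError") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

.splitChars <- function(x) strsplit(x, "", fixed = TRUE)

# Positions of every occurrence of a fixed pattern (possibly none).
.fixedMatches <- function(x, pattern) {
  m <- gregexpr(pattern, x, fixed = TRUE)[[1L]]
  if (length(m) == 1L && m[1L] == -1L) integer(0) else as.integer(m)
}
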