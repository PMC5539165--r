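#' @include AllClasses.R
NULL

## Deterministic per-stage seed derivation: a small string hash folded into
## the master seed, kept inside 32-bit integer range.  Each stochastic stage
## of the pipeline (and each simulated library) gets its own stream so that
## generating libraries in a different order cannot change any of them.
seedFanout <- function(masterSeed, stage) {
  h <- 0
  for (ch in utf8ToInt(as.character(stage)))
    h <- (h * 131 + ch) %% 1000000007
  as.integer((as.numeric(masterSeed) * 2654435 + h) %% 2147483647)
}

## Strand-blind overlap test that tolerates disjoint seqlevels (e.g.
## comparing cistromes from different chromosome subsets).
.ovAny <- function(query, subject)
  suppressWarnings(overlapsAny(query, subject, ignore.strand = TRUE))

## Run `expr` under a temporary seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
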