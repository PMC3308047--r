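# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched. All stochastic operations in the package run through
# this so a root seed plus fixed offsets gives reproducible, independently
# re-runnable substreams.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(expr)
}

# (n-1)-th harmonic number a_{n-1} = sum_{i=1}^{n-1} 1/i
harmonicNumber <- function(n) {
  stopifnot(n >= 2)
  sum(1 / seq_len(n - 1L))
}

# Genotype dosage matrix -> per-site alternate allele count / non-missing
# chromosome count, over an optional sample subset.
altAlleleCounts <- function(genotype, samples = NULL) {
  if (!is.null(samples)) genotype <- genotype[, samples, drop = FALSE]
  list(ac = rowSums(genotype, na.rm = TRUE),
       an = 2L * rowSums(!is.na(genotype)))
}

stopIfNot1 <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
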