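# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards.  seed = NULL runs in the ambient state.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (hadSeed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Independent per-stage RNG substreams from one scenario seed, via the
# L'Ecuyer-CMRG stream mechanism, so any stage can be regenerated in
# isolation and stages never share draws.
withStream <- function(seed, streamIndex, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (hadSeed) get(".Random.seed", envir = globalenv()) else NULL
  oldKind <- RNGkind()
  on.exit({
    RNGkind(oldKind[1], oldKind[2], oldKind[3])
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", envir = globalenv())
  for (i in seq_len(streamIndex)) s <- parallel::nextRNGStream(s)
  assign(".Random.seed", s, envir = globalenv())
  expr
}

# Truncated normal draw by rejection; bounds wide relative to sd in all uses.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  x
}
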