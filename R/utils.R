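# Evaluate expr under a locally-set RNG seed, restoring the caller's RNG
# state afterwards. All randomness in the package funnels through this.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

norm_prefix_limit <- function(prefix_limit) {
  if (is.null(prefix_limit) || is.na(prefix_limit) ||
      !is.finite(prefix_limit) || prefix_limit <= 0) 0L
  else as.integer(prefix_limit)
}
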