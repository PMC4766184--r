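## Internal helpers.

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's RNG state afterwards. With seed = NULL the global RNG stream
## is used (and advanced) as usual.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Single-environment-label check returning the label.
check_env <- function(env) {
  env <- as.character(env)
  if (length(env) != 1L || !env %in% env_levels)
    stop("environment must be a single 'N' or 'A' label")
  env
}
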