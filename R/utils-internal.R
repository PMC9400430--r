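# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards so generators stay pure
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# exact 97.5% normal quantile used for all Wald intervals
Z975 <- 1.959964

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
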