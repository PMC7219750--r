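# Internal error helper: every package error carries a subclass so callers
# (and the CLI exit-code mapping) can dispatch on the failure kind.
abort_qihb <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "qihb_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code without disturbing the caller's RNG stream (used by the copula
# calibration, which needs its own fixed internal seed).
with_preserved_seed <- function(code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  force(code)
}

# Session-level memo cache (copula calibrations).
.qihb_cache <- new.env(parent = emptyenv())

cache_get_or <- function(key, compute) {
  if (!is.null(.qihb_cache[[key]])) return(.qihb_cache[[key]])
  val <- compute()
  .qihb_cache[[key]] <- val
  val
}
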