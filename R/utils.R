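# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so analysis functions do not disturb
# the session stream. Every stochastic entry point funnels through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# One structured log line per pipeline stage, suppressible via
# options(bathyrule.quiet = TRUE).
stage_log <- function(stage, ...) {
  if (isTRUE(getOption("bathyrule.quiet", FALSE))) return(invisible(NULL))
  message(sprintf("[bathyrule:%s] %s", stage, sprintf(...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
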