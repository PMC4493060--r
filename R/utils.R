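#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. All stochastic package functions route
# their randomness through this so that a single top-level seed gives
# bit-identical runs.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
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
  set.seed(seed)
  force(code)
}

# Fan a master seed out into named per-stage sub-seeds (31-bit integers),
# so stages can be re-run independently yet reproducibly.
derive_seeds <- function(master_seed, names) {
  s <- with_seed(master_seed, sample.int(2147483646L, length(names)))
  stats::setNames(s, names)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_netreconfig <- function(...) stop(..., call. = FALSE)
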