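# Small internal helpers.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
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
  expr
}

deg2rad <- function(deg) deg * pi / 180
rad2deg <- function(rad) rad * 180 / pi
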