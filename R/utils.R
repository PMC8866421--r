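## internal helpers

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# x |> soft-threshold at kappa on the log-ratio scale: argmin a*e^x - b*x + k|x|
# for a > 0, b >= 0, k >= 0.  Closed form via the KKT conditions.
softLogRatio <- function(a, b, kappa) {
  up <- log(pmax(b - kappa, 0) / a)   # candidate if x > 0
  dn <- log((b + kappa) / a)          # candidate if x < 0
  out <- numeric(length(a))
  out[up > 0] <- up[up > 0]
  out[dn < 0] <- dn[dn < 0]
  out
}

stopIfNot <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}
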