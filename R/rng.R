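# Deterministic per-stage seed substreams: every randomized stage hashes the
# run seed together with a stage label so that, e.g., Y-scrambling draws never
# perturb the CV fold stream. Plain 32-bit arithmetic, no RNG state leakage.

#' Derive a deterministic substream seed for a pipeline stage
#'
#' @param seed integer master seed.
#' @param label character stage label (e.g. "cv", "ga", "scramble").
#' @param index optional integer (e.g. replicate number) folded into the hash.
#' @return an integer seed in [0, 2^31).
#' @export
substream_seed <- function(seed, label, index = 0L) {
  h <- as.double(seed) %% 2147483647
  for (b in utf8ToInt(label)) h <- (h * 31 + b) %% 2147483647
  h <- (h * 31 + as.double(index)) %% 2147483647
  as.integer(h)
}

# Evaluate expr under a local RNG state seeded from (seed, label, index);
# the caller's .Random.seed is restored afterwards.
with_substream <- function(seed, label, index = 0L, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, label, index))
  expr
}
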