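#' Derive a named substream seed from a master seed
#'
#' All randomness in the simulator flows from one master seed through named
#' substreams (`"ancestor"`, `"deletions"`, `"donor1"`, `"reads7"`, ...), so
#' that any stage can be regenerated independently and reproducibly. The
#' derived seed is a deterministic 31-bit hash of the master seed and the
#' stream name.
#'
#' @param master Integer master seed.
#' @param name Character stream name.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(master, name) {
  h <- as.double(master) %% 2147483647
  for (b in utf8ToInt(name)) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}
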