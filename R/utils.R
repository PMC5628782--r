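#' Inverse logit
#'
#' @param x numeric vector of log-odds.
#' @return probabilities in (0, 1).
#' @export
expit <- function(x) 1 / (1 + exp(-x))

#' Logit
#'
#' @param p numeric vector of probabilities in (0, 1).
#' @return log-odds.
#' @export
logit <- function(p) log(p / (1 - p))

#' Derive a reproducible sub-seed
#'
#' Counter-based per-replicate seed derivation: a linear-congruential mix of
#' (master seed, stream, replicate index) modulo 2^31 - 1. All arithmetic is
#' in doubles with a maximum intermediate near 1e14, so it is exact. Streams
#' keep calibration draws (stream 1), replicate draws (stream 0) and
#' per-preset sub-seeds (stream 2) from colliding; any replicate of any run
#' can be regenerated in isolation from the master seed.
#'
#' @param master master seed (integer-valued).
#' @param replicate replicate counter.
#' @param stream stream id.
#' @return an integer seed in [0, 2^31 - 1).
#' @export
derive_seed <- function(master, replicate = 0L, stream = 0L) {
  m <- 2147483647
  s <- as.numeric(master) %% m
  s <- (s * 48271 + as.numeric(stream) * 99991 +
          as.numeric(replicate) * 69621 + 12345) %% m
  as.integer(s)
}
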