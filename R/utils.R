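#' Inverse logit
#'
#' @param x numeric vector on the log-odds scale.
#' @return probabilities in (0, 1).
#' @keywords internal
expit <- function(x) stats::plogis(x)

#' Logit
#'
#' @param p probabilities strictly in (0, 1).
#' @return log-odds.
#' @keywords internal
logit <- function(p) stats::qlogis(p)

#' Derive a replicate seed from a master seed
#'
#' Replicate-level seeds are a deterministic function of the master seed and a
#' stream index, so any single replicate can be reproduced in isolation. The
#' derivation is `(master * 48271 + 2^15 * stream + index) mod (2^31 - 1)`,
#' a Lehmer-style mix kept inside the 32-bit integer range R requires.
#'
#' @param master integer master seed.
#' @param index replicate index (1-based).
#' @param stream optional sub-stream discriminator (e.g. one per scenario cell).
#' @return an integer seed suitable for [set.seed()].
#' @export
derive_seed <- function(master, index, stream = 0L) {
  m <- 2147483647
  s <- (as.numeric(master) %% m) * 48271 + 32768 * as.numeric(stream) +
    as.numeric(index)
  as.integer(s %% m)
}

stopifnot_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1) {
    stop(sprintf("`%s` must be a single number strictly in (0, 1)", name),
         call. = FALSE)
  }
  invisible(x)
}
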