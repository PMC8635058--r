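#' Derive per-subject random seeds from one master seed
#'
#' One master seed drives a whole simulated study; each subject gets an
#' independent stream derived deterministically from it, so that a subject's
#' data do not change when the number of subjects does.
#'
#' @param seed integer master seed, or `NULL` for a non-reproducible run.
#' @param n number of streams to derive.
#' @return integer vector of `n` seeds, each in `[1, 2^31 - 2]`.
#' @export
derive_subseeds <- function(seed, n) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Hanning window
#' @param n window length in samples.
#' @return numeric vector of `n` weights in `[0, 1]`.
#' @keywords internal
hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
}

# numeric tolerance used when snapping physical units onto grid bins
.bin_eps <- 1e-9

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
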