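# Spectral analysis: zero-phase FIR filtering, Morlet wavelet power and
# event-related spectral perturbation (ERSP).
#
# The Morlet wavelet at frequency f is W(f,t) = exp(2*pi*i*f*t) *
# exp(-t^2 / (2*sigma^2)) with sigma = n / (2*pi*f), where n is the number
# of cycles. The cycles rule n = f makes sigma the constant 1/(2*pi) s at
# every frequency: fixed temporal precision, frequency-proportional
# spectral bandwidth.

#' Morlet wavelet parameters
#'
#' @param freqs frequency grid in Hz, strictly increasing within `[4, 40]`
#'   by default (1-Hz steps).
#' @param cycles cycles rule: a function of frequency or a single number;
#'   the default `function(f) f` ties the cycle count to the frequency.
#' @param times output time grid in seconds relative to stimulus onset;
#'   default 50 points at 20-ms steps covering a 0.5-s prestimulus and a
#'   0.5-s post-stimulus segment.
#' @return a `wavelet_params` list.
#' @export
wavelet_params <- function(freqs = 4:40,
                           cycles = function(f) f,
                           times = seq(-0.5, 0.48, by = 0.02)) {
  stopifnot(all(diff(freqs) > 0), all(freqs > 0))
  n <- .cycles_of(freqs, cycles)
  stopifnot(all(n > 0))
  structure(list(freqs = freqs, cycles = cycles, times = times),
            class = "wavelet_params")
}

.cycles_of <- function(f, cycles) {
  if (is.function(cycles)) cycles(f) else rep(cycles, length.out = length(f))
}

#' Temporal width of the Morlet wavelet
#'
#' `sigma = n(f) / (2 * pi * f)` seconds. Under the cycles rule `n = f`
#' this is the constant `1/(2*pi) ~ 0.159` s at every frequency.
#'
#' @param f frequency in Hz (vectorised, > 0).
#' @param cycles cycles rule as in [wavelet_params()].
#' @return Gaussian width in seconds.
#' @export
#' @examples
#' morlet_sigma(10)            # 0.159...
#' morlet_sigma(10, cycles = 7)  # 0.111...
morlet_sigma <- function(f, cycles = function(f) f) {
  if (any(f <= 0)) stop("frequency must be positive")
  .cycles_of(f, cycles) / (2 * pi * f)
}

#' Zero-phase FIR band-pass and notch filtering
#'
#' Applies a Hamming-windowed FIR band-pass (default 1-100 Hz) and a notch
#' (band-stop around 50 Hz, for power-line interference) to every trial and
#' channel, forward and backward (`filtfilt`) so that no latency distortion
#' is introduced. Each trial/channel is demeaned first.
#'
#' @param epochs an `epoch_set`.
#' @param lo,hi band-pass cut-offs in Hz; `hi` must be below Nyquist.
#' @param notch notch centre frequency in Hz, or `NULL` to skip.
#' @param notch_width half-width of the designed stop band (default 4 Hz;
#'   attenuation at the centre exceeds 40 dB).
#' @param order FIR order; default scales with the sampling rate.
#' @return the filtered `epoch_set` (same shape).
#' @export
bandpass_and_notch <- function(epochs, lo = 1, hi = 100, notch = 50,
                               notch_width = 4, order = NULL) {
  stopifnot(inherits(epochs, "epoch_set") || is.list(epochs))
  fs <- epochs$fs
  if (!(lo < hi)) stop("lo must be below hi")
  if (hi >= fs / 2) stop("upper cut-off must be below the Nyquist frequency")
  nsamp <- dim(epochs$data)[3]
  order <- order %||% min(2 * fs, floor(nsamp / 3) * 2)
  if (order %% 2 == 1) order <- order + 1
  bp <- signal::fir1(order, c(lo, hi) / (fs / 2), type = "pass")
  bs <- NULL
  if (!is.null(notch)) {
    if (notch + notch_width >= fs / 2) stop("notch band exceeds Nyquist")
    bs <- signal::fir1(order, c(notch - notch_width, notch + notch_width) /
                         (fs / 2), type = "stop")
  }
  d <- epochs$data
  for (tr in seq_len(dim(d)[1])) {
    for (ch in seq_len(dim(d)[2])) {
      x <- d[tr, ch, ]
      x <- x - mean(x)
      x <- signal::filtfilt(bp, x)
      if (!is.null(bs)) x <- signal::filtfilt(bs, x)
      d[tr, ch, ] <- x
    }
  }
  epochs$data <- d
  epochs
}

# complex Morlet wavelet sampled at fs, unit-energy normalised
.morlet_kernel <- function(f, fs, sigma) {
  half <- ceiling(4 * sigma * fs)
  t <- (-half:half) / fs
  w <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sigma^2))
  w / sqrt(sum(Mod(w)^2) / fs)
}

#' Morlet wavelet power of an epoch set
#'
#' Convolves every trial and channel with complex Morlet wavelets on the
#' parameter grid and returns squared magnitude sampled at the output time
#' grid. The output window must be at least 3 sigma away from the epoch
#' edges, otherwise convolution edge artifacts would leak in and an error
#' is raised.
#'
#' @param epochs an `epoch_set`.
#' @param params a [wavelet_params()].
#' @return a `wp_array`: trial x channel x frequency x time power array
#'   with attributes `freqs`, `times`, `channels`.
#' @export
wavelet_power <- function(epochs, params = wavelet_params()) {
  fs <- epochs$fs
  window <- epochs$window
  freqs <- params$freqs
  times <- params$times
  if (max(freqs) >= fs / 2)
    stop("top analysis frequency must be below Nyquist")
  sig <- morlet_sigma(freqs, params$cycles)
  if (min(times) - 3 * max(sig) < window[1] ||
      max(times) + 3 * max(sig) > window[2])
    stop("output time grid within 3 sigma of the epoch edge; ",
         "use longer epochs or a narrower grid")
  d <- epochs$data
  ntrial <- dim(d)[1]; nch <- dim(d)[2]; nsamp <- dim(d)[3]
  # sample indices of the output grid (stimulus onset at t = 0)
  tidx <- round((times - window[1]) * fs) + 1
  stopifnot(all(tidx >= 1), all(tidx <= nsamp))
  # batch FFT convolution: columns are trial x channel series; the inverse
  # transform is needed only at the output grid, so extraction for all
  # frequencies and grid times collapses into one complex matrix product
  x <- matrix(aperm(d, c(3, 1, 2)), nrow = nsamp)   # samp x (trial*ch)
  maxlen <- nsamp + 2 * ceiling(4 * max(sig) * fs) + 1
  nfft <- stats::nextn(maxlen, 2)
  X <- mvfft(rbind(x, matrix(0, nfft - nsamp, ncol(x))))
  nt <- length(times); nf <- length(freqs)
  G <- matrix(0i, nt * nf, nfft)
  for (i in seq_len(nf)) {
    k <- .morlet_kernel(freqs[i], fs, sig[i])
    half <- (length(k) - 1L) / 2L
    K <- fft(c(k, rep(0, nfft - length(k))))
    # row m of the inverse DFT restricted to output sample tidx + half
    E <- exp(2i * pi * outer(tidx + half - 1, 0:(nfft - 1)) / nfft)
    G[(i - 1L) * nt + seq_len(nt), ] <-
      E * matrix(K / nfft, nt, nfft, byrow = TRUE)
  }
  P <- Mod(G %*% X)^2                                # (time*freq) x (trial*ch)
  wp <- aperm(array(P, c(nt, nf, ntrial, nch)), c(3, 4, 2, 1))
  structure(wp, freqs = freqs, times = times, channels = epochs$channels,
            class = "wp_array")
}

#' Event-related spectral perturbation
#'
#' `ERSP(ch, f, t) = (WP(ch, f, t) - B(ch, f)) / B(ch, f)`, where `B` is the
#' mean wavelet power over the prestimulus baseline window, computed per
#' trial, channel and frequency. The prestimulus portion of the output
#' hovers near zero by construction, and the quantity is invariant to any
#' global rescaling of the raw signal.
#'
#' @param wp a `wp_array` from [wavelet_power()].
#' @param baseline baseline window in seconds, within the prestimulus
#'   segment; default `c(-0.5, 0)` (left-closed, right-open).
#' @param floor numerical guard: an error naming the offending channel and
#'   frequency is raised if any baseline mean falls below it.
#' @return an `ersp_array`, trial x channel x frequency x time, with
#'   attributes `freqs`, `times`, `channels`, `level = "trial"`.
#' @export
compute_ersp <- function(wp, baseline = c(-0.5, 0), floor = 1e-12) {
  times <- attr(wp, "times")
  if (baseline[1] >= baseline[2] || baseline[2] > 0)
    stop("baseline window must lie in the prestimulus segment")
  bidx <- which(times >= baseline[1] - .bin_eps & times < baseline[2])
  if (length(bidx) == 0) stop("baseline window contains no time bins")
  dm <- dim(wp)
  m <- matrix(unclass(wp), nrow = prod(dm[1:3]))     # (trial*ch*f) x time
  B <- array(rowMeans(m[, bidx, drop = FALSE]), dm[1:3])
  if (any(B < floor)) {
    bad <- which(B < floor, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "baseline power below floor at channel %s, frequency %g Hz",
      attr(wp, "channels")[bad[2]], attr(wp, "freqs")[bad[3]]))
  }
  ersp <- (unclass(wp) - as.vector(B)) / as.vector(B)
  structure(ersp, freqs = attr(wp, "freqs"), times = times,
            channels = attr(wp, "channels"), level = "trial",
            condition = "none", class = "ersp_array")
}

#' Average per-trial ERSP within a condition
#'
#' @param ersp a trial-level `ersp_array`.
#' @param labels per-trial class labels.
#' @param condition the label to average (e.g. `"HA"`).
#' @return channel x frequency x time `ersp_array` with
#'   `level = "subject_mean"`.
#' @export
average_ersp <- function(ersp, labels, condition) {
  stopifnot(length(labels) == dim(ersp)[1])
  sel <- which(labels == condition)
  if (length(sel) == 0) stop("no trials with condition ", condition)
  m <- apply(unclass(ersp)[sel, , , , drop = FALSE], c(2, 3, 4), mean)
  structure(m, freqs = attr(ersp, "freqs"), times = attr(ersp, "times"),
            channels = attr(ersp, "channels"), level = "subject_mean",
            condition = condition, class = "ersp_array")
}

#' Stack per-subject condition means into a 4-D array
#'
#' @param means list of channel x frequency x time subject-mean arrays
#'   sharing axes.
#' @return subject x channel x frequency x time array carrying the axis
#'   attributes of the first element.
#' @export
subject_mean_stack <- function(means) {
  stopifnot(length(means) >= 1)
  d <- dim(means[[1]])
  out <- array(NA_real_, dim = c(length(means), d))
  for (i in seq_along(means)) out[i, , , ] <- means[[i]]
  structure(out, freqs = attr(means[[1]], "freqs"),
            times = attr(means[[1]], "times"),
            channels = attr(means[[1]], "channels"))
}
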