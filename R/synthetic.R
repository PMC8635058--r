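# Synthetic study emulation: Necker-cube style stimulus schedules and
# multichannel stimulus-locked EEG epochs with class-dependent band-limited
# oscillatory bursts over spatially correlated 1/f background noise.

#' The eight inner-edge contrast levels of the emulated stimulus set
#' @export
default_contrasts <- function() c(0.15, 0.25, 0.4, 0.45, 0.55, 0.6, 0.75, 0.85)

#' Map inner-edge contrast to stimulus ambiguity
#'
#' The ambiguity of a two-interpretation cube stimulus is a tent function of
#' the inner-edge contrast `I`: `a = 0` at `I = 0` (unambiguously
#' left-oriented), rising linearly to `a = 100%` at `I = 0.5`, and falling
#' symmetrically back to 0 at `I = 1` (unambiguously right-oriented).
#'
#' @param I inner-edge contrast, in `[0, 1]` (vectorised).
#' @return ambiguity in percent.
#' @export
#' @examples
#' contrast_to_ambiguity(c(0.15, 0.45, 0.85))  # 30, 90, 30
contrast_to_ambiguity <- function(I) {
  if (!is.numeric(I) || any(!is.finite(I)) || any(I < 0 | I > 1))
    stop("contrast I must lie in [0, 1]")
  # round away binary representation error (e.g. 100*0.4/0.5) so that the
  # printed percent levels 30/50/80/90 are exact
  round(ifelse(I <= 0.5, 100 * I / 0.5, 100 * (1 - I) / 0.5), 10)
}

#' Generate a randomized stimulus schedule
#'
#' Builds the trial list of one recording session: `n_per_contrast`
#' presentations of each contrast level in randomized order, with uniform
#' presentation times in `[1, 1.5]` s and inter-stimulus pauses in
#' `[3, 5]` s. Ambiguities of 30% and 50% form the low-ambiguity (LA)
#' class, 80% and 90% the high-ambiguity (HA) class; with the default
#' eight contrasts this yields 100 LA and 100 HA trials, balanced 50/50
#' by cube orientation.
#'
#' @param n_per_contrast trials per contrast level (default 25).
#' @param contrasts contrast levels (default [default_contrasts()]).
#' @param seed integer seed; fixed seed gives an identical schedule.
#' @return a `stimulus_schedule` data frame with columns `trial`,
#'   `contrast_I`, `orientation`, `ambiguity_a`, `class_label`,
#'   `presentation_s`, `pause_s`.
#' @export
generate_schedule <- function(n_per_contrast = 25,
                              contrasts = default_contrasts(),
                              seed = NULL) {
  if (length(contrasts) == 0) stop("contrast list must not be empty")
  stopifnot(n_per_contrast >= 1)
  if (!is.null(seed)) set.seed(seed)
  I <- rep(contrasts, each = n_per_contrast)
  a <- contrast_to_ambiguity(I)
  if (!all(a %in% c(30, 50, 80, 90)))
    stop("contrasts must map to ambiguities 30/50/80/90% for LA/HA labelling")
  n <- length(I)
  ord <- sample.int(n)
  sched <- data.frame(
    trial = seq_len(n),
    contrast_I = I[ord],
    orientation = ifelse(I[ord] <= 0.5, "left", "right"),
    ambiguity_a = a[ord],
    class_label = ifelse(a[ord] %in% c(30, 50), "LA", "HA"),
    presentation_s = runif(n, 1.0, 1.5),
    pause_s = runif(n, 3.0, 5.0),
    stringsAsFactors = FALSE
  )
  structure(sched, class = c("stimulus_schedule", "data.frame"))
}

#' Specify a class-dependent spectral effect
#'
#' An effect is a band- and time-limited oscillatory power increase added to
#' high-ambiguity trials only, on a named set of channels: the simulation's
#' ground-truth stand-in for a real between-class ERSP difference.
#' `amplitude_gain` is the target multiplicative band-power factor during
#' the effect window (2.0 means HA band power is about twice LA band power
#' there); `jitter` gives per-subject standard deviations for random
#' perturbation of the bounds and (log-)gain, emulating between-subject
#' variability.
#'
#' @param channels character vector of montage channel names carrying the
#'   effect.
#' @param f_lo,f_hi frequency band, Hz, inside `[4, 40]`.
#' @param t_lo,t_hi post-stimulus time window, seconds, inside `[0, 0.5]`.
#' @param amplitude_gain multiplicative band-power factor (> 0).
#' @param jitter list with elements `f_sd` (Hz), `t_sd` (s), `gain_sd`
#'   (log-gain); all default 0.
#' @return an `effect_spec`.
#' @export
effect_spec <- function(channels, f_lo, f_hi, t_lo, t_hi, amplitude_gain,
                        jitter = list(f_sd = 0, t_sd = 0, gain_sd = 0)) {
  if (!(4 <= f_lo && f_lo < f_hi && f_hi <= 40))
    stop("effect frequency band must satisfy 4 <= f_lo < f_hi <= 40 Hz")
  if (!(0 <= t_lo && t_lo < t_hi && t_hi <= 0.5))
    stop("effect time window must satisfy 0 <= t_lo < t_hi <= 0.5 s")
  if (amplitude_gain <= 0) stop("amplitude_gain must be positive")
  structure(list(channels = channels, f_lo = f_lo, f_hi = f_hi,
                 t_lo = t_lo, t_hi = t_hi, amplitude_gain = amplitude_gain,
                 jitter = jitter),
            class = "effect_spec")
}

#' Default ground-truth effects of the emulated study
#'
#' Three effects loosely mimicking the reported group-level clusters: an
#' anterior theta increase (7-9 Hz, 0-0.15 s), an occipito-parietal beta
#' increase (22-24 Hz, 0.02-0.2 s) and a fronto-parietal low-gamma increase
#' (31-32 Hz, 0.35-0.42 s), each with band power roughly doubled on HA
#' trials.
#'
#' @param gain amplitude gain applied to all three effects (default 2).
#' @param jitter per-subject perturbation scales passed to [effect_spec()].
#' @return list of three `effect_spec`s.
#' @export
default_effects <- function(gain = 2,
                            jitter = list(f_sd = 0.25, t_sd = 0.01,
                                          gain_sd = 0.1)) {
  list(
    effect_spec(c("Fp1", "Fp2", "F3", "Fz", "F4"),
                7, 9, 0.00, 0.15, gain, jitter),
    effect_spec(c("P3", "Pz", "P4", "O1", "Oz", "O2"),
                22, 24, 0.02, 0.20, gain, jitter),
    effect_spec(c("Fz", "FCz", "Cz", "CPz", "Pz"),
                31, 32, 0.35, 0.42, gain, jitter)
  )
}

# Matrix of 1/f^chi noise columns with approximately unit variance.
# Spectral shaping: Fourier coefficients drawn as complex Gaussians with
# amplitude f^(-chi/2), Hermitian-symmetrised, inverse transformed.
.noise_1f <- function(n_samples, n_series, fs, chi) {
  n <- n_samples
  half <- n %/% 2
  f <- (1:half) * fs / n
  amp <- f^(-chi / 2)
  # complex spectrum: bins 1..half-1 free, Nyquist (if n even) real
  z <- matrix(complex(real = rnorm(half * n_series),
                      imaginary = rnorm(half * n_series)),
              nrow = half)
  spec <- matrix(0i, nrow = n, ncol = n_series)
  spec[2:(half + 1), ] <- z * amp
  if (n %% 2 == 0) {
    spec[half + 1, ] <- complex(real = Re(z[half, ])) * amp[half]
    spec[n:(n - half + 2), ] <- Conj(spec[2:half, , drop = FALSE])
  } else {
    spec[n:(half + 2), ] <- Conj(spec[2:(half + 1), , drop = FALSE])
  }
  x <- Re(mvfft(spec, inverse = TRUE)) / n
  # theoretical variance of the construction, used for normalisation
  if (n %% 2 == 0) {
    v <- (4 * sum(amp[1:(half - 1)]^2) + amp[half]^2) / n^2
  } else {
    v <- 4 * sum(amp^2) / n^2
  }
  x / sqrt(v)
}

# variance of the unit-variance 1/f noise restricted to [f_lo, f_hi],
# estimated from the shaping spectrum (no sampling involved)
.band_power_1f <- function(n_samples, fs, chi, f_lo, f_hi) {
  n <- n_samples
  half <- n %/% 2
  f <- (1:half) * fs / n
  amp2 <- f^(-chi)
  w <- rep(4, half)
  if (n %% 2 == 0) w[half] <- 1
  tot <- sum(w * amp2)
  inband <- f >= f_lo & f <= f_hi
  sum(w[inband] * amp2[inband]) / tot
}

#' Generate synthetic multichannel EEG epochs
#'
#' Simulates per-subject stimulus-locked epoch sets following a common
#' schedule. Each trial is spatially correlated `1/f^chi` background noise
#' (per-channel independent streams mixed with one shared stream) plus an
#' ongoing alpha-band oscillation; on HA trials, every effect in `effects`
#' additionally injects a Hanning-tapered sinusoidal burst on its channels,
#' calibrated so that band power in the effect window is multiplied by
#' approximately `amplitude_gain`. Effect bounds and gain are perturbed per
#' subject according to the effect's `jitter`. Fully reproducible: one
#' master seed deterministically derives one stream per subject.
#'
#' @param n_subjects number of subjects.
#' @param schedule a [generate_schedule()] data frame (shared by subjects).
#' @param effects list of [effect_spec()]s; use gain 1 for null data.
#' @param mtg electrode [montage()]; its channel names become the epoch
#'   channels.
#' @param fs sampling rate, Hz; must be at least twice the highest effect
#'   frequency.
#' @param window epoch window in seconds relative to stimulus onset.
#' @param noise list: `chi` (spectral exponent, default 1), `shared_mix`
#'   (variance fraction of the spatially shared stream, default 0.3),
#'   `alpha_freq`/`alpha_amp` (ongoing oscillation, default 10 Hz, 0.5).
#' @param seed master seed.
#' @return list of `epoch_set`s, one per subject: `subject_id`, `channels`,
#'   `fs`, `window`, `data` (trial x channel x sample), `labels`.
#' @export
generate_epochs <- function(n_subjects, schedule,
                            effects = default_effects(),
                            mtg = default_montage(),
                            fs = 250, window = c(-2, 2),
                            noise = list(), seed = NULL) {
  stopifnot(n_subjects >= 1, inherits(schedule, "data.frame"))
  noise <- utils::modifyList(
    list(chi = 1, shared_mix = 0.3, alpha_freq = 10, alpha_amp = 0.5), noise)
  for (e in effects) {
    if (!all(e$channels %in% mtg$name))
      stop("effect channels not present in montage: ",
           paste(setdiff(e$channels, mtg$name), collapse = ", "))
    if (e$f_hi >= fs / 2)
      stop("effect band exceeds the Nyquist frequency of fs")
  }
  nch <- nrow(mtg)
  nsamp <- round((window[2] - window[1]) * fs)
  tax <- window[1] + (seq_len(nsamp) - 1) / fs
  ntrial <- nrow(schedule)
  is_ha <- schedule$class_label == "HA"
  subseeds <- derive_subseeds(seed, n_subjects)

  lapply(seq_len(n_subjects), function(k) {
    set.seed(subseeds[k])
    # subject-level perturbation of effect parameters
    eff_k <- lapply(effects, function(e) {
      j <- utils::modifyList(list(f_sd = 0, t_sd = 0, gain_sd = 0),
                             e$jitter %||% list())
      e$f_lo <- max(4, e$f_lo + rnorm(1, 0, j$f_sd))
      e$f_hi <- max(e$f_lo + 0.1, e$f_hi + rnorm(1, 0, j$f_sd))
      e$t_lo <- min(max(0, e$t_lo + rnorm(1, 0, j$t_sd)), 0.45)
      e$t_hi <- max(e$t_lo + 0.01, min(0.5, e$t_hi + rnorm(1, 0, j$t_sd)))
      e$amplitude_gain <- e$amplitude_gain * exp(rnorm(1, 0, j$gain_sd))
      e
    })
    # background: shared + independent 1/f streams
    shared <- .noise_1f(nsamp, ntrial, fs, noise$chi)
    indep <- .noise_1f(nsamp, ntrial * nch, fs, noise$chi)
    dim(indep) <- c(nsamp, ntrial, nch)
    w_sh <- sqrt(noise$shared_mix)
    w_in <- sqrt(1 - noise$shared_mix)
    # ongoing alpha: per-trial random phase, per-channel amplitude profile
    ch_alpha <- runif(nch, 0.5, 1.5)
    phase <- runif(ntrial, 0, 2 * pi)
    data <- array(0, dim = c(ntrial, nch, nsamp))
    alpha_t <- outer(phase, 2 * pi * noise$alpha_freq * tax, `+`)  # trial x samp
    alpha_t <- sin(alpha_t) * noise$alpha_amp
    for (ch in seq_len(nch)) {
      bg <- w_sh * shared + w_in * indep[, , ch]          # samp x trial
      data[, ch, ] <- t(bg) + alpha_t * ch_alpha[ch]
    }
    # HA-only oscillatory bursts
    for (e in eff_k) {
      if (e$amplitude_gain <= 1) next
      p_band <- .band_power_1f(nsamp, fs, noise$chi, e$f_lo, e$f_hi)
      f_c <- (e$f_lo + e$f_hi) / 2
      smp <- which(tax >= e$t_lo & tax <= e$t_hi)
      if (length(smp) < 2) stop("effect time window shorter than 2 samples")
      env <- hann_window(length(smp))
      # calibrate so that mean band power over the window is multiplied by
      # amplitude_gain exactly (the Hanning taper's mean square is
      # compensated); sin^2 averages to 1/2
      amp <- sqrt(2 * (e$amplitude_gain - 1) * p_band / mean(env^2))
      chs <- match(e$channels, mtg$name)
      bphase <- runif(ntrial, 0, 2 * pi)
      burst <- amp * sweep(sin(outer(bphase[is_ha],
                                     2 * pi * f_c * tax[smp], `+`)),
                           2, env, `*`)
      for (ch in chs)
        data[is_ha, ch, smp] <- data[is_ha, ch, smp] + burst
    }
    structure(list(subject_id = k, channels = mtg$name, fs = fs,
                   window = window, data = data,
                   labels = schedule$class_label),
              class = "epoch_set")
  })
}
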