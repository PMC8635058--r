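# Shared fixtures: all test data are generated in code at run time.

# two fully connected channels, for hand-checkable clustering
toy_montage <- function() {
  montage(data.frame(name = c("A", "B"), x = c(0, 0.3), y = c(0, 0)))
}

# attach ERSP axis attributes to a subject x ch x f x t array
as_mean_stack <- function(arr, freqs, times, channels) {
  structure(arr, freqs = freqs, times = times, channels = channels)
}

# single-channel sinusoidal epoch set
sine_epochs <- function(freq = 10, amp = 1, fs = 250, dur = 4,
                        n_trials = 1, labels = rep("LA", n_trials)) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs) - dur / 2
  d <- array(rep(amp * sin(2 * pi * freq * t), each = n_trials),
             c(n_trials, 1, length(t)))
  structure(list(subject_id = 1, channels = "Cz", fs = fs,
                 window = c(-dur / 2, dur / 2), data = d, labels = labels),
            class = "epoch_set")
}

# reduced-grid study: simulate subjects, compute per-trial ERSP and
# subject-mean stacks; the workhorse of the statistical tests
reduced_study <- function(n_subjects, n_per_contrast = 25, effects,
                          fs = 100, seed = 1,
                          freqs = seq(4, 22, 2),
                          times = seq(-0.5, 0.45, by = 0.05),
                          mtg = default_montage(),
                          keep_trial_ersp = FALSE) {
  sched <- generate_schedule(n_per_contrast, seed = seed)
  subseeds <- derive_subseeds(seed, n_subjects)
  wpars <- wavelet_params(freqs = freqs, times = times)
  mh <- vector("list", n_subjects); ml <- mh; trials <- mh
  for (k in seq_len(n_subjects)) {
    ep <- generate_epochs(1, sched, effects = effects, mtg = mtg, fs = fs,
                          window = c(-1, 1), seed = subseeds[k])[[1]]
    er <- compute_ersp(wavelet_power(ep, wpars))
    mh[[k]] <- average_ersp(er, sched$class_label, "HA")
    ml[[k]] <- average_ersp(er, sched$class_label, "LA")
    if (keep_trial_ersp) trials[[k]] <- er
  }
  list(schedule = sched, ha = subject_mean_stack(mh),
       la = subject_mean_stack(ml),
       trial_ersp = if (keep_trial_ersp) trials)
}

# interval Jaccard overlap
jaccard <- function(a, b) {
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  union <- max(a[2], b[2]) - min(a[1], b[1])
  if (union <= 0) return(0)
  inter / union
}

# random per-subject topogram stacks with given labels (content-free images,
# used for structural tests where only counts and labels matter)
label_only_stacks <- function(n_subjects, labels, n_clusters = 3,
                              grid = 12, seed = 1) {
  mtg <- default_montage()
  interp <- topo_interpolator(mtg, grid)
  set.seed(seed)
  lapply(seq_len(n_subjects), function(k) {
    vals <- lapply(seq_len(n_clusters), function(ci)
      matrix(rnorm(length(labels) * nrow(mtg)), length(labels)))
    build_topogram_stack(vals, labels, interp, c(-3, 3), subject_id = k)
  })
}
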