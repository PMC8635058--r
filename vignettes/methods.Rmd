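---
title: "Statistics-guided classification of EEG scalp topograms: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistics-guided classification of EEG scalp topograms: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

A brain-computer interface that needs a long calibration session per user
is impractical. One route around calibration is a *pre-trained* decoder:
train a classifier on a representative group of subjects using features
that reflect neurophysiological processes shared across people, then apply
it to a naive user. `erspcluster` implements and tests one concrete recipe
for this idea on a two-class visual task: stimuli of low (LA) versus high
(HA) ambiguity, with class-discriminative features selected by
group-level statistics before any classifier sees the data.

The pipeline is: simulate (or load) stimulus-locked multichannel EEG
epochs; compute event-related spectral perturbation (ERSP) with Morlet
wavelets; contrast HA against LA with a paired cluster-based permutation
test over (channel, frequency, time) triplets; collapse each trial's ERSP
over each significant cluster's time-frequency box and render the
31-channel values as interpolated scalp topograms; classify the topograms
with a small CNN under leave-one-subject-out (LOSO) cross-validation; and
quantify how stable the selected cluster bounds are when single subjects
are excluded from feature extraction.

# The stimulus model

A Necker-cube style stimulus is parameterised by the inner-edge contrast
$I \in [0, 1]$. Ambiguity is the tent function

$$a(I) = \begin{cases}100\,I/0.5 & I \le 0.5\\ 100\,(1 - I)/0.5 & I > 0.5\end{cases}$$

so $a = 0$ at $I \in \{0, 1\}$ (unambiguous) and $a = 100\%$ at $I = 0.5$.
The emulated session uses the eight contrasts
$I \in \{0.15, 0.25, 0.4, 0.45, 0.55, 0.6, 0.75, 0.85\}$, which map to
ambiguities 30, 50, 80, 90, 90, 80, 50, 30 percent; $a \in \{30, 50\}$
forms the LA class, $a \in \{80, 90\}$ the HA class. With 25 trials per
contrast this yields 100 LA and 100 HA trials, balanced across the two
cube orientations. Presentation times are uniform on $[1, 1.5]$ s and
pauses on $[3, 5]$ s, randomized.

# The synthetic EEG generator

`generate_epochs()` emulates the *structure* of the recorded data, not its
biology. Each 4-s stimulus-locked trial (2 s pre, 2 s post at 250 Hz by
default; the sampling rate is a convention, not a recorded fact) is:

* $1/f^{\chi}$ background noise with $\chi = 1$, per-channel independent
  streams mixed with one spatially shared stream (variance fraction 0.3).
  The shared component gives the spatial correlation that sensor-space
  cluster tests rely on.
* an ongoing alpha-band oscillation (10 Hz, amplitude 0.5, random phase
  per trial, random amplitude profile across channels) common to both
  classes.
* on HA trials only, one Hanning-tapered sinusoidal burst per effect
  specification, at the band centre, on the effect's channels. The burst
  amplitude is calibrated against the analytic band power of the noise
  spectrum (compensating the taper's mean square) so that band power in
  the effect window is multiplied by `amplitude_gain` exactly, on
  average. Per subject, the band edges, window edges and log-gain are
  jittered (SDs 0.25 Hz, 0.01 s, 0.1) to emulate between-subject
  variability.

The default ground truth is three effects mimicking the group-level
clusters such a study reports: anterior theta (7–9 Hz, 0–0.15 s),
occipito-parietal beta (22–24 Hz, 0.02–0.2 s), and fronto-parietal
low-gamma (31–32 Hz, 0.35–0.42 s), each with gain 2. One master seed
derives one independent stream per subject, so a subject's data are
invariant to the total subject count.

What the generator does *not* emulate: eye-blink or muscle artifacts (so
no ICA stage is needed or provided), behavioural responses, non-stationary
background statistics, and volume-conduction-realistic topographies.
Passing tests on this data therefore validate the *pipeline's statistics
and plumbing* — calibration of the cluster test, recovery of injected
effects, absence of leakage — not the neurophysiological claims
themselves.

# ERSP

Wavelet power is the squared magnitude of the convolution with the
complex Morlet wavelet $W(f,t) = e^{2i\pi f t}\, e^{-t^2/2\sigma^2}$,
$\sigma = n/(2\pi f)$. The cycles rule is $n = f$, taken literally: it
makes $\sigma \equiv 1/(2\pi) \approx 0.159$ s at every frequency —
constant temporal precision with frequency-proportional spectral
bandwidth. The rule is pluggable (`wavelet_params(cycles =)`) for users
who prefer a conventional 3–7-cycle scheme. Wavelets are unit-energy
normalised; the normalisation cancels in ERSP anyway.

ERSP is the relative change against the prestimulus baseline,

$$\mathrm{ERSP}(ch, f, t) = \frac{WP(ch,f,t) - B(ch,f)}{B(ch,f)},$$

where $B$ is the *time-mean* of prestimulus power per channel and
frequency, computed per trial over the window $[-0.5, 0)$ s. Pointwise
pre/post pairing has no natural alignment, so the time-mean baseline (the
standard ERSP convention) is used. A configurable floor guards against
division by near-zero baselines and names the offending channel and
frequency.

Two numerical properties matter downstream. First, per-trial power ratios
are heavy-tailed: the mean of $X/B$ exceeds 1 even for stationary data
(Jensen's inequality), which inflates single-condition trial-mean ERSP at
times far from the baseline window. The inflation is identical for both
classes, so the paired HA−LA contrast is unaffected — but it is why the
pipeline contrasts conditions rather than interpreting raw ERSP
magnitudes, and why stable subject means need on the order of 100 trials
per class. Second, with $\sigma \approx 0.159$ s the wavelet smears any
effect shorter than ~0.3 s and dilutes its apparent gain; recovered time
bounds are correspondingly wider than the generating window. Grids:
1-Hz steps over 4–40 Hz and 20-ms steps over $[-0.5, 0.48]$ s by default
(50 time points: 25 pre, 25 post), keeping the triplet space at
$31 \times 37 \times 25$ for statistics; reduced studies use coarser,
configurable grids.

Filtering (`bandpass_and_notch`) is a zero-phase (forward–backward)
Hamming FIR band-pass at 1–100 Hz plus a band-stop around 50 Hz
(> 40 dB at the line frequency), applied per trial and channel after
demeaning. Zero-phase application avoids latency distortion of the
cluster time bounds.

# The cluster-based permutation contrast

At each (channel, frequency, time) triplet of the post-stimulus window
$[0, 0.5]$ s, a paired t statistic compares subject-mean HA and LA ERSP
($t = \bar d / (s_d/\sqrt N)$ on within-subject differences,
$df = N - 1$; zero-variance triplets get $t = 0$ with a warning).
Triplets with $|t|$ above the two-tailed Student threshold at
$\alpha = 0.01$ survive only if at least 2 of their spatial channel
neighbours (same frequency/time bin) are suprathreshold with the same
sign — the standard minimum-neighbour criterion, configurable and
disabled at 0. Survivors are grouped into sign-separated connected
components under channel adjacency plus ±1-bin frequency and time
adjacency; diagonal (multi-axis) steps do not connect. Each cluster is
scored by its summed rectified t ("mass"); bounds $[f_1, f_2]$ and
$[t_1, t_2]$ are member minima/maxima mapped to axis units.

Channel adjacency comes from the projected montage: channels within 0.45
projected-head-radius units are neighbours, giving a median degree of 4
on the default 31-channel layout — in the 4–6 range typical of
sensor-space templates. Bounds depend on this graph, so the graph is an
explicit argument everywhere.

The null distribution is the per-polarity maximum cluster mass under
subject-level sign flips of the within-subject difference: the
exchangeable units in a paired design are subjects, not trials. Each of
the 2000 default permutations re-thresholds and re-clusters with
identical settings. P-values use the $+1$ tie-corrected estimator
$p = (1 + \#\{\text{null} \ge \text{mass}\})/(1 + n_{perm})$, so $p > 0$
always and the observed labelling (an identity flip) is implicitly its
own null member. Clusters are significant at $p < 0.025$ per tail
(two-tailed familywise 0.05). For $N \le 20$ the full $2^N$ sign-flip set
can be enumerated (`exhaustive = TRUE`); the test suite checks that
Monte-Carlo p-values converge to the exhaustive ones and that the
familywise positive rate on null data stays within its nominal level.
Both polarities are always computed and reported, whether or not negative
clusters occur.

A technical speed note: across permutations only the difference mean
changes, while $\sum_i d_i^2$ per triplet is sign-invariant, so all
permutation t-maps are obtained from one matrix product plus sufficient
statistics; re-clustering runs only on suprathreshold survivors.

# Topograms

For every trial and every significant cluster, ERSP is averaged over the
cluster's $[f_1, f_2] \times [t_1, t_2]$ box for *all* 31 channels (not
only cluster members — the spatial pattern is the feature). The channel
vector is interpolated over the unit head disc by thin-plate-spline
radial basis interpolation ($U(r) = r^2 \log r$ with affine terms):
smooth, exact at the electrodes, and linear in the values, so the whole
renderer is one precomputed (pixels × channels) operator. Pixels outside
the disc are background. Colour limits are symmetric about zero at the
98th percentile of pooled absolute cluster-averaged ERSP, fixed once per
run: per-image normalisation would destroy the class-informative
intensity scale. Images are single-channel (a colormap adds no
information), rendered on a 64-grid by default and bilinearly rescaled to
the configured CNN input size (224 for full-scale replication). The
per-image / global colour-scale question is a configuration choice; the
global default is the one a classifier needs.

# Classification

LOSO: each fold trains on all images of all subjects but one (with the
full design, 19 × 600 = 11,400 images) and tests on the 600 images of the
held-out subject, so the network never sees the test subject. The default
network is a deliberately small CNN — two strided convolution + ReLU
blocks (8 and 16 filters) and a dense softmax head — trained with Adam on
cross-entropy, implemented directly in R matrix algebra with im2col
convolutions. Training is deterministic for a fixed seed; early stopping
monitors a held-out slice of the *training* images (never the test
subject). A ResNet-scale backbone is out of scope at desk scale: the
claim under test is the feature-selection pipeline, not the backbone.
Epochs, learning rate and batch size are configuration with documented
defaults (30, 2e-3, 32); none are stated facts of the emulated study.

HA is the positive class (LA = 0, HA = 1) — precision and recall are
ambiguous otherwise. Image-level metrics are primary (matching the
600-images-per-subject design); trial-level fusion (mean HA probability
over a trial's cluster images) is reported alongside as a clearly
labelled extension. An image-id check asserts that no test image occurred
in training.

# Stability of the selected features

Leaving out one subject and re-running the whole contrast with identical
settings yields per-cluster individual bounds. A leave-one-out cluster is
matched to a common (all-subject) cluster by maximal time-frequency box
overlap within the same polarity — the matching rule is a design choice;
overlap is the only observable linkage. Unmatched clusters are recorded
absent, never imputed. Bound changes are

$$\Delta f_i = \frac{|(f_i^1)_{ind} - (f_i^1)_{com}| + |(f_i^2)_{ind} - (f_i^2)_{com}|}{2\,[(f_i^2)_{com} - (f_i^1)_{com}]} \times 100\%$$

and the same form in time: non-negative, zero iff the intervals
coincide, scale-covariant, and normalised by twice the common width.
Classification accuracy is then regressed on the per-cluster deltas by
ordinary least squares over complete cases (subjects missing a cluster
are excluded, as are clusters absent from most leave-one-out runs).
Accuracy is the *response* and the deltas are predictors; the
repeated-measures ANOVA layer such studies also report is out of scope
here — standard off-the-shelf statistics, not part of the method.

# Problem sizes used by the tests and scripts

The packaged analysis scripts and the statistical acceptance tests run a
reduced emulation chosen to exercise every stage in minutes on one CPU;
these are the package's own desk-scale choices:

* analysis scripts: 12 subjects × 200 trials, 31 channels, fs = 100 Hz,
  2-s epochs, 4–34 Hz at 2 Hz, 20 time bins, 500 permutations, 32×32
  topograms, gain 4 for a clearly recoverable demonstration.
* null calibration: 200 datasets, 8 subjects, 8 channels × 10
  frequencies × 10 post-stimulus times, 20 trials per class, gain 1, 500
  permutations.
* effect recovery: 20 runs, 12 subjects, 100 trials per class, one
  effect at 8–16 Hz × 0.05–0.40 s, gain 2.5. The box is deliberately
  sized commensurate with the analysis resolution: with $\sigma
  \approx 0.159$ s, a much narrower window cannot be recovered at
  interval-Jaccard 0.5 by any implementation of this analysis.
* classifier check: 6 subjects × 40 trials, one high-gain effect
  (gain 4), 64×64 images, plus a shuffled-label control.

The full-scale emulation (20 subjects, 100 trials per class, 4–40 Hz,
2000 permutations, 224×224 images) runs through the same
`run_pipeline()` entry point.

# Known limitations

* The synthetic background is stationary Gaussian $1/f$; real EEG has
  artifacts, non-stationarity and richer spatial structure. Results on
  synthetic data bound what the code does, not what real data would show.
* Burst effects are sinusoidal at the band centre; a distributed band
  effect would spread energy differently across the wavelet grid.
* The $n = f$ cycles rule makes temporal resolution constant but
  frequency resolution proportional to $f$; narrow high-frequency
  structure is easy to over-smooth in time and under-smooth in frequency
  relative to conventional rules.
* Recovered cluster bounds inherit the analysis grid and the smoothing
  scale; Jaccard agreement with generating boxes, not equality, is the
  right expectation.
* Per-trial ERSP ratios are heavy-tailed; with few trials per class the
  subject means are noisy and weak narrow effects drop below the cluster
  threshold (visible in the demo scripts, where the narrow anterior theta
  effect is not always recovered at desk scale).
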