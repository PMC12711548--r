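---
title: "Methods: band-specific EEG connectivity under respiratory paradigms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: band-specific EEG connectivity under respiratory paradigms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(breathnet)
```

# The analysis problem

Respiratory manoeuvres — breathing at one's own pace (SB), holding the
breath at end-inspiration (BH), pacing the breath to a 0.20 Hz metronome
(PB) — modulate cortical oscillations in a band-specific way. The analysis
implemented here quantifies that modulation from multichannel scalp EEG in
four steps: band-resolved spectral power, phase-locking-value (PLV)
connectivity, weighted graph metrics on the resulting networks, and two
inferential layers (condition contrasts and an FVC covariate analysis),
with a classification stage asking whether the connectivity pattern alone
identifies the respiratory state.

The experimental unit is a single continuous 330-s run per subject holding
all three conditions: 50 s of breathing, then four cycles of 20 s
breath-hold followed by 50 s of breathing, the breathing blocks alternating
between self-paced and computer-paced (`defaultParadigm()`: SB, BH, PB, BH,
SB, BH, PB, BH, SB). Whether the paced and self-paced breathing belong to
one run or to separate runs is a genuinely open design point for this kind
of paradigm; the block table is fully configurable, so either layout can be
expressed, and the single-run default merely keeps each synthetic subject
self-contained.

# The synthetic cohort generator

Because recordings from such protocols are rarely deposited, the package
treats the generator as a first-class, tested component: every downstream
stage is validated against cohorts whose coupling structure is known
exactly.

## Signal model

For each band $b$ with range $[f_{lo}, f_{hi})$ a *shared* oscillator phase
$\Theta_b(t)$ evolves as a random-frequency walk: the instantaneous
frequency is an AR(1) process centred on the band midpoint with a 0.5-s
time constant, clipped to the band interior, and integrated. Each channel
$i$ additionally carries an independent *private* oscillator $\Psi_{ib}(t)$
with the same law. The channel phase is the argument of the circular
mixture

$$\varphi_{ib}(t) = \arg\!\left(\sqrt{\lambda_i}\, e^{i\Theta_b(t)} +
\sqrt{1-\lambda_i}\, e^{i\Psi_{ib}(t)}\right),$$

and the signal is $x_i(t) = \sum_b a_b \cos \varphi_{ib}(t) + \varepsilon$,
with band amplitudes $a_b$ in µV and white sensor noise. A mixture of two
narrowband phasors was chosen over a Kuramoto-style coupled integration
because it is cheaper, trivially deterministic under a seed, and gives a
*monotone* mapping from the coupling parameter to the measured PLV with the
exact endpoints: $\lambda = 1$ collapses both channels onto the shared
phase (PLV $= 1$ identically) and $\lambda = 0$ leaves fully independent
oscillators (PLV at the narrowband Rayleigh-null floor).

The pairwise coupling matrix $\kappa \in [0,1]^{16\times16}$ of a
`CouplingSpec` is realised through per-channel loadings
$\lambda_i = \sqrt{\max_j \kappa_{ij}}$, so a pair's effective coupling is
$\lambda_i \lambda_j$. This rank-one factorisation is exact for uniform and
block-constant $\kappa$ — the regimes the defaults use — and an upper
envelope otherwise (a channel coupled strongly to one partner is mildly
coupled to every other non-isolated channel). The empirical
$\kappa \to$ PLV calibration is monotone but deliberately *not* assumed to
be the identity anywhere in the package; the monotonicity property is
asserted over the grid $\kappa \in \{0, 0.25, 0.5, 0.75, 1\}$ with 20 seeds
per point in the test suite.

## Defaults and their rationale

The default condition effects give the inference stages signed ground
truth in the directions such paradigms are reported to produce: low-frequency
(δ/θ) coupling among the six frontal channels is strongest under SB
(κ 0.6/0.5 vs 0.3 under BH), while broad α/β coupling is strongest under BH
(0.55/0.50) and weakest under PB (0.30/0.25), with a 0.15 background
everywhere. Band amplitudes default to 20/10/15/8 µV for δ/θ/α/β and the
sensor noise to 2 µV — amplitude ratios a practitioner would call ordinary
for eyes-open scalp EEG. The optional private phase jitter (rad/√sample,
default 0) is scaled by $1-\lambda_i$ so that perfect coupling remains
exactly phase-locked.

## The FVC covariate

`generateCohort()` can plant an association between FVC and one (edge,
band, condition): the subject-level coupling at that edge is
$\kappa_0 + 0.1\,z_s$ (clipped to $[0.02, 0.98]$) and FVC is
$\mu_F + r\,\sigma_F z_s + \sigma_F\sqrt{1-r^2}\,e_s$ with independent
standard normals, so the *population* correlation between FVC and the
latent coupling equals the target $r$ by construction. Defaults
$\mu_F = 4.0$ L, $\sigma_F = 0.8$ L sit in the normal adult range for
forced vital capacity. The calibration is verified in the suite: across 500
replicate 35-subject cohorts the mean empirical correlation lies within
±0.05 of the 0.5 target.

What the generator does *not* emulate: ocular and muscle artifacts (the
channel-rejection rule is exercised with constructed spike patterns
instead), volume conduction and shared-reference effects, respiration-locked
infra-slow potentials, 1/f background spectra, and non-stationarity within
a block. Passing tests therefore demonstrate the correctness and
recovery behaviour of the *pipeline*, not robustness to every artifact of
real scalp data — real recordings are expected to arrive already
ICA-cleaned.

# Preprocessing

- **Filtering.** Zero-phase (forward–backward) Butterworth band-pass,
  order 4 per pass; the family and order are a package choice, recorded in
  the provenance. A consequence worth knowing: the broadband 1–45 Hz filter
  attenuates a 50 Hz tone only to about 20 % amplitude (the squared
  magnitude response of an order-4 Butterworth 5 Hz past its edge), so
  mains interference should be handled upstream if present; the test suite
  checks the realised attenuation against the filter's own frequency
  response rather than a wishful round number.
- **Band decomposition** uses lower-inclusive, upper-exclusive edges
  (δ [1,4), θ [4,8), α [8,13), β [13,30)) so the four bands partition
  1–30 Hz despite the conventionally shared printed endpoints; γ (31–45 Hz)
  is excluded by default as residual-EMG territory. Band filtering is
  applied to the *full* recording before segmentation so block-interior
  samples carry no per-segment filter transients; the suite verifies
  filter/segment commutation on interior samples.
- **Channel rejection** tiles the recording into non-overlapping 2-s epochs
  (length configurable; the rule's epoch size is not dictated by anything
  physical) and drops a channel when the share of epochs containing any
  sample beyond ±100 µV strictly exceeds 20 %. No interpolation — the
  montage simply shrinks, and every downstream stage works on the surviving
  channel set.
- **Baseline correction** subtracts the per-channel mean over the
  (−200, 0] ms window anchored at block onset — with a 500 Hz sampling rate,
  exactly 100 samples. The anchoring event is a design decision (block
  onset); for the first block of a run there is no pre-onset context, and
  the window falls back to the first 200 ms of the block itself, flagged in
  the provenance.

Annotations are 0-based, half-open sample intervals throughout.

# Spectral estimation

Welch's averaged modified periodogram with a 128-sample Hamming window,
50 % overlap and zero-padding to 256 points. At 500 Hz this grid has a step
of 500/256 ≈ 1.95 Hz — *not* 1 Hz, whatever the window parameters may
suggest at first glance; the δ band then holds exactly the 1.95 and 3.91 Hz
bins. One-sided density scaling is used so the integral of the PSD over
frequency estimates the variance (verified to 5 % on white noise), and the
single full-length rectangular-window case degenerates exactly to the raw
periodogram (verified against a direct DFT oracle). Band power is the
*mean* over in-band bins (not the integral), matching the mean-PSD
convention; power is averaged across epochs first and log₁₀-transformed
afterwards — the opposite order is a defensible alternative, but averaging
before the log keeps the estimate unbiased for the mean power.

# Connectivity

Instantaneous phases come from the FFT-based analytic signal; constant
channels are rejected since their phase is undefined. The PLV of a pair is
the modulus of the time-averaged unit phasor of the phase difference.
Per condition and band, PLV matrices are computed per segment and averaged
arithmetically across segments (epoch averaging, not pooled-sample PLV —
pooling would conflate within-epoch locking with between-epoch phase
drift). The first and last 5 % of each segment's phase series are discarded
to suppress Hilbert edge effects (configurable). The diagonal is 1 by
definition and excluded from every statistic. No volume-conduction
correction (e.g. imaginary PLV or wPLI) is applied — zero-lag spurious
coupling is a known limitation of sensor-space PLV and is left to the
user's interpretation.

# Network metrics

All metrics operate on the unthresholded weighted matrix (diagonal
removed):

- **CC** — Onnela's geometric-mean triplet form with weights normalised by
  the global maximum, which realises the geometric-mean formula with a
  bounded [0, 1] range; nodes with fewer than two neighbours contribute 0.
- **GE/LE** — weights map to lengths as $1/w$ by default ($1-w$ available),
  shortest paths by Dijkstra (igraph), and the default efficiency is the
  Latora–Marchiori mean of inverse distances, which handles disconnected
  pairs gracefully (they contribute 0). The literal
  inverse-of-the-average-path-length reading is available via
  `variant = "inverse_mean"` because the verbal definition of global
  efficiency is genuinely ambiguous between the two.
- **DC** — mean node strength.

Everything is cross-checked against exhaustive-triplet and Floyd–Warshall
oracles on random graphs up to n = 8 at 10⁻¹² tolerance, and the exact
scale laws (CC invariant, DC and GE linear under weight scaling) are
asserted. `densitySweep()` adds the robustness utility: strongest-edge
thresholding at 10–40 % density with weight-shuffle surrogates that
preserve topology and the weight multiset, reported as z-scores.

# Group statistics

Contrasts default to two-sample pooled-variance t-tests per feature,
matching the original between-block analysis design even though the
conditions are within-subject; a paired mode exists and is the better
choice when subjects are complete, which the documentation recommends.
Family-wise error control defaults to max-T permutation (5000 label
permutations, seeded; sign-flips in paired mode) with Bonferroni behind a
flag — permutation is preferred because EEG feature maps are strongly
correlated and Bonferroni is needlessly conservative there. Features with
zero variance in both groups yield t = 0 (p = 1) when the means agree and a
warning otherwise.

The FVC analysis computes Pearson correlations per edge and condition and
applies Benjamini–Hochberg across the whole family at α = 0.01. Two family
conventions are supported: the full-matrix convention (256 entries × 3
conditions = 768 tests, duplicated pairs and constant diagonal included,
the latter excluded from the ranking as NA), which reproduces the
vectorisation arithmetic used in practice, and the statistically cleaner
unique-pair convention (120 × 3). A power consideration the test suite
measures directly: a *single* edge whose population correlation with FVC is
0.5 in a 35-subject cohort has a raw p around 2 × 10⁻³, while surviving BH
at α = 0.01 among 768 mostly-null tests effectively requires p below
~10⁻⁵; the measured detection rate across 500 replicate cohorts is
accordingly near 10 %, not a comfortable majority. Detecting such an
association reliably at this α and family size needs either several
correlated true edges, a larger cohort, or a smaller family.

# Classification

One band at a time, the 120 unique edges per subject × condition form the
feature matrix (three rows per subject). ReliefF (k = 10 neighbours,
Manhattan distance on range-normalised features, all instances visited so
the ranking is deterministic) retains the top 30 edges, which feed a dense
30→64→32→3 network: ReLU activations, 30 % inverted dropout after each
hidden layer, softmax cross-entropy with L2 penalty 0.001, Adam at 0.001,
batch 16, 200 epochs, all seeded. Evaluation is 10-fold stratified
cross-validation repeated 10 times, reporting mean accuracy and Cohen's κ.

Two protocol choices deserve explicit flags:

- **Leakage.** Running feature selection once on all data before
  cross-validation leaks test information into the ranking and inflates
  accuracy. The default here fits ReliefF and the feature standardisation
  inside each training fold; `selectBeforeSplit = TRUE` reproduces the
  select-then-split protocol for comparability.
- **Subject grouping.** With three rows per subject, folds that split a
  subject's rows across train and test leak subject identity. The default
  does not enforce grouping (matching the common protocol); `groups =`
  assigns whole subjects to folds.

The ReliefF neighbour count interacts with cohort size: k neighbours
require k + 1 same-class training instances, so desk-scale cohorts (the
acceptance suite uses 12 subjects, 36 rows) run with k = 5. An optional
radial-kernel SVM baseline (`svmBaseline()`, via e1071) is provided as an
independent reference classifier.

# Numerical choices and degenerate inputs

- Graph oracle tolerance 10⁻¹²; PLV matrices are symmetrised
  (`(M + Mᵀ)/2`) and clipped to [0, 1] against round-off.
- Hilbert edge trim 5 % per segment end; Welch requires at least one full
  window; empty bands (no grid bins) are an error rather than a silent 0.
- All-rejected channel sets, missing conditions, constant channels,
  constant FVC, empty p-value vectors and degenerate confusion matrices
  raise informative errors; zero-variance features in contrasts are the
  only soft case (warning + signed infinity).
- Every stochastic component (generator, permutations, surrogates, fold
  assignment, dropout) consumes an explicit integer seed; reruns are
  bit-identical, which the suite asserts at recording, pipeline-manifest
  and classifier levels.

# Problem sizes in the test suite

The suite favours many small, seeded simulations over few large ones:
recovery and calibration checks run on 8–30-s single-band recordings or
12-subject cohorts; error-control checks use 1000 null cohorts at the
feature level (12 × 30 with 199 permutations each) and 400–500 null or
planted correlation cohorts at n = 35; the full default test run completes
in under two minutes on one core. The acceptance script regenerates its
inputs from scratch at each invocation from the `--seed` argument.

# Known limitations

Sensor-space PLV with no volume-conduction correction; rank-one realisation
of general coupling matrices (exact only for uniform/block structure); no
artifact model in the generator; EDF ingestion is not implemented — the
delimited-matrix + YAML-sidecar format is the interchange path; the
literal inverse-mean-path global efficiency is undefined on fully
disconnected graphs (returned as 0); and the classification stage models
only the three-condition label, not within-condition depth or rate of
breathing.
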