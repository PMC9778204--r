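---
title: "Multiscale entropy and wavelet-leader features for ECG classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale entropy and wavelet-leader features for ECG classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfecg)
```

## The problem

Congestive heart failure (CHF) alters the beat-to-beat dynamics of the
electrocardiogram: compared with normal sinus rhythm (NSR), the CHF
signal is *more regular* — its fluctuations carry less structure across
time scales. `mfecg` turns that observation into a classifier. From
each fixed-duration ECG segment it extracts complexity descriptors of
two complementary kinds — generalized multiscale sample entropy and
wavelet-leader multifractal singularity indices — and feeds them to an
extreme learning machine (ELM). No R-peak detection is required at any
point: every feature is computed directly from the raw (denoised)
waveform, which makes the method robust to QRS-detection failures and
usable on short records.

## Pre-processing

Records are cut into non-overlapping segments of `t = 64` s (8192
samples at 128 Hz, 16000 at 250 Hz; the two PhysioNet databases the
method targets keep their native rates and equal durations). Shorter
segmentations down to `t = N/fs = 256/128 = 2` s are possible in
principle, but below ~32 s the entropy estimator increasingly returns
undefined values, so 64 s is the default.

Denoising is an 8-level wavelet decomposition with the symmetric
biorthogonal `bior2.6` filter pair. We use the *undecimated* (MODWT)
form of the transform rather than a decimated pyramid: it is
shift-invariant, reconstructs exactly for any segment length (a
decimated 8-level pyramid requires the length to be divisible by
2^8 = 256, which the 16000-sample segments are not), and is the form
most ECG-denoising practice uses. The subband recipe is:

* the coarsest smooth (level-8 approximation, below ~0.25 Hz at
  128 Hz) is dropped entirely — this removes baseline wander;
* the two finest detail bands are soft-thresholded with the universal
  threshold $\sigma\sqrt{2\ln N}$, with $\sigma$ estimated as
  `median(|W1|)/0.6745` from the finest band — this suppresses
  high-frequency noise while leaving QRS-scale bands untouched.

Denoising requires more than 256 samples; it preserves segment length,
removes a constant signal completely, and is idempotent to within a
few percent RMS (both properties are tested).

## Generalized multiscale sample entropy

For a series $x_1,\dots,x_N$ and scale $s$, coarse-graining replaces
each non-overlapping block of $s$ samples by a block statistic: the
mean (first moment, `MSEN1`) or the unbiased variance (second moment,
`MSEN2`). Sample entropy of the coarse-grained series
$y_1,\dots,y_{N_s}$, $N_s = \lfloor N/s \rfloor$, is

$$\mathrm{SampEn}(m, r, s) = -\ln\frac{A^{m+1}(r)}{A^m(r)},$$

where $A^m(r)$ is the average fraction of template pairs of length $m$
within Chebyshev distance $r$ (self-matches excluded). The counting
convention follows the algorithm as printed: order-$m$ probabilities
are averaged over $N_s-m+1$ template origins with denominator
$N_s-m+1$, order-$m+1$ over $N_s-m$ origins with denominator $N_s-m$.
A side effect of these slightly mismatched denominators is that a
constant series yields an entropy of order $10^{-6}$ rather than an
exact 0; tests assert near-zero accordingly.

Parameters and defaults:

* `m = 2` (embedding dimension) — the standard choice; larger `m`
  needs longer series.
* `r = 0.15 sigma`, where **sigma is recomputed from each
  coarse-grained series**. This is a deliberate departure from classic
  multiscale entropy, which fixes `r` from the original series. The
  consequence matters: under the per-scale tolerance, coarse-graining
  of uncorrelated noise no longer reduces entropy (the tolerance
  shrinks along with the variance), so white noise has a nearly flat
  profile instead of the familiar decay, and 1/f noise sits *below*
  white noise at every scale. The classic fixed-tolerance behavior is
  available via `mse_profile(..., r_mode = "fixed")`.
* Feature window: scales 10–20. The classifier feature is the mean of
  the defined entropies over that window, per moment. Undefined
  entropies (zero match counts, the estimator's failure mode on short
  or over-coarse series) are kept as `NA`, counted, and never imputed
  with 0; a feature is itself undefined when more than half its window
  is undefined, and such segments are dropped from training with a
  logged count.

The O(N^2) template counting is implemented in C++; a brute-force R
double-loop oracle checks it to 1e-12 across random series, including
the undefined cases.

## Wavelet-leader multifractal analysis

Detail coefficients $d_X(j,k)$ are computed by a decimated `db3`
pyramid (3 vanishing moments, so polynomial trends up to quadratic are
annihilated) with half-point symmetric extension, and stored with the
L1 normalization $2^{-j/2}$ relative to the orthonormal transform, so
that a local Hölder exponent $h$ manifests as $d \sim 2^{jh}$.
Boundary-affected coefficients are retained by default. The wavelet
leader

$$L_X(j,k) = \sup_{\lambda' \subset 3\lambda_{j,k}} |d_{X,\lambda'}|$$

is the largest coefficient magnitude at any octave $j' \le j$ located
within the cell $(j,k)$ or its two neighbors (out-of-range neighbors
are simply omitted at array edges). Structure functions
$S_L(j,q) = n_j^{-1}\sum_k L_X(j,k)^q$ behave as $2^{j\zeta(q)}$, and
$\zeta(q)$ is estimated as the unweighted OLS slope of
$\log_2 S_L(j,q)$ on $j$ over octaves $j_1..j_2$, with
$j_2 = \lfloor \log_2(N/(2N_\psi+1)) \rfloor$ (10 for $N = 8192$ with
`db3`) and $j_1 = 1$ for the ECG pipeline. Exactly-zero leaders (flat
signal stretches) are excluded from the sums at $q<0$ and floored at
1e-300 otherwise, with a logged count.

Two spectrum estimators are provided:

* **Legendre**: $\alpha(q) = d\zeta/dq$ by central differences on the
  uniform $q$ grid (one-sided at the ends), and
  $f(\alpha) = q\alpha - \zeta(q) + 1$.
* **Direct (weighted-moment)**: canonical weights
  $P_{j,k}^{(q)} = L^q(j,k)/\sum_k L^q(j,k)$; $\alpha(q)$ is the slope
  over octaves of $\sum_k P\log_2 L$ and $f(\alpha(q))$ is **one
  plus** the slope of $\sum_k P\log_2 P + \log_2 n_j$. The $+1$ offset
  is calibrated on the analytic uniform-leader case: with all leaders
  equal at an octave the entropy term exactly cancels $\log_2 n_j$,
  the slope is 0, and $f$ must equal 1 (the support dimension).

The $q$ grid is symmetric, $-q_{\max}..q_{\max}$ in steps of
$\Delta q = 0.25$ with $q_{\max} = 5$; the symmetric extension is what
makes the right endpoint $\alpha_{\max} = \alpha(-q_{\max})$
estimable. The classifier uses two singularity indices:
$\alpha_{\min} = \alpha(+q_{\max})$ (strength of the largest
fluctuations) and $\alpha_0 = \alpha(0)$ (the spectrum apex, the most
probable exponent). The spectrum width
$\Delta\alpha = \alpha_{\max}-\alpha_{\min}$ and the uniform Hölder
bounds $h_{\min}, h_{\max}$ (regression slopes of the per-octave
$\log_2$ max/min coefficient) complete the summary; the wavelet is
adequate for the data when $h_{\max} < \min(r_\psi, N_\psi)$ strictly.

### Estimator settings for the validation fixtures

Two fixture-specific settings deserve explanation, because the package
uses them in its own validation rather than the ECG defaults:

* **Binomial cascade**: the cascade measure lives on an exactly dyadic
  grid, and the `db1` (Haar) filter is the one whose analysis cells
  coincide with that grid. With `db3` the first few octaves carry a
  large initialization bias (the discrete samples of a singular
  measure are a poor stand-in for its scaling-function projection — a
  bias we verified is shared by an independent reference DWT
  implementation), and the last octaves are contaminated by the
  reflection boundary. Analyzing the cascade with `db1` over octaves
  3..12 recovers $\zeta(q)$ within ±0.03 of the closed form
  $1-\log_2(p^q + (1-p)^q)$ over $q \in [-2,5]$; `db3` from octave 1
  leaves errors an order of magnitude larger. The ECG pipeline keeps
  `db3` (ECG is not dyadically aligned and benefits from the extra
  vanishing moments).
* **Hölder bounds on fBm**: per-octave maxima of Gaussian coefficient
  arrays carry an extreme-value factor $\sqrt{2\ln n_j}$ whose drift
  with $j$ biases the $h_{\min}$ regression. The drift is steepest at
  the very fine (large $n_j$) and very coarse (tiny $n_j$) octaves, so
  the fBm validation regresses over mid octaves 3–8.

## Extreme learning machine

The classifier is a single-hidden-layer feedforward network whose
input weights and biases are drawn once from Uniform[-1, 1] under a
caller-supplied seed and never trained; with hidden representation
$H = g(XW + b)$ (logistic sigmoid) the output weights solve the
least-squares problem $\beta = H^+ T$ via SVD pseudoinverse (relative
cutoff 1e-12), with one-hot targets $T$ and argmax decisions (ties to
the lower class index). Features are z-scored with training-fold
statistics before the random projection — an addition to the bare
algorithm, made because raw entropy values (≈0–3) and singularity
indices (≈0–1) otherwise land the sigmoid in very different regimes.
The activation, the weight distribution and the decision rule are
implementation policy: the source description of the classifier fixes
none of them, and these are the canonical choices. `l = 60` hidden
nodes is the default, selected in the source study by 5-fold training
accuracy as the smallest size past which accuracy saturates.

Evaluation is stratified 5-fold cross-validation (stratification
guarantees both classes in every training fold even for unbalanced
sets). Per-fold confusion matrices are *summed* and the pooled counts
give the headline metrics — this pooling reproduces the worked
examples' arithmetic exactly, whereas averaging per-fold percentages
does not; both are reported. Metrics are the usual five (accuracy,
precision, sensitivity, specificity, F1) in percent, rounded half-up
to 2 decimals, with the **Normal (NSR) class as positive** — the
convention fixed by the worked examples' own arithmetic (their prose
definitions of TP/TN are inconsistent). Zero-denominator ratios are
reported as `NA`, never 0 or 100. For comparison,
`compare_classifiers()` feeds the identical folds to an RBF SVM
(`gamma = 0.05`) and KNN with $K = \mathrm{round}(\sqrt{n_{train}})$;
note that rule gives $K = 27$ for a training size of 720, while the
source study reports using 30 — the rule as stated is what is
implemented.

## Synthetic signals: what they emulate and what they do not

All generators are pure functions of their parameters and seed.

* `white_noise()` — uniform i.i.d. samples; `one_over_f_noise()` —
  white noise re-shaped in the frequency domain (amplitude
  $\propto 1/\sqrt{f}$, DC removed, Nyquist-symmetric), giving a
  periodogram slope of −1 ± 0.2 over the central decade.
* `binomial_cascade(J, p)` — the primitive of the deterministic
  binomial measure on $2^J$ cells (optionally node-shuffled), with the
  closed-form exponents attached; the canonical multifractal ground
  truth.
* `fbm(n, H)` — exact circulant-embedding synthesis of fractional
  Brownian motion (Cholesky fallback when the embedding fails for
  small n); the monofractal ground truth $\zeta(q) = qH$.
* `synthetic_ecg()` — a PQRST-like template (five displaced Gaussians,
  ~70 beats/min) plus class-specific noise. The NSR-like class gets 5%
  RR jitter and 1/f noise at 0.10 mV; the CHF-like class gets 0.5%
  jitter and strongly smoothed (0.35 s moving-average) noise at
  0.03 mV. The class difference is deliberately confined to the noise
  process, so the large-scale entropy ordering (NSR > CHF over scales
  10–20) is the controlled variable. These cohorts reproduce the
  *statistical* signature the classifier exploits; they are not
  physiological simulations — no arrhythmia morphology, no
  heart-rate-variability spectra, single channel only — so passing
  tests demonstrate the pipeline's correctness and discriminative
  mechanics, not clinical performance. The published real-data
  accuracies (≈99.5%) require the PhysioNet recordings, which are not
  bundled; `inst/scripts/reproduce_physionet.R` documents that run for
  users with network access.

## Numerical choices and degenerate inputs

* Undefined entropy is `NA` end to end; warnings carry per-scale
  counts.
* A constant coarse-grained series has zero variance; its tolerance is
  floored at machine epsilon so the all-match limit (entropy ≈ 0) is
  returned instead of an error.
* Problem sizes used in the validation suite: cascade $2^{14}$
  samples; fBm $n = 65536$ with 20 seeds; noise benchmarks
  $n = 65536$ at scales {1, 5, 10, 15, 20}; end-to-end cohorts 60 + 60
  segments of 64 s at 128 Hz.
* Cutting a record shorter than one segment yields zero segments with
  a warning (the remainder rule), not an error.
* All randomness is seed-controlled; reports regenerate bit-identically
  from (data, config, seed).

## Package shape

Signals and segments are light S3 records (a sample vector plus
metadata — they are not naturally tabular), while every analysis
result — entropy profiles, spectra, feature tables, evaluation
reports — is a tibble, so pipelines compose with the pipe and the
usual verbs; `autoplot()` methods cover each result type and
`tidy()`/`glance()` follow the broom conventions for fitted objects.

## Known limitations

* The per-scale tolerance convention makes entropy profiles of
  stationary noises nearly flat; users expecting the classic
  white-noise decay should use `r_mode = "fixed"` explicitly.
* Wavelet-leader estimates from a single short segment are biased at
  the extreme octaves; the fit range matters and is exposed
  everywhere.
* The ELM's random features make per-fold accuracies seed-dependent
  (the solved output layer is exact, the input layer is not); all
  reported numbers fix the seed.
* WFDB support covers the common format-16 and format-212 single- and
  two-channel layouts, not the full format zoo.
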