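---
title: "Decoding low-frequency LFP: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding low-frequency LFP: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the two models, the parameters that matter, the numerical decisions, what
the synthetic generator does and does not emulate, and the known
limitations. Nothing stated here goes beyond what the test suite and
`scripts/acceptance.R` actually compute.

## 1. The MISO spike-to-LFP model

Each LFP channel is modelled as a linear time-invariant system with the
recorded spike trains as inputs:

$$y_c(t) = \sum_u \sum_{\tau} h_{u,c}(\tau)\, x_u(t-\tau) + c_0,
\qquad \tau \in [-T_{pre}, +T_{post}].$$

The kernels $h_{u,c}$ — spike-related slow potentials (SRSPs) — are
acausal: negative lags describe LFP preceding the spike, which is
physiologically expected because synaptic input both drives spiking and
contributes to the field. Spike trains enter as binned counts, not
smoothed rates, taking the convolution model literally.

**Lag window.** Default $T_{pre} = T_{post} = 0.5$ s at 10 ms bins
(101 lags). A submovement cycle at 1–4 Hz spans 0.25–1 s; half a second
each side of the spike covers one full cycle of the slowest component.

**Estimator.** The least-squares objective is taken over the *interior*
bins, where the whole lag window fits inside the record; boundary bins are
excluded rather than zero-padded, so no edge bias enters the kernels. The
normal equations are assembled from windowed auto- and cross-correlation
functions of the inputs, using a sliding-window recursion along the Gram
matrix diagonals (stepping both lags together shifts the correlation
window by one bin, so only two boundary products change per step). This
makes the assembled system *exactly* equal to the cross-product of the
explicit lagged design matrix at a fraction of the cost, and the test
suite holds the two routes to each other at 1e-6 on random instances
(they agree at machine precision). Because input cross-correlations enter
the solve, the contribution of correlated spikes in other *recorded*
trains is removed from each unit's SRSP; correlated but *unrecorded*
neurons cannot be accounted for — a documented limitation of the model
class, not of the implementation.

**Ridge.** Default $\lambda = 0$. A singular system (e.g. perfectly
collinear trains) aborts with a suggested $\lambda$, the smallest value on
a $10^{-6}..10^{-2}$ grid (scaled by the mean Gram diagonal) that makes
the system well conditioned. Kernel norms are non-increasing in
$\lambda$, which the suite checks.

## 2. From SRSPs to firing-rate estimates

Per unit, the channel × lag kernel matrix is decomposed by an uncentered
SVD into orthonormal PC waveforms (lag space) and channel loadings; three
sources are the default (`nSources = 3`), matching the observed
low-dimensional structure of SRSP variation across channels. Uncentered,
because a kernel is already a deviation from silence; a centered
decomposition would spend one component on the mean waveform. Source
projections are the Moore–Penrose pseudoinverse of the loadings —
least-squares demixing of the LFP into per-source time series.

Each demixed source is Wiener-deconvolved by its PC waveform,
$G(f) = H^*(f)\,/\,(|H(f)|^2 + \mathrm{nsr})$, and the deconvolved
sources are combined by ordinary least squares against training rates —
the only supervised step. The whole chain is linear and time-invariant,
so it is collapsed into one acausal FIR filter bank per unit and applied
by pure filtering: the estimate at bin $t$ depends only on the LFP within
the filter's lag window around $t$, the real-time contract.

**nsr** (noise-to-signal, default 0.01, dimensionless relative to the
unit-norm PC waveform spectrum): at $10^{-9}$ on an invertible noiseless
system the held-out rate correlation exceeds 0.99; at $\infty$ the
filters vanish and the estimate collapses to the mean-rate offset. Both
limits are tested. Note that near-zero nsr is only meaningful when the
waveform spectrum is bounded away from zero; for band-limited SRSP
waveforms the default 0.01 is what keeps the out-of-band gain sane.

**FIR realization.** The Wiener inverse has infinite support; it is
windowed to the SRSP lag span with a raised-cosine taper to suppress
truncation ripple. Rate estimates may go negative (the linear contract is
the documented behaviour); `clipNonnegative = TRUE` clamps.

**Reconstruction ceiling.** With $U$ units sharing $k$ kernel sources,
all rate estimates live in a $k$-dimensional signal subspace. When
$U > k$ and unit rates are not strongly correlated, per-unit fidelity is
intrinsically capped; population components, in contrast, are estimated
*better* than the median single unit (an ordering the acceptance suite
verifies on synthetic data). This is the quantitative face of the claim
that the low-frequency LFP is particularly suited to decoding the leading
population components.

## 3. Rotational dynamics and areal velocity

The low-frequency LFP trajectory is reduced by covariance PCA (means
removed, variances *not* normalized — amplitude carries the speed
information). A deterministic sign convention (largest-magnitude
coefficient positive) makes planes and AV signs reproducible.

Rotation-maximizing planes come from fitting $\dot{x} \approx M x$ with
$M$ constrained skew-symmetric, solved in closed form by least squares
over the skew basis — no iterative optimization, so the fit is
deterministic and oracle-checkable. Eigenvalues of a real skew matrix are
purely imaginary pairs; each pair gives one plane (orthonormalized
real/imaginary eigenvector parts), ordered by $|\lambda|$, with rotation
frequency $|\lambda|/2\pi$. Planes are oriented so the mean AV over the
fitting span is non-negative. Default pre-reduction `nPcs = 6`
accommodates up to three planes.

Areal velocity is evaluated sample-wise with central-difference
derivatives and *no* mean removal or smoothing of its own: AV is
origin-dependent and phase-sensitive, so centering policy belongs to the
caller (PCA projection is the centered route; the raw-channel pairwise
identity must see the same signal on both sides). Its exact algebraic
properties — antisymmetry, time-reversal antisymmetry, the $c^2$ scale
law, in-phase (rank-1) rejection, rotation invariance, and the
decomposition of any plane's AV into $\tfrac12 N(N-1)$ pairwise terms —
are enforced as property tests at 1e-9, and a unit circle at 1 Hz yields
$AV = \pi$ within the central-difference bound
$\pi\,\omega^2 h^2/6$.

## 4. Submovement analysis

Cursor speed is smoothed at 10 Hz (zero phase); submovements are speed
maxima above 0.1 × the 99th speed percentile (a *relative* threshold, so
detection is invariant to speed rescaling), separated by ≥ 0.2 s.
Direction is the angle of net displacement between the flanking speed
minima: net displacement is robust to the pulse's internal shape, and no
standard definition exists to defer to.

**Speed proportionality.** The regression metric is the areal velocity
*of the triggered-average trajectory* per speed quantile bin: averaging
the trajectory first cancels incoherent noise linearly, before the
quadratic AV is formed. (Averaging the AV signal itself is also
supported, but inherits the full single-trial AV variance.) The default
metric integrates AV over the ±0.25 s window; baseline correction
(subtracting the outer-window mean) is available for recordings with a
strong event-independent AV floor, but is off in the recovery analyses
because with isolated submovements the outer window contains the tails of
the event's own cycle.

**Direction decoding.** Per event the 3D AV vector is integrated over
±0.25 s and normalized to a unit rotation axis. The population rotation
has a dominant common axis; direction lives in the *deviation* around it.
Each cross-validation fold therefore centers the axes on the
training-fold mean before fitting the orthogonal (Procrustes) map to the
targets $(\cos\theta, \sin\theta, 0)$ — an orthogonal map cannot send a
tight cone of raw axes onto the full equator. Accuracy is an angular
coefficient of determination,

$$\mathrm{CoD} = 1 - \frac{\sum d(\hat\theta_i, \theta_i)^2}
{\sum d(\bar\theta, \theta_i)^2},$$

with $d$ the wrapped difference in $(-\pi, \pi]$ and $\bar\theta$ the
circular mean — so predicting the circular mean scores exactly 0 and
perfection scores 1. The null is the same cross-validated pipeline on
`nShuffles = 1000` seeded permutations of the event–direction pairing;
the decoder "passes" when CoD exceeds the 95th percentile. Decoding is
5-fold cross-validated even though a training-set CoD would be higher:
the permutation comparison is only honest out of sample. The construct
(axis integration window, Procrustes map, CoD definition) is this
package's declared choice; alternates such as circular correlation can be
substituted at the analysis level.

## 5. The synthetic generator

`generate()` produces, from one seed, a coupled set of kinematics, spike
trains and LFP with the statistical structure both pipelines assume:

* **Submovements**: a refractory renewal process (default 2 events/s,
  0.3 s minimum gap — inside the physiological 1–4 /s band), eight target
  directions, lognormal peak speeds (median 1, `speedSdLog = 0.35`),
  raised-cosine speed pulses of 0.35 s.
* **Rates**: baseline 4 Hz plus cosine-tuned event-locked activation
  peaking at 40 Hz, with per-unit response latencies spread over ±60 ms.
  The activation amplitude scales with $\sqrt{\text{speed}}$ *by design*:
  areal velocity is quadratic in LFP amplitude, so this makes swept area
  linear in submovement speed — the proportionality the recovery analyses
  then verify.
* **Spikes**: inhomogeneous Poisson by thinning against an upper bound
  covering two overlapping pulses.
* **LFP**: each train convolved with its unit × channel kernel bank plus
  white and 1/f noise (0.3 each by default) and an optional common-mode
  artifact. Kernels are channel mixtures of three damped-sinusoid sources
  (1.5/2.5/3.5 Hz, delays 0/60/120 ms, 0.15 s decay), so the population
  signal appears with different phases on different channels — the
  rank-3, phase-diverse structure the AV method needs. The third source
  reverses polarity across the array midpoint (SRSP polarity flips with
  electrode depth), keeping its spatial pattern from collapsing onto the
  first two.
* **Direction tilt**: the third source's per-unit loading varies with
  $\cos(\phi_u)$ and its latency with $\sin(\phi_u)$ (70 ms spread,
  comparable to a quarter period), giving the rotation axis two
  independent quadrature degrees of freedom in submovement direction —
  without this, a rank-3 model with scalar loadings can only tilt along
  one axis and the eight directions are not separable. The
  `directionTiltDeg` parameter (default 10°) scales both couplings.

What the generator does **not** emulate: spike-sorting errors and unit
loss within a session, non-stationary electrode drift, volume-conduction
geometry, oscillatory alpha/beta rhythms, movement artifacts, and
correlated neurons that are not recorded. Passing recovery tests on this
generator therefore demonstrates the correctness and calibration of the
algorithms under their own model class — not performance on real
recordings, where all of the above degrade the constants (and where the
rank-3 source assumption is only an approximation).

**Study sizes used by the checks** (package choices): oracle equivalence
on 20 random instances of ≤ 3 units × ≤ 2 channels × ≤ 25 lags ×
≤ 5000 bins; noiseless kernel recovery on 300 s; the noise-robustness
ordering on ten 140 s sessions (75/25 train/test at 20 ms bins) at 0.5×,
1× and 2× the default noise; speed proportionality on 300 s at 1.2
events/s with a widened speed range (`speedSdLog = 0.6` — the
proportionality claim is about a wide speed range, and sparser events
isolate single cycles); direction decoding on ten 120 s sessions with
1000-permutation nulls.

## 6. Numerical choices and degenerate inputs

* **Zero-phase filtering** is forward–backward Butterworth (4th order;
  LMP cutoff 5 Hz) with odd-reflection padding and steady-state
  initialization at both ends, so a constant channel passes bit-exactly
  and edge transients stay out of the output. Zero phase is mandatory
  everywhere because AV is phase-sensitive.
* **Derivatives** are central differences (one-sided at the ends):
  local, artifact-robust, consistent with the FIR real-time constraint,
  and exactly commuting with linear channel maps — which is what makes
  the 3D AV vector's components identical to the pairwise AVs of the
  projected signals.
* **Ties and signs**: PCA component signs fixed by the
  largest-magnitude-coefficient rule; plane orientation by non-negative
  mean AV; SRSP PC waveform signs likewise. All randomness flows through
  a single seed argument and the caller's RNG state is restored.
* **Degenerate inputs** fail loudly with named causes: zero-variance
  channels in PCA, singular normal equations (with a ridge suggestion),
  identical directions in the CoD denominator, i = j pairwise requests
  (identically zero, disallowed), windows that leave the recording
  (events dropped and counted).
* **Containers**: fitted models and ground truth travel as a versioned
  single-file container of named arrays plus metadata (exact round
  trip). Delimited text formats carry a leading `# n_rows=` declaration
  so silently truncated files are rejected.

## 7. Known limitations

* Per-unit rate recovery is bounded by the shared-source subspace
  (section 2); on real arrays with richer per-unit SRSP structure the
  ceiling is higher, but the same qualitative ordering (population
  components > single units) is expected.
* The stability analysis compares sessions regenerated from the same
  generative model; real cross-day nonstationarities (electrode
  migration, impedance drift) are outside the generator's scope, so
  cross-day numbers here only demonstrate the *mechanics* of the
  stability report.
* The frequency-domain pairwise variant (imaginary part of the
  cross-spectra) is a noted future extension; only the time-domain
  band-pass-then-AV route is implemented.
* Kalman-style dynamical smoothing on top of the FIR estimates is out of
  scope by design.
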