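---
title: "Just-in-time interpolation of missing R-R intervals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Just-in-time interpolation of missing R-R intervals: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Heart-rate-variability (HRV) analysis consumes a stream of R-R intervals
(RRIs): the times between successive R waves of the ECG, in milliseconds.
Wearable sensors lose R waves to motion artifacts and electrode contact
failures. When one R wave in a run goes undetected, the two true intervals
it separated appear as a single merged measurement

$$ r_j = \tilde r_j + \tilde r_{j+1}, $$

roughly twice a normal beat. Left uncorrected, a single merged beat
distorts window-based HRV features (RMSSD, NN50, band powers) for an
entire window length — three minutes at the standard setting — which is
unacceptable for online monitors (drowsiness detection, seizure
prediction) that cannot pause and edit the record offline.

`lwplsri` detects these events online by a simple threshold
($r_j > \bar r$, default $\bar r = 1500$ ms) and reconstructs the two
underlying intervals with a local regression model built *just in time*
from a FIFO buffer of the $W$ most recent accepted-or-reconstructed
beats. Only the first interval $\hat r_j$ needs estimating; the second is
the complement $\hat r_{j+1} = r_j - \hat r_j$, so the pair always sums
to the observed measurement and cumulative time is conserved exactly.

## The regression engines

### PLS by the eigenvalue form of NIPALS

Partial least squares regresses $y$ on $X$ through $K$ latent variables.
With mean-centered blocks, component $k$ maximises the covariance between
the score $t_k = X_k w_k$ and the response under $\lVert w_k\rVert = 1$,
which makes $w_k$ the leading eigenvector of
$X_k^\top y_k y_k^\top X_k$. Because that matrix is rank one, the
eigenvector is available in closed form as
$w_k = X_k^\top y_k / \lVert X_k^\top y_k\rVert$; `fit_pls()` uses the
closed form and the test suite cross-checks it against a dense
eigensolver and a classical covariance-form NIPALS oracle. Loadings and
coefficients follow as $p_k = X_k^\top t_k / t_k^\top t_k$,
$b_k = y_k^\top t_k / t_k^\top t_k$, with deflation
$X_{k+1} = X_k - t_k p_k^\top$, $y_{k+1} = y_k - b_k t_k$.

Inputs are centered internally and *not* variance-scaled by default: all
variables here are intervals in milliseconds, so scaling would only
amplify noise in the flattest column. An `autoscale` flag restores the
conventional unit-variance treatment for heterogeneous inputs.

### Locally weighted PLS

For a query $x_q$, every stored sample is weighted by its similarity

$$ \omega_n = \exp(-d_n\,\varphi / \sigma_d), \qquad
   d_n = (x_n - x_q)^\top (x_n - x_q), $$

where $\sigma_d$ is the standard deviation of the squared distances
$d_n$ and $\varphi > 0$ the localisation parameter: small $\varphi$
keeps only close neighbours, large $\varphi$ approaches a global fit.
The weighted PLS loop then runs with the diagonal similarity matrix
$\Omega$ inserted in every inner product, starting from the
$\omega$-weighted means, and the local model is discarded after one
estimate. With uniform weights the procedure reduces exactly to ordinary
PLS, a property the suite asserts to $10^{-10}$.

Numerical choices worth recording:

* **$\sigma_d$ convention.** "Standard deviation" is read as the
  population form (divide by $N$); a `sd_type = "sample"` switch is
  equivalent to rescaling $\varphi$ by $\sqrt{(N-1)/N}$, which the tests
  verify.
* **$\sigma_d = 0$.** A constant buffer makes all distances equal. The
  weights are then set uniformly to 1 (the PLS limit) rather than
  dividing by zero; distances whose spread is at float-noise level
  relative to their magnitude are treated the same way.
* **Weight underflow.** Estimates are invariant to scaling all weights
  by a constant (every weight appears homogeneously in numerator and
  denominator), so the implementation uses the max-normalised form
  $\exp(-(d_n - \min d)\varphi/\sigma_d)$, which cannot underflow to an
  all-zero weight vector for strongly localised $\varphi$.
* **Eigenvector sign.** The closed form fixes
  $w_k^\top X_k^\top \Omega y_k \ge 0$; predictions are sign-invariant
  but serialised models become reproducible byte for byte.
* **Degeneracy.** If the deflated covariance vanishes before $K$
  components, the accumulated estimate is returned (the relation is
  exhausted — on noiseless data this is the exact fit); a zero weighted
  score norm aborts with a warning.

## From buffer to regression problem

The query for a merged measurement is
$x_j = [\,r_j/2,\ r_{j-1},\ \dots,\ r_{j-L}\,]$: the halved current
measurement (an estimate of the local two-beat mean) followed by the $L$
most recent buffer values, newest first.

How to form *training* pairs from the buffer is genuinely open: a clean
beat has no merged measurement attached. The package trains, for every
interior buffer position $i$, on

$$ x_i = \left[\tfrac{r_i + r_{i+1}}{2},\ r_{i-1},\ \dots,\ r_{i-L}\right],
   \qquad y_i = r_i, $$

so the leading training column is the same physical quantity the query
supplies — the two-beat local average — rather than, say, $r_i$ itself.
This is the single most consequential convention in the package; it is
isolated in `make_training_set()` so alternatives can be swapped in, and
the ablation switch `use_current = FALSE` (inputs
$[r_{i-1},\dots,r_{i-L}]$ only) quantifies how much the merged
measurement contributes. In the synthetic study dropping it roughly
doubles the model interpolators' RMSE, matching the expectation that
$r_j$ carries most of the information about the pair it hides.

Two successive missed R waves (a triple-merged measurement) are handled
sequentially: the first query leads with $r_j/3$, and the second embeds
the first estimate,
$x_{j,2} = [(r_j - \hat r_{j,1})/2,\ \hat r_{j,1},\ r_{j-1}, \dots]$.
Longer failures are not interpolated: the event is flagged and passed
through, since monitoring should be suspended rather than fed
fabricated beats.

### Guard rails

* **Clamping.** A pathological buffer can put the raw estimate outside
  $(0, r_j)$, which would break positivity of the complement. Estimates
  are clamped into $[0.1\,r_j,\ 0.9\,r_j]$ and the event flagged.
* **Warm-up.** The protocol assumes a pre-filled buffer of $W$ beats.
  If an event arrives earlier the interpolator falls back to the buffer
  mean (given at least $L + 2$ beats) or to equal division below that,
  so the stream tool is total.
* **Online $q$.** With positions unknown, the successive-missing count
  is estimated as $\max(1, \mathrm{round}(r_j / \mathrm{median(buffer)}) - 1)$;
  $q > 2$ triggers the long-failure path.

## HRV features

Eight features per rectangular sliding window (180 s, advancing by a
configurable number of beats): meanNN, SDNN, RMSSD, NN50 (successive
differences strictly above 50 ms), and the spectral set TP, LF, HF,
LF/HF. The tachogram (interval vs cumulative beat time, the time of a
beat being the end of its interval) is cubic-spline interpolated
(`stats::splinefun`, `"fmm"` — reproduces exact cubics, which the suite
checks) and resampled at 4 Hz; an AR(40) model is fitted by Burg's
method (`stats::ar.burg`; Yule-Walker behind a flag) and its one-sided
spectrum integrated over LF 0.04–0.15 Hz, HF 0.15–0.40 Hz and TP
0.0033–0.40 Hz.

The AR polynomial is evaluated on the frequency grid by FFT, and the
default grid (4096 points to Nyquist) is deliberately dense: Burg poles
for strongly periodic signals are narrow, and a coarse grid integrates
such peaks poorly. The periodogram serves as the independent oracle for
peak locations in the tests. Windows with zero variance short-circuit to
zero band powers, and LF/HF is reported absent (not infinite) when HF
is zero.

The exact membership convention — a window ending at beat time $t_e$
contains beats with time in $(t_e - 180\,\mathrm{s},\ t_e]$ — matters
only at window edges; the influence-duration test pins it down.

## The synthetic generator

`generate_rri()` produces the study conditions without any external
download: baseline 850 ms plus an LF sinusoid (30 ms at 0.1 Hz), an HF
sinusoid (20 ms at 0.25 Hz), a slow drift (40 ms, 300 s period) and
AR(1) beat noise (innovation SD 15 ms, coefficient 0.5), all driven by
cumulative beat time and clipped to [300, 1500] ms. The amplitudes sit
in the range reported for healthy resting adults (beats roughly
600–1100 ms with clear LF and HF band power), and the clipping bound
coincides with the detection threshold so clean synthetic beats are
never false-flagged. `generate_cohort()` jitters the per-subject
parameters (baseline ±10%, amplitudes and noise ±20% by default) to
emulate between-subject spread.

What the generator does *not* emulate: ectopic beats and arrhythmia,
respiratory frequency wander, circadian nonstationarity, and the
quantisation of real R-peak detectors. Passing the synthetic study
therefore demonstrates correct mechanics and the expected *ordering* of
interpolators under sinus-rhythm-like variability, not clinical
performance on pathological records.

## The simulation study, scaled down

The evaluation protocol splits each subject's record into contiguous
parameter-optimization / initial-buffer / validation segments (reference
lengths 6000 / 500 / 5000 beats), injects merged beats at rates
$\alpha \in \{0.3\%, 0.5\%, 1\%\}$ at non-adjacent random positions,
interpolates with positions known (so every method faces identical
events), and scores RMSE over the reconstructed interval pairs —
reconstructed values are identical to observed values everywhere else,
so restricting RMSE to the pairs is the informative choice and a flag
away from the all-beats variant. Repetition $k$ draws its injection
seeds deterministically from a base seed, making every report
bit-reproducible.

The in-package study (acceptance tests and `scripts/acceptance.R`) uses
5 synthetic subjects with 500 + 3000 beats, 30 repetitions and the
reference interpolator settings $\varphi = 1.3$, $K = 3$, $L = 3$,
$W = 500$; HRV-level scoring runs at $\alpha = 0.5\%$ with windows
advancing 25 beats. These sizes keep the full study at a few minutes on
one core while leaving Monte-Carlo error well below the
between-method differences being asserted. At this scale the locally
weighted and global PLS interpolators are separated by far less than
either is from the mean or equal-division baselines — expected, since
the generator's local dynamics are close to linear over a 500-beat
buffer; the locally weighted variant's advantage widens with
nonstationarity.

`optimize_parameters()` implements the grid search
($\varphi$ over {0.1 … 3}, $K \le L + 1$) used to pick the reference
settings; on synthetic data its optimum is flat across a broad region,
consistent with the reference study's report that performance hardly
changes with $L$ and $W$.

## Interfaces

RRI files are one-interval-per-row CSV (`rri_ms`, optional `t_ms`;
`rri_s` is auto-converted) or bare one-number-per-line text. Fitted PLS
models serialise to JSON exactly (17 significant digits). The
`exec/lwpls-ri` command-line tool wraps `simulate`, `interpolate`,
`hrv` and `benchmark` around the exported functions; configuration
files are YAML with the same field names as the constructors, and every
flag overrides its file value.

## Known limitations

* Training-pair construction is a convention (above), not an identity;
  other layouts are defensible and would shift RMSE by small amounts.
* The threshold detector cannot see *short* beats (a spurious extra R
  wave) — only merged ones; ectopic-beat editing is out of scope.
* Burg band powers for nearly noise-free periodic signals depend on the
  PSD grid density; the default is chosen for tachogram-like broadband
  signals.
* The synthetic cohort stands in for real Holter records; absolute RMSE
  values depend on its noise and amplitude settings and are not
  comparable to values measured on clinical databases.
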