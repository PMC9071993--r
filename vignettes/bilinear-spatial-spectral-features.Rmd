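---
title: "Bilinear spatial-spectral feature extraction for motor-imagery EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bilinear spatial-spectral feature extraction for motor-imagery EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(b2ddlpp)
```

## The problem

Motor imagery (MI) — imagining a limb movement without executing it — produces
event-related desynchronization (ERD): a drop in band power of the mu
(8–13 Hz) and beta (14–30 Hz) rhythms over the corresponding motor cortex.
A brain-computer interface classifies single EEG trials by where and in which
frequency band this power drop occurs. The information is therefore jointly
*spatial* (which electrodes) and *spectral* (which band), and a feature
extractor should respect that two-way structure instead of flattening it.

This package implements a processing chain that keeps the two axes explicit:

1. **Filter bank.** Nine contiguous 4 Hz Chebyshev type II bandpass filters
   spanning 4–40 Hz decompose each trial into spectral sub-bands.
2. **OVR-FBCSP.** Per band and per class, common spatial patterns (CSP) are
   fitted one-versus-rest; the log-normalized variances of the projected
   trial give, per trial, an $N_f \times N_g$ feature matrix whose rows are
   bands ($N_f = 9$) and whose columns are the $2m$ CSP features of each
   class in class-major order ($N_g = 2\,m\,Z$ for $Z$ classes and $m$
   filter pairs).
3. **Feature reduction.** One of: nothing, LDA, 2DLDA, DLPP, 2DDLPP, or the
   bilinear method B2DDLPP described below.
4. **Linear SVM** with stratified cross-validated selection of $m$ and of the
   reduced dimensionality $d_{\mathrm{op}}$.

## The bilinear model

The discriminant locality preserving projection (DLPP) family minimizes the
heat-kernel-weighted spread of projected samples within a class relative to
the weighted spread of the projected class means. All weights are computed
from the *unprojected* data over **all** within-class pairs
($W^s_{ij} = \exp(-\lVert X^s_i - X^s_j\rVert_F^2/t)$, and
$B_{ab} = \exp(-\lVert F_a - F_b\rVert_F^2/t)$ between class means $F_a$);
no k-nearest-neighbor truncation is applied, and the bandwidth is $t = 1$
throughout by convention. The one-sided 2DDLPP variant projects the feature
matrix from the left only, $Y = A^\top X$, so it compresses the spectral
axis but treats the spatial axis as a passive block.

B2DDLPP instead models the within-class variation as **Kronecker-separable**,
the matrix-variate Gaussian assumption: for the vectorized features,
$\operatorname{cov}(\operatorname{vec} X) = \psi \otimes \phi$ with a
spectral (row) covariance $\phi \in \mathbb{R}^{N_f \times N_f}$ and a
spatial (column) covariance $\psi \in \mathbb{R}^{N_g \times N_g}$. Both are
estimated as weighted pair scatters:

$$\phi = \frac{1}{2N_g}\sum_s \sum_{i,j} (X^s_i - X^s_j)(X^s_i - X^s_j)^\top W^s_{ij},
\qquad
\psi = \frac{1}{2N_f}\sum_s \sum_{i,j} (X^s_i - X^s_j)^\top (X^s_i - X^s_j) W^s_{ij}.$$

These share every weighted squared Frobenius distance, which yields the
identity $2N_g\operatorname{tr}\phi = 2N_f\operatorname{tr}\psi = \sum W^s_{ij}
\lVert X^s_i - X^s_j \rVert_F^2$ — used as a standing self-check in the tests.
The between-class scatter is decomposed the same way over the class means:
a left scatter $S_{BL} = \tfrac12 \sum_{a,b} B_{ab}(F_a - F_b)(F_a - F_b)^\top$
and a right scatter $S_{BR}$, the latter carrying a factor
$1/\operatorname{tr} S_{BL}$ so that for rank-one mean differences
$S_{BR} \otimes S_{BL}$ equals the vectorized between-class scatter exactly.

Two generalized eigenproblems,
$S_{BL} u = \lambda\, \phi\, u$ and $S_{BR} v = \gamma\, \psi\, v$,
give left/right projection bases $U$ and $V$ and the bilinear transform
$Y = U^\top X V$. Every entry $y_{lj}$ of $Y$ is scored by the product
$\lambda_l \gamma_j$ of its row and column eigenvalues, and the $d$
highest-scoring entries are the features. Unlike a one-sided method, the
selected set can mix "row 2 with column 5" and "row 1 with column 3" —
individual spatial-spectral cells rather than whole rows.

With column-major vectorization,
$\operatorname{vec}(U^\top X V) = (V \otimes U)^\top \operatorname{vec}(X)$;
this identity pins the vectorization convention used everywhere in the
package and is asserted to $10^{-10}$ in the test suite.

## Numerical choices

* **Generalized solves.** Both eigenproblems are solved in symmetric-definite
  form via Cholesky reduction of the denominator, never by forming
  $\phi^{-1}S_{BL}$; residuals $\lVert S u - \lambda \phi u\rVert \le 10^{-8}$
  are part of the test contract, and equivalence with the dense
  non-symmetric solve is asserted on small instances.
* **Ridge regularization.** Denominator matrices can be singular: the
  between-class scatter has rank at most $Z-1$, and FBCSP feature counts can
  exceed per-class sample counts. Every denominator receives a ridge
  $\varepsilon\,\operatorname{tr}(S)/p \cdot I$ with $\varepsilon = 10^{-6}$.
  If the Cholesky factorization still fails — which happens when heat-kernel
  weights underflow so far that the trace-proportional ridge drops below the
  absolute floating-point noise of the scatter assembly — the ridge
  escalates by $10^3$ per attempt with a message. The escalation is recorded
  in the fitted model.
* **Eigenvector scale.** Generalized eigenvectors are conventionally
  $B$-orthonormal, but their Euclidean norm is then $1/\sqrt{v^\top B v}$,
  which overflows for tiny denominators. Since the scale of an eigenvector
  is arbitrary, all projection columns are normalized to unit Euclidean
  norm; eigenvalues, selection order, and subspaces are unaffected.
* **Determinism.** Eigenvector signs are fixed by making the
  largest-magnitude coefficient positive; ties in the $\lambda_l\gamma_j$
  ranking break lexicographically by ascending $(l, j)$; grid ties in the
  cross-validation break toward smaller $d$, then smaller $m$.
* **Heat kernel at $t = 1$.** On log-variance FBCSP features the squared
  pair distances are often in the tens, so weights can be numerically tiny
  and the scatters are then dominated by the nearest pairs. This is a
  genuine property of the conventional $t = 1$ on this feature scale; the
  eigen-structure is still well defined because the Rayleigh quotients are
  invariant to the common scale of each side's matrices.
* **Degenerate input.** Equal class means make
  $\operatorname{tr} S_{BL} = 0$ and raise an explicit
  "no between-class structure" error rather than dividing by zero.

## The filter bank

The design is a 6th-order Chebyshev type II bandpass per band (the order of
the bandpass, i.e. a 3rd-order low/high prototype pair), 40 dB stopband
attenuation. Chebyshev II places all ripple in the stopband, keeping the
passband flat so band power is not distorted — the property that matters
when downstream features are variances. Filtering is zero-phase
(forward-backward) by default so group delay does not shift trial content
relative to the cue; a causal single pass is available
(`zero_phase = FALSE`) since recorded practice varies. Stability (poles
inside the unit circle) is checked at design time, and band edges must stay
below Nyquist — at 250 Hz all nine default bands are valid.

## The synthetic benchmark

Real MI corpora need downloads and subject-specific conventions, so the
package ships a generator with *known* recoverable structure. Each trial is

$$x(t) = \sum_k a_k(\text{class})\; p_k\, s_k(t) + \text{noise},$$

with $s_k$ a fresh unit-variance band-limited source per trial (white noise
shaped by the same Chebyshev II design as the analysis bank, so spectral
content matches the analysis bands), $p_k$ a fixed unit-norm channel mixing
pattern, and $a_k = 1 - \text{erd\_depth}$ exactly when source $k$ is the
class's suppressed source. ERD is encoded purely as amplitude attenuation
because CSP-type methods are variance-driven; phase is untouched.

Defaults — chosen once as a realistic small left/right-hand benchmark and
not revisited: 2 classes, 8 channels, 250 Hz, 3 s trials, 60 trials per
class, two orthogonally mixed mu-band (8–12 Hz) sources, ERD depth 0.5 (a
strong but physiological ~50% amplitude suppression, i.e. 75% power
suppression), broadband noise SD 0.5. At these settings the
ideal-observer separation is large (the projected in-band power ratio
between classes is 4:1 against a small in-band noise floor), so Bayes
accuracy is essentially 1 and pipeline accuracy measures implementation
quality rather than task difficulty. With `erd_depth = 0` the classes are
statistically identical — the null configuration used for chance-level
checks. The null check is evaluated at a *fixed* $(m, d)$: under the null
the cross-validated accuracy of a fixed configuration is binomial at
chance, whereas the maximum over a selection grid is biased above chance
(selection optimism) and would invalidate the binomial reference.

What the generator does **not** emulate: volume conduction and realistic
leadfields, ERD time courses within a trial, non-stationarity across a
session, eye/muscle artifacts, inter-subject variability. Passing the
benchmark therefore demonstrates that the chain recovers planted
spatial-spectral band-power structure — not performance on any particular
recorded corpus.

## Protocol

`run_cv()` follows the standard session protocol: stratified 5-fold
cross-validation on the training session; for each CSP pair count $m$
(scanned over 1–4) the front end (CSP) and the feature extractor are
refitted *inside each training fold* — validation trials never enter any
fit, and the report carries an explicit contamination counter (always 0) and
the fold assignment for audit. The $(m, d_{\mathrm{op}})$ cell with the best
mean validation accuracy is then refitted on the whole training session and
applied once to the held-out session (`evaluate_test()`). The `d` grid
(`"auto"`) is every dimension $1..N_f$ for one-sided matrix methods, and a
geometric grid over $1..N_fN_g$ capped at 40 points for vector and bilinear
methods. The classifier is a linear SVM with cost 1 and no feature
standardization; standardization was evaluated once during development and
degraded accuracy for both raw FBCSP and bilinear features, so the simpler
convention is kept. Time-window cropping and integer-factor decimation to
250 Hz are available as preprocessing for high-rate recordings.

Problem sizes used by the shipped checks (chosen so the whole suite runs
comfortably on one CPU): oracle comparisons use $\le 10$ samples of
$3\times4$ matrices; eigen cross-checks stay at or below $20\times20$; the
end-to-end benchmark runs the full $(m, d)$ protocol on 120-trial sessions
over 10 generator seeds; the six-method comparison in the acceptance script
scans $m \in \{1, 2\}$ on one train/test pair.

## Known limitations

* DLPP-family baselines inherit the small-sample pathology of ratio-trace
  embeddings: when the denominator is rank-deficient, the ridge direction
  dominates the smallest eigenvalues and those directions are essentially
  unregularized noise. This is the textbook behavior of these methods, not
  a defect of the solver; the bilinear method is less exposed because its
  two denominators are small and well-populated.
* No artifact handling (EOG/EMG) of any kind; inputs are assumed to be
  cleaned, epoched EEG.
* The one-shot bilinear solution is used — no alternating refinement of
  $U$ and $V$.
* Readers for vendor formats (GDF, MAT exports) are out of scope; any
  epoched array with labels and a sampling rate can be wrapped with
  `validate_epochs()`.

## A worked example

```{r example, eval = FALSE}
ep <- generate_dataset(synthetic_config(seed = 1))
cfg <- experiment_config(method = "b2ddlpp", m_grid = 1:2, n_folds = 5,
                         seed = 1)
rep <- run_cv(ep, cfg)
rep
rep$best
```

The report prints the best mean fold accuracy with the selected $(m,
d_{\mathrm{op}})$; `compare_methods()` produces the six-row method
comparison table, and `scripts/acceptance.R` at the repository root
recomputes all headline quantities from scratch.
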