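---
title: "Measuring EEG turbulence with a kurtosis-operator functional ICA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring EEG turbulence with a kurtosis-operator functional ICA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turbeeg)
```

## The model

`turbeeg` quantifies *turbulence* in multichannel EEG: irregular, broadband
fluctuation of the dominant spatiotemporal activity pattern, the kind of
dynamics expected from cortical systems operating near criticality and
modulated by generalized CNS arousal. The observable is a multichannel
recording per participant $i$ and experimental condition $j$,
$X_{ij}(t, s_k)$, with $K$ channels and a common sampling rate. The analysis
treats windowed segments of these recordings as functional data: within a
sliding window every participant-by-channel series is a curve in $L^2$.

The pipeline has four stages.

**1. Band-limited spatial denoising.** Each recording is zero-phase
Butterworth band-passed to the band of interest (alpha 8--13 Hz or high
gamma 50--80 Hz), spatially filtered by spatio-spectral decomposition (SSD),
and reduced to the rank-1 backprojection onto the dominant spatial direction
estimated under a Cauchy likelihood. SSD solves the generalized eigenproblem
between the band covariance and a flanking-band covariance; the flanks are
built by a band-pass 4 Hz beyond the band edges followed by a band-stop 1 Hz
beyond them, and the signal covariance uses a 2 Hz widening — so the filters
maximize in-band power against the immediately neighbouring bins. The
retained filter count is chosen on the eigenvalue scree by the perpendicular
line method. Channels are preserved through the rank-1 backprojection (the
per-window score vectors downstream have one entry per channel).

**2. Windowed kurtosis-operator decomposition.** Windows of length $w$
(500 ms for alpha, 100 ms for gamma) slide with a 20-ms hop — the scale of
interneuronal transmission latencies — giving $\tau$ overlapping windows.
Within a window, the $N \cdot K$ curves of each condition are expanded on a
shared B-spline basis $\phi$ of dimension $p$, conditions are stacked into a
block system of dimension $pJ$ with block-diagonal Gram matrix $G$, and the
coefficient matrix $A$ is ZCA-whitened in the Gram metric (the symmetric
inverse square root of the sample covariance of $A G^{1/2}$). The kurtosis
matrix
$$\Sigma = \tfrac{1}{N K}\, W^\top \mathrm{diag}(W W^\top)\, W,
\qquad W = \tilde A G^{1/2},$$
is the coefficient-space kernel of the kurtosis operator; for whitened
Gaussian data its spectrum concentrates at $d + 2$ ($d = pJ$), and any
heavy-tailed direction rises above that floor. Its leading eigenvector,
corrected by $G^{-1/2}$, gives the dominant eigenfunction $\psi_1$ (unit
norm, orthogonal system); splitting its coefficients into $J$ consecutive
blocks of $p$ yields the condition-embedded components $\psi_{1j}$, whose
squared norms partition one.

**3. Turbulence field and intensity.** Projecting each condition's curves
onto $\psi_{1j}$ (an inner product computed exactly in coefficient space)
gives, per window, a score vector $\xi_{\ell ij} \in \mathbb{R}^K$. The
collection over windows is a discrete spatio-temporal field, and the
turbulence intensity per participant and condition is the mean squared
adjacent-window difference
$$\mathcal{T}_{ij} = \big\langle \lVert \xi_{\ell ij} - \xi_{\ell+1,ij}
\rVert^2 \big\rangle_\ell ,$$
the rate of change of the dominant activity pattern. It is zero exactly when
the field is constant, scales as $c^2$ under amplitude scaling $c$, and for
a $K$-dimensional random walk with per-coordinate step variance $\sigma^2$
converges to $K\sigma^2$.

**4. Downstream analyses.** Three companions interrogate the field:

- *Scale invariance* (`fluctuation_profile`): the dominant modes are
  reconstructed over the whole recording by Gaussian-tapered overlap-add
  (half-window hop, taper SD = window/4), partitioned into non-overlapping
  segments at every divisor-based level between 0.002 s and half the
  recording, and the level-averaged root-mean-square fluctuations are fitted
  by a log-normal whose adequacy is judged by a parametric-bootstrap
  Kolmogorov–Smirnov test. For a 56-s recording at 1 kHz the divisor
  enumeration gives exactly 54 levels.
- *Departure from Gaussianity* (`enid_threshold`): per-window kurtosis
  coefficients of the pooled scores are compared against the Gaussian
  reference value 3; an entropic split of the inverse coefficients locates
  the kurtosis threshold separating the near-Gaussian regime from the
  turbulent one, and exceedance proportions are reported per condition.
- *Statistics* (`pairwise_wilcoxon_holm`, `friedman_kendall`,
  `wilcoxon_power_sim`, `fit_mixed_model`): paired two-sided Wilcoxon tests
  with Holm correction and effect size $r = |Z|/\sqrt{n}$, the Friedman
  omnibus with Kendall's $W = \chi^2 / (N(J-1))$, an empirical power
  simulation on heavy-tailed $\exp(1)-1$ noise, and REML mixed-effects
  models (random intercept per participant) for behavioral predictors of
  log intensity.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `window_length` | 500 / 100 ms | analysis window per band; resolves 1/length Hz (2 Hz alpha, 10 Hz gamma) |
| `hop` | 20 ms | window hop for the turbulence field |
| `p` | 8 (500 ms), 6 (100 ms) | B-spline dimension per condition; cubic order 4 |
| SSD margins | 2 / 4 / 1 Hz | signal widening, flank band-pass, flank band-stop |
| `width_factor` | 4 | Gaussian taper width (SD = window/4) in overlap-add reconstruction |
| `n_boot` | 1000 | KS bootstrap iterations |
| ENID `min_size`, `k` | 10, 3 | minimum split side, entropy neighbour order |

The basis dimension follows the principle of driving the fit RMSE toward
zero rather than a fixed rule: `fit_basis` reports per-curve RMSE, and $p$
should be grown until the RMSE is a small fraction (by default we check
against roughly 10% of the windowed signal SD) of the data scale. Cubic
splines with $p = 8$ on 500-ms windows and $p = 6$ on 100-ms windows meet
that criterion for band-limited signals at the study's sampling rate while
keeping the whitening well conditioned; both are configurable.

## Numerical choices

- **Whitening** floors covariance eigenvalues at $10^{-10}$ of the largest;
  optional spectral truncation (`rank`) exists but is off by default, since
  well-conditioned windows do not need it. Whitening requires more curves
  than coefficients ($NK > pJ$) and errors otherwise, advising a smaller $p$.
- **Sign conventions.** Eigenfunctions and spatial directions are defined up
  to sign; every eigenvector is canonicalized so its largest-magnitude entry
  is positive. Across consecutive windows the dominant mode is additionally
  aligned by flipping it when the inner product of its coefficients with the
  previous window's is negative — without this, adjacent-window differences
  (and hence intensity) would be ill-defined. A consequence is that negating
  the whole input leaves every intensity unchanged.
- **Perpendicular line method.** Distances are taken from each scree point
  to the chord joining the first and last; the elbow is the maximizing
  point, i.e. the first point of the scree floor, so the retained count is
  its index minus one. Collinear screes and screes with fewer than three
  points return 1 (ties break toward fewer components).
- **Cauchy PCA** is an iteratively reweighted eigendecomposition: sample
  weights $1/(1 + r^2/\gamma^2)$ on the orthogonal-residual norm $r$, with
  $\gamma$ a median-absolute-deviation scale refreshed each sweep;
  convergence when the direction moves less than $10^{-6}$ rad, at most 200
  sweeps (then the best iterate is returned with a warning). Exactly rank-1
  input converges immediately.
- **ENID scorer.** The split criterion seeks two maximally independent
  subsets of the inverse coefficients. We score a split by its *normalized
  entropy gain* — pooled Kozachenko–Leonenko entropy minus the size-weighted
  subset entropies, normalized by the pooled entropy — and maximize. A
  plain absolute entropy difference between the subsets was considered and
  rejected: on well-separated bimodal data a mid-cluster split leaves one
  side a high-entropy mixture, so the absolute difference peaks away from
  the between-mode gap, whereas the entropy gain peaks in the gap (this is
  easy to verify on synthetic bimodal fixtures). The scorer is a pluggable
  function argument, so alternative functionals drop in without touching
  callers.
- **Power simulation.** Each arm of a simulated pair is $\exp(1)-1$ noise,
  with the location shift added to one arm. The *difference* of two i.i.d.
  $\exp(1)-1$ draws is symmetric about the shift, so the signed-rank null is
  exact and the rejection rate at zero shift equals the significance level;
  simulating the differences directly from the skewed $\exp(1)-1$ law would
  break that calibration.
- **Signed-rank details.** Zero differences are handled by the Pratt method
  (ranked, then dropped with adjusted null moments); p values are exact when
  there are no zeros or ties and at most 50 pairs, otherwise the
  tie-corrected normal approximation is used. Effect sizes always use the
  normal-approximation $Z$.
- **Windows** are half-open in sample indices; trailing samples not covered
  by a full window are dropped. Gram matrices use per-interval
  Gauss–Legendre quadrature with as many nodes as the spline order, exact
  for the piecewise-polynomial products.

## The synthetic-data generator

`generate_dataset` emulates the study design the analysis targets: about 30
participants, 6 task conditions (combinations of singing, swaying and
virtual-agent interaction), 64 channels, 56-s recordings at 1 kHz. Sources
are i.i.d. innovations — Gaussian, or scaled Student-t for a prescribed
excess kurtosis — shaped by the band's Butterworth filter, mixed through a
fixed random spatial matrix, with broadband Gaussian noise at a configured
SNR. `inject_nonstationarity` multiplies each recording by a
regime-switching envelope (exponential holding times with mean $1/\ell$ s,
log-normal amplitudes with log-scale $0.5\,\ell$ at level $\ell$), the
controllable analogue of transient amplitude desynchronization: it raises
envelope kurtosis and, downstream, turbulence intensity monotonically.
`generate_behavioral_covariates` produces emotional engagement (Likert 1--5,
discretized-normal around a per-condition location), movement velocity rate
(log-normal, higher in movement conditions) and task demand (deterministic
1--3 by condition). The default covariate locations — engagement rising
with expressive/mirroring interaction, velocity with movement — encode the
qualitative structure such experiments report; their exact values are free
parameters of the simulation, since no printed summaries constrain them.

What the generator does *not* emulate: EEG artifacts (blinks, EMG, cable
sway), volume conduction and realistic electrode geometry, cross-condition
correlation of individual traits, or 1/f background spectra. Passing tests
on this synthetic family therefore demonstrates the estimator's correctness
and sensitivity under controlled ground truth, not robustness to real
recording contamination — artifact handling is assumed to have happened
upstream.

## Study-scale defaults versus test-scale runs

`simulation_config()` defaults document the study conditions (30 × 6 × 64 ×
56 000 samples); materializing that full array takes several gigabytes, so
study-scale analyses should stream per participant × condition. The test
suite and the acceptance script run the same code on reduced instances
chosen to keep every check sharp: typically 2--30 participants, 1--2
conditions, 4--8 channels, 200--1000 Hz, 2--8 s, basis dimensions 4--6, and
20--200 seeded replicates for Monte-Carlo properties. Dense-grid operator
oracles use 4000-point grids on $K \le 8$, $p \le 6$ instances, where the
discretization error is well below the $10^{-4}$ relative tolerance asserted.

## Known limitations

- The per-window kurtosis coefficient is measured along the direction that
  *maximizes* fourth-moment structure, so on finite Gaussian ensembles its
  mean sits above 3 (a selection bias that shrinks as the number of curves
  grows). Departure-from-Gaussianity thresholds should therefore be located
  by the entropic split on the empirical coefficients — which is what the
  pipeline does — rather than compared against 3 directly.
- With a 20-ms hop on 500-ms windows, adjacent windows share 96% of their
  samples: any abrupt regime change is smeared across ~25 window steps, and
  the squared-norm step difference localizes a switch sharply only when the
  within-regime dynamics are slow relative to the jump. Coarser hops
  localize better at the cost of temporal resolution.
- SSD eigenvalues are power ratios between differently wide filters, so
  their white-noise baseline is the filtered-power ratio (about 2 for the
  alpha defaults), not 1; selection uses only the scree shape, which is
  invariant to that baseline.
- Narrowband filtering gaussianizes i.i.d. heavy-tailed innovations, so
  source *innovation* kurtosis is a weak lever on downstream score
  kurtosis; nonstationary envelopes are the effective mechanism, which is
  also the physiologically plausible one.
- The scale-invariance bootstrap refits parameters per replicate; its power
  against short-tailed alternatives at 54 levels is moderate (it reliably
  detects them more often than the nominal rate, but not with overwhelming
  frequency), so non-rejection should be read as "log-normality cannot be
  ruled out", not as confirmation.
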