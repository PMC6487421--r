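---
title: "Hybrid PLS-LS-SVM calibration of ATR-IR spectra: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid PLS-LS-SVM calibration of ATR-IR spectra: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irspeccalib)
```

# The calibration problem

An ATR-IR spectrum of an aqueous pharmaceutical sample is an absorbance
vector over ~900 wavenumbers (4000–400 cm⁻¹ at 4 cm⁻¹ steps). The analyte
(iron, 0.5–25 mg L⁻¹) contributes weak bands that sit on top of dominant,
strongly overlapping water/excipient bands, and every spectrum carries its
own additive baseline offset and multiplicative scatter factor from crystal
contact and optics. The reference concentration comes from AAS, whose
response is linear in concentration over this range (Beer–Lambert regime).
The task is a multivariate calibration `spectrum → concentration` that is
validated well enough to stand in for the reference assay.

# The model chain

**SNV.** Each spectrum is transformed as
$\mathrm{SNV}(x)_i = (x_i - \bar{x}) / s_x$ with $s_x$ the *sample*
standard deviation over the $p$ wavenumbers (denominator $p-1$). SNV is
exactly invariant under $x \mapsto a x + b$ for $a>0$: per-sample baseline
offsets and multiplicative scatter are removed identically, which is the
property the tests assert rather than any approximate "improvement". SNV is
applied to the full data set *before* splitting, so baseline fluctuations
never masquerade as signal during sample selection. A constant (flat)
spectrum has no SNV image and is treated as a hard error naming the sample:
a flat spectrum means an upstream acquisition problem, and silently zeroing
it would poison every downstream distance and score.

**Kennard–Stone.** The calibration set is selected deterministically on the
SNV spectra: the first two samples are the pair at maximum Euclidean
distance; each next sample maximises its minimum distance to the selected
set. Ties are broken by the lowest original row index, so the split needs
no randomness. The selection is compared against an exhaustive greedy
oracle in the tests, not just spot-checked.

**NIPALS PLS1.** With one response, each component needs no inner
iteration: $w = X^\top y / \lVert X^\top y\rVert$, $t = Xw$,
$p = X^\top t/t^\top t$, $q = y^\top t/t^\top t$, then deflation
$X \leftarrow X - t p^\top$, $y \leftarrow y - q t$. The rotation
$R = W (P^\top W)^{-1}$ maps centred spectra straight to scores for new
samples. Each weight vector is sign-fixed (largest-magnitude element
positive) so results are identical across linear-algebra backends. If the
remaining covariance $\lVert X^\top y \rVert$ vanishes at component $a$,
fitting stops with an error reporting the achievable component count —
requesting more components than the data supports is a modelling error, not
something to paper over.

**LS-SVM on the scores.** The least-squares SVM replaces the SVM's
inequality constraints with equalities; training reduces to one symmetric
linear solve
$\begin{bmatrix}0 & \mathbf{1}^\top\\ \mathbf{1} & \Omega + I/\gamma\end{bmatrix}
\begin{bmatrix}b\\ \alpha\end{bmatrix} = \begin{bmatrix}0\\ y\end{bmatrix}$
with $\Omega_{ij} = \exp(-\lVert t_i - t_j\rVert^2 / 2\sigma^2)$. The
solution satisfies the KKT identities $\sum_i \alpha_i = 0$ and
$\alpha_i = \gamma (y_i - \hat y(t_i))$, which the tests verify on every
fit. The kernel uses the Gaussian parameterisation
$\exp(-d^2/2\sigma^2)$; the alternative $\exp(-d^2/\sigma^2)$ convention
differs only by a factor of two in the $\sigma^2$ grid. The LS-SVM is fit
on the *uncentred* response, with the bias $b$ absorbing the offset — the
simplest composition that keeps the KKT identities exact. Systems with an
estimated condition number above $10^{12}$ are rejected with a pointer
toward stronger regularisation rather than silently returning noise.

**Why the hybrid.** PLS compresses ~900 collinear, noisy channels into a
few informative scores; the RBF LS-SVM then models the mildly nonlinear
score–concentration relation that SNV's normalisation induces (see below).
Neither piece alone suffices in this world: linear PLS leaves the
nonlinearity on the table, and a kernel machine on raw 900-channel spectra
would have to learn the denoising itself.

# Tunable parameters

| parameter | units | default | rationale |
|---|---|---|---|
| `A` (latent variables) | count | scan 1–10, pick by LOO PRESS | parsimony rule below |
| `gamma` | dimensionless | grid $10^0..10^6$ | ridge weight $1/\gamma$; decade grid spans under- to near-interpolation |
| `sigma2` | score units² | grid $\{0.1,1,10,100\}\times$ median pairwise $d^2$ | median heuristic anchors the kernel to the realised score scale |
| `n_cal` | count | 158 (of 198) | the reference workflow's split |
| `lmo_fraction` | — | 0.2 | leave-many-out holdout share |
| `lmo_repeats` | count | 25 | each sample expected ≈ 5 holdouts at 20% |
| `n_permutations` | count | 100 | "several times" made concrete; 100 gives a 1%-resolution exceedance |

$(\gamma, \sigma^2)$ are chosen by leave-one-out PRESS of the full hybrid
on the calibration set only (the test set is never touched), at the
midpoint of the LV scan range, and then held fixed across the LV scan, all
cross-validation folds and all permutations. Full nested re-tuning per fold
would be more conservative but is out of scope; holding the pair fixed
matches the granularity at which such calibrations are built in practice
and keeps every quoted Q² attributable to one model. Ties in the grid go to
the smallest $\gamma$, then the largest $\sigma^2$ — the most strongly
regularised candidate.

**LV selection** computes LOO PRESS for each candidate count and picks the
*smallest* A whose PRESS is within 5% of the minimum. A pure argmin happily
buys a component for a 0.1% PRESS change; the 5% band encodes "a component
must earn its keep" and is this package's rule — the underlying study
simply reports its best count.

**Q² convention.** Cross-validated r² is computed against the mean of the
full calibration response, not per-fold training means — the common
chemometrics convention, and the one that makes LOO and LMO Q² directly
comparable.

# The synthetic world

`synthetic_config()` states the world the pipeline is verified in:

- 198 samples, concentrations stratified-uniform over 0.5–25 mg L⁻¹ (one
  draw per equal-width bin, shuffled — bench-style coverage of the range);
- grid 4000→400 cm⁻¹, step 4 (901 channels, instrument-native descending);
- three overlapping analyte bands (1430/1240/1060 cm⁻¹, σ = 60/45/50,
  amplitudes 0.012/0.018/0.015 au per mg L⁻¹);
- three dominant matrix bands (1425/1235/1065 cm⁻¹, σ = 75/60/70,
  amplitudes 1.0/0.7/0.8 au) whose per-sample levels are
  $z_k \sim N(1, 0.12)$ — formulation-to-formulation excipient variation;
- per-sample baseline $N(0, 0.005)$ au, scatter $N(1, 0.1)$ truncated at
  0.1, channel noise $N(0, 0.001)$ au (~what 128 co-added scans deliver);
- an AAS channel $a = 0.032\,c + 0.001 + N(0, 0.002)$, inverted back to the
  modelling response $c_\mathrm{ref} = (a - 0.001)/0.032$ — the response
  the model sees carries reference-method noise, as in reality.

**Why three matrix bands.** SNV maps
$v = c\,\mathbf{a} + \sum_k z_k \mathbf{g}_k$ (after removing baseline and
scatter exactly) to a *scale-free* object: $v$ and $\lambda v$ have the same
SNV image. The post-SNV data manifold therefore has one dimension fewer
than the number of independent source levels. Concentration is only
recoverable *relative to* the matrix bands — they are the internal
standard, and their level variability (12%) sets the accuracy floor. With
two matrix bands the manifold is two-dimensional and two latent variables
plus a flexible kernel are information-complete; the LV selector then
honestly picks A = 2. Three matrix bands give a three-dimensional manifold:
one latent variable confounds iron with matrix fluctuations (the
under-fitting the validation tables show), three resolve all sources, and a
fourth adds nothing. This is a deliberate design choice of the package's
stated world, made so that the qualitative validation pattern — 1 LV fails,
3 LVs work, external prediction holds — emerges from the physics rather
than from tuned thresholds.

**What the generator does not emulate:** ATR penetration-depth dispersion,
water-background subtraction artifacts, instrument drift, within-replicate
correlation (replicates are independent samples), Lorentzian/Voigt line
shapes (Gaussian bands suffice — the calibration math never sees the shape),
and detector nonlinearity. A green end-to-end test therefore establishes
that the *pipeline* recovers a recoverable world; it does not certify any
particular laboratory instrument.

# Numerical choices and degenerate inputs

- CSV round trips write 17 significant digits; read→write→read is
  bit-stable, and tests assert identity, not closeness.
- All randomness flows from one config seed through per-operation derived
  sub-streams (`seed`, operation tag), so regenerating any single stage
  reproduces it without replaying the whole pipeline; derived seeds stay
  below $2^{31}$.
- Kennard–Stone and NIPALS tie-breaks are index-based and sign-convention
  based respectively — no seed, no backend dependence. The initial
  Kennard-Stone pair is reported in index order; its internal order is the
  only part of the selection that is not row-order invariant.
- Degenerate inputs fail loudly with the offending sample/component named:
  constant spectra (SNV), constant responses (PLS), exhausted covariance
  (PLS rank), ill-conditioned duals (LS-SVM), non-numeric CSV cells with
  row/column coordinates.
- JCAMP-DX support is deliberately limited to plain AFFN numeric tables;
  compressed encodings are rejected with a clear message rather than
  half-parsed.

# Runtime scaling in the tests

The acceptance tests run the full 198-sample default once and reuse it: the
permutation criterion uses B = 50 scrambles recording training r² (the
quantity that criterion examines) without per-permutation cross-validation,
and byte-determinism is demonstrated by running a reduced 60-sample
configuration twice. The full report with per-permutation LOO/LMO Q²
(`permutation_cv = TRUE`, the default in `pipeline_config()`) is the
production path and is exercised on a small world in the unit tests.

# Known limitations

- Hyperparameters are tuned once on the calibration set, not nested within
  each CV fold; Q² values are therefore mildly optimistic in the usual way.
- The LMO rounds are Monte-Carlo, not exhaustive; 25 rounds bounds the
  Monte-Carlo error of Q²_LMO but does not eliminate it.
- The permutation test reports an empirical exceedance over B scrambles; it
  is a sanity certificate, not a calibrated p-value.
- The package models absorbance spectra; transmittance input must be
  converted upstream.
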