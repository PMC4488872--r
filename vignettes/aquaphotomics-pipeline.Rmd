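---
title: "Aquaphotomic calibration and class modeling of NIR water spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aquaphotomic calibration and class modeling of NIR water spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquaphot)
```

## The measurement problem

Dilute solutes in water — here, short DNA oligonucleotides and the
cyclobutane thymine dimers (T\<\>T) that UVC irradiation produces in them —
are present at micromolar concentrations, far below anything their own
overtone bands could reveal in a near-infrared spectrum. Aquaphotomics
turns this around: the 1300–1600 nm first overtone of water is a dense
superposition of O–H stretch bands whose relative weights shift with the
hydrogen-bonding state of the water matrix, and solutes perturb that
state. A calibration therefore reads the *water* spectrum, and the
water-band pattern of the resulting regression vector is the evidence
that the model uses solute-driven water structure rather than baseline
artifacts.

`aquaphot` implements that workflow end to end: spectra I/O,
pretreatment, latent-variable calibration and class modeling,
cross-validated error metrics, water-band annotation of model vectors,
and a synthetic-spectra generator that stands in for instrument data.

## Models and procedures

### Pretreatment

The fixed processing order is **smoothing → wavelength selection → (per
validation fold) mean centering → OSC → model**. Smoothing before
windowing lets the window boundaries see real neighbours instead of
reflected ones wherever possible; both steps are sample-wise, so they can
safely happen outside cross-validation. Two kernels are provided,
boxcar (`moving_average`, the default, matching the windowed-mean
"smooth" transforms of spectroscopy packages) and quadratic local
least squares (`polynomial_order2`); both accept the 21- and 45-point
windows typical of NIR work. Row ends are mirrored about the end points
(reflection padding) so the grid never shrinks.

**Orthogonal signal correction** removes, one component at a time, the
dominant spectral variation orthogonal to the centered response. The
Wold-style iteration is: start from the first principal-component score,
orthogonalize it against the response, regress a weight vector through
the tolerance-rank SVD pseudo-inverse of the spectra, renormalize, and
iterate the score to a fixed point (relative change below 1e-10, at most
500 iterations). For centered spectra with many more wavelengths than
samples the orthogonalized score already lies in the spectra's column
space, so the fixed point is y-orthogonal to machine precision — the
property the tests assert as a cosine below 1e-8. Two degenerate regimes
are handled explicitly: spectra numerically proportional to the response
(nothing orthogonal to remove — the component collapses to a null
direction and deflation removes essentially nothing) and scores so far
below the spectral scale that a deflation loading would only amplify
rounding noise (the loading is set to zero).

Because OSC uses the response, it is **always refit inside each
cross-validation fold**; fitting it once on the full data set would leak
the held-out response into the fold model.

### Calibration models

PLSR is classical NIPALS PLS1 with y-deflation: per factor, weight
`w ∝ X'y` (unit norm), score `t = Xw`, loadings `p = X't/(t't)` and
`q = y't/(t't)`, deflation of both blocks, and the regression vector
`b = W(P'W)⁻¹q`. y-deflation does not change PLS1 predictions but fixes
the score sequence, which makes score-level tests exact. PCR regresses
the centered response on the leading PCA scores; because those scores
are orthogonal, per-component slopes are independent and the nested
coefficient vectors used in factor selection accumulate component by
component. PCA itself is a deterministic SVD with each component's sign
fixed so its largest-magnitude loading element is positive — no
iterative eigen-solver, hence bit-stable tests.

PLS-DA is PLS1 on a centered 0/1 dummy; a prediction above 0.5 assigns
the class coded 1, below 0.5 the class coded 0, and exactly 0.5 is left
unassigned. Only two classes are supported.

### SIMCA

Each class gets its own mean and PCA submodel. The pooled residual
standard deviation of class *i* projected on class *j*'s submodel uses
`n_i (m − k_j)` degrees of freedom for cross fits and
`(n_i − k_i − 1)(m − k_i)` for self fits — the self fit spends `k` + 1
degrees of freedom on its own scores and mean. A consequence worth
knowing: for literally identical classes the cross/self ratio is
`sqrt((n−k−1)/n)`, not exactly 1, which is why the identical-class
checks assert distance `1 ± 0.2` and discriminating power `≈ 1` rather
than exact unity.

New samples are accepted by a class when the variance ratio of their
residual to the class residual passes an F-test at the 0.95 quantile
(configurable). Score-range (leverage) limits are deliberately not
applied: the residual distance is the common core of the published SIMCA
variants, and the choice is recorded in the model's `variant` field
rather than asserted to match any proprietary implementation. The
interclass distance is the plain square-root residual ratio with null
value 1 (not the "−1" variant — also flagged in `variant`), and
classification is scored strictly: a sample counts as correct only when
accepted by its true class and no other; multi-accepted and unaccepted
samples count as incorrect.

### Validation metrics

`SEC = sqrt(RSS_cal / (n − k − 1))` — the intercept absorbed by mean
centering consumes one degree of freedom beyond the `k` latent
variables — and `SECV = sqrt(RSS_cv / n)`; both conventions are recorded
in every result so alternative df choices can be compared. The factor
cap is one tenth of the sample count (`max_factors`), the optimum factor
count is the SECV argmin with ties to fewer factors.

## The water band table

`default_band_table()` carries the fifteen first-overtone bands C1–C12
and W1–W3 with their species assignments (S0–S4 denote water molecules
with 0–4 hydrogen bonds). Intervals are closed and may overlap (C1/W1
overlap; C10 and C11 share 1482 nm), so annotation maps a peak to
*every* containing band and never tie-breaks — consistent with how such
peaks are attributed to several species in practice. Peak detection
works on signed vectors (regression vectors, discriminating power):
local maxima of the values and of their negation, filtered by
topographic prominence relative to the largest absolute value (default
threshold 0.1, exposed in the config). Note that the valley between two
positive bumps is itself a legitimate low-amplitude negative extremum
under this contract.

## The synthetic generator

`simulate_dataset()` emulates the statistical structure the analysis
assumes, not water physics. Per sample:

absorbance(λ) = baseline(λ) + Σ_b effect_b · driver · g_b(λ)
  + offset + slope·(λ − λ_mid) + amp·confounder(λ) + noise(λ)

* the **baseline** is a fixed broad Gaussian at 1450 nm (1 AU, sd 60 nm)
  plus twelve 0.05-AU sub-bands (sd 8 nm) at the C-band midpoints — at
  that width, neighbouring sub-bands 10–14 nm apart merge into composite
  humps, as real overtone sub-bands do;
* **drivers** are the DNA concentration and the generated dimer
  concentration; each contributes unit-peak Gaussians at its configured
  band centers (sd = band half-width / 2). The default signs encode the
  qualitative picture the generator is meant to reproduce: DNA raises
  the free-water band C5 and lowers the strongly hydrogen-bonded band
  C11; dimer formation does the reverse. Magnitudes (4e-4 and 5e-3
  AU/µM) are generator conventions chosen to give realistic model
  quality at the default noise, not physical claims;
* the **dimer reference** is `tt = yield · dose · dna + ε`, ε Gaussian
  truncated at zero. The default yield (0.005 µM per kJ/m² per µM DNA)
  and noise sd (0.14 µM) were set from the closed-form expectation
  `1 − R² = sd² / (sd² + slope²·var(dose))` so that a 10-sample
  dose-series fit lands near R² ≈ 0.87 at 10 µM and ≈ 0.97 at 20 µM
  DNA — the range typical of HPLC dose–response determinations;
* the **confounder** is a broad band at 1750 nm whose per-sample
  amplitude is drawn independently of all drivers — the component OSC
  exists to remove. It lives outside the 1300–1600 nm window on purpose:
  analyses windowed to the first overtone are insensitive to it, while
  full-range (1100–1850 nm) analyses must deal with it;
* **draw order is fixed and documented** (dimer noise for all samples,
  then per sample: offset, slope, confounder amplitude, noise vector),
  and every draw is a standard normal scaled by its sd afterwards, so
  the random stream — and hence the output at a given seed — does not
  change when an sd is set to zero.

What passing tests on this generator do *not* show: real spectra have
temperature-sensitive band positions, multiplicative path-length
effects, wavelength-correlated noise and batch structure far richer than
a linear drift plus one confounder shape. The generator demonstrates
that the pipeline recovers what it is designed to recover under its own
assumptions; it cannot certify performance on instrument data.

## Numerical choices and degenerate inputs

* Wavelength grids must be strictly increasing with spacing constant to
  1e-9 nm; windows are closed intervals with a 1e-9 nm tolerance at the
  end points.
* SVD everywhere a decomposition is needed; pseudo-inverses use a
  relative singular-value cutoff of 1e-10 (OSC inner regression) or
  1e-12 (test oracles).
* PLS factor loops fail loudly (`rank error`) when the response
  covariance or score variance collapses, rather than returning silently
  truncated models.
* Ties: factor selection prefers fewer factors; SIMCA nearest-class ties
  break to the first class in model order; a PLS-DA prediction of
  exactly 0.5 is unassigned.
* Zero-variance responses, single-sample centering, undersized SIMCA
  classes and empty wavelength intersections raise typed errors
  (`aquaphot_*_error` classes) that the pipeline propagates with stage
  context.

## Design decisions that were genuinely open

* **File dialect**: plain delimited text with a numeric wavelength
  header and reserved metadata column names — transparent and diffable;
  vendor binary formats are out of scope.
* **Smoothing kind**: the windowed mean is the default because that is
  what spectroscopy "smooth" transforms conventionally do; the quadratic
  kernel is available where peak shapes must survive smoothing.
* **SIMCA variant flags**: acceptance threshold, distance formula and
  the absence of leverage limits are recorded in every model/report
  (`variant`), because SIMCA implementations differ on all three and
  results are only comparable when the variant is known.
* **"Active class" / group validation**: implemented as
  leave-one-group-out over class or batch labels
  (`group_holdout_validate`) — a documented stand-in, since no public
  definition of the vendor scheme exists. With one group per sample it
  reduces exactly to LOO.
* **Replicate handling**: every row of a spectra table is treated as one
  observation; no replicate averaging is performed or assumed.
* **CLI**: a thin `Rscript` wrapper (`inst/exec/aquaphot`) over
  `cli_main()`; the package functions are the primary interface, and
  reports are written atomically (temp file + rename) so a failed run
  leaves nothing partial.

## Problem sizes

The shipped tests and the acceptance script run on deliberately modest
problems — 16–40 samples on 601- or 1501-point grids, 20-replicate
comparison studies, 200-sample null checks for SIMCA — sizes at which
every cross-validation fold refits the full pipeline in milliseconds and
the whole suite completes in well under a minute. These sizes mirror the
sample counts of the experimental designs the package targets (tens of
solutions per series), not an implementation limit.

## Known limitations

* PLS-DA is strictly two-class; SIMCA handles any number of classes.
* No MSC/SNV/derivative pretreatments, no venetian-blind or k-fold CV,
  no permutation testing — only the methods in the supported workflow.
* The synthetic generator is linear in its drivers by construction;
  nonlinear solute effects are outside its vocabulary.
* Interclass distances and discriminating power are formula variants
  (flagged as such); absolute values are not comparable across SIMCA
  implementations using different residual-df or distance conventions.
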