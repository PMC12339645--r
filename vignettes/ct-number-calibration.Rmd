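---
title: "Stoichiometric CT-number calibration and the brain-plug problem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stoichiometric CT-number calibration and the brain-plug problem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctcal)
```

## The problem

Photon dose calculation in a treatment planning system corrects for tissue
inhomogeneity through a CT-number-to-relative-electron-density/mass-density
(CT-RED/MD) conversion table, calibrated by scanning tissue-equivalent
plugs of known composition. The brain-equivalent plug in common calibration
phantoms mimics brain *density* (1.05 g/cm³) well, but its chemistry is
very different from real brain parenchyma: it is a carbon-dominated solid,
whereas brain is essentially oxygen-dominated soft tissue. `ctcal` provides
the full chain of desk computations needed to audit this mismatch: mixture
descriptors (effective atomic number, electron density), a stoichiometric
CT-number model, conversion-table surgery, synthetic phantom images with
ROI statistics, and DVH metric comparison.

## Mixture descriptors

For a material with mass fractions $\omega_i$ (percent by weight), atomic
numbers $Z_i$ and atomic weights $A_i$:

- **Relative electron density**
  $\rho_e = \rho \sum_i \omega_i Z_i/A_i \,/\, (\rho_w \sum_i \omega_i
  Z_i/A_i)_{water}$ — electrons per unit volume normalized to water. It is
  exactly 1 for water, and linear in mass density at fixed composition.
- **Effective atomic number**
  $Z_{eff} = \left(\sum_i \lambda_i Z_i^m\right)^{1/m}$ with electron
  fractions $\lambda_i = (\omega_i Z_i/A_i)/\sum_j \omega_j Z_j/A_j$.
  The exponent `m = 3.3` (the package default) weights the compromise
  between Compton scattering ($\propto Z$) and the photoelectric effect
  ($\propto Z^{4...5}$) at the 50–60 keV effective energy of a 120 kV scan.
  $Z_{eff}$ is invariant under rescaling all fractions and always lies
  between the smallest and largest $Z$ present.

Atomic weights are the IUPAC standard (conventional) values, shipped as a
packaged CSV; the community default when a composition table does not state
its source. Compositions are validated (non-negative fractions, known
symbols) and normalized to sum to exactly 100; a raw sum outside [90, 110]
is rejected as a transcription error rather than silently rescaled.

Elements reported only qualitatively in an elemental analysis (e.g.
"< 0.01 %", or detected by X-ray fluorescence without a printed value) are
**excluded** from the packaged plug composition: only printed values are
treated as ground truth. `with_trace_elements()` lets you add hypothesised
trace fractions for sensitivity analysis — high-Z traces (Ti, Ba) pull
$Z_{eff}$ and the predicted CT number up noticeably, which is the likely
reason a plug's published effective atomic number can sit slightly above
what its printed major-element composition alone yields.

## The stoichiometric CT-number model

The model predicts a CT number from composition and density alone, so a
calibration fitted on a few measured plugs can be evaluated for any
tissue. Attenuation relative to water is parametrized with two power sums,

$$u = \rho_e \cdot
   \frac{1 + k_1 S_{1.86} + k_2 S_{3.62}}
        {1 + k_1 S_{1.86}^{w} + k_2 S_{3.62}^{w}},
  \qquad S_p = \sum_i \lambda_i Z_i^p,$$

where the exponent-1.86 term tracks coherent scattering and the
exponent-3.62 term the photoelectric effect, and Hounsfield conversion is
$HU = \alpha \cdot 1000\,(u - 1)$.

Two conventions here were genuinely open and are the package's design
choices:

- **Pairing of the weights with the exponents.** With weights of magnitude
  $k_1 \sim 10^{-3}$, $k_2 \sim 10^{-5}$, only the pairing
  ($k_1 \to S_{1.86}$, $k_2 \to S_{3.62}$) gives both terms comparable,
  physically plausible contributions for water (each a few percent of the
  cross section); swapping them makes the photoelectric term dominate by
  an order of magnitude and pushes soft-tissue predictions to absurd CT
  numbers. The adopted pairing is confirmed in the test suite against an
  independent brute-force implementation.
- **Placement of $\alpha$.** $\alpha$ scales the HU *contrast*, leaving
  water pinned at exactly 0 HU for any parameters. The alternative
  (scaling $u$ itself) would shift water off zero, contradicting the
  (0 HU, RED 1) anchor every clinical conversion table carries.

### Fitting

`fit_scc()` minimizes the sum of squared HU residuals over
$(k_1, k_2, \alpha)$ with the Nelder–Mead simplex (`stats::optim`), the
standard derivative-free choice for this small, smooth problem. Numerical
choices:

- Parameters are internally rescaled to comparable magnitudes
  ($k_1 \times 10^3$, $k_2 \times 10^5$, $\alpha$), without which the
  simplex collapses along the tiny-$k_2$ axis.
- Start point $(10^{-3}, 3\times10^{-5}, 1.0)$ — the physical regime for
  diagnostic beam qualities; objective tolerance $10^{-10}$ HU²; total
  iteration budget 10,000.
- The simplex is restarted from its own optimum until the objective stops
  improving by more than the tolerance; this reliably drives noiseless
  round-trip fits to parameter recovery at $10^{-3}$ relative error or
  better (verified over 20 random ground truths in the tests).
- Negative $k$ or non-positive $\alpha$ are repelled by a penalty rather
  than a hard constraint, keeping the simplex moves simple.
- Fewer than 3 points is an error (underdetermined); exactly 3 points —
  the air/lung/bone set a minimal phantom calibration provides — is
  accepted but flagged with a warning, because air pins little beyond the
  overall HU scale and the two cross-section weights are then weakly
  determined. Non-convergence within the budget is reported as
  `converged = FALSE`, not an exception.

## Conversion tables

A `ct_conversion_table` is an ordered set of (HU, RED, MD) knots. CT
numbers must be strictly increasing (ties are hard errors); non-monotone
RED/MD only warn, since real clinical tables occasionally interleave
near-water materials. Lookup is linear interpolation in HU for both
branches — the behaviour planning systems implement — and clamps to the
terminal knots outside the range so artifacts can never produce negative
densities.

The packaged clinical table contains only the knots whose printed source
values are unambiguous, plus a best-effort brain-plug knot that is
annotated (`material=BDP`) and explicitly flagged as uncertain in the
file's comments; its exact clinical HU was not reliably legible in the
source document. Knot annotations are carried in a `material` CSV column
(with the variant in a `# variant=` header comment), which keeps the
write–read–write round trip byte-identical.

`modify_table()` produces the two variants whose dose impact one wants to
audit: removing the plug knot (lookups change only inside the open
interval between its former neighbours — the mechanism that keeps the dose
impact small), or re-anchoring the knot at a better brain CT number, e.g.
the stoichiometric prediction for the ICRP 110 reference brain. A
replacement that would cross a neighbouring knot is rejected.

## What the synthetic data emulate — and what they do not

No image or dose data ship with the package; everything is generated.

- **Phantom slices** (`generate_phantom_image()`): homogeneous circular
  plugs in a background, each pixel drawn independently from a Gaussian
  with its region's mean/SD. This reproduces the first-order statistics a
  plug ROI measurement sees (means, SDs, histogram spread) and is exactly
  piecewise-constant at zero noise and bit-reproducible under a fixed
  seed. It does **not** model CT physics: no projections, reconstruction
  kernels, beam hardening, partial-volume edges, or spatially correlated
  noise. Passing ROI tests therefore validate the *statistics pipeline*,
  not scanner realism.
- **ROI analysis**: pixel-center containment for the circular mask (the
  common DICOM-tooling convention; no partial-volume weighting), default
  diameter 1.53 cm as used for plug readings. The ROI SD is the population
  SD (divide by $n$): with $n \approx 18\,000$ pixels in a default ROI the
  distinction from $n-1$ is far below reporting precision, but the choice
  is fixed and documented. Histogram bins default to 5 HU, aligned to
  multiples of the bin width over the observed range, so counts always sum
  to the pixel count.
- **Cohort aggregation** (`summarize_cohort()`): the overall mean is the
  mean of per-case means and the overall SD the mean of per-case SDs —
  the reporting convention of multi-patient CT-number audits — not a
  pooled, volume-weighted SD.
- **Dose grids** (`generate_dose_grid()`): uniform, linear-ramp and
  spherical-falloff patterns with closed-form DVHs, so the DVH reader can
  be checked against analytic truth. `compare_tables_dose()` perturbs the
  grid by the ratio of the mass densities two tables assign to a
  brain-like CT number — a deliberate first-order stand-in for a dose
  engine, adequate for exercising the comparison arithmetic but *not* a
  dose-calculation algorithm; real engines (convolution/superposition,
  LBTE solvers) respond far more weakly than proportionally to a small
  density change.

## DVH metrics

`cumulative_dvh()` evaluates $V(d) = 100\cdot\#\{D_v \ge d\}/n$ on a
regular axis (default bin 0.01 Gy — discretization error well below the
0.1% differences of interest). $D_{x\%}$ is read by linear interpolation
at the crossing of the volume level $x$; on plateaus the left edge of the
crossing bin is taken. Quantile monotonicity ($D_{98\%} \le D_{50\%} \le
D_{2\%}$) holds by construction. Relative differences use
$\Delta D = (D_{mod}-D_{ref})/D_{ref} \times 100$ with a positive
reference required. Report SDs across cases use the sample convention
($n-1$), matching case-level audit tables; the per-plan coverage metric
(`D_reference`) is treated as externally supplied, since its definition is
protocol-specific.

## Problem sizes

The test suite and examples run at deliberately compact sizes: 220×440
phantom slices (ROI of ~18,000 pixels at 0.01 cm spacing, enough for the
central-limit and $\chi^2$ bounds asserted), 40³ dose grids, 20-seed
parameter-recovery sweeps, and five-material calibration sets spanning
lung-like to bone-like compositions. These sizes put every statistical
assertion comfortably in its asymptotic regime while keeping the whole
suite fast.

## Known limitations

- The stoichiometric model is the fitted two-term effective form; no
  polyenergetic spectrum, beam-hardening or energy-resolved cross sections.
- Whole-brain tissue is treated as a single material (white/gray matter
  are not distinguished), following the reference-phantom convention.
- The packaged plug composition carries only printed major elements;
  undetermined traces are a genuine source of a few HU / a few tenths of a
  $Z_{eff}$ unit of uncertainty, exposed via `with_trace_elements()`
  rather than guessed.
- Dose propagation is a density-scaling surrogate; conclusions about
  clinical dose impact require a real dose engine on real plans.
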