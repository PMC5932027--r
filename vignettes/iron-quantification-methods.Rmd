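---
title: "Methods: multi-technique quantification of tissue iron forms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-technique quantification of tissue iron forms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ironforms)
```

This vignette documents the models implemented by `ironforms`, the
assumptions behind them, the numerical choices that were genuinely open,
and what the synthetic-data tests do and do not demonstrate about real
tissue data.

## The measurement problem

Iron in cortical tissue is not one analyte.  The pools that dominate the
magnetic signal are (i) mononuclear high-spin Fe(III) in low-symmetry
sites, visible as the g′ = 4.3 EPR resonance; (ii) ferrihydrite, the
antiferromagnetic mineral core of ferritin, carrying a small uncompensated
moment; and (iii) magnetite/maghemite nanoparticles with large blocked
moments.  Each is probed by a different physics: the EPR transition
amplitude counts paramagnetic spins, low-temperature remanence isolates
blocked particle populations, and the aggregate of all perturbers
shortens the MRI R2\*.  The package treats each probe with its own forward
model and joins them at the subject level.

## Relaxometry

Each voxel of the multi-echo magnitude stack is modelled as a pure
exponential `y = A exp(-TE * R2*)`, with no offset term: the four echo
times (12.5–44.6 ms) cannot constrain a baseline, and the acquisitions
this pipeline targets decay well into the noise floor only at much longer
TE.  The default estimator is a log-linear regression weighted by the
squared signal, which is the Gauss–Markov weighting for log-transformed
data with intensity-proportional absolute noise, is exact on noiseless
input, and has no convergence failure mode — a practical advantage when
fitting tens of thousands of voxels with only four samples each.

Magnitude MRI noise is Rician, and the log-linear estimator inherits two
biases at moderate SNR: the Rician floor inflates late echoes, and the
log transform is convex.  At SNR 20 the combined systematic error of the
log-linear ROI median is about 4%; the Levenberg–Marquardt refinement
(`method = "nonlinear"`) removes the log-transform part and brings it to
about 1%, so the pipeline uses the refinement whenever MRI noise is
nonzero.  No Rician bias correction is applied beyond that: raw
magnitudes are fitted and the residual low-SNR bias is documented here.
The per-voxel random error at SNR 20 is ~11% — essentially the
Cramér–Rao bound of the 4-echo design — which is why the subject-level
summary is the ROI **median**, whose error at ordinary ROI sizes is an
order of magnitude smaller and robust to outlying voxels.  Negative
fitted rates can occur under noise; they are retained and flagged rather
than clipped, so the ROI median is not biased upward.  ROI masks are
user-supplied: hypointense-band-guided manual ROI drawing is not
automatable, and tests use rectangular helper masks.

## EPR simulation and quantification

The S = 5/2 spin Hamiltonian with Zeeman, axial (D) and rhombic (E)
zero-field-splitting terms is represented exactly as a 6×6 complex
Hermitian matrix.  For each powder orientation, resonance fields are the
roots of `E_j(B) − E_i(B) = hν`, located by scanning eigenvalues on a
1 mT grid and refining every sign change by bisection to 10⁻⁴ mT.  This
search is validated in the test suite against an independent dense-grid
eigen-decomposition scan.  Transition weight combines the squared
perpendicular (g-weighted) spin matrix element averaged over the two
microwave polarizations, the Boltzmann population difference at the
measurement temperature (12 K: with D ≈ 1 K the doublet populations are
far from equal, so this matters), and the 1/|d(ΔE)/dB| factor that maps a
frequency-swept line into a field-swept one.

Powder averaging uses a deterministic Fibonacci spiral restricted to one
octant (the Hamiltonian is invariant under sign flips of the field
components), 400 orientations by default — reproducible without
quadrature tables, and doubling the count changes the double integral by
well under 1%.  g-strain enters to first order as a per-orientation
Gaussian field broadening with width `|∂B_res/∂g_k| σ_gk` summed in
quadrature over the three principal axes, the derivatives obtained from
Hellmann–Feynman expectation values at the resonance; an intrinsic
residual width (default 1.5 mT standard deviation) keeps zero-strain
systems well posed.  The 6 G peak-to-peak modulation amplitude (0.6 mT)
is not convolved: it is small against the strain-dominated linewidths of
this system.  The first derivative is taken analytically on the broadened
absorption.

Quantification deliberately does **not** refit the spin Hamiltonian per
sample: one fixed parameter set describes the tissue signal, so only an
amplitude and a linear baseline are estimated per spectrum (a linear
least-squares problem with a non-negativity guard on the amplitude).
Fe(III) concentration then follows from the ratio of second integrals
against an Fe-EDTA reference of known concentration, normalized per wet
gram.  This assumes matched acquisition conditions between sample and
reference; a temperature mismatch triggers a warning rather than an
automatic Curie-law correction.  Field ranges and sweep parameters of the
source acquisitions are not published; the default axis (50–350 mT)
brackets the g′ = 4.3 line with generous margins.  Native Bruker file
formats are out of scope (two-column text plus a JSON sidecar is the
exchange format).

## Magnetometry

IRM curves are fitted to the Langevin model with temperature and
saturation magnetization fixed, estimating the mass fraction `f`, the
mean particle moment `μp` and a constant background.  All internal units
are CGS-Gaussian (emu, gauss, erg) because the saturation magnetizations
and instrument specifications are conventionally quoted that way;
`x = μp H / (kB T)` is dimensionless by construction and `μp` is reported
in Bohr magnetons (μB = 9.274×10⁻²¹ erg/G).  A single mean moment is
fitted rather than a moment distribution — one moment per sample is what
the downstream statistics consume.  Start values come from the curve
itself (background from the lowest field point, fraction from the
high-field plateau, moment from the half-saturation field via x ≈ 1.6);
with these, the Levenberg–Marquardt fit recovers noiseless synthetic
curves to solver precision and is insensitive to the start heuristics.
A degenerate flat curve short-circuits to `f = 0` with a missing moment.

The 100 K curve (blocked magnetite/maghemite; Ms = 84 emu/g, a
particle-size-appropriate literature value between the 5 nm and bulk
limits) yields the magnetite/maghemite concentration in ng/g dry weight;
the 5 K curve (ferrihydrite; Ms = 0.62 emu/g) yields ferrihydrite in
µg/g dry weight.  IRM cannot distinguish magnetite from maghemite and the
package does not attempt to.  Curves whose 100 K peak-to-peak moment is
below `threshold × noise floor` (default 4 × 10⁻⁸ emu, the RSO probe
specification; the boundary case counts as usable) are discarded: the
concentration is reported as zero and the moment as missing, and the
statistics layer excludes those moments pairwise.

The ferritin loading factor inverts `μp = 5.92 μB LF^α`.  The exponent is
only constrained to 0.5–0.6 by theory; the package defaults to α = 0.5
and exposes it in the configuration, so reports can carry the LF interval
over the full α range.  LF is capped at the 4500-atom core capacity with
a warning.

## Statistics

The statistics layer mirrors a conventional two-group cohort analysis.
Mean tests use the pooled-variance Student's t-test by default — matching
the naming conventions of the analyses this package reproduces — with
Welch's test behind a flag, since which variant older reports used is
often unrecoverable; both can be reported.  Variance homogeneity uses the
Brown–Forsythe Levene-type test (one-way ANOVA on absolute deviations
from group medians).  Demographics use Mann–Whitney (age) and chi-square
(sex).  Correlations are Spearman, computed on untransformed data;
p-values use the t approximation, replaced below n = 10 by exact
enumeration of the permutation null.  Two correlations are compared with
the Fisher-z studentized difference and a two-tailed normal test.
Partial correlations are rank-based first-order recursions with a t test
on n − 3 degrees of freedom (Pearson behind a flag).  No multiple-testing
correction is applied across the correlogram, by design parity with the
analyses being reproduced.

Outlier screening automates what is normally a visual-plus-formal-test
decision.  The screen uses the chi-square dispersion statistic
`(x_ext − mean)² / var` of the most extreme point, but assigns it the
calibrated maximum-studentized-deviation (Grubbs) p-value — the raw
chi-square tail probability ignores that the point was selected as the
maximum and would flag ~30% of clean samples.  With the calibrated
p-value the screen has an empirical type-I rate of 5%, verified by
simulation in the test suite.  Screening iterates at most twice and only
flags; removal is the caller's decision.  Braak stratification pools
controls at stage ≤ 3 and reports per-stratum summaries without a formal
trend test.

## The synthetic cohort generator

The generator is the package's test instrument: it emulates the joint
statistical structure of a two-group post-mortem cohort (22 AD / 14
control by default) and produces raw signals consistent with each
subject's ground truth, so that every fitting stage can be checked by
parameter recovery, end to end.

Marginals are specified on the reported scale and are exactly
moment-matched: Fe(III) and the particle moments are lognormal (Fe(III)
requires a log₁₀ transform for normality, so a lognormal marginal is the
consistent choice); R2\* and ferrihydrite are normals truncated at zero
whose underlying parameters are solved numerically so the *truncated*
moments hit the targets; magnetite/maghemite is generated on the
log₁₀(x + 100) scale — i.e. a shifted lognormal — clamped at zero, again
with numerically re-solved parameters, so that the atom at zero mirrors
real below-detection samples while the clamped mean/SD match the targets
exactly.  Only pairwise Spearman targets are published, so the joint
dependence is a modelling choice: a Gaussian copula, with latent Pearson
correlations `2 sin(πρ/6)` (exact for continuous marginals), unspecified
pairs set to zero, and an eigenvalue-clipping repair guarding positive
semidefiniteness (under the default targets both group matrices are
already positive definite and the repair is a no-op).  The ferritin
moment marginals (mean loading ≈ 1600 atoms in controls, ≈ 1960 in AD)
and magnetite moment marginals (tens of thousands of μB, AD larger) are
not published as tables and were chosen once to reproduce the reported
qualitative structure.  Braak stages are assigned by within-group rank of
ferrihydrite (controls 0–3, AD 4–6), which makes per-stage means of the
assignment variable monotone by construction — a generator guarantee, not
a biological claim.

Raw signals use the modality-appropriate noise: Rician for magnitude MRI
(magnitude detection), Gaussian for EPR and SQUID (lock-in / flux
detection).  Default acquisition geometry: 4 echoes at 12.5–44.6 ms;
IRM sweeps of 30 log-spaced fields from 10 G to 2.5 T (the published
low-field range; the actual grids are not published); 50 mg dry SQUID
pellets and 15 mg wet EPR sections, typical for resected gray-matter
blocks.  With ~50 mg pellets, roughly 15–20% of synthetic subjects fall
under the 100 K SNR discard rule — matching the reported experience that
a minority of samples had unusable magnetite signals.  Recovery tests
therefore score the quantities the method actually reports: discarded
subjects correctly return zero concentration and a missing moment.

What passing these tests shows: the estimators invert their own forward
models, exactly at zero noise and within a few percent at realistic
noise, and the statistics are calibrated.  What they cannot show: that
the forward models describe real tissue (fixation chemistry, Aβ and
myelin confounds, spatial structure, field inhomogeneity and multi-site
variation are all outside the generator), so agreement on synthetic data
is necessary, not sufficient, for validity on real cohorts.

## Numerical choices and problem sizes

Tolerances: bisection to 10⁻⁴ mT on resonance fields; Levenberg–Marquardt
with `ftol = ptol = 10⁻¹⁴`; eigenvalue floor 10⁻⁸ in the PSD repair, with
a hard error if repair changes any entry by more than 0.05.  Degenerate
inputs short-circuit (flat IRM curves, all-zero voxels, zero-variance
samples) rather than erroring mid-pipeline.  The test suite exercises the
EPR oracle on 10 orientations with a 0.05 mT dense scan, powder spectra
at 60–120 orientations, recovery on a 36-subject noiseless cohort and a
200-subject noisy cohort, calibration at 2000 null simulations, and
marginal/copula fidelity averaged over 20 cohorts of 10000 per group —
sizes chosen so the whole suite completes in a couple of minutes while
keeping every Monte-Carlo band well below its acceptance threshold.

## Known limitations

- No Rician-floor correction in relaxometry; at SNR well below 20 the
  ROI median will be biased.
- The EPR template uses first-order g-strain mapping; very large strains
  on steep resonances would need the full Monte-Carlo over g.
- Single-moment Langevin fits cannot represent broad particle-size
  distributions; `μp` is an effective mean.
- The copula choice (Gaussian) is not identified by pairwise Spearman
  targets; tail dependence in real cohorts is not emulated.
- The α exponent of the loading relation is not estimable from a single
  IRM curve; LF values inherit its uncertainty.
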