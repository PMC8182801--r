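---
title: "Surveying thermal expansion of molecular crystals from unit-cell data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveying thermal expansion of molecular crystals from unit-cell data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermex)
```

## The problem

Variable-temperature X-ray diffraction gives the unit-cell parameters of a
crystal at a handful of temperatures. From these, thermal expansion is
summarised by the volumetric coefficient
$\alpha_V = (1/V)\,\mathrm{d}V/\mathrm{d}T$ and by the three principal
coefficients $\alpha_L$, the eigenvalues of the temperature derivative of the
strain tensor. Molecular crystals are frequently monoclinic or triclinic, so
the cell axes are not principal axes and the full tensor treatment is
required; anisotropic behaviour — including uniaxial or biaxial negative
thermal expansion (NTE), where one or two principal coefficients are
negative — is only visible through it.

`thermex` implements this calculation for a single family of determinations
(`fit_single_family()`) and, around it, the curation and population
statistics needed to run the same analysis over a whole structure database
extract (`run_survey()`): which determinations belong to the same crystal
phase, which temperatures are trustworthy, and what range of coefficients is
"normal" so that exceptional claims can be calibrated against the population.

## The model and its assumptions

Expansion is assumed linear over the analysis window (90–300 K by default).
This is a pragmatic necessity: most database families contain only two
temperature points, and a two-point family supports nothing richer than a
line. For families with three or more points the assumption is testable, and
the pipeline screens on the $R^2$ of the volume–temperature fit
(threshold 0.96) before trusting a family for population summaries.

Because a constant $\mathrm{d}V/\mathrm{d}T$ makes $\alpha_V$ depend on the
volume at which it is quoted, every coefficient is referenced to 298 K:
$\alpha_V(298) = 10^6\,s/(i + 298\,s)$ p.p.m. K$^{-1}$ for a fitted line
$V = i + sT$, and analogously for each principal axis,
$\alpha(298) = 10^6 k/(1 + k\,(298 - T_{\mathrm{ref}}))$ for a strain rate
$k$ referenced to the lowest-temperature structure. For small strains the
identity $\alpha_V \simeq \Sigma\alpha_L$ holds to first order; the test
suite checks the two routes agree within 2% on closed-form families.

Strain tensors use the linear (infinitesimal) Lagrangian form
$e = \tfrac12(F + F^\top) - I$, with the deformation gradient
$F = A(T)\,A_{\mathrm{ref}}^{-1}$ between orthogonalized bases. The
orthogonalization convention is fixed to $x \parallel a$, $y$ in the
$a$–$b$ plane, $z \parallel c^{*}$; any fixed convention gives the same
eigenvalues, the convention only decides how axis vectors are printed.

For families with three or more points, each of the six independent strain
components is fitted linearly against temperature (free intercept, reference
point included) and the fitted slope tensor is diagonalised. Diagonalising
the slope tensor, rather than averaging per-pair eigen-decompositions, makes
the result deterministic when the unconstrained principal axes of a
monoclinic or triclinic crystal drift slightly between temperature pairs:
under the linear assumption the two procedures coincide, and the slope
tensor realises the average orientation in one step. The intercept is left
free so that small errors in the reference structure are absorbed rather
than propagated into every slope. Per-axis standard uncertainties come from
a fit of the strain projected onto each fixed eigenvector, so axis
uncertainty reflects scatter along that axis only.

Uncertainties on fitted slopes are heteroscedasticity-consistent (HC1
sandwich) standard errors rather than classical OLS errors: residual
variance in real determinations grows with temperature and differs between
instruments, and the HC family is robust to that. HC1 is the common
small-sample default; the variant is exposed in `survey_config()`.
Two-point families get the exact line and no uncertainties — they are kept
(they dominate the population) but carry a `two_point` flag through every
report.

## Building structure families

Database extracts identify compounds, not phases. Determinations sharing a
refcode root may be redeterminations at different temperatures, polymorphs,
or one lattice published in different space-group settings. The partition is
deliberately metric-only — no symmetry information is used, since requiring
space-group matches discards valid families published in alternative
settings:

1. Every cell is Niggli-reduced (Krivy–Gruber iteration, stabilised
   comparisons at relative tolerance $10^{-5}$, iteration cap 100 —
   convergence takes a few dozen steps on any physical cell, the cap guards
   near-degenerate input). Cells that fail to reduce are quarantined with a
   logged warning, never silently dropped.
2. Entries are clustered by greedy single linkage on a metric deformation
   measure between reduced cells — the Frobenius norm of the finite
   Lagrangian strain between the two bases — with acceptance threshold 0.12.
   Single linkage means membership is a chain condition: each entry joins a
   family if it is within tolerance of *any* current member, and clusters
   bridged by a new entry are merged. Entries are processed in refcode-then-
   temperature order, so the partition is deterministic.
3. Within a family, one representative is kept per unique temperature
   (10 K grouping tolerance, greedy from the sorted list, lowest R-factor
   wins; a reported R beats a missing one, remaining ties go to the earliest
   refcode). Missing temperatures are assigned 293 K as the room-temperature
   convention; explicitly recorded values in the room range are *not*
   snapped.
4. Families are restricted to 90–300 K and must retain a point at or above
   273 K, span at least 50 K, and keep at least two points.

### Reduction discontinuities

Niggli reduction is discontinuous at its boundary conditions, and molecular
crystals sit on those boundaries as a matter of course: every monoclinic
cell has two angles at exactly 90°, so measurement noise can flip the
reduced cell between the all-acute and all-obtuse settings
($\beta \leftrightarrow 180° - \beta$), and a large expansion can carry a
lattice across a reduction inequality so that consecutive temperatures
reduce to shear-related bases. Compared naively, such pairs look like
different polymorphs. The deformation measure therefore minimises over
lattice-equivalent re-basings of one cell: the 48 signed axis permutations
first and, when those stay above 0.1, all unimodular transformations with
entries in $\{-1, 0, 1\}$. The same matching is applied before strain
construction (`match_cell_setting()`), so all members of a family are
strained against the reference in one consistent setting. A guard still
refuses pairs whose minimal deformation exceeds the family tolerance —
those really are different phases.

## Population statistics

Coefficient distributions are summarised from histograms with fixed
25 p.p.m. K$^{-1}$ bins anchored at zero. Distribution curves are fitted to
the bin counts at bin midpoints by nonlinear least squares with a *free
amplitude*, which decouples the recovered shape from the bin-count scaling
and makes the fit robust to excess population in the tails — precisely the
contamination (mis-reported temperatures, unflagged pressure points) the
survey expects.

The volumetric coefficient is fitted with a normal curve. The pooled
principal coefficients (all three per family — the question is how any axis
compares to all axes in the population) are visibly skewed and get a
skew-normal fit, $f(x) = A\,(2/\omega)\,\phi(z)\,\Phi(\alpha z)$ with
$z = (x-\xi)/\omega$. For quotable one-sided thresholds the skew-normal
curve is then approximated by two half-normal curves sharing its mode and
peak height, with the two standard deviations fitted by least squares to
the curve on each side. This mode-centred, equal-peak recipe is this
package's own construction (the approximation is not uniquely defined);
the composite density is continuous and equal to the skew-normal at the
centre by construction, and reduces exactly to the symmetric case at zero
shape. Exceptionality thresholds are $\mu \pm k\sigma$ for the normal fit
and (centre $- k\,\sigma_{\mathrm{lower}}$,
centre $+ k\,\sigma_{\mathrm{upper}}$) for the two-half-normal, with
$k = 3$ by default.

Outlier tables mirror the survey logic: high-$\alpha_V$ families are only
tabulated when they rest on at least four temperature points; families at
or below the lower threshold are flagged *suspect* when they are two-point
(apparent negative expansion from two points is almost always an unflagged
pressure point or a mis-reported temperature, not physics); and
extreme-anisotropy families must additionally show a good linear fit. The
anisotropy measure is
$(\alpha_L^{\max} - \alpha_L^{\min})/\Sigma\alpha_L$; the volumetric
coefficient can be substituted as denominator via
`survey_config(anisotropy_denominator = "alpha_v")`, since the two
conventions coexist in the literature. Negative anisotropy can only arise
from a negative denominator and is treated as invalid downstream.

## The synthetic database

Real structure databases are proprietary, so the package carries a
generator (`generate_survey()`) that emulates an extract with planted
ground truth, making every stage testable offline. Its defaults are the
study conditions of the survey design:

* **Family sizes**: ~84.5% two-entry families, 9.3% three-entry, 2.5%
  four-entry and a geometric tail to 14 entries; every family is topped by
  a room-temperature determination (recorded at 293 K, recorded at an
  explicit value in 283–300 K, or unrecorded — in which case the pipeline
  must assign 293 K).
* **Coefficients**: planted $\alpha_V(298) \sim$ Normal(161, 51)
  p.p.m. K$^{-1}$, split across three principal axes with a log-normal
  spread and a 30% uniaxial / 3% biaxial NTE rate, values any worker in
  the field would recognise as typical for organic molecular crystals.
* **Cells**: triclinic/monoclinic/orthorhombic reference cells in a
  25/50/25 mix, edges 5–15 Å; monoclinic slope tensors keep one
  eigenvector pinned to the unique axis, orthorhombic tensors are
  axis-aligned.
* **Noise**: relative $\sigma = 2\times10^{-4}$ (0.02%) on lengths and
  0.02° on angles — the precision of a routine modern determination.
* **Error modes** (2% of families each by default, at most one per
  family, recorded in the truth tables): a warm structure archived with a
  temperature ~100 K too low; an unflagged high-pressure determination
  (volume shrunk 3–10% at the warmest point); an order–disorder-style
  volume jump of 2–4% mid-range; a duplicate publication of one
  determination (same cell within noise, different publication and
  R-factor); and one entry re-expressed in an alternative space-group
  setting. Modes that corrupt a linear fit are only injected into families
  with at least four points, where they are diagnosable.

Strain evolution is applied to the metric through the exact finite
deformation $A(T) = (I + \dot e\,(T - T_{\mathrm{ref}}))A_{\mathrm{ref}}$,
so the linear-fit approximation error in the recovered volumetric
coefficient is realistic rather than zero by construction.

What the generator does **not** emulate: atomic structure and space-group
statistics (the pipeline is metric-only, so these do not matter to it),
genuinely non-linear expansion, correlated systematic errors between
determinations from one instrument, and the long tail of archival
pathologies beyond the five modelled modes. Passing recovery tests
therefore demonstrate that the pipeline is correct *given* the linear
model and these error modes — not that the linear model is adequate for
any particular real crystal.

## Validation design and problem sizes

The package's quantitative validation, shared between the test suite and
`scripts/acceptance.R`, uses two seeded experiments chosen for statistical
power at desk scale:

* a **1000-family survey** at the generator defaults, on which the fitted
  normal mean and standard deviation of $\alpha_V$ are required to land
  within ±5 p.p.m. K$^{-1}$ of the planted population parameters and the
  regression of recovered on planted $\alpha_L$ (over uncorrupted
  families) within 1 ± 0.02;
* a **250-family injection experiment** restricted to families of 4–6
  points with one error mode injected per family (roughly 80 injections
  per mode), on which the screening and outlier logic must catch at least
  90% of each of the three diagnosable modes — a wrongly reported
  temperature and a planted phase transition must fail the $R^2$ screen,
  an unflagged pressure point must fail the screen or fall below the
  lower volumetric threshold. Detection rates at the default 2% injection
  rate are the same, but a 1000-family survey yields only a handful of
  eligible injections per mode, too few to measure a rate against.

Smaller fixed-seed cases (isotropic closed forms, symmetry-constrained
monoclinic and orthorhombic families, oracle comparisons for reduction,
strain and sandwich errors) make up the rest of the suite.

## Known limitations

* The 0.12 deformation tolerance is a calibration for typical organic
  crystals; polymorph pairs with very similar metrics will merge and
  heavily strained redeterminations of one phase may split. It is a
  configuration parameter, not a constant of nature.
* Two-point families — the bulk of any real extract — carry no
  uncertainties and no linearity check; all their flags propagate, but
  their coefficients are only as good as the two cells behind them.
* No finite (quadratic) strain option, no equation-of-state or Grüneisen
  modelling, no phase-transition detection beyond the $R^2$ screen.
* The anisotropy measure is unstable when $\Sigma\alpha_L$ is small; such
  families appear in the extreme-anisotropy tail and are filtered by the
  good-linear-fit requirement rather than re-weighted.
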