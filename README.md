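# thermex

Thermal expansion coefficients of organic molecular crystals from
variable-temperature unit-cell determinations — for a single data set or a
whole structure-database extract.

Temperature-dependent diffraction gives the unit cell of a crystal at a few
temperatures. `thermex` turns such series into:

* the **volumetric expansion coefficient**
  α_V = (1/V) dV/dT, from an unweighted linear fit of V against T,
  referenced to the volume extrapolated to 298 K and quoted in p.p.m. K⁻¹,
  with a heteroscedasticity-consistent (HC1) standard error;
* the three **principal expansion coefficients** α_L: linear Lagrangian
  strain tensors e = ½(F + Fᵀ) − I are built against the lowest-temperature
  structure, the fitted slope tensor de/dT is diagonalised, and each
  eigenvalue k is referenced to 298 K via α = 10⁶·k / (1 + k(298 − T_ref)).
  Molecular crystals are mostly monoclinic or triclinic, so this full tensor
  route — not the cell edges — is what exposes anisotropy and negative
  thermal expansion (NTE);
* the **anisotropy measure** (α_L(max) − α_L(min)) / Σα_L and an NTE class
  (none / uniaxial / biaxial / triaxial, with a conclusiveness flag per
  negative axis).

Around that core sits a database pipeline: entries sharing a refcode root
are partitioned into *structure families* (same phase, different
temperatures) by Niggli cell reduction and a metric deformation measure
(tolerance 0.12) that is robust to alternative space-group settings and to
the reduction's boundary discontinuities; determinations are deduplicated by
temperature (10 K tolerance, lowest R-factor retained) and filtered to a
90–300 K window with a point at ≥ 273 K and ≥ 50 K span. Population
statistics then fit the coefficient histograms (normal for α_V; skew-normal
approximated by two half-normals for the pooled α_L), derive 3σ
exceptionality thresholds, count NTE, and tabulate outliers. A synthetic
database generator with planted ground truth stands in for proprietary
sources and makes every stage testable offline.

## Worked example: one family

Four determinations of a monoclinic crystal between 100 and 293 K:

```r
library(thermex)
tab <- data.frame(
  a     = c(11.640, 11.652, 11.668, 11.687),
  b     = c(12.893, 12.903, 12.916, 12.929),
  c     = c(15.021, 15.031, 15.043, 15.057),
  alpha = c(90, 90, 90, 90),
  beta  = c(101.35, 101.42, 101.51, 101.60),
  gamma = c(90, 90, 90, 90),
  temperature_K = c(100, 160, 220, 293))
fit_single_family(tab)
#> expansion result for family-1 (4 points, 100-293 K)
#>   alpha_V(298 K) = 43.4 (1.3) p.p.m./K  (R^2 = 0.9978)
#>   alpha_L1(298 K) = 2.0 (0.4) p.p.m./K along (+0.484, -0.000, +0.875)
#>   alpha_L2(298 K) = 14.6 (0.3) p.p.m./K along (-0.000, +1.000, -0.000)
#>   alpha_L3(298 K) = 26.9 (0.8) p.p.m./K along (+0.875, +0.000, -0.484)
#>   anisotropy = 0.573; NTE class: none
```

The volume grows nearly linearly (R² = 0.998) for a modest
α_V(298 K) = 43 p.p.m. K⁻¹. Expansion is strongly anisotropic: one
principal axis lies exactly along **b** (forced by monoclinic symmetry —
parentheses give HC1 standard uncertainties), while the other two lie in
the a–c plane, one of them almost rigid (2 p.p.m. K⁻¹). The sum of the
three principal coefficients, 43.5, matches α_V to first order, as it must
for small strains. No coefficient is negative, so the NTE class is `none`.

## The database-scale workflow

The survey is organised as numbered scripts under `analysis/`, each a thin
driver over package functions, writing its tables to `results/`:

```sh
Rscript analysis/01_simulate_survey.R        # synthetic entries + truth tables
Rscript analysis/02_build_families.R         # screening, partitioning, filters
Rscript analysis/03_fit_expansion.R          # per-family coefficients
Rscript analysis/04_survey_distributions.R   # histogram fits + 3-sigma thresholds
Rscript analysis/05_outliers_and_validation.R # outlier tables, planted-truth recovery
```

The same computation is available in one call:

```r
syn <- generate_survey(generator_config(n_families = 1000), seed = 101)
sv  <- run_survey(syn$entries)
sv
#> expansion survey: 2469 input entries -> 1055 accepted families
#>   family sizes: 2 entries x894, 3 entries x98, 4 entries x32, ...
#>   alpha_V normal fit: mean 161.5, sd 51.1 p.p.m./K; 3-sigma (8, 315)
#>   alpha_L two-half-normal: centre 47.8, sd 23.5 / 37.4 p.p.m./K
#>   NTE: 309 uniaxial, 23 biaxial of 1055 families
```

Every discarded entry or family lands in `sv$log` with a machine-readable
reason code (`pressure`, `no_273K`, `range_lt_50K`, `duplicate_temperature`,
…), and `error_recall()` scores the screening logic against the generator's
planted error modes.

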