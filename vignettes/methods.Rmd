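---
title: "Models, numerical choices and simulation design in rusitecr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, numerical choices and simulation design in rusitecr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rusitecr)
```

rusitecr re-implements, as a tested pipeline, the derived quantities of
a 2×2 factorial (forage × vitamin E) rumen fermentation study run in
Rusitec semi-continuous fermenters, together with the batch-culture
assays that accompanied it. This vignette records the models, their
assumptions, the parameters that matter, and the design decisions taken
where the published methods left the choice open.

## VFA stoichiometry and the hydrogen balance

Hexose fermented to acetate or propionate yields two acid molecules per
hexose; butyrate and valerate consume a whole hexose each. Hence
fermentable organic matter in hexose equivalents is
`FOM = 0.5·Ac + 0.5·Pr + But + Val`. Reducing-equivalent bookkeeping
follows the same source stoichiometry: `[2H] produced = 2·Ac + Pr +
4·But + 3·Val` and `[2H] incorporated = 2·Pr + 2·But + 4·Val + 4·CH₄`.

Two choices deserve comment:

* **The methane coefficient.** Methanogenesis consumes four H₂ per
  CH₄, so methane enters the incorporated side with coefficient 4
  (`hydrogen_incorporated(..., ch4_coefficient = 4)`). The coefficient
  is an explicit argument because shorthand presentations of the
  formula sometimes print a bare CH₄ term; only the value 4 makes the
  balance consistent with the published recovery percentages.
* **Branched-chain acids.** Isobutyrate and isovalerate derive from
  amino-acid fermentation, not hexose, and are carried in
  `vfa_profile` for reporting (branched-chain proportions, totals) but
  excluded from the formulas.

FOM is converted to mass at 162 mg/mmol (anhydro-hexose, i.e. the
monomer mass of polymerised glucan), configurable in `fom_mass()`. In
batch mode, concentrations (mM) are converted to amounts with a
declared vessel liquid volume (default 0.05 L, a 120-mL bottle holding
50 mL). Redox readings taken against an Ag-AgCl reference electrode are
corrected to the standard-hydrogen-electrode scale by `Eh = E0 + C`
with `C = +198` mV at 39 °C.

**Reproduction of the published summary cells.** The bundled treatment
means (`ref_outflow_means()`, `ref_fermentation_means()`) let
`reproduce_hydrogen_table()` recompute every hydrogen-balance cell.
The linear rows (produced, incorporated) reproduce within one unit of
the last printed digit under the tables' round-half-up convention
(`round_half_up()`). The ratio rows (recovery, CH₄:VFA) were computed
per vessel and then averaged in the source; recomputing them from
treatment means therefore carries a Jensen-type gap of up to ~0.5
percentage points (recovery) and ~0.002 mol/mol (CH₄:VFA) for the
fresh-grass control, which no rounding convention can close. The
package reports both variants: per-sample ratios via
`hydrogen_balance()` on vessel-level data, and on-means ratios via the
reproduction table.

Published totals of the six acids slightly exceed the sum of the
printed per-acid means (again per-vessel rounding); the CH₄:VFA ratio
therefore accepts an independently measured `total_vfa`.

## ¹⁵N tracer partitioning

The ammonia pool is labelled with ¹⁵N ammonium sulphate, so microbial N
built from ammonia becomes enriched while by-pass feed protein does
not. At steady state, two enrichment ratios (atom % excess over one
shared background) partition the flows; both are scale-invariant, so
absolute calibration of the mass spectrometer cancels as long as a
single background is used per run — `enrichment_15n()` assumes exactly
that.

Degradability definitions are reconstructed from flow bookkeeping:
apparent N degradability charges the whole NAN outflow against intake,
`100·(intake − NAN)/intake`; true degradability removes only the
by-pass fraction, `100·(intake − NANM-N)/intake`. These definitions
reproduce the published degradability rows from the published flows and
diet composition; the alternative apparent form that also subtracts the
ammonia outflow is computed (`apparent_with_ammonia`) but is not the
default, because it does not reproduce the published cells. A microbial
fraction above 1 (digesta more enriched than the bacterial pellet)
indicates measurement error and is clipped to 1 with a warning;
NANM-N is correspondingly floored at zero.

N intake uses the intake-weighted diet N content at the 80:20
forage:concentrate ratio and 11.25 g DM/d feeding rate
(`ref_feeding()`), giving 221.2 (grass) and 208.6 (hay) mg N/d.

## Gas kinetics

Pressure transducers report headspace pressure excess; at fixed
incubation temperature the ideal gas law gives
`V = V_headspace · ΔP / P_atm` per reading. No transducer calibration
curve is published, so this physical conversion is adopted with
configurable headspace (default 70 mL) and ambient pressure (default
101.325 kPa). Readings are treated as vented increments and cumulated
(`vented = TRUE`); a non-venting mode is available.

The France single-pool model `Y = A(1 − e^(−ct))` is fitted by
Levenberg-Marquardt least squares with bounds `A, c > 0`. Start values:
`A₀` = the largest observed volume, `c₀` from a log-linear regression
of `log(1 − Y/(1.05·A₀))` on time; if that fit fails, a coarse
multi-start sweep over `A ∈ {1, 1.2, 2}·max(Y)`, `c ∈ {0.01, 0.05,
0.1, 0.2}` is tried before the fit is flagged unconverged (flagged, not
raised — only an all-zero curve raises a degenerate-fit error). On
noise-free curves the optimizer recovers parameters to better than
1e-6 relative anywhere in `A ∈ [50, 300]`, `c ∈ [0.01, 0.2]`.

Published batch-culture tables report a "gas-production rate" in μL/h,
which is dimensionally inconsistent with a first-order fractional rate.
The package does not guess which quantity was meant: it reports `c` in
h⁻¹ and additionally `A·c` (mL/h), the model's initial rate, so either
reading can be compared. The bundled batch-culture defaults read the
printed control value 64.5 as `c = 0.0645 h⁻¹`, consistent with a
116-mL asymptote on the 2–96 h grid.

The ¹⁴C protozoal-activity assay is a simple linear regression of
percent label released on time (0–4 h); the OLS slope (%/h) is the
bacterial degradation rate. It equals the closed form
`Σ(t−t̄)(y−ȳ)/Σ(t−t̄)²` and is tested against brute-force SSE
minimization.

## Community statistics

The published index values constrain but do not state the formulas;
the package adopts the standard forms consistent with their ranges:
natural-log Shannon `H = −Σ pᵢ ln pᵢ`, Pielou evenness `H/ln S`,
Gini-Simpson `1 − Σ pᵢ²` (values near 0.97, as printed), classic
bias-corrected Chao1 `S + F₁(F₁−1)/(2(F₂+1))`, and Good's coverage
`1 − F₁/N`.

* **Normalization** is random subsampling without replacement to the
  minimum sample depth (`rarefy_to_min()`, seeded). Proportional
  scaling would preserve expected composition but break the
  count-based estimators (Chao1, Good's), so it is not used.
* **Bray-Curtis** is computed on `log(x+1)` abundances — a zero-safe
  reading of "log-transformed data"; the transform is an argument.
  Identity, symmetry and boundedness hold by construction; the
  triangle inequality is not asserted.
* **UPGMA** uses average-linkage agglomeration with deterministic
  lowest-index tie-breaking, exported as newick text.
* **PERMANOVA** is implemented in the package: Gower-centering of
  `−D²/2`, projection ("hat") matrices per design term, marginal sums
  of squares (each term adjusted for all others; identical to
  sequential SS in balanced factorials), and pseudo-F against the full-
  model residual. Significance uses permutation of residuals under the
  reduced model (Freedman-Lane): residuals of the model without the
  tested term are permuted, the fitted part retained, and the pseudo-F
  recomputed; `p = (1 + #[F* ≥ F]) / (1 + n_perm)` with 999
  permutations by default. For ≤ 8 samples an exhaustive mode
  enumerates all n! relabellings and returns the exact p. The
  partitioning is cross-checked against an independent implementation
  in the test suite; the asymptotic Monte-Carlo p-value variant is out
  of scope.
* **CCA** delegates to vegan's ter Braak algorithm; per-variable
  significance uses marginal (one-at-a-time) permutation tests. The
  conservation identity — constrained analysis has the same total
  inertia as unconstrained correspondence analysis — is asserted in
  tests.
* **FDR** is Benjamini-Hochberg step-up.

## The synthetic-data generator

`simulation_config()` defaults *are* the study conditions: 4 vessels
per treatment in a 2×2 design, treatment means mirroring the bundled
published tables, vessel noise Normal on the measurement scale with
SD = SED·√2 (SEDs were published for differences of 4-vessel means,
SED = s·√(2/n) at n = 4), amounts truncated at zero. Enrichments are
generated backwards from each vessel's microbial fraction and
ammonia-derived share, so the tracer stage recovers the generating
values exactly — the vessel-level noise lives on the fractions
themselves, keeping the noisy round trip unbiased by construction.

Gas curves add Normal(0, 1 mL) noise to model volumes plus a small
blank baseline (8 mL pool at 0.04 h⁻¹) and are inverted to vented
pressure increments with the same ideal-gas convention the analysis
uses. OTU tables are Dirichlet-multinomial: a long-tailed gamma-
generated rank-abundance curve (971 OTUs, matching the study's
bacterial OTU count), concentration parameter 50 for between-sample
overdispersion, a designated 10% of OTUs multiplied by a fold-change
(default 4) in HAY samples, and depths uniform on 10,000–15,000 reads.
Metadata mirrors the design factors (forage, vitamin E, time point,
inoculum animal).

What the generator deliberately does **not** emulate: taxonomic or
phylogenetic structure, read-level sequencing error, temporal
autocorrelation between the two sampling time points, vessel-level
correlations among analytes, and the inoculum-animal random effect.
Passing tests therefore demonstrate correctness of the computational
chain under the stated statistical model, not robustness to every
feature of real Rusitec data.

## Numerical conventions and test scales

* Table-reproduction comparisons round half away from zero
  (`round_half_up()`) to the printed number of decimals, the convention
  of the published tables.
* Validation errors are classed conditions (`rusitecr_validation_error`,
  `rusitecr_undefined_result`, `rusitecr_degenerate_fit`,
  `rusitecr_schema_error`, `rusitecr_missing_file`), so callers can
  distinguish bad inputs from undefined ratios.
* Degenerate inputs: zero denominators raise undefined-result errors;
  all-zero gas curves raise degenerate-fit errors; unconverged fits
  are flagged, not raised.
* Statistical checks in the test suite use deliberately modest problem
  sizes chosen to give stable verdicts: 100-seed recovery simulations
  for the France asymptote and the release slope, 200 null
  Dirichlet-multinomial tables (16 samples, 100 OTUs, 999
  permutations) for PERMANOVA type-I calibration, and 6-sample
  exhaustive enumeration (720 relabellings) for exactness.

## Known limitations

* Ratio-valued summary rows recomputed from treatment means differ
  from per-vessel averages by a Jensen gap (see above); vessel-level
  data should be used when available.
* The published FOM-in-mg cells cannot be reproduced exactly because
  per-treatment valerate proportions behind them are not printed; the
  162 mg/mmol conversion is documented, not asserted.
* PERMANOVA terms are main effects (or user-precomputed interaction
  factors); automatic interaction expansion and nested/random strata
  are not implemented.
* The steady-state two-pool tracer model excludes dynamic isotope
  recycling; enrichment time courses cannot be analysed.
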