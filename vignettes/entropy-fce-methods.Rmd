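---
title: "Entropy-weighted fuzzy evaluation of water quality: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-weighted fuzzy evaluation of water quality: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcewater)
```

This vignette is the package's own account of the science it
implements: the grading model and its assumptions, the parameters that
matter, the places where the design was genuinely open and how we
resolved them, and what the tests do — and do not — establish.

## The grading problem

A monitoring survey yields, per site, concentrations of five routine
indicators: dissolved oxygen (DO, a benefit indicator — higher is
better), and four cost indicators — total nitrogen (TN), ammonia
nitrogen (NH₃-N), total phosphorus (TP) and the permanganate index
(COD_Mn). Regulatory practice classes each site into grades I–V by
comparing concentrations with threshold tables; the package ships the
GB 3838-2002 thresholds (`"gb3838"`) and a drinking-water-source
variant (`"customized"`) that tightens the COD_Mn column and the lower
DO classes. Crisp interval lookup (the *single-factor* method,
`single_factor_grade()` / `worst_factor_grade()`) is transparent but
brittle: a site at 1.01 mg/L TN and one at 1.49 mg/L land in the same
class, and the worst indicator alone decides. Fuzzy comprehensive
evaluation replaces the crisp lookup with graded memberships and an
explicit weight vector.

Interval closure follows the threshold tables' own notation: intervals
are `(lower, upper]`, with the grade-I regulatory bound inclusive
(TN ≤ 0.2 is grade I; DO ≥ 7.5 is grade I). The national table prints
its DO row with closed brackets (`[6.5, 7.5]`); we use the half-open
convention uniformly for both schemes, which changes only which of two
adjacent grades a boundary value belongs to. Concentrations beyond the
grade-V outer bound are graded V and flagged `exceeds_v` rather than
rejected — surveys routinely contain such sites. Below-detection
readings are stored as 0.0, with no half-LOD imputation.

## Entropy weights

Weights are objective, derived from the data's dispersion
(`entropy_weights()`): min-max standardization with polarity maps
every column to [0, 1] with 1 = best observed; column proportions
p_ij feed the normalized Shannon entropy E_j = −(1/ln n) Σ p_ij ln
p_ij; and w_j ∝ 1 − E_j. Numerical conventions, stated because the
formulas are silent on them:

* `0 · ln 0 := 0` in the entropy sum.
* A constant column standardizes to all ones (not 0/0): uniform
  proportions give E_j = 1 and weight 0 — the correct "no
  information" outcome.
* If *every* column has E_j = 1 the weight vector is undefined; the
  package raises an error advising an explicit uniform-weight
  fallback rather than silently inventing one.
* Normalization is asserted to 1e−12 absolute; the implementation is
  cross-checked against a deliberately naive brute-force evaluation of
  the defining formulas to 1e−10 on random matrices.

Weights are computed over whatever site set the caller passes; the
default pipeline (`fce()`) uses one joint vector over all supplied
sites, mirroring the single published weight table such surveys
report. A caveat worth knowing: for a heavy-tailed cost indicator like
TN, min-max standardization compresses the clean majority of sites
toward 1, so the proportions are nearly uniform and the indicator can
receive a *small* weight even though its extremes are the story. That
is a property of the method, not a bug; it is why the package also
reports single-factor grades and the EWQI comparator.

## Membership construction

The threshold tables define intervals, not membership parameters, so
the mapping from one to the other is a modeling choice. We place each
grade's apex (membership 1) at the midpoint of its interval; grade I
of a cost indicator uses the midpoint of [0, t₁], and DO's unbounded
grade-I apex sits at its regulatory bound 7.5 mg/L. Grades II–IV get
triangles with feet at the neighbouring apexes; grades I and V get
semi-trapezoids saturating outward (toward clean and polluted water
respectively). For the customized scheme this yields, e.g., TN apexes
(0.1, 0.35, 0.75, 1.25, 1.75) mg/L and DO apexes (7.5, 7.0, 6.25,
5.75, 5.0).

This construction is standard and has the property that makes the
algebra clean: the five functions form a **partition of unity**
between the outer apexes — every concentration's memberships sum to 1
with at most two adjacent grades nonzero. The triangle's two branches
overlap at the apex; we evaluate the peak branch there (value 1), so
the functions are continuous. The degree of membership is linear
interpolation between apexes, so DO is exactly a cost indicator under
reflection of the concentration axis (a tested construction).

## Composite evaluation, ties, ambiguity

`evaluate_sample()` forms B = W × R and assigns the grade with maximal
b_k. Two details:

* **Ties break toward the worse grade** — the conservative call for a
  drinking-water source. Ties are recognized within 1e−9: composite
  masses assembled in different summation orders can differ by
  floating-point noise, and a sub-epsilon deficit must not flip a
  conservative call.
* **Ambiguity margin**: B is normalized to sum 1 and the gap between
  the top two entries is reported; below 0.2 (configurable) the call
  is flagged ambiguous. Maximum-membership grading is genuinely
  unstable near ties, and the flag is the honest signal of that.

One limitation deserves emphasis because it is easy to assume
otherwise: **the assigned grade number is not monotone under uniform
degradation**. The composite vector B is — degrading every indicator
moves B toward worse grades in the first-order stochastic dominance
sense, a theorem given the row-wise monotonicity of the memberships —
but the *argmax* can improve: mass arriving in a middle grade from the
clean side (say DO slipping from grade I into II) can overtake a
saturated class-V block and flip a V call to II. The test suite
asserts the true FOSD form, exhibits the argmax pathology, and the
ambiguity margin is the designed mitigation: such flips occur at small
margins.

## The EWQI comparator

The scalar comparator is an entropy-weighted quality index,
EWQI = Σ w_j q_j, with q_j = 100·C_j/S_j for cost indicators (S_j the
grade-III upper bound), q_j = 100·S_j/C_j for DO (S_j its grade-III
lower bound), each rating capped at 500 so zero DO never divides by
zero, and class bands I ≤ 50 < II ≤ 100 < III ≤ 150 < IV ≤ 200 < V. A
site sitting exactly at every grade-III bound scores exactly 100 by
construction. The surrounding literature does not fix a single EWQI
formula; this is a documented reconstruction of the common form, and
the bands and cap are configurable arguments, not constants.

Structurally, the two methods disagree in characteristic ways: the
index *averages*, so one saturated pollutant is diluted by four clean
ratings, while fuzzy grading with the maximum-membership rule can let
that single saturated class-V block win — so FCE issues class-V calls
the index smooths over (the tested direction of disagreement). At the
clean end the index is the harsher judge: its DO rating floors near
60 even for pristine water, so well-mixed clean sites score above the
class-I band. `compare_methods()` tabulates the per-site confusion
matrix and discordant sites rather than presuming either method
correct.

## Compliance statistics

`compliance_stats()` grades each indicator crisply and reports, per
stratum (reach × section by default), the share of sites meeting a
stated class. "Exceedance" defaults to failing class III — the usual
regulatory reference — with the class level a parameter because
surveys also quote class-I/II compliance. Every rate is computed from
integer counts which are retained alongside it (rate × n always
reproduces the count), denominators always come from the data rather
than from any externally stated site totals, and empty strata are an
explicit error, never a silent 0/0. `descriptive_stats()` reports the
sample standard deviation and CV = sd/mean, flagging CV undefined when
the mean is zero. `grade_distribution()` stores counts and recomputes
percentages from them; the print method renders one decimal.

## Emission accounting

`aggregate_emissions()` consumes a source-resolved inventory (source
type × subcategory × pollutant, tonnes/year) and produces totals,
source-type subtotals and subcategory contribution shares. Two
semantic decisions: `/` (not-assessed) entries are `NA`, excluded from
sums and never conflated with zero; and the accounting starts from
already-computed discharge amounts — emission-coefficient estimation
(headcounts × handbook coefficients) is out of scope because the
coefficient tables live in regulatory handbooks, not in data the
package could validate. The packaged inventory
(`wanan_inventory()`) reproduces its published column totals within
the rounding of its two-decimal components (±0.02 t).

## The synthetic generator

Real survey tables are rarely public, so the generator
(`generate_sites()`) exists to make every stage testable and is
first-class, tested code. It emulates the survey structure the
evaluation targets:

* **Marginals**: DO and COD_Mn are normal; TN, NH₃-N and TP are
  lognormal — TN's published moments (mean 2.277, sd 3.714, max 18.94
  mg/L) imply a heavy right tail that a normal cannot produce without
  negative mass. Draws are *winsorized* to the observed min–max
  ranges.
* **Calibration**: clamping changes moments (naively moment-matched
  TN loses ~9% of its mean and ~21% of its sd to the cap), so the
  generator solves for the underlying location/scale whose
  *winsorized* distribution hits the target mean and sd exactly,
  using closed-form censored moments and a Nelder–Mead fit at
  configuration time. Large-sample checks (the 83-site layout scaled
  ×120, ≈10⁴ sites) confirm means within ±5% and sds within ±10%.
* **Spatial gradient**: cost indicators are multiplied by (1∓0.25)
  upstream/downstream and DO is shifted by ±1.0 mg/L, so pollution
  worsens downstream as reservoir surveys typically find; the strata
  default to 18 main-stream and 65 tributary sites (23/23/19 across
  sections), matching the 83-site survey layout.
* **Detection limits**: TN and TP draws below configurable LODs
  (0.05, 0.005 mg/L) are stored as exact zeros, mimicking published
  0.000 minima.
* **Dependence**: indicators are independent by default; a Gaussian
  copula knob (`rho`) induces positive TN–NH₃-N–TP association when
  wanted. No between-indicator correlations are published, so the
  default is a stand-in, not an inference.

`generate_planted_cohort()` draws every indicator from the central 60%
of one grade's interval, making the planted class nearly separable;
recovery of planted grades by the full pipeline under uniform weights
is required to reach 90% and in practice is essentially complete.

**What passing these tests shows — and does not.** They show the
arithmetic chain is right and behaves sensibly on data with realistic
marginals, tails, censoring and a spatial gradient. They do not show
the method recovers truth on real reservoirs: the generator has no
seasonality, no hydrological transport, no spatial autocorrelation
beyond the section gradient, independent indicators by default, and
atoms at the range bounds from winsorization that real data lack.
Planted cohorts are deliberately easy (central draws); real sites
straddle boundaries, which is exactly when the ambiguity flag fires.

## Problem sizes and numerical settings

The test suite uses: random 5×5 and 7×5 matrices for the weight
oracle; 10⁴ random concentrations per indicator for partition of
unity (1e−9); the 83-site default cohort for conservation and
end-to-end runs; ~10⁴ sites for generator calibration checks; 500
planted sites for recovery; and 5-seed sweeps for the FCE/EWQI
comparison. Tolerances: weight normalization 1e−12, oracle agreement
1e−10, membership row sums 1e−9, tie recognition 1e−9, emission share
normalization 1e−12. These sizes keep the full suite in seconds while
leaving each property with real statistical teeth.
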