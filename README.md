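# fcewater

Entropy-weighted fuzzy comprehensive evaluation (FCE) of surface-water
quality, for reservoir and river monitoring surveys graded against the
five Chinese surface-water classes (GB 3838-2002, grade I cleanest to
grade V worst). The package is aimed at environmental scientists who
have per-site concentrations of the five routine indicators — dissolved
oxygen (DO), total nitrogen (TN), ammonia nitrogen (NH₃-N), total
phosphorus (TP) and the permanganate index (COD_Mn), all in mg/L — and
want defensible class calls, weight diagnostics, compliance statistics
and pollutant-source accounting from one tested pipeline.

## The method

**Entropy weights.** Concentrations are min-max standardized with
polarity (DO is a benefit indicator, the rest are cost indicators):

    x*_ij = (x_ij − x_j,min) / (x_j,max − x_j,min)        (benefit)
    x*_ij = (x_j,max − x_ij) / (x_j,max − x_j,min)        (cost)

Each indicator's information entropy is computed from its sample
proportions p_ij = x*_ij / Σ_i x*_ij,

    E_j = −(1/ln n) Σ_i p_ij ln p_ij,     0·ln 0 := 0,

and the weight vector is w_j = (1 − E_j) / Σ_j (1 − E_j): indicators
whose values are more concentrated on a few sites carry more
information and more weight.

**Fuzzy grading.** Each indicator gets five membership functions, one
per grade: semi-trapezoids saturating beyond the grade-I and grade-V
apexes, triangles in between, with apexes at the midpoints of the
scheme's grade intervals. A sample's m×5 membership matrix R is
composed with the weights, B = W × R, and the site is assigned the
grade with maximal composite membership b_k (ties break toward the
worse grade). When the top two normalized memberships differ by less
than 0.2 the call is flagged *ambiguous*. An entropy-weighted water
quality index (EWQI = Σ_j w_j q_j with q_j = 100·C_j/S_III,j for cost
indicators) is provided as a scalar comparator, and single-factor
(worst-indicator) grading, stratified compliance/exceedance rates and
source-resolved emission accounting round out the pipeline.

## Worked example

```r
library(fcewater)

sites <- generate_sites(seed = 42)   # synthetic 83-site survey
res <- fce(sites)                    # entropy weights + fuzzy grading
res
#> Fuzzy comprehensive evaluation of 83 sites (scheme: customized )
#> Weights: DO=0.482, TN=0.134, NH3N=0.071, TP=0.076, CODMn=0.236
#> Grades:  I:65  II:5  III:6  IV:4  V:3   (14 ambiguous)
```

The weights say that, across this cohort, DO and COD_Mn varied most
informatively; the grade line counts the class calls and how many were
too close to call (margin < 0.2). The class-V sites sit midstream and
downstream, as the generator's degradation gradient intends:

```r
res$results[res$results$grade == 5,
            c("site_id", "section", "grade_label", "b5", "margin")]
#>    site_id    section grade_label        b5    margin
#> 12    WA12  midstream           V 0.4823197 0.1082166
#> 81     L63 downstream           V 0.6164704 0.3515872
#> 82     L64 downstream           V 0.4823197 0.2427555
```

The scalar index can disagree with the fuzzy call — that disagreement
is itself diagnostic:

```r
ewqi(sites[sites$site_id == "L3", ], res$weights)$score
#> [1] 38.62022    # class I: the index averages, FCE saturates
```

Emission accounting, from the packaged source inventory:

```r
aggregate_emissions(wanan_inventory())
#> Annual pollutant discharge totals (t/a):
#>   CODMn    NH3N      TN      TP
#> 3681.81  457.76  348.50   42.86
round(contribution_ratios(wanan_inventory(), "CODMn"), 4)
#> aquaculture    facility   livestock       rural       urban
#>      0.0578      0.0003      0.3114      0.1483      0.4823
```

So COD_Mn discharge is dominated by urban domestic sources (48%) and
livestock farming (31%).

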