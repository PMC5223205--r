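# floodshift

Detecting simultaneous abrupt regime shifts in river flood-pulse
hydrology and floodplain fish assemblage structure.

Long-term monitoring of tropical floodplain lakes produces two parallel
records: daily river stage at a gauge, and standardised fish catches
(counts per gillnet area) organised by annual flood-pulse cycle. After an
extreme event — a severe drought, say — both records may jump to a new
persistent state. `floodshift` implements the full analytical chain for
asking whether they jumped *together*:

1. **Hydrology** — segment the daily stage series into annual flood-pulse
   cycles (dry / rising / flood / receding seasons split at 20 m and 26 m
   thresholds) and compute seven metrics per cycle: amplitude, minimum,
   maximum, and the four season day-counts.
2. **Assemblage structure** — CPUE matrices, common-species filtering
   (> 0.01 ind/m²), diversity and evenness, abundance anomalies, and
   three ordinations: taxonomic (√-transform → Bray–Curtis → PCoA),
   life-history and trophic (group aggregation → Hellinger → PCA), with
   broken-stick axis retention and a before/after repeated-measures
   ANOVA.
3. **Regime detection** — STARS, the sequential t-test analysis of regime
   shifts: candidate shifts are points deviating from the running regime
   mean by more than `t_crit · sqrt(2σ_l²/l)` and are confirmed or
   rejected by the cumulative Regime Shift Index over the following
   window; optional AR(1) prewhitening.
4. **Response functions** — seven candidate shapes (null, linear, four
   segmented families, sigmoid) fitted by Gaussian (generalised) least
   squares with optional AR(1) errors and per-regime variances, ranked by
   AICc with a parsimony convention for effectively tied models:

   AICc = −2 logL + 2k + 2k(k+1)/(n−k−1)

5. **Missing-cycle sweep** — impute a single missing cycle over the full
   observed range in 0.001 steps, rerun selection at every value, and
   report each family's winning share.
6. **Driver inference** — concordant response type plus coincident shift
   timing between the environmental and biological series ⇒ extrinsically
   driven shift; anything else ⇒ "internal or unmeasured driver".
7. **Synthetic data** — generators for daily hydrographs and species ×
   cycle communities with known regime structure, so the whole pipeline is
   testable without any download.

## Worked example

Simulate sixteen years of daily stage with a programmed regime change
(amplitude +2 m, dry-season minimum −1.5 m) at year 9, compute cycle
metrics, ordinate, detect the shift, and identify the response shape:

```r
library(floodshift)

stage <- gen_hydrograph(n_years = 16, change_year = 9, seed = 42)
fm <- hydro_feature_matrix(stage)
head(fm$raw[, 1:5], 3)
#>    cycle_id amplitude_m    min_m    max_m days_dry
#> 1 2000-2001   10.153549 17.79760 27.95115      108
#> 2 2001-2002    8.999064 17.75855 26.75762      117
#> 3 2002-2003    8.772987 18.06943 26.84242      107

env <- annual_series(seq_len(nrow(fm$standardized)),
                     pca(fm$standardized)$scores[, 1])
shift <- stars(env, list(significance = 0.05, window = 7))
shift
#> STARS (p = 0.05, l = 7): 1 shift(s)
#>   shift at 8 (RSI = 1.130)

select_best(env, tau = shift$shifts[1])
#> Response-function comparison (iid errors, tau = 8)
#>         family k      logL     aicc phi delta_aicc selected
#>      step_mean 3 -22.74787 53.67756   0   0.000000     TRUE
#>  stable_linear 4 -21.98490 55.96979   0   2.292230    FALSE
#>         linear 3 -23.92660 56.03502   0   2.357457    FALSE
#>  linear_stable 4 -22.50359 57.00719   0   3.329627    FALSE
#>        sigmoid 5 -21.14647 58.95960   0   5.282038    FALSE
#>  linear_linear 5 -21.71398 60.09463   0   6.417069    FALSE
#>           null 2 -32.94071 70.88142   0  17.203860    FALSE
```

The detector confirms one shift within a cycle of the programmed change
(the hand-over cycle mixes old and new regime metrics, so landing on
either side of it is expected), and the step-mean response — an abrupt
jump to a new persistent level — beats every alternative shape by more
than two AICc units. The RSI (1.13) is the normalised cumulative evidence
for the shift; positive throughout its confirmation window means no
subsequent year contradicted the new regime.

`compare_drivers()` runs the same machinery on a biological series (for
example PCoA axis 1 of the taxonomic structure) and labels the pair
*extrinsic* when response types and shift timing agree.

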