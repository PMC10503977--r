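# qsarkit

Building and validating linear 2D-QSAR (quantitative structure–activity
relationship) models for small-molecule enzyme inhibitors, in R.

QSAR practitioners fit a linear map from molecular descriptors to activity,

    pIC50 = a0 + a1·x1 + … + ap·xp,

with pIC50 = −log10 of the molar IC50, and then spend most of their effort
proving the model is real: leave-one-out cross-validation (Q²_LOO =
1 − PRESS/SST), Roy's r²m agreement metrics, Y-randomization with the cRp²
chance-correlation statistic, external test-set validation (r²test, Q²F2,
the Golbraikh–Tropsha checklist with origin-constrained slopes k and k′),
and a leverage-based applicability domain (Williams plot, h* = 3(p+1)/n).
qsarkit implements that entire battery, plus descriptor screening (variance,
response correlation, VIF), rule-based drug-likeness evaluation (Lipinski,
Veber, Egan, Muegge, Ghose, Abbott bioavailability score), docking-score vs
activity correlation, and a seedable synthetic-data generator.

The central container, `QSARDataset`, extends Bioconductor's
`SummarizedExperiment` (descriptor matrix as the assay; activity, split
labels, properties and docking affinities as `colData`). A curated dataset
of 25 chalcone MAO-B inhibitors — descriptors, activities, an 80/20
train/test split, collinearity and correlation tables, Y-randomization
runs, physicochemical properties with drug-likeness verdicts, and docking
affinities — ships as plain-text fixtures via `qsarFixture()`.

## Worked example

```r
library(qsarkit)

ds <- qsarFixture("table4")      # 25 chalcones, 20 train / 5 test
screenDescriptors(ds)            # all four descriptors survive VIF < 5

model <- fitQSAR(ds)
model
#> QSARModel with 4 descriptors, fitted on 20 compounds
#>   pIC50 = -3.755 + 0.6357*logP(o/w) + 0.0571*SlogP_VSA4
#>           - 0.4421*vsurf_IW3 + 8.471*BCUT_SMR_2

fitStatistics(model, ds)
#> QSAR fit on 20 compounds, 4 descriptors
#>   r2 = 0.8810  r2adj = 0.8493  RMSE = 0.2873  MAE = 0.2062  F = 27.77

looCrossValidation(ds)
#> LOO cross-validation (n = 20): Q2 = 0.8062  RMSE = 0.3176  MAE = 0.2709

externalValidation(model, ds)
#> External validation (n = 5): r2_test = 0.7065  Q2F2 = 0.5293
#>                              k = 0.9577  k' = 1.0389
#>   [pass] Q2_LOO > 0.5 (0.8062)
#>   [pass] r2_test > 0.6 (0.7065)
#>   [pass] (r2-r02)/r2 < 0.1 & 0.85 <= k <= 1.15 (or primed) (0.0096)
#>   [pass] |r02 - r02'| < 0.3 (0.0508)

applicabilityDomain(ds)
#> Applicability domain: h* = 0.7500, +/-2 sigma residual cut
#>   inside             24
#>   response-outlier   1
#>   outliers: 10d
```

Reading: the model explains 88% of the training activity variance with a
residual error of ~0.29 log units; it survives internal cross-validation
(Q² = 0.81), predicts the five held-out compounds well (r²test = 0.71, all
four Golbraikh–Tropsha conditions pass), and every compound except the
response outlier 10d lies inside the leverage/residual applicability
domain, so predictions for chalcone-like structures in that descriptor
region are defensible. `yRandomization(ds)` confirms the fit is not chance
correlation (random-response refits average R² ≈ 0.2 with negative Q²),
`descriptorContributions(model, ds)` ranks SlogP_VSA4 as the dominant
descriptor once coefficients are standardized, and
`affinityActivityCorrelation()` shows the docking scores track activity
(r² = 0.73). See the methods vignette (`vignettes/qsar-methods.Rmd`) for
the formulas, conventions and design decisions.

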