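# pHflux

Quantification of intracellular pH (pH<sub>i</sub>) regulation in breast
tissue organoids, and the downstream clinical statistics that link it to
tumor biology.

Tumor cells sustain an alkaline pH<sub>i</sub> against a high metabolic
acid load through two membrane acid extruders: Na⁺/H⁺ exchange (NHE1,
CO₂/HCO₃⁻-independent) and Na⁺,HCO₃⁻ cotransport (NBCn1,
CO₂/HCO₃⁻-dependent). `pHflux` is for physiologists and biostatisticians
who work with NH₄⁺-prepulse recordings of BCECF-type ratiometric
fluorescence and with the cohort- and transcriptome-level analyses built
on them.

## What it computes

**Trace quantification.** From a background-subtracted F495/F440 trace
plus a solution-event log: a linear nigericin calibration
(pH = a·ratio + b), protocol segmentation (baseline, NH₄Cl epoch, acid
nadir, recovery), steady-state pH<sub>i</sub>, the intrinsic buffering
capacity β<sub>i</sub> = |Δ[NH₄⁺]<sub>i</sub>/ΔpH<sub>i</sub>| from the
NH₄Cl step, and the net acid extrusion flux

&nbsp;&nbsp;&nbsp;&nbsp;J = β<sub>total</sub>(pH<sub>i</sub>) · dpH<sub>i</sub>/dt,&nbsp;&nbsp;
β<sub>total</sub> = β<sub>i</sub> + 2.3·[HCO₃⁻]<sub>i</sub>,

computed over consecutive 30-s windows of the recovery phase, with the
transport rate extracted at pH<sub>i</sub> 6.5–6.6 and an acid-range
rule that discards windows entirely below pH<sub>i</sub> 6.4 while
preserving at least 0.1 pH of analyzed span. Bicarbonate and ammonium
speciation follow the Henderson–Hasselbalch relation.

**Mechanistic simulators.** An ODE prepulse generator with known
transporter fluxes (logistic pH activation), ammonium-pool chemistry and
calibration noise; a clinicopathological cohort generator with
configurable odds ratios; and a seven-dataset expression/survival
generator with batch shifts, centroid-separable subtypes and hazards
tied to gene z-score groups.

**Cohort statistics.** Mixed-effects paired ±CO₂/HCO₃⁻ comparisons with
Sidak-adjusted contrasts, χ² tests for trend on 6-level IHC scores,
Spearman correlation, multiple linear regression, and binomial/ordinal
logistic regression with odds ratios (e.g. Ki67-high per 0.1 ΔpH, node
metastasis per 10 mM/min of Na⁺,HCO₃⁻ cotransport).

**Survival meta-analysis.** Probe collapse by maximum mean intensity,
double cross-sample standardization (population SD), nearest-centroid
molecular subtyping, z-score stratification (±0.5, fallback ±0.3 when a
group has fewer than 10 deaths), Kaplan–Meier curves, log-rank and
Gehan–Breslow–Wilcoxon tests, and Mantel–Haenszel hazard ratios
HR = (O₁/E₁)/(O₂/E₂).

## Worked example

```r
library(pHflux)

## simulate one organoid recording and quantify it
p   <- transporterParams()                      # vNHE 10, vNBC 8 mM/min
sim <- simulatePrepulseTrace(p, prepulseProtocol(co2 = TRUE),
                             noiseSD = 0.005, seed = 1)
res <- analyzeTrace(sim$trace, defaultCalibration())
res$metrics
#> PhiMetrics (with_co2): steady-state pH_i 7.331 | beta_i 12.0 mM/pH
#>   (cohort_default) | J(6.5-6.6) 15.00 mM/min | QC included
sim$truth$fluxFunction(6.55)                    # ground truth: 15.15
```

The analyzer recovers the simulator's true net acid extrusion at
pH<sub>i</sub> 6.55 (15.0 vs 15.15 mM/min, −1% here; within 10% across
the whole transporter grid at this noise level).

```r
## cohort: the Ki67 model at n = 2000
co <- simulateCohort(cohortSpec(nPatients = 2000), seed = 1)
f  <- logisticBinomial(ki67_group ~ delta_phi, co$patients)
o  <- f$oddsRatios[2, ]
sprintf("Ki67 OR per 0.1 pH: %.2f [%.2f, %.2f]", o$or^0.1,
        o$lower^0.1, o$upper^0.1)
#> "Ki67 OR per 0.1 pH: 3.15 [2.75, 3.60]"
```

The fitted odds ratio for proliferation per 0.1 pH of
CO₂/HCO₃⁻-dependent pH<sub>i</sub> elevation brackets the generating
value of 3.12.

```r
## survival: SLC4A7 within luminal A tumors
ex   <- simulateExpressionStudy(seed = 1)
cd   <- SummarizedExperiment::colData(ex$study)
meta <- survivalMetaAnalysis(ex$probeMatrix, ex$probeMap, cd$dataset,
                             cd$time, cd$event, ex$truth$spec$centroids,
                             targets = data.frame(gene = "SLC4A7",
                                                  subtype = "lumA"))
meta$results[["SLC4A7|lumA"]]
#> SurvivalResult: n = 47/252 | deaths = 18/155
#>   log-rank chi2 = 9.362 (p = 0.00222) | Wilcoxon chi2 = 6.712 (p = 0.00957)
#>   HR = 2.101 [1.443, 3.058]
```

High *SLC4A7* expression within the luminal A subtype carries a hazard
ratio whose interval covers the generating value of 2.18; the group
sizes, deaths and the z-thresholds actually applied are always reported.

See `vignettes/pHflux-methods.Rmd` for the models, estimator choices,
generator design and limitations.

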