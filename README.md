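# lotkar

Cohort life-table demography for interval-censused experiments, with the
sequence-side filters used in de novo transcriptome studies of laboratory
cohorts.

## Who this is for

Experimental ecologists and evolutionary physiologists running classic
life-table assays — individually housed females of a short-lived
invertebrate (the package's presets emulate planktonic rotifers),
censused at fixed intervals (every 12 h) across temperature treatments
until the whole cohort has died — and needing the full downstream
analysis: survivorship and fecundity schedules, intrinsic rate of
increase with bootstrap confidence intervals, survival and fecundity
hypothesis tests, and, for paired RNA-seq work, decontamination of
assembled contigs and count-matrix pre-filtering.

## What it computes

From individual records the package builds the cohort life table: `x`
(age in days at interval starts), `lx` (proportion of the initial cohort
alive at the start of each interval) and `mx` (offspring in the interval
per female alive at its start). The intrinsic rate of population
increase `r` (per day) is the unique root of the Euler–Lotka renewal
equation

    sum_x  exp(-r x) * lx * mx  =  1,

solved by bracketed Brent iteration with Newton polishing to a residual
below 1e-10; `R0 = sum(lx mx)` is the net reproductive rate, and
`sign(r) = sign(R0 - 1)`. Confidence intervals come from resampling
individuals with replacement (199 replicates, 95% percentile interval
from the 5th and 195th order statistics, by default; BCa behind a flag).

The statistical battery is implemented from first principles (reference
implementations are used only as cross-checks in the test suite):
Kaplan–Meier product-limit curves, pairwise log-rank tests with pooled-tie
hypergeometric variance, Kruskal–Wallis with tie correction, pairwise
Wilcoxon rank-sum (exact null enumeration for small untied samples,
tie/continuity-corrected normal approximation otherwise) with Bonferroni
correction, and gaussian/poisson GLMs fitted by IRLS with AIC model
selection over the `species * temperature` lattice.

On the sequence side: competitive contig assignment (a contig is host
material only when its top BLAST hit is the host database *and* the
bit-score gain over the best contaminant hit strictly exceeds 100), rRNA
flagging at an e-value ceiling of 1e-10, FASTA partitioning by class,
and the low-count gene filter (total count >= 10 and detected in >= 2
samples). Synthetic generators with exact ground truth cover all inputs,
so everything is testable without any external data.

## Worked example

Simulate the default two-species thermal design (tolerant species at
20/23/26/32 °C, sensitive at 20/23/26 °C, 24 females each, 12-h census)
and estimate the demography per treatment:

```r
library(lotkar)
rec  <- simulateDesign(defaultDesign(seed = 2024))
demo <- demographyTable(rec, nBoot = 199, seed = 2024)
print(demo, digits = 3)
#>        species temperature_C  n mean_lifespan_days    R0 r_per_day ci_low ci_high n_boot_failed
#> 1  tolerant_sp            20 24               9.08 11.83     0.747  0.674   0.802             0
#> 2  tolerant_sp            23 24               9.23 11.71     0.751  0.688   0.825             0
#> 3  tolerant_sp            26 24               7.06 11.25     0.784  0.700   0.872             0
#> 4  tolerant_sp            32 24               4.38  3.33     0.420  0.301   0.538             0
#> 5 sensitive_sp            20 24              11.19 13.58     0.767  0.688   0.846             0
#> 6 sensitive_sp            23 24               6.90  9.17     0.711  0.612   0.791             0
#> 7 sensitive_sp            26 24               4.85  4.75     0.507  0.364   0.650             0
```

Each row is one cohort: mean lifespan in days (death placed at the end
of its 12-h census interval), net reproductive rate `R0` (expected
lifetime offspring per female), the solved intrinsic rate `r_per_day`,
and its 95% percentile-bootstrap interval. Both species keep `r` around
0.7–0.8 per day at benign temperatures; at each species' top treatment
survival and fecundity collapse together and `r` drops sharply — the
sensitive species already at 26 °C (0.51 per day), the tolerant one only
at 32 °C (0.42 per day).

Fecundity differences across all seven treatments, and the strongest
pairwise contrasts after Bonferroni correction:

```r
fec <- totalOffspring(rec)
grp <- paste0(speciesOf(rec), "@", temperatureOf(rec))
kruskalWallisTest(fec, grp)
#>           method statistic df  p.value p.adjusted
#> 1 kruskal-wallis      55.8  6 3.16e-10         NA

wx <- pairwiseWilcoxon(fec, grp)
head(wx[order(wx$p.adjusted), ], 3)
#>           group_a         group_b          method statistic df  p.value p.adjusted
#> 3  tolerant_sp@20  tolerant_sp@32 wilcoxon-normal       546 NA 1.10e-07   2.31e-06
#> 16 tolerant_sp@32 sensitive_sp@20 wilcoxon-normal        36 NA 2.04e-07   4.28e-06
#> 8  tolerant_sp@23  tolerant_sp@32 wilcoxon-normal       537 NA 2.81e-07   5.90e-06
```

A single cohort's life table and its solved rate:

```r
tab <- buildLifeTable(splitByTreatment(rec)[["tolerant_sp@20"]])
tab
#> CohortTable (tolerant_sp @ 20°C): 30 intervals of 0.5 d, n0 = 24
#>  R0 = 11.83; final lx = 0.08333
solveLotka(tab)
#> [1] 0.747 (residual attribute < 1e-10)
```

`runPipeline()` chains all of this (plus the optional contamination and
count filters) from a YAML config and writes a manifest with seeds,
parameters and MD5 checksums of every output, so reruns are
byte-identical; `inst/scripts/run_pipeline.R` is a thin shell wrapper.

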