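# audcage

Behavioral phenotyping of alcohol use disorder (AUD)-like behavior in mice
from IntelliCage-style home-cage event logs.

## What it does, and for whom

Long-term alcohol self-administration protocols in automated group cages
produce per-animal event logs — every corner visit, nosepoke and lick over
~3 months. For researchers running such protocols, `audcage` turns those
logs into a per-animal AUD-like phenotype:

1. **Five behavioral indices**, one per diagnostic-style test:
   * **M** — motivation: the breakpoint (FR level reached) of a
     progressive-ratio test with the nosepoke-requirement ladder
     2, 4, 8, …, 36, where bursts of pokes spaced < 1 s within one visit
     complete "sets" and ten sets advance the requirement;
   * **E** — extinction: average daily reward-corner nosepokes over the
     7-day extinction test;
   * **CR** — cue reactivity: reward-corner nosepokes during the 24-h
     cue-relapse test;
   * **AR** — loss of control over intake: first-relapse-day alcohol
     consumption, `licks × lick volume × alcohol fraction × 1 g/ml /
     body weight` in g/kg/day (lick volume calibrated cohort-wide, default
     1.94 µl);
   * **P** — persistence: nosepokes during the signalled non-active
     periods of the 3-day persistence test.
2. **Criterion classification**: an animal is positive for a criterion
   when its index is in the uppermost 35 % of the population
   (nearest-rank threshold, strictly-above rule); the **AUD index** is the
   criterion count (0–5), and animals with ≥ 2 criteria are **AUD-prone**,
   the rest **AUD-resistant**. The **AUD score**
   `AS_i = Σ_b (V_ib − mean_b) / SD_b` is the companion continuous
   severity measure.
3. **Structure analysis**: group-conditional Spearman correlation matrices
   and correlation-matrix PCA of the five behaviors, plus the binomial
   independence null for the ≥ k-criteria fraction.
4. **A synthetic-cohort simulator** with latent ground truth (prone
   subpopulation with equicorrelated behavioral propensities, resistant
   subpopulation with independent ones) for validating the whole pipeline.

## Worked example

```r
library(audcage)

cohort <- simulate_cohort(sim_config(n_animals = 58, seed = 1))
bm  <- build_behavior_matrix(cohort$log)
fit <- aud_phenotype(bm, q = 0.35, k = 2)
fit
#> AUD phenotype classification (top 35% criterion rule, >= 2 criteria = prone)
#>   58 animals: 23 AUD-prone (39.7%), 35 AUD-resistant
#>   criterion thresholds:
#>      M      E     CR     AR      P
#>  12.00  39.14  93.00   3.63 102.00
```

23/58 animals met at least two of the five top-35 % criteria; the
thresholds line gives each behavior's criterion cut-point (an FR level for
M, nosepokes/day for E and CR, g/kg/day for AR, nosepokes for P).

```r
phenotype_structure(bm, fit$class)
#> Group-conditional behavior structure
#>   prone: n = 23, mean off-diagonal Spearman r = 0.296, PC1 explains 46.5%
#>   resistant: n = 35, mean off-diagonal Spearman r = -0.060, PC1 explains 30.4%
#>   all: n = 58, mean off-diagonal Spearman r = 0.503, PC1 explains 63.5%

independence_null(0.35, 5, 2)
#> [1] 0.5716007
```

Within the prone group the five behaviors are positively inter-correlated
and load heavily on PC1 (one underlying severity factor); among resistant
animals they are essentially independent. The observed prone fraction
(~0.40) sits well below the 0.572 expected if the five criteria were
independent across the whole cohort — the dependence is concentrated in
the prone subgroup.

`run_pipeline("simulate", out_dir = "out", sim = sim_config(58, seed = 1))`
runs all stages and writes `behavior_matrix.csv`, `aud_results.csv`,
`report.json` and `run_manifest.json`; the same configuration and seed
reproduce the bundle byte for byte. Real data enter through
`run_pipeline("files", events = ..., schedule = ..., registry = ...)` using
the documented CSV dialect (see `?read_event_log`).

## Documentation

The methods vignette (`vignettes/aud-phenotyping.Rmd`) describes the
indices, the classification rules and their edge-case conventions, the
generative model behind the simulator, and known limitations.
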