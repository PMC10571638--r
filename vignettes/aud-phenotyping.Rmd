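---
title: "Phenotyping AUD-like behavior from home-cage event logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping AUD-like behavior from home-cage event logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(audcage)
```

## The problem

Automated group-housing systems such as the IntelliCage record every corner
visit, nosepoke and lick of transponder-tagged mice around the clock for
months. In long-term alcohol self-administration protocols this yields an
event log from which several clinically motivated facets of alcohol use
disorder (AUD)-like behavior can be quantified per animal: motivation to
work for alcohol, perseverative seeking when it is withheld, reactivity to
alcohol-predicting cues, loss of control over intake after abstinence, and
persistence of seeking during signalled non-reward periods. `audcage`
implements this analysis end to end: event-log ingestion and validation,
the five behavioral indices, a composite severity classification, the
group-conditional correlation/PCA structure of the behaviors, and a
synthetic-cohort simulator with latent ground truth so every stage can be
validated without animal data.

## The five behavioral indices

All indices are oriented so that **larger = more AUD-like**, and all daily
quantities use 24-h bins anchored at the dark-phase onset of day 0
(timestamps are seconds since that onset; phase windows are half-open
`[start, end)`, so a boundary event belongs to the later window).

**Motivation (M)** — the breakpoint of a progressive-ratio test. The
nosepoke requirement climbs the ladder 2, 4, 8, 12, 16, 20, 24, 28, 32, 36.
Within one visit, consecutive reward-corner pokes separated by less than
1 s form a burst; a burst reaching the current requirement completes one
*set*, and ten completed sets advance the requirement. `M` is the
requirement in effect at the end of the test — the level the animal
advanced *to*. The protocol does not pin down two details, which we fixed
as follows and exposed as configuration: (i) a partial burst interrupted by
a ≥ 1 s gap or a visit boundary is *lost*, not resumed, because the ladder
is defined by pokes "spaced by less than 1 s during one visit"; (ii)
"level reached" can alternatively be read as the highest level at which a
set was completed — `compute_breakpoint(rule = "last_completed")` gives
that reading.

**Extinction (E)** — average daily reward-corner nosepokes over the 7-day
extinction test (total/7). The alternate `E_delta` subtracts the count of
the last pre-extinction day.

**Cue relapse (CR)** — reward-corner nosepokes during the 24-h cue test;
`CR_delta` subtracts the last extinction day.

**Alcohol relapse (AR)** — intake on the first relapse day in g/kg/day:

\[
\mathrm{AR} = \frac{n_\text{licks} \times v_\text{lick}\,[\mathrm{ml}]
\times f_\text{alcohol} \times 1\,\mathrm{g/ml}}{m_\text{body}\,[\mathrm{kg}]}
\]

with the cohort-wide lick-volume calibration \(v_\text{lick}\) = total
volume / licks (default constant 1.94 µl when no calibration is supplied),
the alcohol volume fraction taken from the schedule of the relapse phase,
and the conventional 1 g/ml density applied to the alcohol fraction of the
consumed volume (not ethanol's physical density — the formula is a field
convention, applied exactly).

**Persistence (P)** — the 3-day persistence test alternates six 6-h
"active" (FR1, cue light) and six 6-h "non-active" periods, active first
(tests start at dark onset). `P` is the nosepoke sum over non-active
periods; `P_delta` is the non-active minus active contrast. Where a
protocol reports both a count and a difference per test, the scored default
is the first-listed quantity (`E`, `CR`, `P`), with the alternates always
computed and selectable via the `behaviors` argument of `aud_phenotype()`.

Lick side (left/right nozzle) is retained in the event model but unused by
the indices; no analysis here is side-resolved.

## Criterion classification and the AUD score

An animal is **positive for one criterion** when its index lies in the
uppermost 35 % of the population (`q = 0.35`). Because quantiles of small
discrete samples are ambiguous, the rule is fully specified as: the
threshold is the nearest-rank \( \lceil (1-q)\,n \rceil \)-th smallest
value of the column, and an animal is flagged iff it is *strictly above*
the threshold. On 100 distinct values exactly 35 animals flag; animals tied
with the threshold never flag (a conservative, deterministic tie rule — a
documented choice, not an inference); a zero-variance column flags nobody
and warns. The **AUD index** is the criterion count (0–5); animals with
index ≥ 2 are **AUD-prone**, the rest **AUD-resistant**. The **AUD score**
is the z-sum \( \mathrm{AS}_i = \sum_b (V_{ib} - \bar V_b)/\mathrm{SD}_b \)
with the sample (n − 1) SD (a `sd_type` switch gives the population
convention); each z-column has mean 0 and SD 1, so the population AS sums
to zero and AS is invariant to affine rescaling of any behavior.

As context for the observed prone fraction, `independence_null(q, m, k)`
returns the binomial tail \( \sum_{j \ge k} \binom{m}{j} q^j (1-q)^{m-j} \):
for independent criteria at `q = 0.35`, 57.2 % of animals would meet ≥ 2 of
5 criteria. A prone fraction well below that value indicates positively
dependent criteria concentrated in a subpopulation.

## Structure analysis

`phenotype_structure()` reports, per group (prone / resistant / all), the
5 × 5 Spearman matrix with two-sided p-values and a PCA. Choices: PCA is an
eigendecomposition of the group's **correlation** matrix, since the
behaviors have incommensurable units (this matches the z-scoring used by
the AS); components are ordered by eigenvalue and signed so each
component's largest-magnitude loading is positive. Spearman p-values use
the large-sample t approximation by default, with `exact = TRUE` available
for the exact permutation null, advisable below ~10 animals per group.
No multiple-testing correction is applied by default (raw r matrices are
the field's reporting convention); `stats::p.adjust` can be applied to the
returned p matrix if desired. Groups smaller than 4 are omitted (or raise,
per `on_small`).

## The synthetic-cohort generator

The generator is a first-class, tested module, not a fixture. Each animal
is latently **prone** (probability 0.38) or **resistant**; its five
behavioral propensities are drawn from a multivariate normal that is
equicorrelated within class — `rho_prone = 0.7` versus
`rho_resistant = 0` — and mapped to non-negative event rates by a
normalized softplus link (propensity 0 maps to multiplier 1). This is the
minimal generative model producing the qualitative two-group contrast the
pipeline is meant to detect: behaviors that are measures of a single factor
within the prone subgroup, and mutually independent behaviors among
resistant animals. The equicorrelation must satisfy rho > −1/4 for
positive definiteness of a 5 × 5 equicorrelation matrix.

The default schedule spans ~89 days: 4 d adaptation, alcohol initiation at
4/8/12 % (3/3/6 d), 32 d free access to 10 % alcohol, 3 d motivation test,
3 d persistence test, 3 d free access (so the extinction baseline day is an
ordinary drinking day), 7 d extinction, 24 h cue relapse, 2 d alcohol
relapse, 12 d free access, and a second 7-d extinction test. Event rates
default to values realistic for group-housed C57BL/6J females: ~29 corner
visits/day with a 3:1 dark:light ratio, ~1.3 nosepokes per visit, ~15
licks per rewarded poke, giving ~2–3 g/kg/day at 10 % alcohol. Phase
behavior is propensity-driven: a progressive-ratio agent completes sets up
to a propensity-scaled capacity; extinction counts are Poisson with
propensity-scaled level and slowed decay (baseline 0.35/day); cue-day,
first-relapse-day and non-active persistence responding are
propensity-scaled Poisson counts. The protocol's motivation-test
termination rule ("stop once 90 % of animals are stable for 24 h") is a
*scheduling* concern and lives in the generator's fixed 3-day window;
scoring takes the slice as given.

Determinism: one root seed draws classes, propensities and body weights;
each animal is then simulated on its own substream with seed
`(root + 1000003·i) mod (2^31 − 1)`, so cohorts are byte-reproducible and
animal *i* does not change when the cohort grows. Timestamps carry
millisecond resolution so CSV round trips are exact.

What the generator does **not** emulate: social interaction and corner
competition, circadian shape beyond the 3:1 dark:light step, alcohol
pharmacokinetics, day-to-day drift, sex/strain effects, and equipment
artifacts (missed transponder reads, double-triggered sensors). Passing
tests on synthetic cohorts therefore demonstrate that the pipeline
recovers a planted two-group correlation structure from realistic event
volumes — not that real cohorts have that structure.

## Validation strategy and problem sizes

The test suite checks every index against hand-computed examples, checks
the breakpoint replay against an independently written burst-decomposition
simulator on hundreds of randomized streams, checks Spearman/PCA against
first-principles rank arithmetic and an SVD-route decomposition, and checks
the binomial independence null against direct Monte-Carlo. End-to-end,
cohorts of 200 animals (10 seeds) are simulated to verify that ≥ 2-criteria
classification recovers the latent class in well over 75 % of animals, with
agreement degrading monotonically as the class trait gap shrinks to zero;
20 cohorts of 58 animals verify that the latent-prone subgroup shows a
higher mean off-diagonal Spearman correlation and higher PC1 explained
variance than the latent-resistant subgroup. These sizes (58 and 200
animals; 5–20 seeds per claim) were chosen to keep Monte-Carlo error well
below the tested margins while remaining desk-scale.

## Worked example

```{r example, eval = FALSE}
cohort <- simulate_cohort(sim_config(n_animals = 58, seed = 1))
bm <- build_behavior_matrix(cohort$log)
fit <- aud_phenotype(bm, q = 0.35, k = 2)
fit
summary(fit)
plot(fit)
phenotype_structure(bm, fit$class)
```

`run_pipeline()` wraps these stages and writes `behavior_matrix.csv`,
`aud_results.csv`, `report.json` and `run_manifest.json` (config echo,
seed, package version, input checksums); identical configuration and seed
reproduce the bundle byte for byte.

## Known limitations

* The criterion rule is population-relative: thresholds, flags and classes
  are only meaningful within the cohort they were fitted on. `predict()`
  scores new animals against a fitted population without refitting, which
  is a deliberate asymmetry.
* The breakpoint is coarse (ten ladder values), so criterion flags for `M`
  involve heavy ties; the strict tie rule then flags fewer than `q·n`
  animals — a property of any quantile rule on discrete data.
* Spearman matrices on groups of 5–20 animals carry sampling SDs of
  ~0.2–0.45 per pair; single-cohort structure contrasts should be read
  qualitatively, which is why validation aggregates over seeds.
* The simulator's lick microstructure (fixed ~7.7 Hz bursts after rewarded
  pokes) is schematic; only lick *counts* enter the indices.
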