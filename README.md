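# hoiscan

Detection of higher-order interactions (HOIs) in experimental microcosm
food webs from abundance time series.

## What it does, and for whom

Community ecologists usually model competition as fixed pairwise links.
An HOI — also called an interaction modification — occurs when the
per-capita effect of one species on another changes with the density of
an additional species (interspecific HOI) or of one of the interacting
pair itself (intraspecific HOI). `hoiscan` is for experimentalists who
have density time series of small communities (here: two focal ciliate
competitors, *Colpidium* `C` and *Dexiostoma* `D`, cultured alone or
with *Paramecium* `P`, *Spirostomum* `S`, and/or the predator
*Spathidium* `Pd` — six compositions × four replicate microcosms,
sampled every second day for 53 days) and want to know whether HOIs are
detectable and whether they matter for species persistence.

The workflow:

1. **Growth rates** — the response for focal species *i* is the
   interval-scaled density ratio
   `r = (N[i,t+dt]/N[i,t]) / dt`
   with all species' densities at time *t* as covariates
   (`compute_growth_rates()`).
2. **Six-model suite** (`fit_all_models()`) — Gaussian GLMs of `r` on
   densities:
   - additive Lotka–Volterra: `r = λ − Σ_j α_ij N_j` (identity link)
   - interactive LV with intraspecific HOIs: adds `− Σ_j β_ijj N_j²`
   - interactive LV with interspecific HOIs: adds `− Σ_{j<k} β_ijk N_j N_k`
   - interactive LV, full HOI: both term sets
   - additive Ricker: `r = λ exp(− Σ_j α_ij N_j)` (log link)
   - interactive Ricker: Ricker with the cross-product HOI terms
3. **Model selection** (`select_model()`) — small-sample
   `AICc = −2ℓ + 2K + 2K(K+1)/(n−K−1)`; among models within
   ΔAICc < 2 of the best, the one with fewest parameters K wins
   (K counts intercept, slopes and the Gaussian dispersion).
4. **Persistence** — time-to-extinction with right-censoring at day 53,
   Kaplan–Meier curves, k-group and pairwise log-rank tests
   (`extract_survival()`, `km_estimate()`, `logrank_test()`,
   `pairwise_logrank()`).
5. **Abundance** — per-microcosm mean densities and a two-factor
   (third-species identity × predator presence) linear model on the
   log10(mean+1) scale (`summarize_abundance()`, `abundance_effects()`).

A seeded synthetic-data generator (`generate_study()`) emulates the
full 24-microcosm experiment — LV/Ricker dynamics with optional HOI
terms, lognormal process noise, the day-4/day-8 predator introduction
schedule, and Poisson subsample counting at 250 µL × 3 — so the entire
pipeline is testable without any external data.

## Worked example

```r
library(hoiscan)
run <- run_pipeline(pipeline_config(seed = 42))
print(run)
```

```
<hoi_run>
  microcosms: 24 | records: 2052
  growth observations: 624
  model selections: 6
    C/CD -> additive_LV
    C/CDP -> interactive_Ricker
    C/CDS -> additive_LV
    D/CD -> interactive_Ricker
    D/CDP -> interactive_Ricker
    D/CDS -> additive_Ricker
```

24 simulated microcosms yield 624 usable growth transitions; for each
focal species × predator-free community the six models are fitted on
the pooled replicates and the most parsimonious model is reported. One
selection table in full:

```r
print(run$selections[["C_CD"]])
```

```
Model selection | focal C | community CD | n = 104
                model K    AICc dAICc parsimonious
   interactive_Ricker 5 -390.81  0.00        FALSE
          additive_LV 4 -390.72  0.09         TRUE
 interactive_LV_inter 5 -390.57  0.25        FALSE
 interactive_LV_intra 6 -389.13  1.69        FALSE
  interactive_LV_full 7 -388.28  2.54        FALSE
      additive_Ricker 4 -366.18 24.63        FALSE
```

Four models sit within ΔAICc < 2 of the best; the additive LV model has
the fewest parameters (K = 4) among them and is selected — the correct
call here, since this synthetic community was generated from an
additive LV model. Persistence in the same run:

```r
print(run$survival$C$competitive$logrank)
#> Log-rank test: chisq = 0 on 2 df, p = 1 (groups: CD, CDP, CDS)
```

No *Colpidium* extinctions occur in these predator-free simulated
communities, so the survival curves are identical.

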