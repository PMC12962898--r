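# napcensus

Measuring **output homogeneity** in network-analysis (network
pharmacology) literatures: the tendency of studies on entirely different
herbal preparations and diseases to report the same narrow set of "key"
metabolites (quercetin, kaempferol, ...), targets (AKT1, TNF, ...) and
pathways (PI3K-Akt, AGE-RAGE, ...). The package is aimed at meta-research
on this literature: it turns a structured corpus of per-study extraction
records into eligibility cohorts, prevalence rankings, robustness analyses
and a compound–target network audit, with every step validated on
synthetic corpora whose statistical structure is known by construction.

## What it computes

For each category (metabolite / target / pathway), studies pass a fixed
gate sequence — single-compound focus (metabolite census only),
completeness, glossary heading match, smallest-list selection, synonym
standardization, and an item-count threshold (default ≤ 30) — yielding a
cohort of size *N* with a complete exclusion ledger. The census statistic
is per-element prevalence

> prevalence(e) = n(e)/N, the fraction of cohort studies whose
> standardized key-element list contains e,

ranked by count with deterministic tie-breaks and printed as half-up
one-decimal percentages. Robustness analyses: **threshold sensitivity**
(Top-k keeps studies reporting ≤ k elements; cohorts nest as k grows),
**methodology stratification** (database-dependent vs experiment/omics-
integrated studies), and **chemical-class share** (e.g. flavonoids among
the top-20 metabolites).

The network audit takes a compound–target edge list plus an in-vivo
detection evidence list and quantifies the "chemical ghost" problem:
compounds lacking in-vivo evidence (*ghosts*), their distinct-target
degrees versus the background, targets connected *only* through ghosts,
and Jaccard comparison of core target sets.

A synthetic generator (`synthetic_config()` / `generate_corpus()` /
`generate_network()`) emulates a popularity-biased (Zipf) literature with
configurable exclusion rates and an integration mixture, with an exact
analytic inclusion-probability oracle (`expected_prevalence()`) for
parameter-recovery validation.

## Worked example

```r
library(napcensus)
gl <- synth_glossary(); sy <- synth_synonyms()

# a 1,038-study corpus pinned to the census exclusion profile
corp <- generate_corpus(synthetic_config(n_studies = 1038, seed = 1),
                        mode = "exact")
co <- build_cohort(corp, "metabolite", gl, sy)
co
#> <napc_cohort> metabolite, threshold 30: N = 465 included
#>   excluded single_compound_study  305
#>   excluded incomplete_data        1
#>   excluded no_matching_heading    259
#>   excluded exceeds_threshold      8

head(prevalence(co), 3)[, c("element", "n", "N", "percent")]
#>       element     n     N percent
#> 1:  Quercetin   295   465    63.4
#> 2: Kaempferol   205   465    44.1
#> 3:   Luteolin   165   465    35.5
```

465 of 1,038 studies survive the metabolite gates; under the biased
generative defaults the top flavonoids dominate the ranking. The ghost
audit on the embedded re-analysis network:

```r
fx <- fixture_taohong(seed = 1)
aud <- ghost_audit(fx$network, fx$evidence,
                   core_a = fx$core_empirical, core_b = fx$core_database)
aud
#> <napc_ghost_audit> 5 ghosts (mean degree 138.8 -> 139), 149 ghost-only targets
aud$core_comparison$jaccard
#> [1] 0.1111111
"AKT1" %in% aud$ghost_only_targets
#> [1] TRUE
```

The five database-derived ghost compounds average 138.8 predicted targets
(≈ 139) against an evidenced-compound mean of 32; AKT1 enters the network
only through ghosts; the empirically anchored and database-derived core
target sets share a single protein (Jaccard 1/9).

The `analysis/` directory holds the numbered workflow
(`01_simulate.R` … `04_network_audit.R`) that generates the corpora, runs
the census, the robustness analyses and the audit, and writes all tables
under `results/`.

## Vignette

`vignettes/census-methods.Rmd` documents the model, the gate semantics,
the rounding and tie-break rules, the synthetic generative model and its
analytic oracle, and the package's limitations.
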