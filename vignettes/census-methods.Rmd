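---
title: "A homogeneity census for network-pharmacology literatures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A homogeneity census for network-pharmacology literatures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(napcensus)
```

## The problem

Network analysis (network pharmacology) studies of herbal preparations map
database-predicted constituents to targets and pathways and then report a
short list of "key" elements. Across that literature the same few molecules
recur with striking regularity — quercetin among metabolites, AKT1 among
targets, PI3K-Akt among pathways — largely independent of the remedy or the
disease. `napcensus` implements the machinery needed to *measure* that
output homogeneity on a structured corpus of per-study extraction records:
standardized extraction of key-element lists, eligibility cohorts with full
exclusion ledgers, prevalence rankings with sensitivity and stratified
analyses, and a compound–target network audit that quantifies the "chemical
ghost" phenomenon (database compounds never detected in vivo carrying
inflated target degrees).

Because the corresponding field-level dataset is a supplementary artifact
rather than a public database, the package pairs every analysis with a
synthetic-corpus generator that reproduces the statistical structure the
census assumes, so the full pipeline is testable and its estimators
checkable against analytic expectations without any downloads.

## Corpus model

A corpus is two delimited tables. `studies.csv` holds one row per article:
a unique `article_id`, the study focus (`mixture` vs `single_compound`),
two independent per-category methodology flags (`metabolite_method`:
database-only vs experimental identification-integrated; `target_method`:
database-only vs omics-integrated; both may be `unknown`), and per-category
completeness booleans. `findings.csv` is long format — one row per reported
item, keyed by (`article_id`, `category`, `heading_phrase`) with
`item_rank` carrying within-list order. This keeps items ordered and makes
round-trips bit-exact; the one representational constraint is that two
distinct lists under a byte-identical heading within the same study and
category cannot be distinguished and are read as one list.

Validation reports *every* violation with table and row coordinates rather
than stopping at the first, which matters when auditing hand-extracted
corpora.

## Extraction gates

Per study and category the outcome is exactly one of: a standardized
element list, or one exclusion reason. The gate order is fixed and tested:

1. **Focus gate** — single-compound studies are excluded from the
   *metabolite* census only. A study of one purified compound has no
   meaningful "key metabolite list", but its target and pathway findings
   remain valid, and the cohort arithmetic (1,038 → 465/880/917 in the
   motivating census) is only consistent with this reading.
2. **Completeness gate** — categories flagged incomplete are excluded.
3. **Heading match** — a list counts only if its heading, normalized,
   *exactly equals* a glossary phrase for the category. Substring matching
   is deliberately avoided ("non-core targets" must not match "core
   targets"); glossaries enumerate variants instead. The shipped glossary
   ("key targets", "core targets", "hub genes", ...) is a placeholder:
   real analyses should load a curated one via `read_glossary()`.
4. **List selection** — if several non-identical lists match, the smallest
   (most refined) is taken; byte-identical lists collapse. An equal-size
   tie keeps the first-occurring list and emits a warning — the refinement
   rule gives no guidance, so determinism plus a visible signal is the
   safest behaviour.
5. **Standardization** — names are normalized (case folding, whitespace
   collapsing, Greek transliteration, dash unification) and mapped through
   the synonym table; post-mapping duplicates are dropped, keeping first
   occurrence. Synonym maps are validated at load: an alias with two
   canonicals or a chained canonical is a hard error, and every canonical
   is self-registered so that applying the map twice is a no-op.
6. **Threshold gate** — lists longer than `max_items` (default 30) are
   excluded. The threshold is applied *after* standardization and
   deduplication: duplicates and synonyms are nomenclature artifacts, and
   the census counts unique elements. Because the alternative reading
   (raw item count) is defensible, both are exposed via
   `dedupe_before_threshold` so the choice itself can be
   sensitivity-checked.

## Census statistics

**Prevalence** is the fraction `n/N` of cohort studies whose standardized
list contains an element; each study counts at most once per element.
Tables order by count descending, ties broken by canonical name ascending
(deterministic across runs); percentages are `100 n/N` rounded **half-up**
to one decimal. Half-up (rather than R's banker's rounding) is the rule
consistent with the bulk of the printed values this pipeline is validated
against, e.g. `429/880 -> 48.8` on an exact `.75` tie; a small epsilon
absorbs binary representation error in the ratios. A few printed values in
the motivating census are instead consistent with truncation; the rule is
therefore a documented choice, not a claim about the source's software.

**Threshold sensitivity** recomputes the census at stricter thresholds
(default 30, 20, 10, 5). "Top-*k*" filters *studies* (standardized list
length at most *k*); it never truncates lists, which carry no intrinsic
ranking — the shrinking printed denominators (465 → 258) identify study
filtering as the intended semantics. Cohorts therefore nest across
thresholds, a property the tests assert for arbitrary corpora.

**Stratified analysis** contrasts database-dependent against
experiment/omics-integrated studies per category. Studies with `unknown`
flags stay in the overall cohort but are dropped from both strata (their
count is logged); stratum tables must recombine — per element, the flagged
overall count equals the sum across strata — and this is tested.
Pathways carry no methodology flag and cannot be stratified. No
inferential statistics are attached: the census is descriptive by design.

**Class share** reports the fraction of the top-*k* (default 20) ranked
metabolites belonging to a focal chemical class (default flavonoid),
using a user-supplied class map with unmapped elements labelled
`unclassified`.

## The chemical-ghost network audit

The audit consumes a user-supplied compound–target edge list and an
in-vivo detection evidence list (e.g. blood-absorbed constituents); it
never queries prediction databases. After canonicalization and
deduplication:

- a **ghost** is a network compound absent from the evidence set;
- a compound's **degree** is its number of *distinct* targets (multiple
  sources never double-count);
- a **ghost-only target** has at least one edge and every incident
  compound is a ghost — it entered the network exclusively through
  unverified chemistry;
- core target sets are compared by intersection, Jaccard index and
  asymmetric differences.

`ghost_only_targets()` is antitone in evidence (adding evidence can only
shrink the set) and all operations are invariant under synonym-aliased
input; both are property-tested. The embedded re-analysis fixture carries
five ghost compounds with degrees 223, 125, 119, 118 and 109 (mean 138.8,
i.e. 139 to the nearest integer), six evidenced constituents with a mean
degree of 32, a ghost-only AKT1, and two five-element core sets whose
Jaccard index is 1/9.

## The synthetic generative model

`synthetic_config()` parameterizes the generator; its defaults are the
package's study conditions and are not tuned per analysis:

- **Population**: 1,038 studies; single-compound rate 0.294; per-category
  no-matching-heading rates 0.249/0.103/0.084; incomplete rates
  0.001/0.002/0.004 — the observed exclusion profile of the motivating
  census, read as rates.
- **Element universes**: 300 metabolites, 500 targets, 200 pathways,
  popularity-ranked with Zipf exponent `s = 1` (weight of rank *r*
  proportional to `1/r^s`). The head of each universe carries realistic
  names; 75% of the top-20 metabolites come from a flavonoid roster.
- **List lengths**: a shifted negative binomial (`size` 3, mean 10)
  truncated at `L_max = 40`, leaving a small tail above the 30-item
  threshold so over-threshold exclusions occur at a realistic few-per-mille
  rate.
- **Methodology mixture**: a study is integrated with probability 0.295
  (metabolites) / 0.174 (targets) — the observed stratum proportions.
  Database-dependent studies draw their lists (weighted, without
  replacement) from the popularity law; integrated studies from
  `w * popularity + (1 - w) * uniform` over a disease-specific
  sub-universe, defaulting to the low-popularity half with `w = 0.3`.
  These two mixture parameters have no counterpart reported by the
  motivating census; they were chosen once to produce a clear but not
  degenerate integration contrast and are the model's main free knobs.
- **Nomenclature noise**: 15% of items are rendered as a known synonym of
  their canonical name, exercising the standardization path.
- A single integer seed drives one generator stream; the same
  configuration is byte-reproducible. An **exact mode** pins per-category
  exclusion counts into disjoint study blocks, reproducing prescribed
  cohort arithmetic exactly — this is how the 465/880/917 fixtures are
  built.

**What the generator does not emulate**: real heading diversity (it samples
from the glossary plus a fixed decoy list), disease-area structure beyond
a single sub-universe, correlations between categories within a study,
secular trends, and any ADME/assay-interference chemistry. Passing tests
on synthetic corpora therefore validate the *pipeline's arithmetic and
invariants*, not any claim about the real literature's parameter values.

### Analytic oracle

`expected_prevalence()` returns the probability that a study's list
contains a given element under the configured stratum weights and length
law. For successive weighted sampling without replacement this has no
simple closed form; the package computes it exactly by a subset-mass
dynamic program (probability mass over sets of already-drawn non-focal
elements, advanced one draw at a time), feasible for universes up to ~16
elements and the list lengths used in validation, and by Monte Carlo with
a reported standard error otherwise. The exact path is verified against
brute-force enumeration over ordered draws on a four-element universe, and
the generator is validated against the oracle by parameter recovery:
across 20 seeds at 2,000 studies each, empirical stratum prevalences of
the leading elements fall within three binomial standard errors of the
analytic values in at least 95% of checks. The oracle also certifies the
qualitative homogeneity mechanics: the top element's inclusion probability
is monotone in the Zipf exponent, and integration (`w < 1`) lowers it.

## Numerical and degenerate-input choices

- Rounding: half-up via `floor(x * 10^d + 0.5 + 1e-9) / 10^d`; the epsilon
  is orders of magnitude above representation error of `100 n/N` and
  orders below any half-tie gap.
- Empty inputs: an empty corpus yields `N = 0` ledgers and empty tables;
  an element appearing in zero studies is never emitted; Jaccard of two
  empty sets is defined as 1; the mean degree of an empty compound subset
  is an error, not `NaN`.
- Determinism: all rankings and tie-breaks are total orders; two runs on
  the same inputs produce byte-identical report bundles.
- Validation sizes: the test suite exercises 1,000 random small corpora
  for ledger conservation, nested-loop recounts up to ~50 studies,
  20 x 2,000-study corpora for parameter recovery, and the pinned
  1,038-study fixtures for the cohort and percentage arithmetic.

## Limitations

The census is only as good as its inputs: the package deliberately does no
PDF/text mining, no fuzzy name matching and no structure-based identity
resolution (InChI/SMILES), so nomenclature unification is bounded by the
curated synonym table, and heading coverage by the glossary. Pathway lists
transcribed from enrichment-plot figures are assumed already present in the
findings table. The network audit is confined to degree statistics and set
comparisons — no enrichment statistics, docking or non-degree centralities —
and the shipped fixtures, while arithmetically pinned to published worked
examples, are synthetic reconstructions, not the original networks.
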