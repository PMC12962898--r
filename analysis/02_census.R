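#!/usr/bin/env Rscript
# Step 2 — eligibility cohorts and overall prevalence census.
#
# Reads the exact-mode corpus from step 1, partitions every study into the
# included cohort or an exclusion bucket per category, and writes the
# prevalence tables and exclusion ledgers under results/census/.

suppressPackageStartupMessages(library(napcensus))
seed <- 20260926L
corp <- read_corpus("results/corpus/census_studies.csv",
                    "results/corpus/census_findings.csv")
gl <- synth_glossary(); sy <- synth_synonyms()

res <- run_census(corp, gl, sy, thresholds = NULL, stratified = FALSE,
                  out_dir = "results/census", seed = seed)
for (cat in names(res$cohorts)) {
  co <- res$cohorts[[cat]]
  tb <- res$tables[[cat]]
  cat(sprintf("\n%s cohort: N = %d (excluded: %s)\n", cat, co$N,
              paste(sprintf("%s=%d", names(co$excluded), lengths(co$excluded)),
                    collapse = ", ")))
  cat("top 3:\n")
  for (i in seq_len(min(3, nrow(tb)))) {
    cat(sprintf("  %d. %s %s\n", i, tb$element[i],
                format_prevalence(tb$n[i], tb$N[i])))
  }
}
cat("\nwrote census tables to results/census\n")
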