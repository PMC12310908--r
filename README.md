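# beetlegut

Core microbiota, diversity and functional prediction for small-cohort insect
gut 16S amplicon surveys.

Ground beetles (*Poecilus*, Carabidae) are agriculturally important
predators whose gut microbiome reflects both host biology and farming
practice. Surveys of such hosts typically yield an OTU count table for a
handful of individuals (here, 17), a taxonomy assignment per OTU, and a
qPCR panel quantifying total bacteria and selected targets per gut. This
package implements the downstream analysis of such a survey, for
microbiome researchers who want every step reproducible and testable:

1. **Mutual-information OTU filtering.** OTU relative-abundance profiles
   are discretized (equal-frequency bins) and every pair is scored by
   plug-in mutual information, MI = Σ p(x,y) ln[p(x,y)/(p(x)p(y))] (nats).
   Pairwise MIs are screened against a margin-preserving permutation null
   (Bonferroni over each OTU's partners); an OTU's filter score is its
   strongest significant association, and OTUs with score below τ
   (default 0.01) are removed. A τ scan reports retained OTU counts and
   cumulative relative abundance per candidate threshold, and the removed
   read mass is reported as percent information loss.
2. **Core microbiota.** A taxon is core when prevalence ≥ 80% of samples
   *and* mean relative abundance ≥ 0.01% (zeros included), at any
   taxonomic rank; qPCR total loads convert relative to absolute
   abundance (16S copies/gut).
3. **Diversity.** Seeded rarefaction; Shannon, Gini-Simpson, observed
   richness, classic Chao1 (S + F1²/2F2) and the Zahl jackknife Shannon
   estimator; Bray-Curtis, PCoA and PERMANOVA.
4. **Functional prediction.** Abundance-weighted capacity scores
   raw(s,c) = Σ_g RA(s,g)·C(g,c) over a packaged 10-genus × 12-class
   pathway capacity matrix (or any genus × EC table), normalized per
   sample to "predicted score values" that sum to 100; EC scores
   aggregate to pathways through an offline snapshot map.
5. **Associations.** Spearman + Benjamini-Hochberg per diversity metric,
   small-n exact Kendall τ_b, multiple regression of function on the five
   alpha indices, PAM clustering of the ordination with per-category
   Kruskal-Wallis tests, and Mood's median test.

A synthetic-study generator (`generate_study()`) emulates the survey's
shape — 17 samples in three composition clusters, 17 planted core OTUs
over ten known gut genera, correlated satellite OTUs, independent
transients, one 99.1%-dominated dysbiotic sample, log-normal qPCR loads —
with known ground truth, so every stage is testable offline. See the
methods vignette (`vignettes/beetlegut-methods.Rmd`) for models, defaults
and design rationale.

## Worked example

```r
library(beetlegut)

study <- generate_study(study_design(seed = 1))
study$table
#> count_table: 17 samples x 63 OTUs, 1,182,817 reads

filt <- apply_mi_filter(study$table)
filt$report
#> mi_filter_report: 37 retained, 26 removed (tau = 0.01, 3 bins); information loss 4.37%

core <- detect_core(filt$table)
core
#> core_result: 17 of 37 taxa are core (prevalence >= 0.8, mean RA >= 0.0001)

cap <- load_capacity_fixture()
scores <- functional_scores(
  core_genus_abundance(filt$table, study$taxonomy, core), cap)
scores
#> score_table: 17 samples x 12 categories; total scores 1309.68..1919.85
#>  skipped (no capacity row): unclassified_Enterobacteriaceae

round(head(scores$predicted_score_value[, 1:5], 3), 2)
#>    amino_acid_synthesis fatty_acid_biosynthesis monosaccharides
#> P1                21.30                    3.47           18.97
#> P2                22.22                    3.68           16.74
#> P3                21.35                    3.49           18.81
#>    nitrogen_metabolism protein_degradation
#> P1               10.63               21.73
#> P2               10.58               20.35
#> P3               10.66               21.75
```

Reading the output: the MI filter removed 26 of 63 OTUs — the planted
transients plus the mono-dominant Spiroplasma OTU — costing 4.4% of reads;
core detection recovered exactly the 17 planted core OTUs; and the
per-sample predicted score values (percentages summing to 100) show the
familiar picture for these communities: amino-acid synthesis and protein
degradation are the best-supported pathway classes, with one core OTU
resolved only to family level reported in the scorer's skip list rather
than silently dropped.

`run_pipeline(pipeline_config(...))` chains all stages, persists every
intermediate (filtered table, τ scan, network edges, core summary, alpha
and beta diversity, scores, association tables) under an output directory
and writes a provenance manifest with per-stage checksums. A thin CLI
wrapper lives at `inst/scripts/beetlegut.R`.

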