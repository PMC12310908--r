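---
title: "Methods: models, estimators and design choices in beetlegut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in beetlegut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beetlegut)
```

beetlegut analyses small-cohort insect gut 16S surveys starting from an OTU
count table. The pipeline has five stages: mutual-information (MI) filtering
of the OTU table, core-microbiota detection, diversity profiling, functional
capacity scoring, and an association layer linking function to diversity.
This vignette documents the models behind each stage, the tunable parameters
and their defaults, and the choices made where the design was genuinely open.

## The mutual-information OTU filter

Low-abundance amplicon surveys carry hundreds of OTUs whose counts are noise:
sporadic detections, cross-talk, transient passengers. Rather than an
arbitrary abundance cutoff, the filter asks whether an OTU participates in at
least one informative association with another OTU.

Each OTU's relative-abundance profile across the $n$ samples is discretized
by equal-frequency binning (ties share a bin). For a pair of discretized
profiles $X, Y$ the plug-in mutual information, in natural-log units (nats),
is

$$\widehat{I}(X;Y) \;=\; \sum_{x,y} \hat p(x,y)\,
  \ln\frac{\hat p(x,y)}{\hat p(x)\,\hat p(y)} .$$

**Why raw MI cannot be thresholded at small n.** $\widehat{I}$ is biased
upward by roughly $(r-1)(c-1)/(2n)$ nats ($r \times c$ bins). With 17
samples and 3 bins this bias is about 0.12 nats, and in simulation the
*smallest* plug-in MI observed between independent 17-sample profiles is
about 0.011 — already above a threshold of $\tau = 0.01$. A filter that
compared raw MI to $\tau$ would therefore retain everything except
exactly-constant profiles. The filter consequently separates two concerns:

1. **Is the association real?** Each pairwise MI is screened against its
   margin-preserving permutation null (a shared, fixed-seed permutation set
   of size `n_null_perm = 2000`, so the filter is fully deterministic). The
   pair is significant when its MI exceeds the null's
   $1 - \alpha/(m-1)$ quantile, a Bonferroni correction over the $m-1$
   candidate partners of each OTU (`edge_alpha = 0.05`). By construction the
   expected fraction of pure-noise OTUs that survive the screen is at most
   `edge_alpha`.
2. **How strong is it?** An OTU's filter score is the largest plug-in MI
   among its *significant* partners (`score_rule = "max_pairwise"`;
   `"mean_pairwise"` is available), and 0 when it has none. The threshold
   $\tau$ (default 0.01, candidate scan 0.005/0.01/0.02/0.05) applies to
   this score. Two OTUs with identical profiles both score their common
   profile entropy; a constant profile scores 0. Setting `edge_alpha = 1`
   disables the screen and recovers thresholding of raw MI.

**Bins.** The bin count defaults to
$\max(2, \min(\lfloor\sqrt n\rfloor, \lfloor n/5 \rfloor))$: the familiar
square-root rule, capped so that every marginal stratum keeps at least five
samples (the usual contingency-table adequacy rule). At $n = 17$ this gives
3 bins; an uncapped $\lfloor\sqrt{17}\rfloor = 4$ would place 17 samples in a
16-cell joint table, and in simulation measurably degrades the screen's
power.

**Prefilter and accounting.** OTUs with fewer than
`abundance_prefilter_min_count = 10` total reads are dropped before scoring
(they cannot support a stable discretized profile). "Information loss" is
reported as the percentage of total read mass removed — prefilter included —
so that loss plus retained mass is exactly 100%. The network edge list
contains the significant pairs with MI $\ge \tau$.

## Core microbiota

A taxon is core when it satisfies jointly: prevalence $\ge$ 80% of samples
(presence meaning count strictly above `detection_min = 0`) and mean
relative abundance $\ge$ 0.01% computed over *all* samples, zeros included.
Comparisons use exact fractions — with 17 samples, the prevalence cutoff
means presence in at least $\lceil 0.8 \times 17\rceil = 14$ samples — so no
rounding artifacts arise at the boundary. Detection can be run at any rank;
aggregation sums raw counts within the rank *before* converting to relative
abundance, preserving compositional weighting. Raising either threshold can
only shrink the core set (anti-monotonicity, property-tested).

Absolute abundances are obtained by multiplying each sample's relative
abundances by its total bacterial load from qPCR (16S copies per gut), so
each scaled row sums exactly to the measured load. A missing qPCR row is
"not detected", deliberately distinct from a measured zero.

## Diversity

All entropy-based indices are in nats; the log base is fixed and declared
because published values without a stated base are not comparable.

* Shannon $H = -\sum_i p_i \ln p_i$ and Gini-Simpson $1 - \sum_i p_i^2$
  (via vegan).
* Observed richness and classic Chao1
  $S_{obs} + F_1^2/(2F_2)$, falling back to the bias-corrected
  $S_{obs} + F_1(F_1-1)/2$ when no doubletons exist.
* The Zahl jackknife Shannon estimator
  $\widehat H_{Z} = nH - \frac{n-1}{n}\sum_{i=1}^{n} H_{(-i)}$, where
  $H_{(-i)}$ removes one individual; the $n$ leave-one-out terms are grouped
  by species for an $O(S)$ evaluation, and the implementation is tested
  against direct enumeration.
* Bray-Curtis $d(a,b) = \sum_i |a_i-b_i| / \sum_i (a_i+b_i)$, PCoA by
  classical metric scaling (negative eigenvalues reported, their axes
  dropped), and one-factor PERMANOVA with
  $p = (1 + \#\{F_{perm} \ge F_{obs}\})/(1 + n_{perm})$ under free
  permutation of labels (no strata; the emulated study is single-factor).
* Rarefaction is a single seeded draw without replacement at the requested
  depth (conventionally the dataset minimum).

## Functional capacity scores

The package ships a 10-genus × 12-pathway-class capacity matrix for the gut
genera of *Poecilus* ground beetles (pathway counts from annotated
type-strain genomes; checksum-verified on load). For a sample $s$ with core
relative abundances $RA(s,g)$:

$$\text{raw}(s, c) = \sum_g RA(s,g)\, C(g,c), \qquad
  \text{PSV}(s, c) = 100 \cdot \frac{\text{raw}(s,c)}{\sum_{c'}
  \text{raw}(s,c')}.$$

The abundances entering the scorer are renormalized over the core taxa
(summing to 1 per sample), because the score is defined on the core
community; a flag keeps whole-community fractions instead, in which case a
sample's total score directly reflects how much of its community is core.
OTUs are matched to capacity rows by exact genus name (species map to their
genus); taxa without a capacity row — e.g. a family-level core OTU — are
reported in a skip list, never silently dropped. Per-sample predicted score
values sum to 100 wherever the total is positive; all-zero samples are
flagged rather than divided by zero. The same rule applies per enzyme (EC)
with a deterministic per-sample top-k ranking (ties broken by EC string),
and EC scores aggregate to pathways through an offline snapshot map in which
an EC contributes its full score to every pathway it maps to; unmapped ECs
accumulate in an explicit bucket so mass is conserved.

## Association layer

* **Spearman/BH**: rho with average ranks; one Benjamini-Hochberg family per
  diversity metric across the 12 categories (the conservative reading of
  "corrected for each metric"); pairs with a constant member are flagged and
  excluded from their family. Asymptotic p-values that underflow to 0 at
  $|\rho| = 1$ are clamped to the smallest positive double before
  adjustment.
* **Kendall**: tie-corrected $\tau_b$. The exact-permutation p-value is
  enumerated for $n \le 7$ (5040 permutations); beyond that the
  tie-corrected normal approximation applies — full enumeration at $n = 10$
  would cost 3.6M permutations for negligible inferential gain at this
  cohort size.
* **Regression**: OLS of each category score on the five alpha indices
  jointly, with an explicit rank-deficiency error naming collinear columns.
* **Ordination clusters**: partitioning-around-medoids (deterministic
  build + swap) on the Bray-Curtis matrix, $k = 3$ by default, then
  Kruskal-Wallis per category across clusters, BH-adjusted within the
  family. PAM was chosen because it operates directly on a dissimilarity
  matrix and has no stochastic initialization; $k$ is configurable.
* **Mood's median test** for two-group comparisons: 2×2 table of
  above/not-above the pooled median, chi-square without continuity
  correction, Fisher's exact test when any expected cell is below 5.

## The synthetic study generator

`generate_study()` produces data shaped like a 17-beetle gut survey with
known ground truth, so every stage is testable without downloads:

* **Samples**: 17, in three planted composition clusters (6/6/5), read
  depths uniform on 29,611–102,067.
* **Core taxa**: 17 OTUs over ten known gut genera (three *Enterobacter*,
  two *Gilliamella*, three *Enterococcus* species, two *Weissella*, one
  each of six further genera, and one family-level Enterobacteriaceae OTU
  that deliberately exercises the scorer's skip list). Each core taxon gets
  a random permutation of cluster offsets $\{-2.5, 0, +2.5\}$ log units
  (≈12-fold spacing, strong compositional clustering) plus N(0, 0.2)
  within-cluster noise; base scales are log-normal (sdlog 1).
* **Correlated satellites** (20): copy a random core parent's profile with
  sdlog 0.15 multiplicative noise, then are censored to zero in their four
  lowest samples — detection-limit dropout, which keeps their rank structure
  (a censored tail stays at the bottom) while guaranteeing prevalence
  13/17 < 80%, so they can never satisfy the core criteria.
* **Independent transients** (25): i.i.d. log-normal profiles with a large
  spread (sdlog 1.75) censored in their 4–9 lowest samples. The large
  spread matters: relative abundance couples every taxon through the shared
  denominator, and a transient whose own variation is too small would
  inherit the core taxa's cluster structure from that denominator.
* **Mass allocation**: core 95%, satellites 3.5%, transients 1.5% of reads.
* **Dysbiosis**: sample P1 is overridden to 99.1% dominance by a planted
  Spiroplasma OTU and receives the floor depth — the shallow, mono-dominant
  library of the emulated survey.
* **qPCR**: total loads log-normal (median $10^7$ copies/gut, sdlog 1);
  Nosema detected in every sample (spores/gut), Serratia in 6 of 17
  (luxS copies/gut), Spiroplasma quantified everywhere and tied to the
  dominated sample's load.
* **Verification loop**: after sampling counts, the generator checks that
  every planted core OTU actually satisfies the core criteria in the
  realized table and that every non-core OTU fails them, redrawing (bounded
  retries) otherwise — the advertised ground truth always holds.

All randomness flows from one integer seed through R's default generator,
so equal seeds give bit-identical studies across platforms.

**What the generator does not emulate.** Real amplicon data have
overdispersion beyond multinomial sampling, taxonomic misassignment, chimeric
inflation of richness, copy-number variation of the 16S gene, and
compositional effects far messier than three clean clusters. Tests passing
on these communities show the pipeline's estimators and decision rules are
correct under their stated models — not that the biological conclusions of
any particular survey are robust to those real-world artifacts.

## Numerical choices and degenerate inputs

* Counts are validated as integers with a $10^{-9}$ tolerance (BIOM-JSON
  stores floats).
* Relative-abundance rows must sum to 1 within $10^{-9}$; zero-sum samples
  are rejected upstream with the sample named.
* Ties at score $= \tau$ are retained ($\ge$, not $>$); ties in equal-
  frequency binning share a bin; ties in the EC top-k break by EC string.
* Permutation p-values are never 0 (always $\ge 1/(n_{perm}+1)$).
* A measured qPCR zero is stored as 0; a missing row is "absent".
* `k = n` clustering, all-tied Kendall inputs, all-zero score rows and
  degenerate median tests are flagged or raise errors naming the cause
  rather than returning silent NaNs.

## Problem sizes used by the test suite

The suite exercises the estimators at the scale of the emulated study
(17 samples, ~60 OTUs): 20 generator seeds for core recovery, 10 seeds for
filter discrimination, 50 small tables (≤ 10 × 10) for the MI oracle
comparison, and 500 null replicates each for the PERMANOVA and regression
type-I calibrations. These sizes make the whole suite run in about a minute
while keeping Monte-Carlo intervals tight enough to detect calibration
errors of a few percentage points.

## Known limitations

* The MI screen's permutation null conditions on the pair's margins only;
  shared global structure (e.g. one extreme sample, compositional closure)
  is treated as signal, which is conservative for removal.
* The capacity scores are genome-derived potential, not activity; they
  inherit every bias of type-strain annotation, and genus-level matching
  ignores strain variation.
* With 17 samples, the association layer's power is modest by construction;
  the package reports calibrated p-values but cannot conjure power the
  design does not have.
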