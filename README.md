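# essprofile

Feature profiling of essential versus viable genes.

Essential genes — those whose null allele kills a mouse before postnatal
day 3 — differ from viable (knockout-survivable) genes across nearly every
layer of annotation. `essprofile` implements that two-group comparison as a
reproducible, fully offline R pipeline:

* **Gene features** — length, GC%, transcript and exon counts, exon/intron
  length under the longest-transcript convention
  (intron = gene − exon total).
* **Protein features** — the 20 residue frequencies, and Pepstats-style
  molecular weight, charge, isoelectric point and nine residue-category
  percentages (tiny, small, aliphatic, aromatic, non-polar, polar,
  charged, basic, acidic) with EMBOSS-compatible constants.
* **Redundancy culling** — global-alignment identity (BLOSUM62, open 10,
  extend 0.5; identity = matches / alignment length), similarity graphs at
  20/40/60/80% thresholds, and removal of a small vertex set so no
  retained pair meets the threshold (exact maximum independent set on
  components ≤ 12 nodes, deterministic greedy above).
* **Expression** — EST counts over 13 developmental stages normalised to
  transcripts per million, `TPM_ij = ESTs_ij / total ESTs in stage j × 1e6`,
  expressed-at-stage frequencies and bin-50 histograms.
* **Evolutionary age** — MRD (nearest duplication ancestor), DCA (oldest
  duplication ancestor) and SCA (root-age fallback) from
  duplication-annotated Newick gene trees, binned into the 16 taxon age
  groups from Murinae (25 MYA) to Opisthokonta (1215 MYA).
* **PPI topology** — graph cleaning plus nine per-node scores: degree,
  average shortest path, betweenness (normalised into [0, 1]), clustering
  coefficient, closeness (literal 1/Σd within the component), BottleNeck
  (BFS shortest-path-tree routing, ≥ n/4 rule, compiled kernel), edge
  percolation component (seeded Monte-Carlo), MNC and DMNC
  (E_M / N^1.7).
* **Statistics** — Kolmogorov–Smirnov (Lilliefors) normality gate choosing
  Welch t versus two-tailed Mann–Whitney U (exact by enumeration when
  feasible, tie-corrected normal approximation otherwise), Pearson χ²
  without continuity correction with Fisher-exact fallback, per-family
  Bonferroni thresholds α/m, and hypergeometric annotation-term
  enrichment.
* **Synthetic cohorts** — a seeded generator whose defaults are the study
  conditions (1,301 essential / 3,451 viable genes, the published medians,
  rates and age-group weights), so every stage is testable end to end
  without any database download.

## Worked example

```r
library(essprofile)

cfg <- cohortConfig(nEssential = 300L, nViable = 300L, seed = 42L)
rep <- runPipeline(cfg, epcRepetitions = 20L)
tb  <- reportTables(rep)
tb$gene_features[, c("feature", "median_a", "median_b", "test",
                     "p", "threshold", "significant")]
```

```
        feature median_a median_b           test        p threshold significant
1   gene_length  28297.0  20469.0 mann_whitney_u 3.06e-05   0.00833        TRUE
2    gc_percent     46.3     47.2        welch_t 3.56e-04   0.00833        TRUE
3 n_transcripts      4.0      2.0 mann_whitney_u 1.13e-26   0.00833        TRUE
4       n_exons     11.0      8.0 mann_whitney_u 2.50e-29   0.00833        TRUE
5   exon_length   3305.5   2906.5 mann_whitney_u 4.74e-04   0.00833        TRUE
6 intron_length  24729.5  17038.0 mann_whitney_u 1.46e-04   0.00833        TRUE
```

Each row is one feature: group medians (`median_a` = essential), the test
the normality gate selected, the raw two-tailed p, the per-family
Bonferroni threshold (six gene features → 0.05/6 ≈ 0.0083) and the
significance call. The synthetic essential genes are longer, more
exon- and transcript-rich, more intron-heavy and slightly GC-poorer than
the viable genes — the directions configured into the generator. The same
bundle carries keyword, subcellular, enzyme-class, expression-stage,
age-group and PPI-metric tables:

```r
tb$keywords[, c("feature", "pct_a", "pct_b", "test", "statistic", "p",
                "significant")]
```

```
         feature pct_a pct_b        test statistic        p significant
1 phosphoprotein  53.0    36 chi_squared      17.6 2.80e-05        TRUE
2   glycoprotein  20.0    37 chi_squared      21.3 3.98e-06        TRUE
3    acetylation  31.0    15 chi_squared      21.7 3.22e-06        TRUE
4  transcription  32.3    10 chi_squared      44.8 2.14e-11        TRUE
```

Phosphorylation, acetylation and transcription keywords are enriched in
the essential group, N-glycosylation in the viable group — each called
against the four-keyword family threshold 0.05/4 = 0.0125.

Cohorts round-trip through plain-text files (`writeCohort()` /
`readCohort()`: FASTA, annotated Newick, tab-separated tables, an edge
list), and `inst/scripts/essprofile.R` exposes `simulate`, `run`, `cull`
and `ppi-metrics` subcommands for shell use.

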