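---
title: "Profiling essential versus viable genes: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling essential versus viable genes: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(essprofile)
```

## The question

Essential genes — those whose knockout kills a mouse before or shortly
after birth — differ systematically from viable (non-essential) genes
across many layers of annotation: gene architecture, protein sequence
composition, developmental expression, evolutionary age, enzyme and
keyword annotations, subcellular location, and position in the
protein–protein interaction (PPI) network. `essprofile` packages that
comparison as a reusable, fully offline pipeline: every feature extractor
and the two-group statistical machinery are tested against a seeded
synthetic-cohort generator that emulates the two-group study design, so
no database access is required to exercise or validate any stage.

The pipeline compares one *essential* group against one *viable* group,
feature block by feature block, with Bonferroni control applied per block
(per "family" of tests).

## The synthetic cohort generator

The generator (`cohortConfig()` / `generateCohort()`) is first-class,
tested code: its defaults *are* the study conditions, and all randomness
flows from a single integer seed, so a configuration identifies a cohort
exactly.

Distributional families were chosen as the simplest forms whose location
parameters can be set directly to published group medians and rates;
published sources report medians and percentages but no dispersions, so
every dispersion below is a free parameter exposed in the configuration:

* **Gene length**: log-normal, medians 28,913 bp (essential) and
  21,629 bp (viable); `sdlog` 0.9 spans the few-kb-to-Mb range seen in
  mammalian genes.
* **Total exon length**: log-normal (medians 3,398 / 2,780 bp,
  `sdlog` 0.55), truncated at the gene length. Intron length is the
  difference, so the architectural identity *intron = gene − exon* holds
  by construction.
* **Exon and transcript counts**: Poisson truncated at ≥ 1, means 11/8
  and 4/2. The longest transcript carries the configured exon count; any
  additional transcripts are strictly shorter, so the longest-transcript
  convention picks the intended one.
* **GC**: Beta with means 0.4646/0.4716 and concentration 200
  (SD ≈ 3.5 percentage points).
* **Protein sequences**: length = longest-transcript exon length / 3
  (floored, minimum 30 aa), which keeps gene-level and protein-level
  features coherent within a gene at the cost of a longer-than-real
  median protein. Residues are Dirichlet–multinomial with per-group base
  measures set to the published 20-residue frequency profiles, so the
  direction of every residue-usage shift (more Asp/Glu/Lys/Gln/Ser in
  essential proteins, more Leu/Cys/Phe/Val/Trp in viable) is reproduced.
* **Annotation flags** (keywords, signal peptide, subcellular locations,
  housekeeping/tissue-enrichment): independent Bernoulli draws at the
  published per-group rates, e.g. signal peptide 0.164/0.291,
  phosphoprotein 0.514/0.355, nuclear localisation 0.482/0.236. Enzyme
  class is a single categorical draw per gene (six classes plus
  non-enzyme).
* **Expression**: 13 developmental stages (oocyte → adult). Per stage, a
  gene is expressed with the configured per-group probability (the
  complement is the zero-inflation probability) and, if expressed, its
  EST count is 1 + a gamma–Poisson (negative binomial) draw. Writing the
  zero-inflation directly as the expressed fraction makes the
  "expressed at stage" recovery exactly binomial, which the tests
  exploit.
* **PPI graph**: growing preferential attachment over all genes in
  random arrival order; each incoming node attaches `ppiEdgesPerNode`
  (default 3) edges with probability proportional to
  (degree + 1) × fitness, where essential nodes carry fitness
  `ppiFitnessMultiplier` (default 2). This produces the qualitative hub
  enrichment of essential proteins without modelling any real
  interactome.
* **Gene trees**: each gene receives a most-recent-duplication (or
  singleton) age sampled from per-group weights over the 16 taxon age
  groups (Murinae 25 MYA … Opisthokonta 1215 MYA); with probability
  `treeDuplicationProb` (default 0.7) that age is a duplication node
  under an older speciation root, and with probability 0.5 an
  intermediate older duplication is inserted, exercising the
  MRD ≠ DCA code paths.

What the generator does **not** emulate: real sequence content or
homology structure (proteins are i.i.d. residue bags, so culling thresholds
bite only on deliberately constructed families), correlations between
feature layers beyond the protein-length/gene coupling, real tree
topologies, and real network clustering. Passing tests therefore
demonstrate that the pipeline recovers *configured* effects at the
configured sample sizes — not that any biological conclusion transfers to
a particular database snapshot.

## Feature extraction conventions

**Gene features.** For multi-transcript genes, exon count and total exon
length come from the transcript with the greatest total exon length;
intron length is gene length minus that total, and a transcript whose
exons exceed the gene length is a hard error. GC is reported as a
percentage with two decimals.

**Protein features.** The nine residue categories use the exact
membership sets: tiny ACGST; small ABCDGNPSTV; aliphatic ILV; aromatic
FHWY; non-polar ACFGILMPVWY; polar DEHKNQRSTZ; charged BDEHKRZ; basic
HKR; acidic BDEZ. Ambiguity codes B and Z are accepted and count in the
categories that list them, but are excluded from the denominator of the
20-residue frequencies (which therefore always sum to 100). Molecular
weight uses EMBOSS-compatible average residue masses plus one water;
charge is (K + R + H/2) − (D + E); the isoelectric point is solved by
bisection on the Henderson–Hasselbalch net-charge function with
EMBOSS-compatible pK values (N-terminus 8.6, C-terminus 3.6, K 10.8,
R 12.5, H 6.5, D 3.9, E 4.1, C 8.5, Y 10.1).

**Redundancy culling.** Pairwise identity is a global (Needleman–Wunsch)
alignment with BLOSUM62, gap open 10, gap extension 0.5, and identity =
100 × matches / alignment length. Using the alignment length (rather
than the shorter sequence) as denominator is the conservative choice: it
can only lower identities, which loosens edges near a threshold —
documented because it changes edge sets. The similarity graph connects
pairs at or above the threshold; culling then removes vertices so the
retained set is independent. Connected components of up to 12 vertices
are solved exactly for a maximum independent set; larger components are
culled greedily by repeated removal of the highest-degree vertex with
lexicographic tie-breaking, which makes the whole procedure
deterministic. Thresholds below 20% are refused: at that level sequence
identity no longer implies redundancy, so non-redundant sets are not
constructed there.

**Expression.** TPM of gene *i* at stage *j* is
`ESTs[i, j] / sum(ESTs[, j]) * 1e6`; a stage with no ESTs yields an
all-zero column, and every populated column sums to exactly one million
over the genes supplied. Two semantics deserve note. First, "expressed
at a stage" means TPM > 0 (equivalently ESTs > 0) — no positive
threshold is imposed, consistent with describing unexpressed genes as
those with zero transcripts. Second, the denominator is the total over
the genes in the table, not over an external all-genes universe; with a
different gene universe absolute TPM values shift by a common per-stage
factor, which leaves the expressed/unexpressed dichotomy and the
scale-free column structure untouched. Per-stage comparison denominators
are exposed as a parameter since expression data may cover only part of
each group. Histograms use half-open bins [k·b, (k+1)·b) with b = 50 by
default.

**Evolutionary age.** Trees arrive as Newick with
`[&age=<MYA>,event=<duplication|speciation>]` comments on internal
nodes. For a gene's leaf, MRD is the age of the nearest duplication
ancestor and DCA the age of the farthest; a gene with no duplication
ancestor is a singleton and both fall back to the SCA, interpreted as
the root age of the gene's own tree — the age of the most distant
ancestor represented in that tree, which is the only root-level
information a single gene tree carries. Ages must match the 16 taxon
ages exactly by default; `snapAges = TRUE` maps to the nearest group
instead, with strict matching preferred so data errors surface rather
than silently binning. Frequency tables always report all 16 groups,
even those that are structurally empty for DCA ages.

## PPI topology scores

Graphs are cleaned to undirected simple graphs (self-loops and duplicate
edges removed, with counts reported). Nine per-node scores follow:

* **Degree**, and **average shortest path length** (ASP) over the nodes
  actually reachable from the node; an isolated node has no defined ASP
  and reports `NA`. All distance-based quantities are restricted to the
  node's connected component, since real interactomes are fragmented.
* **Betweenness** is the shortest-path ratio sum, normalised by
  (N−1)(N−2)/2 so it lands in [0, 1]; the unnormalised sum is available
  via `rawBetweenness = TRUE`. The normalisation is applied because the
  score is specified to lie in the unit interval, which the bare sum
  does not.
* **Clustering coefficient**: 2·e / (k(k−1)) over the node's
  neighbourhood, 0 for degree < 2.
* **Closeness** is implemented literally as the reciprocal of the *sum*
  of shortest-path lengths within the component (an equation-over-prose
  decision, since the defining equation and its verbal description
  disagree); the conventional (reachable nodes)/sum variant is one flag
  away (`closeness = "normalized"`). Isolated nodes score 0.
* **BottleNeck (BN)**: for every root r a breadth-first shortest-path
  tree is built with parents tie-broken to the lexicographically
  smallest id, making the score deterministic and input-order
  independent (the one metric where relabelling can matter, via
  tie-breaks). A node b ≠ r is a bottleneck for r when at least
  n_r/4 nodes of the tree route to r through b, where n_r counts the
  tree's nodes and the routing count excludes b itself; BN(b) is the
  number of such roots. Both ambiguous conventions (what n counts, and
  whether b counts itself) are fixed this way and noted here. The
  per-root BFS kernel is compiled (Rcpp) so the score scales to
  interactome-sized graphs.
* **EPC (edge percolation component)**: Monte-Carlo — each of n
  replicate graphs keeps every edge independently with a retention
  probability, and EPC(v) is the replicate-average number of nodes still
  connected to v. Replicate count (100) and retention (0.5) are
  defaults of this implementation, exposed and seeded, since the
  reference tool does not publish its internals; retention 1 degenerates
  to component size − 1 and retention 0 to 0, which the tests pin down
  together with 3-standard-error convergence bounds on graphs with
  closed-form expectations.
* **MNC / DMNC**: the node count of the largest connected component of
  the subgraph induced by the node's neighbourhood (the node itself
  excluded), and that component's edge count divided by its node count
  to the power 1.7. Degenerate neighbourhoods (fewer than two nodes, or
  no edges) score 0.

## Statistical machinery

Numeric features pass a normality gate: a Kolmogorov–Smirnov test
against a normal with sample-estimated parameters. Because estimating
the parameters invalidates plain K-S critical values, the gate applies
the Lilliefors correction by default; the uncorrected test is exposed
(`method = "ks"`) for fidelity to the original wording. If both groups
pass, a Welch unequal-variance t-test is used; otherwise the two-tailed
Mann–Whitney U. The U test enumerates all group assignments exactly
(midranks for ties) whenever the number of combinations is feasible
(≤ 1e5), and otherwise uses the normal approximation with tie correction
and *no* continuity correction, matching common statistical-package
output. With n = 500 per group, a log-normal shift of the magnitude of
the gene-length medians (28,913 vs 21,629 at sdlog 0.9) is rejected at
the six-feature family threshold with power above 0.9, which the test
suite measures by simulation.

Binary features use Pearson's chi-squared on the 2×2 table without
continuity correction; when any expected cell is ≤ 5 the comparison
falls back to Fisher's exact test and flags it. Recomputing published
chi-squared p-values from published counts does not reproduce them
exactly (the underlying per-feature denominators were evidently not the
group totals), so printed p-values are never asserted — only quantities
that are analytically forced by printed counts are.

Bonferroni control is applied as a per-family *threshold*: a raw p is
compared against alpha/m, matching how the comparison tables are
captioned (m = 6 genomic features → 0.0083; m = 13 protein features →
0.00385 — the 13 counts length, MW, charge, pI and the nine categories,
which is how the published 0.0038 threshold is reconstructed, and the
family size is configurable; m = 20 residues → 0.0025; m = 16 age
groups → 0.003125; m = 4 keywords → 0.0125). Term enrichment instead
reports DAVID-style inflated p-values, min(1, m·p) over the m terms
tested, from a one-tailed Fisher/hypergeometric over-representation
test.

## The pipeline and its report

`runPipeline()` chains generation (or a supplied cohort), feature
extraction, optional culling, and all comparison blocks into a
`ReportBundle` of tidy tables plus a manifest (group sizes, seed, family
sizes, culling thresholds). Comparisons run independently on the
non-culled set and on each culled set; culling applies to the proteins
and carries the retained genes' gene-level features with it. Report
percentages are rounded to one decimal at the presentation layer only;
p-values and statistics stay at full precision. End-to-end determinism
under a fixed configuration is asserted by the test suite
(`identical()` on whole bundles). A thin command-line front end
(`inst/scripts/essprofile.R`: `simulate`, `run`, `cull`, `ppi-metrics`)
wraps these functions for shell use.

## Problem sizes used by the tests and acceptance script

The suite chooses sizes that make each check sharp but cheap: oracle
comparisons run on 500 random graphs of up to 8 nodes (exhaustive
path enumeration), culling optimality on graphs of up to 12 nodes
(exhaustive independent sets), exact Mann–Whitney agreement on every
layout with up to 10 observations, type-I calibration on 200 null
cohorts of 100 + 100 genes, and effect recovery on 20 paper-effect
cohorts of 500 + 500 genes with all layers generated. The acceptance
script reproduces the family thresholds and printed-count percentages
analytically, generates one full-sized cohort (1,301 + 3,451 genes) to
report the study-condition group sizes and recovered medians, and runs
100 null replicates plus one 500 + 500 paper-effect pipeline for the
calibration and sign-consistency numbers.

## Known limitations

* Generated protein sequences share no homology, so realistic culling
  behaviour appears only on constructed sequence families; published
  non-redundant set sizes depend on a specific database snapshot and are
  not reproduction targets.
* The expression denominator semantics differ from a whole-database
  universe (documented above).
* EPC is a Monte-Carlo estimate; two runs agree only under a shared
  seed.
* BN depends (deliberately, deterministically) on lexicographic
  tie-breaking; other tools may break shortest-path-tree ties
  differently and report slightly different BN values on graphs with
  tied geodesics.
* Annotation flags are generated independently per gene; real keyword
  co-occurrence structure (e.g. glycoprotein–signal peptide coupling) is
  not modelled, so multivariate analyses should not be read into the
  synthetic cohorts.
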