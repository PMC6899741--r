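---
title: "Methods: module completion scoring and MAG functional profiling"
author: "magscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: module completion scoring and MAG functional profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magscore)
```

# Overview

`magscore` quantifies the functional potential and expression of
metagenome-assembled genomes (MAGs). Its stages mirror a genome-resolved
field study: quality/taxonomy filtering of bins, normalization of
key-gene and per-MAG abundances in metagenomes (DNA) and
metatranscriptomes (RNA), z-scored expression profiles clustered with
Ward linkage, module completion scoring of each MAG against KEGG-style
metabolic modules, and rank-based tests for pathway enrichment between
groups of MAGs with different expression patterns. This vignette
documents the models, the parameters that matter, the numerical
conventions, and what the synthetic validation does and does not show.

# The module completion score

## Definition grammar

A metabolic module is a boolean expression over KO identifiers
(`K#####`). The grammar, from loosest to tightest binding:

* space — serial reaction steps, all required;
* `,` — alternatives, any one sufficient;
* `+` — components of an enzyme complex, all required;
* `-` *prefix* — a non-essential (optional) component;
* `--` — an unspecified enzyme;
* parentheses — grouping.

`parseModuleDefinition()` is a recursive-descent parser producing an
expression tree whose top-level units are the reaction steps. Errors
(unbalanced parentheses, malformed KO tokens, empty input) carry the
character offset. `serializeDefinition()` emits a canonical string whose
re-parse is structurally identical to the original tree; the surface
style of all-required groups (spaced steps versus `+`-complexes) is
preserved so step counts survive the round trip.

## Scoring semantics

For a MAG KO set $S$, step completeness is defined recursively:

* atom: $1$ if its KO is in $S$, else $0$;
* all-required group: the arithmetic **mean** of its parts — a MAG with
  half the subunits of a complex gets half credit;
* alternatives: the **max** over branches — a pathway step is complete
  as soon as any one enzyme combination is present;
* `--`: 1 (an unspecifiable enzyme must not cap the score of a complete
  genome);
* optional components are excluded from both numerator and denominator
  of their parent's mean, so they can never change a score.

The MCS is the mean of the step scores, a real number in $[0,1]$: 1
means the pathway is completely encoded, 0 that it is absent (for
wildcard-free modules). The "mean within a combination, max across
alternatives" reading resolves the tension between proportional credit
and any-sufficient-combination semantics; it is the one genuinely open
design decision in the scorer, and the test suite pins it against an
independent brute-force oracle that expands every alternative into
explicit combinations and takes the per-step maximum. Note that for
nested parenthesized groups the proportional semantics is *structural*
(a mean of means), not a flat fraction of all KOs: in
`(K00001 (K00002 K00003))` the first ortholog carries half the weight of
the group, not a third. The oracle evaluates the expanded OR-free trees
with the same structural weighting; where expansions are flat the two
readings coincide and both are asserted.

Degenerate cases: a group consisting only of optional components is
vacuous and is itself excluded from its parent's mean; a module with no
scoreable step scores 0. The generator never emits such modules, and
real KEGG definitions do not contain them.

`computeMcsMatrix()` unions KO annotations over each MAG's ORFs
(duplicate annotations collapse; ids are upper-cased) and fills a dense
MAG × module matrix — a module absent from a MAG scores 0, never `NA`,
so downstream clustering and plotting see a complete matrix.

# Abundance normalization

Read counts enter pre-computed (mapping, ORF calling and KO assignment
are out of scope). Two conventions, chosen to match how gene abundances
are conventionally reported in metagenome surveys:

* **Metagenomes** (`normalizeGeneAbundanceMg`): the read hits of a key
  gene divided by the mean read hits to a panel of single-copy marker
  COGs (35 by default). Because every genome carries one copy of each
  marker, the ratio approximates copies per genome and is invariant
  under uniform scaling of a sample's counts. An all-zero marker panel
  is a typed error, never `NaN`/`Inf`.
* **Metatranscriptomes** (`normalizeTranscriptAbundance`): read hits
  divided by the sample's total read count. The scalar function returns
  the raw ratio; `buildAbundanceMatrix()` multiplies metatranscriptomic
  values by a display constant (default $10^6$, hits per million) and
  records it in the object, so raw ratios are always recoverable.

When several ORFs share an annotation their hit counts are averaged
first — zero-hit ORFs are real observations and count toward the mean.
A key gene mapping to several KOs (e.g. hydrogenase subfamilies)
averages the per-KO mean hits over the KOs observed in the sample,
mirroring the same-annotation averaging rule; the panel mean likewise
averages per-COG means rather than pooling all marker ORFs, which keeps
a deeply duplicated marker from dominating the denominator.

# MAG profiles and clustering

* `filterMags()` keeps bins with completeness **strictly above** 70% and
  redundancy **strictly below** 10% (the thresholds are quoted as strict
  inequalities, so boundary values are excluded), then drops MAGs whose
  taxonomy contains an excluded order — by default Pseudomonadales and
  Sphingomonadales, lineages that typically represent seawater mixed
  into vent fluid at sampling.
* `normalizeMagCoverage()` divides each MAG's mean per-base coverage by
  the sample's total reads.
* `zscoreRows()` centres each row and scales by the **sample** standard
  deviation (n−1), chosen so the 3-point row `[1, 2, 3]` maps to
  `[-1, 0, 1]`; z-scores are scale-invariant, so any cosmetic
  pre-scaling of coverage is irrelevant. Zero-variance rows are emitted
  as zeros and flagged rather than dropped, keeping the matrix shape
  stable for heatmaps.
* `clusterRows()` performs agglomerative clustering with Euclidean
  distance and Ward linkage via `stats::hclust(method = "ward.D2")`,
  the same criterion used by the common Python `clustermap`
  implementation. The result is deterministic given its input; equal
  merge costs are resolved by `hclust`'s fixed internal ordering.
  Dendrograms serialize to Newick (branch lengths are merge-height
  deltas), and `applyClusterOrder()` lets the metagenomic heatmap reuse
  the ordering derived from the metatranscriptomic clustering, so DNA
  and RNA profiles are directly comparable row by row.

# Enrichment testing

`enrichModules()` asks, per module, whether the MCS values of two MAG
groups come from the same distribution, with a two-tailed Mann–Whitney
U test (`stats::wilcox.test`): exact p-values for small untied samples,
the normal approximation with tie and continuity correction otherwise;
the policy used is recorded with each result. All-identical inputs
return $p = 1$ rather than a tie warning. No multiple-testing
correction is applied by default — module-level thresholds are
conventionally reported raw — but Benjamini–Hochberg adjustment is
available as an option.

The grouping itself is either supplied explicitly (a `mag_id`/`group`
file) or derived by `assignExpressionGroups()`: each MAG is assigned to
the vent field or site where its summed normalized transcript abundance
is maximal (argmax; ties resolve to the first label), and the grouping
splits the focal label's MAGs from all others. MAGs with all-zero
transcript rows carry no signal and are excluded and reported. The
argmax rule is a deliberate concretization of "expressed at" — it is
simple, deterministic, and exact on site-restricted expression, but it
will assign weakly or broadly expressed MAGs to whichever site happens
to lead; supplying an explicit grouping bypasses it.

# The synthetic-data generator

The generator's defaults are the study conditions the package models:
64 MAGs passing the filters plus 9 high-quality bins in the excluded
orders (73 bins total), 15 metagenomes, 10 metatranscriptomes and 56
modules. All randomness flows from one seed through named per-stage
substreams, and identical configurations produce byte-identical files.

* **Module corpus** — 56 definitions covering every operator class
  (chains, complexes, alternatives, complexes-of-alternatives, nested
  groups, optional components, wildcards, and wide 9–12-KO modules),
  with disjoint synthetic KO pools (reserved `K9xxxx` range) so planted
  per-module KO sets cannot interfere.
* **Annotations** — per MAG × module, a target MCS drawn from
  $\{0, 0.25, 0.5, 0.75, 1\}$ is realized constructively: achievable
  per-step scores are enumerated with minimal witness KO subsets, and a
  greedy per-step fill tracks the remaining target mass. Infeasible
  targets snap to the nearest achievable value and the snapped value is
  recorded as the planted truth — the generator never lies about its own
  output, and recomputing the MCS on the generated table reproduces the
  planted matrix exactly. The first six modules carry a planted
  group-wise shift (default 0.6) between expression block 1 and the
  rest, for the enrichment analyses.
* **Coverage** — a block model of site-restricted expression: each MAG
  has high mean coverage (50×) in its block's samples and
  `blockSeparation`-fold less (default 10×) elsewhere, under
  multiplicative lognormal noise with mean 1 and coefficient of
  variation `noiseCv` (default 0.25; 0 reproduces block means exactly).
  A configurable fraction of MAGs (default 0.1) get decoupled DNA/RNA
  blocks, emulating populations whose genomic and transcriptional
  abundance patterns disagree. Sample totals are drawn uniformly
  (metagenomes 2–6 × 10⁷ reads, metatranscriptomes 1–4 × 10⁷).
* **Metadata** — passing records draw completeness in (70, 100] and
  redundancy in [0, 10); excluded-order and quality-failing records are
  generated on request.
* **Read hits** — single-copy marker COGs receive a constant per-sample
  hit count and gene counts are planted multiples of it, so normalized
  abundances equal the planted values exactly.

What the generator does **not** emulate: sequence content and read-level
error (no FASTQ), compositional coupling between genes, phylogenetic
correlation of module content, gradual (non-block) expression gradients,
and annotation error. Passing tests therefore demonstrate algorithmic
correctness — recovery of what was planted under the stated noise — not
robustness to misannotation or to expression structure outside the block
model.

# Validation sizes and numerical conventions

The test suite exercises: exhaustive subset enumeration
(oracle equivalence and monotonicity) over the full 56-module corpus
(all modules have ≤ 12 KOs, giving on the order of $10^4$ scored
subsets); planted-MCS recovery at the full 64 × 56 scale; rank-test
calibration with 2000 null simulations ($n = 10$ per group, exact
branch; type-I error within 0.05 ± 0.02) and power with 200 replicates
of a 0.6 planted shift (≥ 95% detection at $\alpha = 0.05$); clustering
recovery over 100 seeded block fixtures (separation 10×, cv 0.1;
adjusted Rand index ≥ 0.9); normalization invariances to $10^{-9}$; and
byte-identical reruns of the full pipeline. Smaller configurations of
the same generators are used in the per-module unit tests.

Numerical conventions: scores and normalized abundances are plain
doubles; equality tests on planted constructions use $10^{-12}$,
invariance properties $10^{-9}$. The MCS matrix is written to TSV with
4-decimal fixed-point values; all other matrices at full precision. The
run manifest records settings, input checksums and package/R versions
but no timestamps, so identical runs are byte-identical.

# Known limitations

* The MCS does not capture *where* completeness resides: 0.5 can mean
  half of every step or all of half the steps; it also cannot separate
  pathways that share a gene complement (e.g. methanogenesis versus
  anaerobic methane oxidation), which require phylogenetic evidence.
* Optional-component and wildcard conventions follow public KEGG usage;
  scoring choices for modules outside those conventions are undefined.
* The expression-grouping argmax is coarse for MAGs expressed at
  similar levels across sites; explicit groupings are preferred there.
* Enrichment p-values are conditional on the grouping; deriving the
  grouping from the same transcript data tested for enrichment is a
  form of selective inference the package does not correct for.
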