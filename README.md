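# magscore

Genome-resolved functional profiling of microbial communities from
metagenomes and metatranscriptomes.

Deep-sea hydrothermal vents (and many other environments) host microbial
communities whose *metabolic potential* (genes present in a genome) and
*realized activity* (genes actually transcribed) can diverge sharply
between sites. `magscore` implements the analysis layer for studying this
at the level of metagenome-assembled genomes (MAGs): it scores how
completely each MAG encodes each metabolic pathway, quantifies gene- and
genome-level abundance in DNA and RNA, clusters MAGs and samples by
expression pattern, and tests which pathways are enriched in groups of
MAGs that are expressed at particular vent fields or sites. It is aimed at
microbial ecologists working with binned assemblies, KEGG Orthology (KO)
annotations, and read-mapping summaries.

## The module completion score (MCS)

A KEGG metabolic module is a boolean expression over KO identifiers:
serial reaction steps (spaces), alternative enzymes or sub-pathways
(commas — any one suffices), enzyme-complex components (`+` — all
required), non-essential components (`-` prefix) and unspecified enzymes
(`--`). For a MAG with KO set *S* and a module with reaction steps
*r₁ … r_R*:

- an atom scores **1**[K ∈ S];
- an all-required group scores the **mean** of its parts (proportional
  credit within a combination);
- a group of alternatives scores the **max** over its branches (any
  sufficient combination completes the step);
- optional components are excluded from their parent's mean, and `--`
  scores 1;

and the MCS is the arithmetic mean of the step scores:

MCS(S) = (1/R) · Σᵣ completeness(rᵣ, S) ∈ [0, 1].

MCS = 1 means the MAG encodes a complete pathway; MCS = 0 means the
pathway is absent (for wildcard-free modules). The recursive scorer is
verified in the test suite against an independent brute-force oracle that
expands every alternative into explicit combinations.

Around this core the package provides:

- **Abundance normalization** — key-gene metagenomic read hits divided by
  the mean hits to 35 single-copy marker COGs (≈ copies per genome);
  transcript hits divided by library size; read hits of ORFs sharing an
  annotation are averaged first.
- **MAG profiles** — per-MAG coverage normalized by sample read counts,
  row z-scoring, and hierarchical clustering of MAGs and samples
  (Euclidean distance, Ward linkage), serializable as Newick.
- **Enrichment** — per-module two-tailed Mann–Whitney U tests comparing
  MCS between MAG groups defined by where they are expressed.
- **Synthetic studies** — a fully seeded generator that plants known
  module completion, block expression structure and group-wise MCS shifts
  at study scale (64 MAGs, 15 metagenomes, 10 metatranscriptomes,
  56 modules), so every stage can be validated against ground truth.

## Worked example

```r
library(magscore)

m <- parseModuleDefinition("M00567",
    "K00399+K00401+K00402 (K00001,K00002) K00003",
    name = "methyl-CoM reductase toy pathway")
m
#> ModuleDefinition M00567 (methyl-CoM reductase toy pathway)
#>   steps: 3  KOs: 6
#>   definition: K00399+K00401+K00402 (K00001,K00002) K00003

moduleCompletionScore(m, c("K00399", "K00401", "K00402", "K00002"))
#> [1] 0.6666667
```

The mcr complex (step 1) is fully present, step 2 is satisfied by the
K00002 alternative, step 3 is missing: (1 + 1 + 0)/3 ≈ 0.667.

A complete synthetic study, end to end:

```r
cfg <- simulationConfig(seed = 42)   # 64 MAGs, 56 modules, 15 MG / 10 MT
sim <- file.path(tempdir(), "study")
out <- file.path(tempdir(), "run")
simulateDataset(cfg, sim)
res <- runPipeline(sim, out)

res$mcs
#> MCSMatrix: 64 MAGs x 56 modules; mean MCS 0.467

head(res$enrichment[, c("module_id", "n_a", "n_b", "mean_a", "mean_b",
                        "u", "p", "direction")], 3)
#>   module_id n_a n_b    mean_a    mean_b     u            p direction
#> 1    M90003  26  38 0.5512821 0.3333333 741.0 1.521475e-06  A_higher
#> 2    M90005  26  38 0.6217949 0.3903509 751.5 1.250666e-04  A_higher
#> 3    M90002  26  38 0.5769231 0.1940789 737.5 3.606298e-04  A_higher
```

The top-ranked modules are exactly those in which the generator planted a
group-wise completion shift: MAGs expressed at the focal vent field
(group A, n = 26) carry substantially more complete pathways than MAGs
expressed elsewhere (group B, n = 38), and the two-tailed Mann–Whitney
test ranks them far above the unshifted modules. `out/` contains the MCS
matrix, normalized and z-scored abundance matrices ordered by the
transcript dendrogram, Newick trees, the enrichment table and a
`manifest.json` with input checksums — rerunning on the same inputs
reproduces every file byte for byte.

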