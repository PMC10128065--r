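---
title: "Methods: genomic and community profiling of bee-gut bacteria"
author: "beeprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genomic and community profiling of bee-gut bacteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressMessages(library(beeprofiler))
```

# Overview

Gut communities of social bees (honey bees, bumblebees, stingless bees) are
dominated by a small number of host-associated bacterial families. Comparing
isolate genomes from these communities raises four recurring computational
tasks, which this package implements as one tested pipeline:

1. **Pathway-completeness profiling** — scoring, per genome, what fraction of
   the steps of a metabolic pathway its KEGG Orthology (KO) annotations can
   satisfy, plus CAZyme (GH/PL) gene counting.
2. **Genome divergence** — fragment-based average nucleotide identity (ANI),
   16S rRNA gene identity, and species delineation at the 95% ANI threshold.
3. **Community profiling** — filtering and summarising 16S amplicon sequence
   variant (ASV) tables, shared-ASV statistics across host species,
   Bray-Curtis dissimilarities and one-factor PERMANOVA.
4. **Core-genome supermatrix** — selecting single-copy orthologs, trimming
   gap-heavy alignment columns, and concatenating into a partitioned matrix
   ready for maximum-likelihood tree inference.

A fifth module generates synthetic inputs with known ground truth so every
stage can be validated at desk scale without any downloads. Upstream tools
(assembly, annotation, orthology inference, aligners, denoisers, taxonomic
classifiers) are out of scope: the package consumes their tabular/FASTA
outputs.

# Pathway completeness

A *pathway rule* is an ordered list of steps; each step is a boolean
expression over KO identifiers with two operators: `OR` (alternative enzymes
catalysing the same step) and `AND` (subunits of a complex that are all
required). `AND` binds tighter than `OR`; parentheses override. Completeness
of a genome for a rule is

$$\mathrm{completeness} = \frac{\#\{\text{steps satisfied by the genome's KO set}\}}{\#\{\text{steps}\}},$$

an exact rational reported together with its numerator and denominator
(`stepsPresent()`, `stepsTotal()`). Scoring uses the **union** of a genome's
KO assignments — gene-level structure is deliberately ignored, because a step
is biologically satisfied by the presence of the function anywhere in the
genome. Two consequences worth knowing:

* Completeness is monotone under KO addition, and invariant to gene and KO
  ordering.
* A partially present complex (`AND` with some subunits missing) scores the
  whole step as absent. This is the stricter of the two defensible choices;
  it avoids crediting non-functional partial complexes.

The rule grammar is the package's own design: two operators are the minimum
that can express both alternative enzymes and multi-subunit complexes, and
every published completeness heat map we are aware of needs exactly those
two semantics. The shipped rule file
(`inst/extdata/example_pathway_rules.yaml`) is a **reconstruction** of
typical central-metabolism definitions (EMP glycolysis, pentose phosphate,
Entner-Doudoroff, TCA, oxidative phosphorylation, selected cofactor and
secretion/motility systems) so the profiler runs out of the box; the engine
accepts any rule file in the documented format.

Externally scored pathway calls — e.g. amino-acid biosynthesis from
GapMind-style tools, or secretion-system presence from TXSS scanners — are
consumed as categorical tables and mapped `complete/partial/absent` to
`1/0.5/0` (`readCategoricalCompleteness()`); re-implementing those tools is
out of scope.

CAZyme counting (`countCazymes()`) is plain bookkeeping: a gene assigned to
k families contributes one count to each, and per-genome totals are reported
over the glycoside hydrolase (GH) and polysaccharide lyase (PL) classes.

# ANI and species delineation

The ANI definition follows the classic fragment scheme: the query genome is
cut into consecutive **1,020-nt** fragments (a trailing remainder is not
scored), each fragment is aligned to its best location in the reference, and
a fragment is *kept* when its alignment reaches **≥ 30% identity over ≥ 70%
of the fragment length**. ANI is the mean identity of kept fragments, in
percent. When no fragment passes the filter the result is an explicit
no-homology `NA` — never 0 — which is what unrelated random sequences
produce. The symmetric ANI of a pair is the arithmetic mean of the two
directions (or the defined one, if only one direction finds homology).

The aligner is seed-and-extend: exact 16-mer seeds every 20 nt vote on a
diagonal per reference contig; the fragment is then aligned end-to-end
against the winning window (±30 nt pad) with match +1 / mismatch −1 / gap
open 4 / gap extend 2, reference ends free. Identity is matches over
alignment columns. Aligning the *full* fragment (rather than taking the best
local sub-alignment) avoids the small upward identity bias local alignment
acquires by trimming mismatching fragment ends; under the substitution-only
simulation the expected identity is then exactly $1-d$ for divergence $d$,
which the acceptance checks exploit (recovery within 0.5 percentage points
across $d \in \{0.01, 0.03, 0.05, 0.10\}$ on 100-kb genomes).

Species clusters are the connected components of the graph with an edge
wherever ANI ≥ threshold (default 95%, the conventional bacterial species
boundary) — single linkage, which is parameter-free and matches how clusters
are read off a thresholded ANI heat map. A pair at exactly 95% joins a
cluster, since distinct species are defined by ANI *strictly below* the
threshold. Note the usual single-linkage caveat: chains (A–B ≥ 95, B–C ≥ 95,
A–C < 95) merge into one cluster.

16S identity uses a semi-global alignment (end gaps free; match +1,
mismatch −1, gap open 2, gap extend 0.5) with identity computed over aligned
columns excluding terminal overhangs — the convention of common pairwise
viewers, fixed here so values are reproducible bit for bit. Because free end
gaps can absorb terminal mismatch runs, observed identity can sit a few
tenths of a point above $100(1-d)$; the package's tests account for that.

# Community profiling

The central container is `AsvExperiment`, a `SummarizedExperiment` with ASVs
as rows (counts assay + taxonomy + optional sequence) and samples as columns
(host species/genus, location, colony). Defaults encode the standard V4
amplicon workflow thresholds, all strict where documented as strict:

* `filterAsvs()` keeps sequences of **250-256 nt inclusive** and drops ASVs
  whose taxonomy matches `Eukaryota`, `Chloroplast` or `Mitochondria` at any
  rank.
* `filterSamples()` drops samples with **fewer than 5,000** reads (a sample
  at exactly 5,000 stays). No rarefaction is performed — depth filtering
  replaces it.
* `aggregateFamilies()` pools ASVs with per-sample relative abundance
  **strictly below 1%** into `Other`, then sums by family; rows still sum
  to 1 (mass conservation is asserted to 1e-12 in the tests).
* `sharedAsvSummary()` calls an ASV *present* in a host group when it has
  **at least one read** in at least one of the group's samples, and *shared*
  when present in ≥ 2 groups. ASVs with zero reads everywhere (impossible in
  a filtered table) count as specific, so specific + shared always equals
  the total.

Bray-Curtis dissimilarity is computed from relative abundances as
$d(j,k) = \sum_i |x_{ij}-x_{ik}| \,/\, \sum_i (x_{ij}+x_{ik})$, and PERMANOVA
uses Anderson's one-factor formulation on the distance matrix directly:
$SS_{total}$ from all pairwise squared distances divided by $N$;
$SS_{within}$ from within-group pairs divided by group size;
$F = (SS_{between}/(a-1)) / (SS_{within}/(N-a))$. The permutation p-value is
$(\#\{F_{perm} \ge F_{obs}\}+1)/(n_{perm}+1)$ under seeded label
permutations, or the exact fraction over all $N!$ orderings with
`exhaustive = TRUE` (capped at N ≤ 8). Multi-factor sequential models are
out of scope — factors of interest (location, host genus, host species) are
tested separately, and `vegan::adonis2` serves as an independent
cross-check in the test suite. Ordination (NMDS) is visualisation and is not
computed; the distance matrix is the exported contract.

# Core-genome supermatrix

`selectSingleCopy()` keeps orthogroups with exactly one gene in every
considered genome. `trimAlignment()` removes alignment columns with
**more than 50% gaps** (strict: a column at exactly 50% stays); `-` and `.`
both count as gaps, ambiguous residues (`X`) do not. Per-orthogroup
alignments are trimmed *before* concatenation. `concatenateAlignments()`
records 1-based inclusive partition coordinates per orthogroup, and
`writeSupermatrix()` emits FASTA plus a RAxML/IQ-TREE-style partition file —
tree inference itself is exported, not performed. Trimming is idempotent,
and the kept-column indices give full column provenance from supermatrix
back to source alignments (asserted in the tests).

# Synthetic data: what it emulates, and what it does not

The generators plant the exact statistical structure the analyses assume:

* `simulateAnnotations()` constructs KO sets satisfying exactly k of n steps
  per pathway (plus distractor KOs), verified by re-scoring at generation
  time; planted fractions must be representable as k/n.
* `mutateSequence()` is substitution-only (each site independently replaced
  by a different base with probability d), so ANI recovery has a closed-form
  expectation. Indels, rearrangements, horizontally transferred regions and
  compositional bias — all present in real genomes — are not modelled;
  recovery under those is a robustness question, not an exactness one.
* `simulateAsvTable()` draws negative-binomial counts (per-ASV log-normal
  base mean, sdlog 1, dispersion size 2 — overdispersion typical of amplicon
  data) with zero counts outside each ASV's designed host species and at
  least one read inside (so the sharing design is exactly recoverable).
  `groupEffect` multiplies the mean in each ASV's first-listed species by
  (1 + effect); with effect 0 and an all-species design the host labels are
  exchangeable, giving a clean null for the type-I-error experiment.
  Real amplicon features not modelled: compositional coupling from fixed
  sequencing depth, chimeras, contamination, taxon-specific amplification
  bias.
* `simulateOrthogroups()` gaps alignment cells i.i.d. at `gapRate`, making
  the expected trimmed-column fraction the binomial tail
  P(Binom(n_rows, gapRate) > n_rows/2); real alignments have clustered,
  indel-driven gaps instead.

Passing tests on these fixtures therefore demonstrates correctness of the
computations under their stated models — not robustness to every artefact of
real sequencing data.

All generators fork a per-stream seed from one global integer seed (an
MINSTD-style integer hash), so each module's fixtures are reproducible
independently of call order, and the caller's RNG state is left untouched.

# Numerical and design choices

* Completeness cells are exact rationals (`stepsPresent/stepsTotal`); the
  float view agrees to 12 decimal places.
* ANI keep-filter ties: identity ≥ 0.30 and coverage ≥ 0.70 both inclusive.
* Thresholded boundaries follow the documented wording exactly: length range
  inclusive, read filter strict-below, "Other" pooling strict-below, gap
  trimming strict-above, ANI clustering inclusive-at-threshold.
* Cluster ids are assigned in first-appearance order of the input genomes,
  making outputs deterministic.
* PERMANOVA with zero within-group variance yields an infinite pseudo-F;
  the permutation p remains well-defined.
* Degenerate inputs error loudly: empty genomes/alignments, zero-total
  samples, all-samples-filtered tables, single-group PERMANOVA, orthogroup
  alignments missing a genome.

Problem sizes used by the test and acceptance runs are deliberately
desk-scale — 100-kb genomes for the ANI divergence grid, 50 genomes × 20
rules for completeness recovery, 500 null replicates × 99 permutations for
the PERMANOVA type-I experiment — chosen so the whole validation suite runs
on a laptop in a few minutes while keeping Monte-Carlo error well inside the
asserted bounds.

# Pipeline orchestration

`runPipeline()` takes a strict YAML configuration (unknown keys rejected;
thresholds range-checked: `ani_threshold` 95, `gap_fraction` 0.5,
`min_reads` 5000, `other_threshold` 0.01 by default) and executes the
enabled stages in dependency order: simulate → profile → ani → community →
supermatrix. Configuration problems abort before any stage runs; a stage
failure aborts with the failing stage named. The returned manifest records
the config (with an md5 checksum of the analysis-relevant part), per-stage
status and wall time, and an md5 checksum of every output file — identical
config and inputs give identical checksums. When the simulate stage provides
the ASV table, the depth filter is skipped (synthetic tables are desk-scale
by design); rules for planting are generated with disjoint KO pools so any
planted step count is constructible.

# Known limitations

* ANI here is one member of the fragment-ANI family; implementations differ
  in aligner and filters, and pairs sitting exactly at 95% can cluster
  differently across engines. Cluster counts near the threshold should be
  read with that caveat.
* Single-linkage clustering can chain distinct species through intermediate
  genomes.
* The PERMANOVA is one-factor; confounded factors (e.g. geography vs host
  taxonomy) must be tested separately and interpreted jointly.
* The 16S identity convention (end-gap-free, overhangs excluded) is one of
  several in circulation; absolute values can differ by a few tenths of a
  point from other tools.
* The rule engine evaluates presence/absence only; copy number, expression
  and pathway flux are out of scope.
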