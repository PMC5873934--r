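---
title: "Methods and design of stressPrio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of stressPrio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressPrio)
```

# The screening model

`stressPrio` prioritizes candidate genes for multiple abiotic stress
tolerance by demanding convergent evidence across independent sources. The
protocol, driven end-to-end by `runPipeline()`, is a funnel:

1. **Per-ontology collection.** For each of the five plant ontologies (GO,
   TO, PO, GRO, EO) a stress *term set* is built from seed accessions by
   descendant closure (`buildTermSet()`), and genes associated with any
   member term are collected. Associations are first propagated up the
   ontology (`propagateAnnotations()`): under the true-path rule an
   annotation to a term entails annotations to all its `is_a`/`part_of`
   ancestors. Where the target species lacks a direct association,
   annotations of orthologs in related species are transferred
   (`transferTransitive()`), with provenance recorded per record.
2. **Merge and de-duplication** of the per-ontology gene sets
   (`mergeUnique()`).
3. **All-ontology support filter** (`allOntologyFilter()`): only genes
   supported by every configured ontology group survive. "Supported" means
   at least one surviving association to the group's term set, not to every
   listed term — requiring every term would empty the funnel for any group
   with several developmental-stage or regimen terms.
4. **Enrichment gate** (`enrichTerms()`): terms over-represented among the
   surviving genes at BH-FDR < 0.01 define the screened candidate set.
5. **Integration with expression** (intersection of screened candidates
   with significantly up-regulated genes), **cross-stress / cross-species
   partitioning**, **QTL co-localization** and an optional **NJ phylogeny**.

The funnel's assumptions are worth stating: ortholog transfer assumes
functional conservation across the grasses and Arabidopsis (many-to-many
pairs are all kept — no one-to-one filter is applied by default, though a
`homologyType` filter is available on `readOrthologs()`); the enrichment
background assumes the association snapshot covers the species' gene space
fairly; and interval co-localization assumes QTL coordinates and gene
models are on the same assembly.

# Statistical components

## Hypergeometric enrichment

For a study set of $n$ genes in a universe of $N$ of which $K$ carry a
term, the over-representation p-value is the upper tail
$P(X \ge k)$, $X \sim \mathrm{Hypergeometric}(N, K, n)$ — the one-sided
Fisher exact test (`hypergeomTail()`, exact via the distribution's tail
function and verified against exhaustive subset enumeration for all
$N \le 12$). Multiplicity across terms is handled by Benjamini–Hochberg
step-up (`bhAdjust()`; the Benjamini–Yekutieli variant is available where
dependence between terms is a worry).

**Background universe.** The default universe is every gene of the target
species present in the propagated association table. This is the largest
genuinely open choice in the design: published analyses often use a
tool-internal background that cannot be reconstructed. An explicit
`universe` argument overrides the default.

## Differential expression

Expression matrices are linear-scale (RPKM-like) with per-sample metadata
(tissue, treatment, genotype), wrapped in a `SummarizedExperiment`. For a
two-level contrast `runDE()` computes, per gene:

* a **Welch t-test** (unequal variances, Welch–Satterthwaite df, two-sided
  p). Welch is the default because equal group variances cannot be assumed
  for stressed vs control tissue; a pooled-variance flag (`varEqual`)
  covers the classical reading of a "parametric t-test".
* the test runs on $\log_2(x + 1)$ values by default (`testLog`): linear
  RPKM values are strongly right-skewed and the log transform puts the
  planted-effect model (Gaussian noise on the log scale) in its natural
  coordinates. The **fold change** is computed on linear-scale group means
  with a pseudo-count of $10^{-9}$ guarding zero means.
* the class gate is conjoint: `up` requires significance (BH q by default,
  raw p with `useFDR = FALSE`) *and* $\log_2$ fold change at or beyond the
  threshold (default fold 2). Degenerate genes (both groups constant) are
  flagged, never an error: equal constants give $t = 0, p = 1$; unequal
  give $p = 0$.

At the documented operating point (planted $\log_2$ fold change 3, noise sd
1 on the log2 scale, 5 samples per group, two-sided $\alpha = 0.01$) the
exact power of a two-sided equal-variance t-test is
`power.t.test(n = 5, delta = 3, sd = 1, sig.level = 0.01)` $= 0.874$, and
Welch is slightly below it; a detection rate of 0.9 at these settings is
achievable only one-sided. The acceptance suite asserts the stricter
published bound and therefore documents this as a known red; the type-I
error assertion (within 3 binomial SE of 0.05 on 2000 null genes) passes.

## Set decomposition and reporting conventions

`vennPartition()` decomposes up to 8 named gene sets into disjoint
membership regions (regions are keyed by `+`-joined sorted labels — a
stable serialization). `multistressClassify()` labels a focal stress's
genes by region breadth: specific, dual, triple, universal (= all sets);
with five or more sets intermediate breadths are labelled `"<k>-way"`.

`percentageReport()` rounds **half away from zero** at the requested
precision. This is the convention that makes the package's printed
percentages self-consistent (e.g. $37/169 = 21.89\% \to 21.9$,
$169/272 = 62.13\% \to 62$, $352/1116 = 31.54\% \to 32$); banker's
rounding would disagree on `.5` ties.

`orthologyClass()` maps a presence vector over {sorghum-specific, maize,
rice, arabidopsis} to a label: `SO` + the letters `M`, `R`, `A` of the
species carrying orthologs, prefixed `Sorghum_` when the gene is also
sorghum-specific, plain `Sorghum` when it is only that. The scheme
generates 15 labels for the 15 non-empty vectors; conventional legends list
14 because `Sorghum_SOM` rarely occurs — the generative scheme keeps the
mapping total and bijective (`orthologyClassTable()` documents it).

## QTL co-localization

Coordinates are 1-based inclusive; BED input is converted on read and
chromosome labels are normalised (`"Chr 1"` → `"chr1"`). The default mode
is **full containment** (the gene interval inside the QTL interval),
matching the usual "falls within" criterion; `overlap` mode is provided
because boundary-straddling genes are biologically plausible, and
containment output is always a subset of overlap output. Genes inside
several overlapping QTLs are assigned to each, with a de-duplicated gene
total reported alongside. `bestHits()` makes the alignment-based route
deterministic: per query, descending bit score, ascending e-value,
descending identity, descending alignment length, then subject id — a
total order, so the result is invariant under input row permutation.

The packaged fixture (`loadTable3Fixture()`) transcribes the 22 published
sorghum drought-QTL regions with one representative co-localized gene each
and the per-QTL candidate totals. Four representative end coordinates are
truncated in the printed source (leading digits missing); the fixture
restores the evident values and flags those rows (`corrected`). One QTL's
citation tag disagrees with its trait family in the source; the fixture
classifies by trait name. Totals are carried as metadata because only the
representative locus per QTL is published.

## Phylogenetics

`pDistance()` computes percent divergence with **complete gap deletion** by
default (every column containing any gap is dropped), the behaviour that
matches distance tools' "gaps excluded" setting; pairwise deletion is
available and errors informatively when a pair has no comparable columns.
The optional distance correction is Kimura's protein approximation
$d = -\ln(1 - p - 0.2p^2)$; it saturates for $p \gtrsim 0.85$, where the
package either errors or caps with a flag (`onSaturate`).

`neighborJoining()` is a from-scratch Saitou–Nei implementation because the
package pins behaviours generic NJ code leaves unspecified: ties in the
Q-criterion are broken by the lexicographically smallest pair of cluster
names (clusters are named by their smallest leaf), and negative limb
lengths are clamped to zero with the deficit moved to the sibling limb
(raw lengths behind `clampNegative = FALSE`). On additive matrices NJ is
exact; the test suite uses path-metric recovery from random binary trees
(branch lengths ≥ 0.1 so no split is degenerate) as the primary oracle and
cross-checks topologies against an independent NJ implementation.

`bootstrapNJ()` resamples alignment columns with replacement (seeded),
counts, per internal edge of the point tree, the replicates containing the
same bipartition (encoded rooting-invariantly), and stores supports as node
labels on the 0..`nReps` scale. Clades under a support floor (default 5% of
replicates) can be collapsed to multifurcations (`collapseLowSupport()`).
An all-identical alignment is flagged degenerate: the topology is then
arbitrary. Newick output (`writeNewickTree()`) writes branch lengths to 6
decimals and quotes labels containing metacharacters; round-trips preserve
topology exactly and lengths within $10^{-6}$.

# The synthetic-data module

The generators emulate the statistical structure of the pipeline's inputs,
not their biology:

* `simulateOntology()` — random DAGs, acyclic by construction (each term's
  parents drawn among earlier terms).
* `simulateAssociations()` — a background of genes all annotated to the
  root (so the universe size is exact), Poisson-distributed random
  annotations (mean `density` = 2), and a planted term whose study and
  background coverages are realized as **exact counts**, defaulting to
  40/50 study vs 100/1000 background — a strong, unambiguous enrichment
  signal. A `transitiveFraction` reroutes gene records through named
  orthologs so transfer logic is exercised with known truth.
* `simulateExpression()` — per-gene log2 baselines uniform on [4, 8],
  Gaussian noise (sd 1) per sample on the log2 scale, a planted log2 fold
  change (default 3) in the stress group, exponentiated to the linear
  scale: a two-group design with 5 samples per condition, matching a
  typical small stress-profiling experiment.
* `simulateQTLScenario()` — non-overlapping QTLs with genes placed strictly
  inside, strictly outside, or straddling a boundary; the generator's
  ground truth equals containment-mode output by construction.

Every generator saves and restores the caller's RNG state and derives its
stream from a global seed via `deriveSeed()`, so adding a generator never
perturbs existing fixtures. What passing tests on these fixtures show is
that the *procedures* are correct at their operating points; they do not
show that real association snapshots are complete, that real expression
noise is log-Gaussian, or that real QTL/gene coordinates share an assembly
— those remain data-quality obligations on the user.

# Numerical and scale choices

* Hypergeometric tails come from the distribution's tail function
  (log-space internally), exact to well beyond 10 significant digits for
  universes up to $10^4$.
* All gene orderings are lexicographic and all region/tie-break keys are
  sorted, so every output is bit-reproducible.
* Test and acceptance problem sizes were chosen to characterize each
  statistic tightly at desk scale: the enumeration grid for the
  hypergeometric check covers all $N \le 12$; enrichment recovery uses 200
  simulated backgrounds of 1000 genes; DE error rates use 2000 genes per
  arm; NJ recovery uses 100 random trees of up to 8 taxa; bootstraps use
  100–200 replicates on 6-taxon alignments of 100 columns.

# Known limitations

* The published screening counts of the motivating study (candidate and
  merged gene totals, per-term p-values) depend on 2017-era database
  snapshots and are not reproducible from the procedure alone; the package
  reproduces the *procedure* on any snapshot, plus the in-table arithmetic
  that is self-contained (QTL totals, category percentages, share
  arithmetic).
* Descendant closure of seed accessions is exposed as a flag
  (`closure`, default on) because source protocols rarely state whether
  term queries were closed; both counts can be reported.
* The enrichment gate and the DE gate can disagree on a gene;
  `runPipeline()` reports the intersection by default (the minimal,
  conservative reading) with a union mode behind `integration`.
* No multiple-sequence alignment, OWL parsing, live database access or
  visualization: alignments, ontologies and association snapshots are
  inputs, and outputs are tables, partition files and Newick text.
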