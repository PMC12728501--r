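---
title: "Testing the significance of shared chromosomal linkage groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing the significance of shared chromosomal linkage groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synlink)
```

## The problem

Chromosome-scale assemblies let us ask whether a set of orthologous genes
that co-reside on one chromosome in one species also co-reside in others.
Such conserved co-residence — macrosynteny, assessed without regard to gene
order — is evidence that the genes sat on one chromosome in the common
ancestor (an ancestral linkage group, ALG), and shared *rearrangements* of
ALGs (notably fusion followed by intra-chromosomal mixing, which is
effectively irreversible) have been used as phylogenetic characters, for
example in the dispute over whether sponges or ctenophores are the sister
group of all other animals. Those arguments only carry weight if the
underlying linkage groups are statistically supported: a group of few shared
genes on large chromosomes is exactly what random gene placement produces.

synlink implements and contrasts two ways of attaching significance to
shared chromosome combinations, plus the machinery needed to exercise them
on data with a known answer.

## Data model

The input is a table of strictly single-copy N-way orthologs: one row per
ortholog group, and per species a gene id, a chromosome id, and an integer
gene rank on that chromosome (`read_rbh()`; base-pair coordinates are
rank-transformed on read because only order and adjacency enter any
computation). One species — in the motivating application a unicellular
relative of animals such as a filasterean or a choanoflagellate — is the
outgroup; the metazoans form the ingroup. `cross_reference_clusters()`
builds such tables from pairwise best-hit lists produced by an external
aligner: a cluster is a clique in the reciprocal-best-hit graph, with
E-values below 0.1 and ties for "best" treated as no best hit at all (the
conservative choice keeps clusters strictly single-copy). Alignment itself
is out of scope: the package consumes hit tables, it never computes them.

## Permutation null models: shuffle one species, not all

A common null model for linked-ortholog counts permutes the
gene-to-chromosome assignment of *every* species and tallies how often a
combination of chromosomes is supported by 1, 2, ... shared orthologs
(`shuffle_null(mode = "all")`). The defect of that strategy is that it
treats all genomes as statistically independent even when they are
phylogenetically correlated. The clean thought experiment: duplicate one
species exactly (`copy_species()`). The biology is unchanged — the copy
carries no new information — so the null distribution should be the
distribution of the original pair. Shuffling only a designated species
(`mode = "single"`, the outgroup) achieves exactly that; shuffling all
species instead splits every random group across an extra independent axis,
thins the right tail of the group-size distribution, and therefore makes
observed groups look more significant than they are. The package's
acceptance suite reproduces both facts at 10,000 randomizations.

Shuffling permutes the (chromosome, position) labels among genes, so the
multiset of per-chromosome gene counts is preserved exactly. Each replicate
`r` under root seed `s` uses a derived stream seed (`derive_seed(s, r)`),
making replicates reproducible and order-independent; the tally bins the
sizes of *all* observed combinations in each replicate, not only the
largest. `fdr_by_group_size()` converts such a null into one FDR estimate
per group size — the expected number of random combinations of at least
that size per randomization divided by the observed number, clamped to
[0, 1]. This statistic is a documented reconstruction of the
group-size-level FDR used by shuffle-based screens; it deliberately ignores
chromosome sizes, which is its weakness: five genes shared by the largest
chromosomes of four species are far less surprising than five shared by the
smallest.

## The exact test

The package's preferred statistic conditions on chromosome sizes. For an
ingroup chromosome combination (merged id joining the ingroup chromosome
ids, e.g. `HCA7_RES2_EMU19`) and an outgroup chromosome, the 2x2
contingency table is built from four counts: `k` orthologs shared, `K_out`
orthologs on the outgroup chromosome, `K_in` on the ingroup combination,
`N` in total — ortholog counts serving as the proxy for chromosome size.
The p-value is the upper tail of the hypergeometric distribution,
`P(X >= k)` computed as the survival function at `k - 1`, equal to the
one-sided Fisher exact test and symmetric in the two margins. Every
observed combination is one hypothesis; `linkage_fisher()` tests the whole
observed family and applies Benjamini-Hochberg at `alpha = 0.05` (both
configurable; `min_count` can floor the family for sensitivity analysis,
default 1).

```{r worked}
ct <- contingency_table(k = 15, K_out = 182, K_in = 27, N = 1874)
ct
signif(hypergeom_tail(ct), 2)
```

Degenerate tables are guarded: `k = 0` or an empty margin returns
probability 1. Correctness is pinned by three independent oracles in the
test suite: exhaustive enumeration of all draws for every table with
`N <= 12`, the one-sided Fisher exact test on random tables (relative error
below 1e-10), and hand-computed small cases; BH adjustment is checked
against a literal step-up implementation.

## Hierarchical buildup

Testing every observed combination against the outgroup pays a heavy
multiplicity price. `build_hierarchy()` instead builds candidate ancestral
chromosomes one species at a time — first a chromosome pair of the two
ingroup species compared, then extensions by each further species, finally
the outgroup — restricting each level's family to extensions of the
previous level's BH survivors, with one shared alpha. The final, hardest
comparison (metazoan combination versus unicellular chromosome) is then
made within a small family of well-supported candidates. The statistic at
each level is unchanged; only the family shrinks, so for a combination
present in both analyses the final-level raw p-value equals the flat one.
The species order is user-chosen (default: table order, outgroup last);
levels may optionally use separate, larger ortholog tables computed without
the later species (`level_tables`), reflecting that pairwise ortholog sets
are bigger than four-way ones.

Each level also carries the observed count matrix with standardized Pearson
residuals, `(O - E) / sqrt(E (1 - r/N)(1 - c/N))`, and the omnibus
chi-squared statistic, for heatmap rendering (`export_heatmap()`,
`plot()`). Cells with a zero margin have undefined residuals and are
excluded from the statistic. Residuals are diagnostics only; they never
enter the tests.

## Conserved adjacent pairs

Two genes immediately neighboring on a chromosome whose orthologs remain
neighbors (or at least co-chromosomal) across distant species are strong
small-scale evidence of shared descent, independent of the chromosome-level
tests. `find_adjacent_pairs()` reports every pair of ortholog rows adjacent
in at least `min_adjacent` species and co-chromosomal in at least
`min_cochrom`. Adjacency is defined on ranks *within the table's gene set*:
intervening genes absent from the single-copy table do not break adjacency.
Published uses of this idea differ on that point, so the rule is explicit
and both thresholds are exposed rather than hard-coded; strand and
orientation are ignored. The defaults (`species_count - 1`,
`species_count`) tolerate one species in which the pair has separated but
stayed co-chromosomal.

## The simulator

`simulate_genomes()` exists so that every claim above can be exercised on
data with known truth. An ancestor (`ancestral_genome()`) has one
chromosome per planted ALG; each species then applies, in a fixed order
chosen for reproducibility: chromosome fusions, post-fusion mixing,
fissions, per-gene translocations, per-gene losses.

* **Fusion and mixing.** A fusion concatenates two chromosomes; `mixing` in
  [0, 1] is the fraction of the fused chromosome's genes then repositioned
  uniformly along it. `mixing = 0` leaves the two ancestral blocks intact
  (fusion without mixing), `mixing = 1` scrambles them completely — the
  simplest model that separates the two regimes the fusion-with-mixing
  argument distinguishes.
* **Translocation.** Each gene independently moves with probability
  `translocation_rate` to a uniformly chosen chromosome (a draw equal to
  the source is an intra-chromosomal reposition). The destination is
  uniform over *all* chromosomes so that the rate-1 limit genuinely
  decouples chromosome from linkage group; excluding the source would
  leave a permanent anti-association with the ancestral chromosome.
* **Loss.** Applied independently per species; a gene lost anywhere drops
  the whole row, mirroring single-copy reciprocal-best-hit filtering.

Positions are gene ranks among surviving genes. Ground truth (gene-to-ALG
map, per-chromosome ALG composition) accompanies the table, and
`truth_evaluate()` scores recovered combinations: a significant combination
is a true positive iff its chromosomes share a common plurality ALG; recall
is the fraction of planted ALGs recovered.

What the simulator does *not* emulate: realistic chromosome length
distributions, segmental (multi-gene) rearrangements, gene family dynamics
beyond presence/absence, or rate heterogeneity along chromosomes. Passing
tests therefore demonstrate the statistical machinery on idealized
rearrangement histories, not performance on real genomes — in particular,
real ortholog identification noise is absent.

## Numerical and design choices

* Tail convention is strictly "k or more" (`phyper(k - 1, ...,
  lower.tail = FALSE)`); p-values are displayed at two significant figures
  but kept at full precision internally and in TSV output.
* Merged combination ids join chromosome ids with `_` for reporting; all
  internal matching uses a separator that cannot occur in ids, so
  underscores in chromosome names are safe.
* The BH family in flat mode is every observed (ingroup combination,
  outgroup chromosome) pair with at least `min_count` shared orthologs;
  each such pair is one hypothesis.
* One root seed drives everything; derived stream seeds keep replicates
  and species independent of evaluation order. All seeds stay below 2^31.
* `run_reanalysis()` validates its configuration (e.g. `alpha` in (0, 1))
  before touching data, logs family sizes at each stage — family size being
  the scientific crux of the correction — and writes a manifest (seed,
  package version, configuration hash). Identical configurations give
  byte-identical statistical outputs. Combinations whose metazoan part the
  hierarchy does not support are reported with an explicit `x` status,
  never as silently missing rows.

## Problem sizes used in the test suite

The suite runs at desk scale: permutation contrasts use a simulated pair
of 320 orthologs over 15-18 chromosomes at 10,000 randomizations;
planted-recovery checks use three 30-gene ALGs across four species over 20
seeds; the false-discovery check shuffles a 200-ortholog, 4-species
table 100 times; the enumeration oracle covers every contingency table with
`N <= 12`. These sizes were chosen so the whole suite completes in minutes
while keeping Monte-Carlo error well below the margins being asserted.

## Known limitations

The exact test conditions on the observed marginals, as Fisher's test
always does; discreteness makes it conservative on small counts. With very
few chromosomes per genome, independently translocated genes occasionally
land together and form a genuinely co-resident small group in all species;
the flat test can flag such a convergent group as significant (it *is*
enriched — it is simply not ancestral), while the hierarchical buildup
tends to reject it because its ingroup support is too weak at earlier
levels. This is the small-numbers caveat at the heart of the method:
syntenies supported by a handful of genes cannot be distinguished from
convergent relocation by enrichment statistics alone, and the package makes
no attempt to do so. Finally, the group-size FDR reconstruction is provided
for comparison with shuffle-based screens, not as a recommended statistic.
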