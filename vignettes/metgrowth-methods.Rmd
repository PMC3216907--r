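---
title: "Measuring horizontal and vertical growth of a metabolic network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring horizontal and vertical growth of a metabolic network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metgrowth)
```

## The question

A metabolic network can grow in two ways when a gene duplicates. If the
new enzyme processes metabolites that were not in the network before,
the *metabolic space* — the set of all metabolites — expands
(*horizontal* growth). If instead the duplicate catalyses a reaction
the network already performs, the space is unchanged and the network
grows *vertically*: it accumulates isozymes, typically specialised for
different compartments, conditions or regulatory programs. Telling the
two modes apart for the duplicate pairs still detectable in a genome
says which evolutionary regime — stepwise recruitment of neighbouring
reactions versus specialisation of broad-specificity enzymes — shaped
the network.

`metgrowth` implements this analysis as a reusable pipeline over
*metabolite-centric* networks: metabolites are nodes, and every edge is
one enzyme catalysing one main substrate/product pair. The
metabolite-centric view matters: in the dual (enzyme-centric) network,
two isozymes of the same reaction and two enzymes of consecutive
reactions can sit at the same graph distance, whereas here isozymes are
parallel edges and are cleanly identified by their overlap coefficient.

## Network model

`build_metabolic_network()` turns validated reaction records into a
directed multigraph:

* one edge per (enzyme, substrate, product) triple, so a protein
  complex contributes one parallel edge per member and isozymes are
  parallel edges;
* reversible reactions contribute edges in both directions, since the
  sources state only that edge direction follows reaction direction;
* only *main* ("primary") reactant pairs are represented. Currency
  metabolites (ATP, NADH, water, ...) never enter the graph, which
  would otherwise be dominated by spurious hubs. No additional
  stop-list is applied beyond the source database's own
  primary/main classification.

The *canonical profile* of an enzyme (`enzyme_metabolite_pairs()`)
counts each reaction once regardless of reversibility: A ⇌ B is the
pair (A, B) in the source direction, never additionally (B, A). Two
genuinely distinct irreversible reactions A → B and B → A do yield two
pairs.

Degree (`degree_distribution()`) counts incident edges including
parallels — edges denote proteins, so two isozymes contribute 2 to each
endpoint — with a `count_parallel = FALSE` switch for the
distinct-neighbour alternative. Shortest paths
(`shortest_path_length()`) default to breadth-first distance on the
undirected simple view; sparse directed metabolic graphs rarely give
finite directed distances between arbitrary metabolite pairs, and the
finite mean path lengths this analysis reports are only meaningful on
the undirected view. A `directed = TRUE` switch exists.

## Overlap statistics

For a paralog pair (E1, E2) with canonical profiles X1, X2:

$$\mathrm{Dice}_M = \frac{2\,|X_1 \cap X_2|}{|X_1| + |X_2|}$$

which is 1 exactly when the profiles coincide (isozymes; vertical
growth) and 0 when they share no transformation (horizontal growth).
We use the standard Dice denominator $|X_1|+|X_2|$: a set-union
denominator would give 2 for identical profiles and could not satisfy
the defining boundary behaviour. $\mathrm{Dice}_P$ is the same
coefficient over pathway-membership sets. Pairs are classified FULL
(= 1), PARTIAL (0 < d < 1) or NONE (= 0); a pair with a member absent
from a network is N/A for that network rather than 0.

Divergent pairs are localised by `pair_metabolite_distance()`: the mean
undirected shortest path over all ordered pairs (m1, m2) with m1
incident to E1 and m2 incident to E2. Identical metabolites contribute
distance 0 and unreachable pairs are excluded from the mean but
counted. Under this convention a pair of enzymes catalysing contiguous
reactions (products of one are substrates of the other) scores exactly
1 on a two-step chain — the calibration point for the statistic — while
divergent paralogs in distant network regions score much higher.

Duplication-age enrichment among NONE pairs uses the upper-tail
hypergeometric test (`stats::phyper`), with population = all pairs
with a defined Dice in the network and selection = its NONE pairs.
Raw p values are reported; a Bonferroni column over the four age
groups is emitted alongside but not used for the headline test.

Expression similarity is the Pearson correlation over
pairwise-complete experiments after missing-data filtering
(`filter_expression_matrix()`): experiments with more than 5% missing
genes are dropped first, then genes with more than 5% missing values
over the *surviving* experiments. The order matters and is fixed —
a gene can be rescued by the removal of the experiments it was
missing in.

## The collapse experiment

`collapse_ensemble()` asks the counterfactual: what would the
metabolic space look like had each paralogous family stayed a single
gene? For every family with at least two members labelling network
edges, one member is kept uniformly at random, the others' edges are
deleted, and metabolites left with no incident edge are removed. Only
then is the preserved-metabolite fraction recorded. We deliberately do
*not* delete every metabolite touched by a removed enzyme: that
reading would also delete metabolites still served by kept enzymes and
could not produce near-complete preservation even for pure isozyme
families, contradicting the behaviour the statistic is meant to
detect. When every family is fully overlapping the preserved fraction
is exactly 1.0 in every replicate — the vertical-growth signature —
and this is asserted by the tests.

The ensemble (default 1000 replicates) is drawn from a seeded
generator; identical seeds give bit-identical summaries. Degree
distributions of the collapsed networks are compared with the original
by the Kolmogorov–Smirnov distance between the degree CDFs plus an
overlay table of P(k).

## Paralogy detection

Families are defined three ways, mirroring common practice: from
sequence, and from two kinds of external resources (pair lists with
per-pair ages, and ortholog-group files with family-level ages), all
reduced to the same `family_set` representation and mergeable by edge
union (`merge_family_sets()`).

The sequence route aligns all protein pairs with a global
Needleman–Wunsch alignment under affine gaps (compiled in C++),
connects pairs with identity strictly greater than 30% — a literal
reading of "more than 30%" — and takes connected components as
families. Identity is matches over alignment length (the global
alignment report convention, as opposed to shorter-sequence length);
similarity additionally counts positive-scoring substitutions.
Numerical conventions, all config-exposed:

* substitution matrix BLOSUM62 (any Biostrings matrix can be named),
  gap open 10, gap extend 0.5;
* a gap of length L costs `gap_open + L * gap_extend`; end gaps are
  penalized (true global alignment);
* traceback tie-break is fixed (diagonal > gap-in-second >
  gap-in-first), so results are deterministic;
* sequences shorter than 30 residues are aligned like any other but
  flagged, since percent identity saturates there; no length
  correction is applied.

An optional 4-mer prefilter skips pairs sharing no length-4 substring;
exact all-pairs alignment is the default. Ages are always ingested
from external tables, never inferred from sequences.

## The synthetic-study generator

Because every real-data headline number depends on versioned external
databases, the package ships a generator (`generate_study()`) that
emits complete, self-consistent study bundles with planted ground
truth, in *both* database dialects, plus proteome, family tables and
expression — so every pipeline stage is testable offline and
end-to-end.

Design: a connected scaffold (default 150 reactions; a chain with 20%
random branching) carries singleton background enzymes. Families
(default 100; sizes 2–4 with probabilities 0.7/0.2/0.1) draw a class
with probabilities `f_full/f_partial/f_none` (defaults 0.8/0.1/0.1,
the class split this kind of analysis reports for yeast):

* FULL members all catalyse one scaffold reaction → every pair has
  Dice\(_M\) = 1 and collapsing can never lose a metabolite;
* PARTIAL members share one reaction and hold one private reaction
  each → every pair has Dice\(_M\) exactly 0.5, a deterministic,
  assertable intermediate;
* NONE members each catalyse a private branch reaction (anchor → new
  metabolite) with anchors at least 4 scaffold steps apart → Dice\(_M\)
  = 0, large metabolite distances, and genuine metabolic-space loss
  under collapse.

Ages are drawn per family from a mixture (defaults 0.15/0.15/0.45/0.25
over the pre-WGD Euascomycete, pre-WGD Hemiascomycete, WGD and
post-WGD classes, emulating the dominance of whole-genome-duplication
pairs among yeast duplicates); NONE families take the oldest class
with probability `p_none_given_oldest` (default 0.9), planting the age
concentration of divergent pairs. Proteomes mutate a per-family seed
sequence at 0.1 substitutions per site (within-family identity far
above the 30% threshold; between-family identity of independent random
sequences stays below 25%, verified by alignment in the tests).
Expression profiles share a common factor within FULL families
(pairwise correlation 0.8 by default) and are independent noise
otherwise, with 2% missing cells. Every reaction also carries a
planted non-primary ATP/ADP currency pair that a correct reader must
discard. The whole bundle is a deterministic function of the seed.

What the generator does *not* emulate: real yeast biochemistry and
stoichiometry, realistic protein evolution (no indels within families,
uniform residue usage), hub metabolites beyond the planted currency
pair, and families whose members span classes. Passing tests therefore
demonstrate correctness of the machinery and recoverability of planted
signal — not that any particular organism grew one way or the other.

## Statistical calibration of the recovery tests

The generator draws the overlap class once per family; all within-
family pairs inherit it. Pair-level class fractions are therefore
clustered samples (a size-4 family contributes six identically-classed
pairs), and a binomial standard error computed at the pair count would
understate their variance. The recovery tests consequently check two
things: that the pipeline classification agrees with the planted truth
pair by pair (exact, by construction of the generator), and that
family-level estimated fractions fall within 3 binomial standard
errors of the configured fractions, with the family as the sampling
unit.

## Problem sizes used by the test suite

The shipped tests run at desk scale, chosen as the smallest sizes that
leave no property untested: oracle equivalence for the aligner over
the full space of sequence pairs of length ≤ 6 on a three-letter
alphabet against an independently written dynamic-programming oracle
(itself validated against exhaustive alignment enumeration);
hypergeometric tails against full enumeration for every parameter
combination with N ≤ 12; shortest paths against Floyd–Warshall on
random networks of up to 20 nodes; collapse ensembles of 1000
replicates (10,000 for the two-outcome calibration toy, whose exact
mean preserved fraction 0.75 follows by enumeration); and parameter
recovery over 20 generator seeds at the default study size.

## Known limitations

* Metabolite identity is the source database identifier, case
  sensitive; no cross-dialect compound mapping is attempted (the two
  dialects are never merged into one network).
* Reader grammars are minimal dialects sufficient for the fields this
  analysis uses, not full BioCyc/KEGG schema support; records a parser
  cannot use are skipped with counted, logged reasons rather than
  failing the run.
* Complexes lacking gene-level members keep the complex id as the
  enzyme label and are flagged, which slightly inflates apparent
  enzyme counts if such records are common.
* Mean-path statistics are reported per pair; pooling all metabolite
  pairs across a pair cohort and averaging per-pair means are both
  available, since the two aggregations differ on unbalanced profiles.
* The expression correlation uses pairwise-complete observations
  within the filtered matrix; with very sparse profiles the effective
  n varies between pairs and is reported alongside r.
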