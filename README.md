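# metgrowth

Did gene duplication expand a metabolic network's *metabolic space*
(horizontal growth: new metabolites), or did it multiply enzymes over
the space that was already there (vertical growth: isozymes)?
`metgrowth` implements the full analysis for answering that question
from pathway-database flat files, for systems biologists studying
metabolic network evolution:

* **metabolite-centric network reconstruction** — metabolites as
  nodes, one labelled edge per (enzyme, main substrate/product pair);
  readers for a BioCyc/MetaCyc-style dialect (`pathways.dat`,
  `enzrxns.dat`, `protcplxs.col`) and a KEGG-style dialect (reaction
  list with "main" RPAIR annotations + KGML), with complex expansion
  and currency-metabolite exclusion via the primary/main filter;
* **paralogous family detection** — all-pairs global Needleman–Wunsch
  alignment (affine gaps, BLOSUM62), identity > 30% edges, connected
  components; plus readers for external pair-list and ortholog-group
  family definitions with duplication-age labels;
* **the collapse experiment** — keep one random member per family,
  delete the rest, and compare the metabolic space and degree
  distribution P(k) of the original network with an ensemble of
  collapsed ones;
* **functional overlap** — for each paralog pair (E1, E2) with
  canonical metabolite-pair profiles X1, X2,

  Dice_M = 2 |X1 ∩ X2| / (|X1| + |X2|),

  1 for isozymes, 0 for no shared transformation, with an analogous
  Dice_P over pathway memberships, a random-pair null distribution,
  mean shortest-path localisation of divergent pairs, upper-tail
  hypergeometric enrichment of duplication-age groups among
  zero-overlap pairs, and Pearson expression correlation after
  5%-missingness filtering;
* **a synthetic-study generator** — complete study bundles (both
  database dialects, FASTA proteome, family/age tables, expression
  matrix) with planted ground truth, so the whole pipeline is testable
  without any download.

## Worked example

The built-in worked toy is a six-metabolite linear pathway carrying a
FULL isozyme pair (E1, E2 share one reaction), a NONE divergent pair
(E3, E5 in different pathway sections) and a contiguous enzyme pair
(E3, E4):

```r
library(metgrowth)
toy <- generate_worked_toy()
toy$network
#> <metabolic_network> 6 metabolites, 6 edges, 5 enzymes
enzyme_dice_m(toy$network, "E1", "E2")   # isozymes
#> [1] 1
enzyme_dice_m(toy$network, "E3", "E5")   # no functional overlap
#> [1] 0
pair_metabolite_distance(toy$network, "E3", "E4")$mean_path
#> [1] 1
```

Dice_M = 1 marks a vertical growing move, 0 a horizontal one, and the
mean path of exactly 1 is the calibration value for enzymes catalysing
contiguous reactions (the products of the first are the substrates of
the second).

A full synthetic study with planted class fractions 0.8/0.1/0.1 and
divergent pairs concentrated in the oldest duplication-age class:

```r
st  <- generate_study(synthetic_config(seed = 42))
net <- build_metabolic_network(st$reactions)
net
#> <metabolic_network> 179 metabolites, 407 edges, 283 enzymes

pairs <- enumerate_network_pairs(st$families, net)
tab <- overlap_table(pairs, list(synth = net), ages = st$families,
                     expression = filter_expression_matrix(st$expression),
                     distances = FALSE)
summarise_overlap(tab)
#> <overlap_summary>
#>  network   class count   fraction
#>    synth    FULL   145 0.80110497
#>    synth PARTIAL    18 0.09944751
#>    synth    NONE    18 0.09944751
#> 18 divergent pair(s)
```

The recovered fractions match the planted 80/10/10 split, and the
oldest age group is strongly enriched among the zero-overlap pairs
(16 of the 18 NONE pairs, upper-tail hypergeometric
p = 4.9e-09). The collapse ensemble shows the counterfactual
single-copy network:

```r
collapse_ensemble(net, st$families, n_replicates = 1000, seed = 42)
#> <collapse_summary> 1000 replicates (seed 42)
#>   preserved metabolites: 0.8967 +/- 0.0062
#>   removed edges:         202.4 +/- 1.9
```

About 10% of metabolites are lost — exactly the horizontal
contribution of the planted NONE families — while FULL and PARTIAL
families cost edges but no metabolic space.

`run_pipeline(pipeline_config(...))` orchestrates the same steps for
any combination of networks and paralogy definitions and writes TSV
result tables plus a JSON manifest.

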