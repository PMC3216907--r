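# Fixture networks built in code.

# A -> B by isozymes E1/E2, B -> C by E3, C <=> D by E4.
toy_records <- function() {
  list(reaction_record("RA", "A", "B", enzymes = c("E1", "E2")),
       reaction_record("RB", "B", "C", enzymes = "E3"),
       reaction_record("RC", "C", "D", reversible = TRUE, enzymes = "E4"))
}

toy_network <- function() build_metabolic_network(toy_records())

# Network whose single two-member family yields equiprobable collapse
# outcomes with preserved fractions 1.0 (E2 kept; E3 still covers
# A -> B) and 0.5 (E1 kept; C, D become isolated). Exact mean 0.75.
two_outcome_network <- function() {
  build_metabolic_network(list(
    reaction_record("R1", "A", "B", enzymes = "E1"),
    reaction_record("R1b", "A", "B", enzymes = "E3"),
    reaction_record("R2", "C", "D", enzymes = "E2")))
}

two_outcome_family <- function() {
  metgrowth:::new_family_set(list(F1 = c("E1", "E2")))
}

# Random connected-ish multigraph network for property tests.
random_records <- function(n_nodes, n_reactions, p_reversible = 0.3) {
  nodes <- paste0("N", seq_len(n_nodes))
  lapply(seq_len(n_reactions), function(i) {
    sp <- sample(nodes, 2)
    reaction_record(paste0("R", i), sp[1], sp[2],
                    reversible = runif(1) < p_reversible,
                    enzymes = paste0("E", sample(5, 1)))
  })
}

blosum62_acd <- function() {
  p <- alignment_params()
  p$matrix[c("A", "C", "D"), c("A", "C", "D")]
}
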