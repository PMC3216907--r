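#' Collapse a network by keeping one random member per paralogous family
#'
#' For every family with at least two members labelling network edges,
#' one member is chosen uniformly at random and kept; the edges of all
#' other members are deleted, and metabolites left without any incident
#' edge are then removed. Enzymes outside any multi-member family are
#' untouched. Uses R's global random number generator; seed it (or use
#' [collapse_ensemble()]) for reproducibility.
#'
#' @param network A `metabolic_network`.
#' @param families A `family_set`.
#' @return A list with `network` (the collapsed `metabolic_network`)
#'   and `replicate`, a list holding `kept` (named character: family ->
#'   kept enzyme), `removed_enzymes`, `removed_edge_count`,
#'   `preserved_metabolite_fraction` and the collapsed network's
#'   `degree_distribution`.
#' @export
collapse_network <- function(network, families) {
  stopifnot(inherits(network, "metabolic_network"),
            inherits(families, "family_set"))
  enz <- network_enzymes(network)
  kept <- character()
  removed <- character()
  for (fid in names(families$families)) {
    present <- intersect(families$families[[fid]], enz)
    if (length(present) < 2L) next
    keep <- present[sample.int(length(present), 1L)]
    kept[[fid]] <- keep
    removed <- c(removed, setdiff(present, keep))
  }
  e <- network$edges
  drop <- e$enzyme %in% removed
  e2 <- e[!drop, , drop = FALSE]
  rownames(e2) <- NULL
  nodes2 <- sort(unique(c(e2$from, e2$to)))
  collapsed <- new_metabolic_network(
    e2, nodes2, network$pathways[setdiff(names(network$pathways), removed)])
  rep_info <- list(
    kept = kept,
    removed_enzymes = removed,
    removed_edge_count = sum(drop),
    preserved_metabolite_fraction =
      length(intersect(nodes2, network$nodes)) / length(network$nodes),
    degree_distribution = if (length(nodes2))
      degree_distribution(collapsed) else NULL)
  list(network = collapsed, replicate = rep_info)
}

#' Ensemble of randomly collapsed networks
#'
#' Draws `n_replicates` independent collapses from a seeded generator
#' and aggregates the preserved-metabolite fraction, removed-edge count
#' and degree distributions. The same seed reproduces the ensemble
#' bit for bit.
#'
#' @param network A `metabolic_network`.
#' @param families A `family_set`.
#' @param n_replicates Number of collapsed networks (>= 1).
#' @param seed Integer seed.
#' @param keep_distributions Keep each replicate's degree distribution
#'   (needed by [compare_degree_distributions()]); default `TRUE`.
#' @return An object of class `collapse_summary`: list with
#'   `replicates` (data frame: one row per replicate with
#'   `removed_edge_count` and `preserved_metabolite_fraction`),
#'   `mean_preserved`, `sd_preserved`, `mean_removed_edges`,
#'   `sd_removed_edges`, `distributions` (list or `NULL`), `seed` and
#'   `n_replicates`.
#' @export
collapse_ensemble <- function(network, families, n_replicates = 1000L,
                              seed = 1L, keep_distributions = TRUE) {
  stopifnot(n_replicates >= 1L)
  reps <- with_local_seed(seed, lapply(seq_len(n_replicates), function(i)
    collapse_network(network, families)$replicate))
  preserved <- vapply(reps, `[[`, 0, "preserved_metabolite_fraction")
  removed <- vapply(reps, `[[`, 0, "removed_edge_count")
  structure(list(
    replicates = data.frame(
      replicate = seq_len(n_replicates),
      removed_edge_count = removed,
      preserved_metabolite_fraction = preserved),
    mean_preserved = mean(preserved), sd_preserved = stats::sd(preserved),
    mean_removed_edges = mean(removed),
    sd_removed_edges = stats::sd(removed),
    distributions = if (keep_distributions)
      lapply(reps, `[[`, "degree_distribution") else NULL,
    kept = lapply(reps, `[[`, "kept"),
    seed = seed, n_replicates = n_replicates),
    class = "collapse_summary")
}

#' @export
print.collapse_summary <- function(x, ...) {
  cat("<collapse_summary> ", x$n_replicates, " replicates (seed ",
      x$seed, ")\n  preserved metabolites: ",
      sprintf("%.4f +/- %.4f", x$mean_preserved, x$sd_preserved),
      "\n  removed edges:         ",
      sprintf("%.1f +/- %.1f", x$mean_removed_edges, x$sd_removed_edges),
      "\n", sep = "")
  invisible(x)
}

# Run code under a temporary seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

degree_cdf <- function(dist, support) {
  p <- stats::setNames(rep(0, length(support)), support)
  p[as.character(dist$k)] <- dist$p
  cumsum(p)
}

#' Compare an original degree distribution with a collapsed ensemble
#'
#' Computes the Kolmogorov-Smirnov distance (maximum absolute CDF
#' difference over the union support) between the original distribution
#' and each replicate's, plus an overlay table suitable for plotting
#' P(k) of the empirical network against the collapsed ensemble.
#'
#' @param original A `degree_distribution`.
#' @param ensemble A list of `degree_distribution` objects (e.g. the
#'   `distributions` element of a `collapse_summary`).
#' @return List with `ks` (numeric vector, one distance per replicate)
#'   and `overlay` (data frame: `k`, `p_original`, `mean_p_collapsed`,
#'   `sd_p_collapsed`).
#' @export
compare_degree_distributions <- function(original, ensemble) {
  stopifnot(inherits(original, "degree_distribution"),
            length(ensemble) >= 1L)
  ensemble <- Filter(Negate(is.null), ensemble)
  all_k <- sort(unique(c(original$k,
                         unlist(lapply(ensemble, `[[`, "k")))))
  cdf0 <- degree_cdf(original, all_k)
  ks <- vapply(ensemble, function(d)
    max(abs(degree_cdf(d, all_k) - cdf0)), 0)
  pmat <- vapply(ensemble, function(d) {
    p <- stats::setNames(rep(0, length(all_k)), all_k)
    p[as.character(d$k)] <- d$p
    p
  }, numeric(length(all_k)))
  pmat <- matrix(pmat, nrow = length(all_k))
  p0 <- stats::setNames(rep(0, length(all_k)), all_k)
  p0[as.character(original$k)] <- original$p
  list(ks = ks,
       overlay = data.frame(
         k = all_k, p_original = unname(p0),
         mean_p_collapsed = rowMeans(pmat),
         sd_p_collapsed = apply(pmat, 1L, stats::sd)))
}
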