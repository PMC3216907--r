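#' Create a reaction record
#'
#' A reaction record is one catalysed transformation restricted to its main
#' ("primary") reactants: currency metabolites are expected to have been
#' stripped by the reader that produced the record. Reactions catalysed by a
#' protein complex carry one entry in `enzymes` per complex member, so the
#' resulting network holds one parallel edge per member.
#'
#' @param reaction_id Character scalar, unique reaction identifier.
#' @param substrates Character vector of main substrate metabolite ids.
#' @param products Character vector of main product metabolite ids.
#' @param reversible Logical scalar; `TRUE` for a reversible reaction.
#' @param enzymes Character vector of catalysing protein ids (one per
#'   complex member).
#' @param pathways Character vector of pathway ids the reaction belongs to.
#' @param source Either `"YBP_DIALECT"` or `"KEGG_DIALECT"`.
#' @return An object of class `reaction_record`.
#' @examples
#' reaction_record("R1", "orotate", "orotidine-5'-phosphate",
#'                 enzymes = "URA5")
#' @export
reaction_record <- function(reaction_id, substrates, products,
                            reversible = FALSE, enzymes,
                            pathways = character(),
                            source = c("YBP_DIALECT", "KEGG_DIALECT")) {
  source <- match.arg(source)
  rec <- structure(
    list(reaction_id = as.character(reaction_id),
         substrates  = as.character(substrates),
         products    = as.character(products),
         reversible  = isTRUE(reversible),
         enzymes     = as.character(enzymes),
         pathways    = as.character(pathways),
         source      = source),
    class = "reaction_record")
  validate_reaction_record(rec)
  rec
}

validate_reaction_record <- function(rec) {
  if (length(rec$reaction_id) != 1L || !nzchar(rec$reaction_id))
    stop("reaction_id must be a single non-empty string", call. = FALSE)
  if (length(rec$substrates) == 0L || length(rec$products) == 0L)
    stop("reaction '", rec$reaction_id,
         "': substrates and products must be non-empty", call. = FALSE)
  if (any(!nzchar(c(rec$substrates, rec$products))))
    stop("reaction '", rec$reaction_id,
         "': empty metabolite id", call. = FALSE)
  if (length(rec$enzymes) == 0L || any(!nzchar(rec$enzymes)))
    stop("reaction '", rec$reaction_id,
         "': enzymes must be a non-empty set of ids", call. = FALSE)
  invisible(rec)
}

#' @export
print.reaction_record <- function(x, ...) {
  arrow <- if (x$reversible) " <=> " else " => "
  cat("<reaction_record> ", x$reaction_id, ": ",
      paste(x$substrates, collapse = " + "), arrow,
      paste(x$products, collapse = " + "),
      "  [", paste(x$enzymes, collapse = ","), "]\n", sep = "")
  invisible(x)
}

#' Build a metabolite-centric metabolic network
#'
#' Nodes are metabolites and every edge is one enzyme catalysing one
#' main substrate/product pair, so two isozymes of the same reaction give
#' two parallel edges. Reversible reactions contribute edges in both
#' directions; the reverse edge is flagged so that canonical enzyme
#' profiles (see [enzyme_metabolite_pairs()]) count each reaction once.
#'
#' @param reactions A list of [reaction_record()] objects.
#' @return An object of class `metabolic_network`: a list with an `edges`
#'   data frame (`from`, `to`, `enzyme`, `reaction`, `reverse`), the
#'   `nodes` character vector, and `pathways`, a named list mapping each
#'   enzyme id to the pathway ids of the reactions it catalyses.
#' @examples
#' net <- build_metabolic_network(list(
#'   reaction_record("R1", "A", "B", enzymes = c("E1", "E2")),
#'   reaction_record("R2", "B", "C", enzymes = "E3"),
#'   reaction_record("R3", "C", "D", reversible = TRUE, enzymes = "E4")))
#' net
#' @export
build_metabolic_network <- function(reactions) {
  if (length(reactions) == 0L)
    return(new_metabolic_network(empty_edges(), character(), list()))
  from <- to <- enzyme <- reaction <- list()
  rev_flag <- list()
  pathways <- list()
  i <- 0L
  for (rec in reactions) {
    validate_reaction_record(rec)
    pairs <- expand.grid(s = rec$substrates, p = rec$products,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    pairs <- unique(pairs)
    if (any(pairs$s == pairs$p))
      stop("reaction '", rec$reaction_id, "': metabolite '",
           pairs$s[pairs$s == pairs$p][1L],
           "' appears as both substrate and product of the same pair",
           call. = FALSE)
    for (enz in rec$enzymes) {
      i <- i + 1L
      from[[i]] <- pairs$s; to[[i]] <- pairs$p
      enzyme[[i]] <- rep(enz, nrow(pairs))
      reaction[[i]] <- rep(rec$reaction_id, nrow(pairs))
      rev_flag[[i]] <- rep(FALSE, nrow(pairs))
      if (rec$reversible) {
        i <- i + 1L
        from[[i]] <- pairs$p; to[[i]] <- pairs$s
        enzyme[[i]] <- rep(enz, nrow(pairs))
        reaction[[i]] <- rep(rec$reaction_id, nrow(pairs))
        rev_flag[[i]] <- rep(TRUE, nrow(pairs))
      }
      pathways[[enz]] <- union(pathways[[enz]], rec$pathways)
    }
  }
  edges <- data.frame(from = unlist(from), to = unlist(to),
                      enzyme = unlist(enzyme), reaction = unlist(reaction),
                      reverse = unlist(rev_flag), stringsAsFactors = FALSE)
  key <- paste(edges$from, edges$to, edges$enzyme, edges$reaction, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)),
            " duplicate (from,to,enzyme,reaction) edge(s) collapsed",
            call. = FALSE)
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  rownames(edges) <- NULL
  new_metabolic_network(edges, sort(unique(c(edges$from, edges$to))),
                        pathways)
}

new_metabolic_network <- function(edges, nodes, pathways) {
  structure(list(edges = edges, nodes = nodes, pathways = pathways),
            class = "metabolic_network")
}

empty_edges <- function() {
  data.frame(from = character(), to = character(), enzyme = character(),
             reaction = character(), reverse = logical(),
             stringsAsFactors = FALSE)
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("<metabolic_network> ", length(x$nodes), " metabolites, ",
      nrow(x$edges), " edges, ",
      length(network_enzymes(x)), " enzymes\n", sep = "")
  invisible(x)
}

#' Enzymes labelling at least one edge of a network
#'
#' @param network A `metabolic_network`.
#' @return Sorted character vector of enzyme ids.
#' @export
network_enzymes <- function(network) {
  stopifnot(inherits(network, "metabolic_network"))
  sort(unique(network$edges$enzyme))
}

#' Canonical metabolite pairs processed by one enzyme
#'
#' The functional profile of an enzyme is the set of (substrate, product)
#' metabolite pairs it connects, with each reaction counted once
#' regardless of reversibility: a reversible A <=> B is listed as the
#' pair (A, B) in the source direction, never additionally as (B, A).
#' Two genuinely distinct irreversible reactions A -> B and B -> A do,
#' however, yield two pairs.
#'
#' @param network A `metabolic_network`.
#' @param enzyme_id Enzyme identifier.
#' @return A data frame with columns `from` and `to`, one row per
#'   canonical metabolite pair.
#' @seealso [dice_m()] which compares two such profiles.
#' @export
enzyme_metabolite_pairs <- function(network, enzyme_id) {
  stopifnot(inherits(network, "metabolic_network"),
            length(enzyme_id) == 1L)
  if (!enzyme_id %in% network$edges$enzyme)
    stop("enzyme '", enzyme_id, "' absent from network", call. = FALSE)
  e <- network$edges
  e <- e[e$enzyme == enzyme_id & !e$reverse, c("from", "to")]
  e <- unique(e)
  rownames(e) <- NULL
  e
}

met_pair_keys <- function(pairs) paste(pairs$from, pairs$to, sep = "\r")

#' Metabolites incident to an enzyme's edges
#'
#' @param network A `metabolic_network`.
#' @param enzyme_id Enzyme identifier.
#' @return Character vector of metabolite ids touched by the enzyme.
#' @export
enzyme_metabolites <- function(network, enzyme_id) {
  p <- enzyme_metabolite_pairs(network, enzyme_id)
  sort(unique(c(p$from, p$to)))
}

#' Degree distribution of the metabolites
#'
#' The degree of a metabolite is its number of incident edges (in plus
#' out), counting parallel edges by default: two isozymes catalysing the
#' same transformation each contribute one edge, hence 2 to each
#' endpoint's degree. Set `count_parallel = FALSE` to count distinct
#' neighbouring metabolites instead.
#'
#' @param network A non-empty `metabolic_network`.
#' @param count_parallel Logical; count parallel edges separately
#'   (default) or collapse them to distinct adjacencies.
#' @return An object of class `degree_distribution`: a data frame with
#'   columns `k` (degree), `count` (number of metabolites) and `p`
#'   (fraction of metabolites, summing to 1).
#' @export
degree_distribution <- function(network, count_parallel = TRUE) {
  stopifnot(inherits(network, "metabolic_network"))
  if (length(network$nodes) == 0L)
    stop("degree distribution of an empty network is undefined",
         call. = FALSE)
  e <- network$edges
  if (!count_parallel) {
    und <- unique(data.frame(a = pmin(e$from, e$to), b = pmax(e$from, e$to),
                             stringsAsFactors = FALSE))
    ends <- c(und$a, und$b)
  } else {
    ends <- c(e$from, e$to)
  }
  deg <- table(factor(ends, levels = network$nodes))
  tab <- table(as.integer(deg))
  out <- data.frame(k = as.integer(names(tab)),
                    count = as.integer(tab))
  out$p <- out$count / sum(out$count)
  structure(out, class = c("degree_distribution", "data.frame"))
}

#' Convert a metabolic network to an igraph graph
#'
#' @param network A `metabolic_network`.
#' @param directed Keep edge directions (`TRUE`) or take the undirected
#'   simple view used for path lengths (`FALSE`, collapses parallel and
#'   reverse edges).
#' @return An [igraph::graph] object with a `name` vertex attribute.
#' @export
as_igraph <- function(network, directed = TRUE) {
  stopifnot(inherits(network, "metabolic_network"))
  g <- igraph::graph_from_data_frame(
    network$edges[, c("from", "to", "enzyme", "reaction")],
    directed = directed,
    vertices = data.frame(name = network$nodes, stringsAsFactors = FALSE))
  if (!directed)
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  g
}

#' Shortest path length between two metabolites
#'
#' Breadth-first distance on the underlying undirected simple graph
#' (parallel edges count once); `directed = TRUE` switches to directed
#' reachability. Unreachable pairs return `Inf`.
#'
#' @param network A `metabolic_network`.
#' @param m1,m2 Metabolite ids; both must be nodes of the network.
#' @param directed Logical, default `FALSE` (undirected view).
#' @return Non-negative integer path length, 0 when `m1 == m2`, or `Inf`
#'   when no path exists.
#' @export
shortest_path_length <- function(network, m1, m2, directed = FALSE) {
  stopifnot(inherits(network, "metabolic_network"))
  miss <- setdiff(c(m1, m2), network$nodes)
  if (length(miss))
    stop("metabolite(s) absent from network: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (m1 == m2) return(0)
  g <- as_igraph(network, directed = directed)
  d <- igraph::distances(g, v = m1, to = m2,
                         mode = if (directed) "out" else "all")
  as.numeric(d[1L, 1L])
}

#' Matrix of shortest path lengths between two metabolite sets
#'
#' Computes all pairwise distances in one breadth-first sweep; used by
#' [pair_metabolite_distance()].
#'
#' @inheritParams shortest_path_length
#' @param from,to Character vectors of metabolite ids.
#' @return Numeric matrix of distances (`Inf` when unreachable).
#' @keywords internal
shortest_path_matrix <- function(network, from, to, directed = FALSE) {
  miss <- setdiff(c(from, to), network$nodes)
  if (length(miss))
    stop("metabolite(s) absent from network: ",
         paste(miss, collapse = ", "), call. = FALSE)
  g <- as_igraph(network, directed = directed)
  igraph::distances(g, v = from, to = to,
                    mode = if (directed) "out" else "all")
}
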