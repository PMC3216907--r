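AA_ALPHABET_20X <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                     "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")

#' Alignment parameters for paralogy detection
#'
#' Defaults follow the usual global-alignment protein settings: BLOSUM62
#' scoring with gap open 10 and gap extend 0.5. A gap of length L costs
#' `gap_open + L * gap_extend`; end gaps are penalized. Identity is
#' always the number of matches over the alignment length (the global
#' alignment report convention).
#'
#' @param matrix Substitution matrix name (any matrix shipped by
#'   Biostrings, e.g. `"BLOSUM62"`, `"BLOSUM50"`, `"PAM250"`) or a
#'   numeric matrix with amino-acid dimnames.
#' @param gap_open Non-negative gap opening penalty.
#' @param gap_extend Non-negative per-residue gap extension penalty.
#' @return A list of class `alignment_params`.
#' @export
alignment_params <- function(matrix = "BLOSUM62", gap_open = 10,
                             gap_extend = 0.5) {
  stopifnot(gap_open >= 0, gap_extend >= 0)
  if (is.character(matrix)) {
    name <- matrix
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    matrix <- get(name, envir = e)
  } else {
    name <- "custom"
  }
  alpha <- intersect(AA_ALPHABET_20X, rownames(matrix))
  matrix <- matrix[alpha, alpha, drop = FALSE]
  structure(list(matrix_name = name, matrix = matrix, alphabet = alpha,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "alignment_params")
}

#' Global percent identity between two protein sequences
#'
#' Needleman-Wunsch global alignment with affine gaps, deterministic
#' traceback (diagonal preferred over a gap in the second sequence,
#' preferred over a gap in the first). Identity is
#' `100 * matches / alignment_length`; similarity additionally counts
#' substitutions with a positive substitution score.
#'
#' @param seq1,seq2 Non-empty amino-acid strings (20 residues plus X).
#' @param params An [alignment_params()] object.
#' @return A list with `identity`, `similarity` (both percentages in
#'   \[0, 100\]), `score`, `matches`, `alignment_length` and the two
#'   aligned strings.
#' @examples
#' global_percent_identity("MKVLA", "MKVLA")$identity  # 100
#' @export
global_percent_identity <- function(seq1, seq2,
                                    params = alignment_params()) {
  stopifnot(inherits(params, "alignment_params"),
            is.character(seq1), is.character(seq2),
            length(seq1) == 1L, length(seq2) == 1L)
  if (!nzchar(seq1) || !nzchar(seq2))
    stop("sequences must be non-empty", call. = FALSE)
  .nw_align_cpp(toupper(seq1), toupper(seq2), params$matrix,
                params$alphabet, params$gap_open, params$gap_extend)
}

#' All-pairs percent identity matrix
#'
#' @param proteome Named character vector of sequences.
#' @param params An [alignment_params()] object.
#' @param kmer_prefilter If `TRUE`, pairs sharing no 4-mer are assigned
#'   identity 0 without alignment (a speed heuristic; exact alignment of
#'   every pair is the default).
#' @return Symmetric numeric matrix of percent identities.
#' @export
pairwise_identity <- function(proteome, params = alignment_params(),
                              kmer_prefilter = FALSE) {
  stopifnot(length(proteome) >= 1L, !is.null(names(proteome)))
  m <- .pairwise_identity_cpp(unname(toupper(proteome)), params$matrix,
                              params$alphabet, params$gap_open,
                              params$gap_extend, isTRUE(kmer_prefilter))
  dimnames(m) <- list(names(proteome), names(proteome))
  m
}

#' Detect paralogous families from a proteome
#'
#' All protein pairs are globally aligned; pairs with identity strictly
#' greater than `threshold` are connected in an undirected paralogy
#' graph and its connected components define the families (singletons
#' are retained as size-1 families). Sequences shorter than 30 residues
#' are aligned like any other but listed in the `short_sequences`
#' attribute, since percent identity saturates for very short proteins.
#'
#' @param proteome Named character vector of at least 2 sequences.
#' @param threshold Percent identity threshold; an edge requires
#'   identity > `threshold` (default 30).
#' @param params An [alignment_params()] object.
#' @param kmer_prefilter Passed to [pairwise_identity()].
#' @return A `family_set` with an `identity` attribute (the pairwise
#'   identity matrix) and a `short_sequences` attribute.
#' @export
build_paralogy_families <- function(proteome, threshold = 30,
                                    params = alignment_params(),
                                    kmer_prefilter = FALSE) {
  stopifnot(length(proteome) >= 2L)
  idm <- pairwise_identity(proteome, params, kmer_prefilter)
  adj <- idm > threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  fam <- split(names(comp$membership), comp$membership)
  fam <- lapply(fam, sort)
  names(fam) <- paste0("F", seq_along(fam))
  fs <- new_family_set(fam)
  attr(fs, "identity") <- idm
  attr(fs, "short_sequences") <- names(proteome)[nchar(proteome) < 30L]
  fs
}

#' Merge two family sets
#'
#' Unions the implied paralogy edges (every within-family pair of each
#' input) and re-derives connected components, so merging is symmetric
#' and idempotent. Pair ages are combined; on conflict the first set
#' wins with a warning.
#'
#' @param a,b `family_set` objects.
#' @return A merged `family_set`.
#' @export
merge_family_sets <- function(a, b) {
  stopifnot(inherits(a, "family_set"), inherits(b, "family_set"))
  edges_of <- function(fs) {
    do.call(rbind, c(list(data.frame(g1 = character(), g2 = character())),
      lapply(fs$families, function(m) {
        if (length(m) < 2L) return(NULL)
        idx <- utils::combn(m, 2L)
        data.frame(g1 = idx[1L, ], g2 = idx[2L, ])
      })))
  }
  singletons <- unlist(c(a$families[lengths(a$families) == 1L],
                         b$families[lengths(b$families) == 1L]),
                       use.names = FALSE)
  ed <- rbind(edges_of(a), edges_of(b))
  g <- igraph::graph_from_data_frame(ed, directed = FALSE,
    vertices = data.frame(name = unique(c(ed$g1, ed$g2, singletons))))
  comp <- igraph::components(g)
  fam <- lapply(split(names(comp$membership), comp$membership), sort)
  names(fam) <- paste0("F", seq_along(fam))
  ages <- a$pair_ages
  dup <- intersect(names(b$pair_ages), names(ages))
  conflicts <- dup[b$pair_ages[dup] != ages[dup]]
  if (length(conflicts))
    warning(length(conflicts), " conflicting pair age(s); keeping the ",
            "first set's labels", call. = FALSE)
  ages[setdiff(names(b$pair_ages), names(ages))] <-
    b$pair_ages[setdiff(names(b$pair_ages), names(ages))]
  new_family_set(fam, ages)
}

#' Enumerate within-family paralog pairs present in a network
#'
#' All unordered within-family pairs are classified by how many members
#' label at least one network edge: pairs with both members present are
#' the analysable paralog pairs; pairs with exactly one member present
#' are reported with `in_network = FALSE` (their overlap is undefined,
#' the "N/A" case); pairs with neither member present are dropped.
#'
#' @param families A `family_set`.
#' @param network A `metabolic_network`.
#' @return Data frame with columns `gene1`, `gene2` (sorted within
#'   pair), `family`, `n_in_network`, `in_network`.
#' @export
enumerate_network_pairs <- function(families, network) {
  stopifnot(inherits(families, "family_set"),
            inherits(network, "metabolic_network"))
  enz <- network_enzymes(network)
  out <- lapply(names(families$families), function(fid) {
    m <- sort(families$families[[fid]])
    if (length(m) < 2L) return(NULL)
    idx <- utils::combn(m, 2L)
    n_in <- matrix(idx %in% enz, nrow = 2L)
    n_in <- colSums(n_in)
    keep <- n_in >= 1L
    if (!any(keep)) return(NULL)
    data.frame(gene1 = idx[1L, keep], gene2 = idx[2L, keep],
               family = fid, n_in_network = n_in[keep],
               in_network = n_in[keep] == 2L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(list(data.frame(
    gene1 = character(), gene2 = character(), family = character(),
    n_in_network = integer(), in_network = logical())), out))
  rownames(out) <- NULL
  out
}

#' Annotate paralog pairs with duplication-age groups
#'
#' @param pairs Data frame with `gene1`/`gene2` columns (e.g. from
#'   [enumerate_network_pairs()]).
#' @param ages Named character vector of age labels keyed by the sorted
#'   pair (as in `family_set$pair_ages`), or a `family_set`.
#' @return `pairs` with an `age` column; pairs absent from the map get
#'   `"UNKNOWN"`.
#' @export
assign_age_group <- function(pairs, ages) {
  if (inherits(ages, "family_set")) ages <- ages$pair_ages
  key <- pair_key(pairs$gene1, pairs$gene2)
  a <- unname(ages[key])
  a[is.na(a)] <- "UNKNOWN"
  pairs$age <- a
  pairs
}
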