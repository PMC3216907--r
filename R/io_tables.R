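#' Read a proteome from a FASTA file
#'
#' @param path Path to an amino-acid FASTA file. The id of each record
#'   is the first whitespace-delimited token of its header.
#' @return Named character vector of upper-cased sequences.
#' @export
read_fasta_proteome <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  seqs <- toupper(as.character(aa))
  if (any(!nzchar(seqs)))
    stop("empty sequence for id(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "), call. = FALSE)
  stats::setNames(seqs, ids)
}

#' Permitted duplication-age labels
#'
#' Four duplication-age classes, from the most ancient (duplications
#' predating the Euascomycete-Hemiascomycete divergence) to duplicates
#' younger than the whole-genome duplication, plus `UNKNOWN`.
#' @return Character vector of labels.
#' @export
age_groups <- function() {
  c("PRE_WGD_EUASCOMYCETES", "PRE_WGD_HEMIASCOMYCETES",
    "WGD", "POST_WGD", "UNKNOWN")
}

new_family_set <- function(families, pair_ages = character()) {
  if (length(families)) {
    members <- unlist(families, use.names = FALSE)
    if (anyDuplicated(members))
      stop("families must be disjoint; duplicated member(s): ",
           paste(unique(members[duplicated(members)]), collapse = ", "),
           call. = FALSE)
  }
  structure(list(families = families, pair_ages = pair_ages),
            class = "family_set")
}

#' @export
print.family_set <- function(x, ...) {
  sizes <- lengths(x$families)
  cat("<family_set> ", length(x$families), " families, ",
      sum(sizes), " proteins (", sum(sizes > 1L), " multi-member), ",
      length(x$pair_ages), " aged pair(s)\n", sep = "")
  invisible(x)
}

pair_key <- function(g1, g2) {
  paste(pmin(g1, g2), pmax(g1, g2), sep = "\r")
}

#' Read a paralogous-family table
#'
#' Two dialects are supported. `PAIR_LIST` rows are
#' `geneA<TAB>geneB[<TAB>age]` (Ensembl-compara-style pair lists); the
#' pairs are closed into families by connected components and ages are
#' stored per pair. `GROUP_LIST` rows are
#' `family_id<TAB>member1,member2,...[<TAB>age]` (Wapinski-style
#' ortholog groups); a family-level age propagates to every
#' within-family pair. Lines starting with `#` are ignored.
#'
#' @param path Path to the TSV file.
#' @param dialect `"PAIR_LIST"` or `"GROUP_LIST"`.
#' @return A `family_set`: list with `families` (named list of member
#'   id vectors) and `pair_ages` (named character vector keyed by the
#'   sorted gene pair).
#' @export
read_family_table <- function(path, dialect = c("PAIR_LIST", "GROUP_LIST")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) return(new_family_set(list()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  check_age <- function(a) {
    bad <- setdiff(a, age_groups())
    if (length(bad))
      stop("unknown age label(s) ", paste(unique(bad), collapse = ", "),
           "; permitted: ", paste(age_groups(), collapse = ", "),
           call. = FALSE)
  }
  pair_ages <- character()
  if (dialect == "PAIR_LIST") {
    g1 <- vapply(fields, `[[`, "", 1L)
    g2 <- vapply(fields, `[[`, "", 2L)
    age <- vapply(fields, function(f) if (length(f) >= 3L) f[[3L]] else NA_character_, "")
    check_age(age[!is.na(age)])
    pair_ages <- stats::setNames(age[!is.na(age)],
                                 pair_key(g1, g2)[!is.na(age)])
    g <- igraph::graph_from_data_frame(data.frame(g1, g2), directed = FALSE)
    comp <- igraph::components(g)
    fam <- split(names(comp$membership), comp$membership)
  } else {
    ids <- vapply(fields, `[[`, "", 1L)
    fam <- lapply(fields, function(f)
      trimws(strsplit(f[[2L]], ",", fixed = TRUE)[[1L]]))
    age <- vapply(fields, function(f) if (length(f) >= 3L) f[[3L]] else NA_character_, "")
    check_age(age[!is.na(age)])
    names(fam) <- ids
    for (i in which(!is.na(age))) {
      mem <- fam[[i]]
      if (length(mem) >= 2L) {
        idx <- utils::combn(sort(mem), 2L)
        keys <- pair_key(idx[1L, ], idx[2L, ])
        pair_ages[keys] <- age[[i]]
      }
    }
  }
  fam <- lapply(fam, function(m) sort(unique(m)))
  names(fam) <- paste0("F", seq_along(fam))
  new_family_set(fam, pair_ages)
}

#' Write a family set in the GROUP_LIST dialect
#'
#' @param families A `family_set`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_family_table <- function(families, path) {
  stopifnot(inherits(families, "family_set"))
  rows <- vapply(names(families$families), function(fid) {
    mem <- families$families[[fid]]
    age <- ""
    if (length(mem) >= 2L) {
      keys <- pair_key(mem[[1L]], mem[[2L]])
      if (keys %in% names(families$pair_ages))
        age <- families$pair_ages[[keys]]
    }
    paste(c(fid, paste(mem, collapse = ","),
            if (nzchar(age)) age), collapse = "\t")
  }, "")
  writeLines(rows, path)
  invisible(path)
}

#' Read a gene-by-experiment expression matrix
#'
#' Expects a TSV with experiment ids in the first row, gene ids in the
#' first column, and log2 expression values in the cells; empty cells
#' are missing values.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix (genes in rows, experiments in columns) with
#'   `NA` for missing entries.
#' @export
read_expression_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) stop("empty expression file", call. = FALSE)
  # strsplit drops trailing empty fields; pad to the true tab count so
  # rows ending in missing cells keep their width
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ntab <- vapply(gregexpr("\t", lines, fixed = TRUE), function(g)
    if (g[[1L]] == -1L) 0L else length(g), 0L)
  fields <- Map(function(v, k) c(v, rep("", k + 1L - length(v))),
                fields, ntab)
  n <- vapply(fields[-1L], length, 0L)
  want <- n[[1L]]
  if (any(n != want))
    stop("ragged expression table: row ", which(n != want)[1L] + 1L,
         " has ", n[n != want][1L], " fields, expected ", want,
         call. = FALSE)
  # the header may or may not carry a corner cell above the gene column
  header <- fields[[1L]]
  experiments <- if (length(header) == want) header[-1L]
                 else if (length(header) == want - 1L) header
                 else stop("header has ", length(header),
                           " fields, expected ", want, " or ", want - 1L,
                           call. = FALSE)
  genes <- vapply(fields[-1L], `[[`, "", 1L)
  if (anyDuplicated(genes) || anyDuplicated(experiments))
    stop("duplicate gene or experiment id", call. = FALSE)
  vals <- vapply(fields[-1L], function(f) {
    v <- f[-1L]
    v[!nzchar(v)] <- NA_character_
    as.numeric(v)
  }, numeric(length(experiments)))
  m <- t(matrix(vals, nrow = length(experiments),
                dimnames = list(experiments, genes)))
  m
}

#' Write an expression matrix as TSV (empty cells for missing values)
#'
#' @param m Numeric matrix, genes in rows.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  header <- paste(c("gene", colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i) {
    v <- format_num(m[i, ])
    v[is.na(m[i, ])] <- ""
    paste(c(rownames(m)[i], v), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

format_num <- function(x) formatC(x, format = "g", digits = 10)

#' Export a network as a tab-separated edge list
#'
#' Columns: `from`, `to`, `enzyme`, `reaction`, `reversible` (0/1).
#' Reverse edges of reversible reactions are not written; they are
#' recreated on re-import, so a write/read round trip reproduces the
#' network exactly.
#'
#' @param network A `metabolic_network`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "metabolic_network"))
  e <- network$edges
  rev_rxn <- unique(e$reaction[e$reverse])
  e <- e[!e$reverse, , drop = FALSE]
  rows <- paste(e$from, e$to, e$enzyme, e$reaction,
                as.integer(e$reaction %in% rev_rxn), sep = "\t")
  writeLines(c("from\tto\tenzyme\treaction\treversible", rows), path)
  invisible(path)
}

#' Read a network from a tab-separated edge list
#'
#' @param path Path written by [write_edge_list()].
#' @return A `metabolic_network` (pathway annotations are not part of
#'   the edge-list format and come back empty).
#' @export
read_edge_list <- function(path) {
  tab <- utils::read.delim(path, colClasses = c(rep("character", 4L),
                                                "integer"))
  recs <- lapply(seq_len(nrow(tab)), function(i)
    reaction_record(paste0(tab$reaction[i], "@", tab$enzyme[i], "@", i),
                    tab$from[i], tab$to[i],
                    reversible = tab$reversible[i] == 1L,
                    enzymes = tab$enzyme[i]))
  net <- build_metabolic_network(recs)
  net$edges$reaction <- sub("@.*$", "", net$edges$reaction)
  net$edges <- unique(net$edges)
  rownames(net$edges) <- NULL
  net
}

#' Export a network as GraphML for external viewers
#'
#' @param network A `metabolic_network`.
#' @param path Output `.graphml` path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network, directed = TRUE), path,
                      format = "graphml")
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
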