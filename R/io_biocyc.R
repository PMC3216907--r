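#' Parse a BioCyc-style pathway bundle into reaction records
#'
#' Reads the three flat files of a BioCyc/MetaCyc-style pathway database
#' export: the reaction file (`pathways.dat`-like), the enzyme-reaction
#' file (`enzrxns.dat`-like) and the protein-complex table
#' (`protcplxs.col`-like). Only a minimal attribute-record grammar is
#' supported: `KEY - VALUE` lines, records terminated by `//`,
#' continuation lines starting with `^`. Recognised reaction keys are
#' `UNIQUE-ID`, `LEFT`, `RIGHT` (each optionally followed by a
#' `^PRIMARY - T` continuation marking a main reactant),
#' `REACTION-DIRECTION` (`LEFT-TO-RIGHT`, `RIGHT-TO-LEFT` or
#' `REVERSIBLE`) and `IN-PATHWAY`; unknown keys are ignored.
#'
#' Only reactants marked primary are kept, so currency metabolites never
#' enter the network. Catalysts are resolved through the enzyme-reaction
#' file and expanded to complex members using the complex table; a
#' complex id with no member entry is kept as the enzyme id itself and
#' flagged in the skip log. Reactions left with no primary substrate or
#' no primary product are skipped with a warning.
#'
#' @param pathways_file Path to the reaction flat file.
#' @param enzrxns_file Path to the enzyme-reaction flat file.
#' @param complexes_file Path to the tab-separated complex table
#'   (`complex_id<TAB>name<TAB>member1,member2,...`), or `NULL`.
#' @return A list of [reaction_record()] objects with a `skipped`
#'   attribute (named integer vector of skip reasons).
#' @export
parse_biocyc_bundle <- function(pathways_file, enzrxns_file,
                                complexes_file = NULL) {
  complexes <- if (is.null(complexes_file)) list() else
    read_complex_table(complexes_file)
  enz_map <- parse_enzrxns(enzrxns_file)      # reaction id -> catalyst ids
  recs <- parse_attr_records(readLines(pathways_file, warn = FALSE))
  out <- list()
  skipped <- c(no_primary_substrate = 0L, no_primary_product = 0L,
               no_id = 0L, no_catalyst = 0L, degenerate_pair = 0L)
  flagged_complexes <- character()
  for (r in recs) {
    id <- r$single[["UNIQUE-ID"]]
    if (is.null(id) || !nzchar(id)) {
      skipped[["no_id"]] <- skipped[["no_id"]] + 1L
      next
    }
    left  <- primary_values(r, "LEFT")
    right <- primary_values(r, "RIGHT")
    if (length(left) == 0L) {
      skipped[["no_primary_substrate"]] <- skipped[["no_primary_substrate"]] + 1L
      next
    }
    if (length(right) == 0L) {
      skipped[["no_primary_product"]] <- skipped[["no_primary_product"]] + 1L
      next
    }
    if (length(intersect(left, right))) {
      skipped[["degenerate_pair"]] <- skipped[["degenerate_pair"]] + 1L
      next
    }
    dir <- r$single[["REACTION-DIRECTION"]]
    if (is.null(dir)) dir <- "LEFT-TO-RIGHT"
    if (identical(dir, "RIGHT-TO-LEFT")) {
      tmp <- left; left <- right; right <- tmp
      dir <- "LEFT-TO-RIGHT"
    }
    catalysts <- enz_map[[id]]
    if (is.null(catalysts)) {
      skipped[["no_catalyst"]] <- skipped[["no_catalyst"]] + 1L
      next
    }
    enzymes <- character()
    for (cat_id in catalysts) {
      if (!is.null(complexes[[cat_id]])) {
        enzymes <- c(enzymes, complexes[[cat_id]])
      } else {
        if (grepl("^CPLX", cat_id)) flagged_complexes <-
            union(flagged_complexes, cat_id)
        enzymes <- c(enzymes, cat_id)
      }
    }
    out[[length(out) + 1L]] <- reaction_record(
      reaction_id = id, substrates = left, products = right,
      reversible = identical(dir, "REVERSIBLE"),
      enzymes = unique(enzymes),
      pathways = r$multi[["IN-PATHWAY"]] %||% character(),
      source = "YBP_DIALECT")
  }
  if (sum(skipped) > 0L)
    warning("skipped ", sum(skipped), " reaction record(s): ",
            paste(names(skipped)[skipped > 0L], skipped[skipped > 0L],
                  sep = "=", collapse = ", "), call. = FALSE)
  attr(out, "skipped") <- skipped
  attr(out, "unresolved_complexes") <- flagged_complexes
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Split an attribute-record flat file into records. Each record is a list
# with `single` (last value per key), `multi` (all values per key) and
# `entries` (ordered key/value/continuations, needed for ^PRIMARY).
parse_attr_records <- function(lines) {
  lines <- lines[!grepl("^#", lines)]
  recs <- list()
  cur <- list()
  flush <- function(cur) {
    if (length(cur) == 0L) return(NULL)
    keys <- vapply(cur, `[[`, "", "key")
    vals <- vapply(cur, `[[`, "", "value")
    list(single = as.list(stats::setNames(vals, keys))[!duplicated(keys)],
         multi = split(vals, keys),
         entries = cur)
  }
  for (ln in lines) {
    if (grepl("^//\\s*$", ln)) {
      r <- flush(cur)
      if (!is.null(r)) recs[[length(recs) + 1L]] <- r
      cur <- list()
      next
    }
    if (!nzchar(trimws(ln))) next
    if (startsWith(ln, "^")) {
      if (length(cur) == 0L) next   # stray continuation: ignore
      m <- regmatches(ln, regexec("^\\^([A-Z-]+) - (.*)$", ln))[[1L]]
      if (length(m) == 3L)
        cur[[length(cur)]]$continuations[[m[[2L]]]] <- trimws(m[[3L]])
      next
    }
    m <- regmatches(ln, regexec("^([A-Z0-9-]+) - (.*)$", ln))[[1L]]
    if (length(m) != 3L) next       # malformed line: ignore
    cur[[length(cur) + 1L]] <- list(key = m[[2L]], value = trimws(m[[3L]]),
                                    continuations = list())
  }
  r <- flush(cur)
  if (!is.null(r)) recs[[length(recs) + 1L]] <- r
  recs
}

primary_values <- function(rec, key) {
  vals <- character()
  for (e in rec$entries) {
    if (e$key == key && identical(e$continuations[["PRIMARY"]], "T"))
      vals <- c(vals, e$value)
  }
  unique(vals)
}

# enzrxns.dat-like: UNIQUE-ID / ENZYME / REACTION records.
parse_enzrxns <- function(path) {
  recs <- parse_attr_records(readLines(path, warn = FALSE))
  map <- list()
  for (r in recs) {
    rxn <- r$single[["REACTION"]]
    enz <- r$single[["ENZYME"]]
    if (is.null(rxn) || is.null(enz)) next
    map[[rxn]] <- union(map[[rxn]], enz)
  }
  map
}

# protcplxs.col-like: complex_id <TAB> name <TAB> comma-separated members.
read_complex_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  map <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) next
    members <- trimws(strsplit(f[[3L]], ",", fixed = TRUE)[[1L]])
    map[[trimws(f[[1L]])]] <- members[nzchar(members)]
  }
  map
}
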