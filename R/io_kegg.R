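#' Parse a KEGG-style reaction bundle into reaction records
#'
#' Reads a KEGG LIGAND-style reaction list plus one or more KGML pathway
#' files. The reaction list uses `ENTRY`, `EQUATION` and `RPAIR` lines
#' with records terminated by `///`; reversibility comes from the
#' equation arrow (`<=>` reversible, `=>` irreversible) and is
#' overridden by a KGML `type` attribute when present. Only reactant
#' pairs classified `main` are kept, one [reaction_record()] per
#' (reaction, main pair): the `trans`/`cofac`-class pairs carry the
#' currency metabolites and are discarded. Enzyme-reaction associations
#' and pathway membership come from the KGML files: every `gene` entry
#' with a `reaction` attribute maps its gene ids (organism prefixes such
#' as `sce:` are stripped; a multi-gene entry is treated as a complex,
#' one record entry per member) to that reaction.
#'
#' @param reaction_file Path to the reaction list.
#' @param kgml_files Character vector of KGML (XML) pathway file paths.
#' @return A list of [reaction_record()] objects with a `skipped`
#'   attribute counting dropped reactions by reason.
#' @export
parse_kegg_bundle <- function(reaction_file, kgml_files) {
  kg <- parse_kgml(kgml_files)
  lines <- readLines(reaction_file, warn = FALSE)
  out <- list()
  skipped <- c(no_main_pair = 0L, no_gene = 0L, degenerate_pair = 0L)
  cur <- list(rpairs = list())
  flush <- function(cur) {
    if (is.null(cur$id)) return(NULL)
    cur
  }
  reactions <- list()
  for (ln in c(lines, "///")) {
    if (grepl("^///", ln)) {
      r <- flush(cur)
      if (!is.null(r)) reactions[[length(reactions) + 1L]] <- r
      cur <- list(rpairs = list())
      next
    }
    m <- regmatches(ln, regexec("^([A-Z]+)\\s+(.*)$", ln))[[1L]]
    if (length(m) != 3L) next
    key <- m[[2L]]; val <- trimws(m[[3L]])
    if (key == "ENTRY") {
      cur$id <- strsplit(val, "\\s+")[[1L]][[1L]]
    } else if (key == "EQUATION") {
      cur$reversible <- grepl("<=>", val, fixed = TRUE)
    } else if (key == "RPAIR") {
      f <- strsplit(val, "\\s+")[[1L]]
      if (length(f) >= 3L) {
        cpds <- strsplit(f[[2L]], "_", fixed = TRUE)[[1L]]
        if (length(cpds) == 2L)
          cur$rpairs[[length(cur$rpairs) + 1L]] <-
            list(from = cpds[[1L]], to = cpds[[2L]], class = f[[3L]])
      }
    }
  }
  seen <- character()
  for (r in reactions) {
    seen <- c(seen, r$id)
    main <- Filter(function(p) identical(p$class, "main"), r$rpairs)
    if (length(main) == 0L) {
      skipped[["no_main_pair"]] <- skipped[["no_main_pair"]] + 1L
      next
    }
    genes <- kg$genes[[r$id]]
    if (is.null(genes)) {
      skipped[["no_gene"]] <- skipped[["no_gene"]] + 1L
      next
    }
    reversible <- isTRUE(r$reversible)
    if (!is.null(kg$reversible[[r$id]])) reversible <- kg$reversible[[r$id]]
    k <- 0L
    for (p in main) {
      if (p$from == p$to) {
        skipped[["degenerate_pair"]] <- skipped[["degenerate_pair"]] + 1L
        next
      }
      k <- k + 1L
      out[[length(out) + 1L]] <- reaction_record(
        reaction_id = if (length(main) > 1L) paste0(r$id, "_", k) else r$id,
        substrates = p$from, products = p$to,
        reversible = reversible, enzymes = genes,
        pathways = kg$pathway_of[[r$id]] %||% character(),
        source = "KEGG_DIALECT")
    }
  }
  orphans <- setdiff(names(kg$genes), seen)
  if (length(orphans))
    warning(length(orphans), " reaction(s) present in KGML but absent ",
            "from the reaction list: ",
            paste(utils::head(orphans, 5L), collapse = ", "), call. = FALSE)
  if (sum(skipped) > 0L)
    warning("dropped ", sum(skipped), " reaction record(s): ",
            paste(names(skipped)[skipped > 0L], skipped[skipped > 0L],
                  sep = "=", collapse = ", "), call. = FALSE)
  attr(out, "skipped") <- skipped
  out
}

# Read KGML files: reaction -> gene ids, reaction -> pathway ids,
# reaction -> reversibility override.
parse_kgml <- function(kgml_files) {
  genes <- list(); pathway_of <- list(); reversible <- list()
  for (path in kgml_files) {
    doc <- xml2::read_xml(path)
    pw <- sub("^path:", "", xml2::xml_attr(doc, "name"))
    for (entry in xml2::xml_find_all(doc, ".//entry[@type='gene']")) {
      rxn <- xml2::xml_attr(entry, "reaction")
      if (is.na(rxn)) next
      ids <- strsplit(xml2::xml_attr(entry, "name"), "\\s+")[[1L]]
      ids <- sub("^[a-z]+:", "", ids)
      for (rx in sub("^rn:", "", strsplit(rxn, "\\s+")[[1L]])) {
        genes[[rx]] <- union(genes[[rx]], ids)
        pathway_of[[rx]] <- union(pathway_of[[rx]], pw)
      }
    }
    for (rxn in xml2::xml_find_all(doc, ".//reaction")) {
      rx <- sub("^rn:", "", xml2::xml_attr(rxn, "name"))
      ty <- xml2::xml_attr(rxn, "type")
      if (!is.na(ty)) reversible[[rx]] <- identical(ty, "reversible")
    }
  }
  list(genes = genes, pathway_of = pathway_of, reversible = reversible)
}
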