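#' Configuration for a synthetic metabolic study
#'
#' Describes a complete self-consistent study bundle: a connected
#' reaction scaffold, paralogous enzyme families with planted overlap
#' classes (FULL isozyme families sharing one reaction; PARTIAL
#' families sharing one reaction with one private reaction per member,
#' hence pairwise Dice_M exactly 0.5; NONE families whose members
#' catalyse disjoint branch reactions anchored at least
#' `none_min_separation` scaffold steps apart), duplication-age labels
#' optionally concentrated in the oldest class for divergent pairs, a
#' proteome in which within-family identity exceeds the paralogy
#' threshold while between-family identity stays below it, and
#' expression profiles correlated within FULL pairs.
#'
#' @param n_scaffold_reactions Number of scaffold reactions (default
#'   150); the scaffold is a connected chain with random branches.
#' @param n_families Number of paralogous families (default 100).
#' @param family_size_distribution Named probabilities over sizes
#'   2, 3, 4.
#' @param f_full,f_partial,f_none Class fractions, summing to 1
#'   (defaults 0.8 / 0.1 / 0.1).
#' @param age_mixture Named probabilities over the four age groups.
#' @param p_none_given_oldest Probability that a NONE family is
#'   assigned the oldest age class (default 0.9).
#' @param reversible_fraction Fraction of reversible reactions
#'   (default 0.3).
#' @param complex_fraction Fraction of background-catalysed scaffold
#'   reactions catalysed by a two-member complex (default 0.1).
#' @param n_experiments Number of expression experiments (default 50).
#' @param expression_correlation Pairwise expression correlation
#'   planted within FULL families (default 0.8).
#' @param missing_rate Probability that an expression cell is missing
#'   (default 0.02).
#' @param mutation_rate_within_family Substitutions per site applied
#'   to the family seed sequence for each member (default 0.1).
#' @param seq_length Protein length in residues (default 120).
#' @param none_min_separation Minimum scaffold distance between the
#'   branch anchors of a NONE family's reactions (default 4).
#' @param seed Integer seed; the whole bundle is a deterministic
#'   function of the configuration.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_scaffold_reactions = 150L,
                             n_families = 100L,
                             family_size_distribution =
                               c("2" = 0.7, "3" = 0.2, "4" = 0.1),
                             f_full = 0.8, f_partial = 0.1, f_none = 0.1,
                             age_mixture = c(
                               PRE_WGD_EUASCOMYCETES = 0.15,
                               PRE_WGD_HEMIASCOMYCETES = 0.15,
                               WGD = 0.45, POST_WGD = 0.25),
                             p_none_given_oldest = 0.9,
                             reversible_fraction = 0.3,
                             complex_fraction = 0.1,
                             n_experiments = 50L,
                             expression_correlation = 0.8,
                             missing_rate = 0.02,
                             mutation_rate_within_family = 0.1,
                             seq_length = 120L,
                             none_min_separation = 4L,
                             seed = 1L) {
  cfg <- as.list(environment())
  fr <- c(f_full, f_partial, f_none, reversible_fraction,
          complex_fraction, p_none_given_oldest, missing_rate,
          mutation_rate_within_family)
  if (any(fr < 0 | fr > 1))
    stop("all fractions must lie in [0, 1]", call. = FALSE)
  if (abs(f_full + f_partial + f_none - 1) > 1e-9)
    stop("f_full + f_partial + f_none must sum to 1", call. = FALSE)
  if (abs(sum(age_mixture) - 1) > 1e-9 ||
      !setequal(names(age_mixture), setdiff(age_groups(), "UNKNOWN")))
    stop("age_mixture must cover the four age groups and sum to 1",
         call. = FALSE)
  if (abs(sum(family_size_distribution) - 1) > 1e-9 ||
      !all(names(family_size_distribution) %in% c("2", "3", "4")))
    stop("family_size_distribution must be probabilities over sizes 2-4",
         call. = FALSE)
  if (n_scaffold_reactions < 5L || n_families < 1L)
    stop("need at least 5 scaffold reactions and 1 family", call. = FALSE)
  # worst case every family is PARTIAL of size 4: 5 claims each
  structure(cfg, class = "synthetic_config")
}

OLDEST_AGE <- "PRE_WGD_EUASCOMYCETES"
CURRENCY <- c("ATP", "ADP")   # planted currency pair, never primary/main

#' Generate a synthetic study bundle with planted ground truth
#'
#' Builds, deterministically from the seed: the scaffold reaction set,
#' family memberships and planted overlap classes, age labels, a
#' proteome and an expression matrix, together with the ground truth
#' needed to score any downstream estimate. Use [write_study()] to emit
#' the bundle in both pathway-database dialects plus FASTA/TSV/JSON
#' files.
#'
#' @param config A [synthetic_config()].
#' @return An object of class `synthetic_study`: list with `reactions`
#'   (list of [reaction_record()]), `proteome` (named character),
#'   `families` (a `family_set` with pair ages), `expression` (matrix),
#'   `truth` (list: `family_class`, `pairs` data frame with planted
#'   class and age per within-family pair, `scaffold_metabolites`,
#'   `config`).
#' @export
generate_study <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_local_seed(config$seed, generate_study_impl(config))
}

generate_study_impl <- function(cfg) {
  n_r <- cfg$n_scaffold_reactions
  ## --- scaffold: connected chain with random branches ---------------
  mets <- sprintf("M%04d", seq_len(n_r + 1L))
  parent <- character(n_r)
  tip <- mets[[1L]]
  for (i in seq_len(n_r)) {
    parent[[i]] <- if (i == 1L || stats::runif(1) > 0.2) tip
                   else sample(mets[seq_len(i)], 1L)
    tip <- mets[[i + 1L]]
  }
  rxn_id <- sprintf("R%04d", seq_len(n_r))
  rxn_sub <- parent
  rxn_prod <- mets[-1L]
  reversible <- stats::runif(n_r) < cfg$reversible_fraction
  pathway_of <- sprintf("PWY%02d", ((seq_len(n_r) - 1L) %/% 15L) + 1L)

  ## --- families: sizes, classes, claims -----------------------------
  sizes <- as.integer(sample(names(cfg$family_size_distribution),
                             cfg$n_families, replace = TRUE,
                             prob = cfg$family_size_distribution))
  classes <- sample(c("FULL", "PARTIAL", "NONE"), cfg$n_families,
                    replace = TRUE,
                    prob = c(cfg$f_full, cfg$f_partial, cfg$f_none))
  fam_id <- sprintf("FAM%03d", seq_len(cfg$n_families))
  members <- lapply(seq_len(cfg$n_families), function(i)
    sprintf("G%03d%s", i, LETTERS[seq_len(sizes[[i]])]))

  unclaimed <- seq_len(n_r)
  claim <- function(k) {
    if (length(unclaimed) < k)
      stop("infeasible configuration: not enough scaffold reactions ",
           "for the requested families", call. = FALSE)
    take <- unclaimed[sample.int(length(unclaimed), k)]
    unclaimed <<- setdiff(unclaimed, take)
    take
  }
  # catalysts[[i]]: enzymes of scaffold reaction i (claimed families
  # replace the background catalyst)
  catalysts <- vector("list", n_r)
  branch <- list()   # extra reactions of NONE members

  # scaffold distances for NONE anchor placement
  gsc <- igraph::graph_from_data_frame(
    data.frame(rxn_sub, rxn_prod), directed = FALSE,
    vertices = data.frame(name = mets))
  dsc <- igraph::distances(gsc)

  for (i in seq_len(cfg$n_families)) {
    mem <- members[[i]]
    if (classes[[i]] == "FULL") {
      r <- claim(1L)
      catalysts[[r]] <- c(catalysts[[r]], mem)
    } else if (classes[[i]] == "PARTIAL") {
      rs <- claim(1L + length(mem))
      shared <- rs[[1L]]
      catalysts[[shared]] <- c(catalysts[[shared]], mem)
      for (j in seq_along(mem))
        catalysts[[rs[[j + 1L]]]] <- c(catalysts[[rs[[j + 1L]]]], mem[[j]])
    } else {
      anchors <- place_none_anchors(dsc, length(mem),
                                    cfg$none_min_separation)
      for (j in seq_along(mem)) {
        # no underscores: metabolite ids must survive the KEGG-dialect
        # RPAIR compound separator
        branch[[length(branch) + 1L]] <- list(
          id = sprintf("RN%03d%s", i, LETTERS[[j]]),
          sub = rownames(dsc)[[anchors[[j]]]],
          prod = sprintf("MN%03d%s", i, LETTERS[[j]]),
          enzyme = mem[[j]],
          reversible = stats::runif(1) < cfg$reversible_fraction)
      }
    }
  }

  ## --- background catalysts and complexes ---------------------------
  complexes <- list()
  for (i in seq_len(n_r)) {
    if (is.null(catalysts[[i]])) {
      if (stats::runif(1) < cfg$complex_fraction) {
        cid <- sprintf("CPLX%04d", i)
        complexes[[cid]] <- sprintf("B%04d%s", i, c("A", "B"))
        catalysts[[i]] <- complexes[[cid]]
        attr(catalysts[[i]], "complex") <- cid
      } else {
        catalysts[[i]] <- sprintf("B%04d", i)
      }
    }
  }

  ## --- reaction records ---------------------------------------------
  reactions <- vector("list", n_r + length(branch))
  for (i in seq_len(n_r)) {
    reactions[[i]] <- reaction_record(
      rxn_id[[i]], rxn_sub[[i]], rxn_prod[[i]],
      reversible = reversible[[i]],
      enzymes = as.character(catalysts[[i]]),
      pathways = pathway_of[[i]], source = "YBP_DIALECT")
    attr(reactions[[i]], "complex") <- attr(catalysts[[i]], "complex")
  }
  anchor_pathway <- stats::setNames(pathway_of, rxn_prod)
  anchor_pathway[mets[[1L]]] <- pathway_of[[1L]]
  for (j in seq_along(branch)) {
    b <- branch[[j]]
    reactions[[n_r + j]] <- reaction_record(
      b$id, b$sub, b$prod, reversible = b$reversible, enzymes = b$enzyme,
      pathways = unname(anchor_pathway[[b$sub]]), source = "YBP_DIALECT")
  }

  ## --- ages ----------------------------------------------------------
  other_ages <- setdiff(names(cfg$age_mixture), OLDEST_AGE)
  other_p <- cfg$age_mixture[other_ages] / sum(cfg$age_mixture[other_ages])
  fam_age <- vapply(seq_len(cfg$n_families), function(i) {
    if (classes[[i]] == "NONE") {
      if (stats::runif(1) < cfg$p_none_given_oldest) OLDEST_AGE
      else sample(other_ages, 1L, prob = other_p)
    } else {
      sample(names(cfg$age_mixture), 1L, prob = cfg$age_mixture)
    }
  }, "")

  pairs <- do.call(rbind, lapply(seq_len(cfg$n_families), function(i) {
    idx <- utils::combn(sort(members[[i]]), 2L)
    data.frame(gene1 = idx[1L, ], gene2 = idx[2L, ], family = fam_id[[i]],
               class = classes[[i]], age = fam_age[[i]],
               stringsAsFactors = FALSE)
  }))
  pair_ages <- stats::setNames(pairs$age, pair_key(pairs$gene1, pairs$gene2))
  families <- new_family_set(stats::setNames(members, fam_id), pair_ages)

  ## --- proteome -------------------------------------------------------
  aa20 <- setdiff(AA_ALPHABET_20X, "X")
  rand_seq <- function() paste(sample(aa20, cfg$seq_length, TRUE),
                               collapse = "")
  mutate <- function(s) {
    v <- strsplit(s, "")[[1L]]
    hit <- stats::runif(length(v)) < cfg$mutation_rate_within_family
    v[hit] <- vapply(v[hit], function(orig)
      sample(setdiff(aa20, orig), 1L), "")
    paste(v, collapse = "")
  }
  proteome <- character()
  for (i in seq_len(cfg$n_families)) {
    seed_seq <- rand_seq()
    for (m in members[[i]]) proteome[[m]] <- mutate(seed_seq)
  }
  for (i in seq_len(n_r)) {
    for (e in setdiff(as.character(catalysts[[i]]), names(proteome)))
      proteome[[e]] <- rand_seq()
  }

  ## --- expression -----------------------------------------------------
  genes <- names(proteome)
  expr <- matrix(stats::rnorm(length(genes) * cfg$n_experiments),
                 nrow = length(genes),
                 dimnames = list(genes,
                   sprintf("EXP%03d", seq_len(cfg$n_experiments))))
  rho <- cfg$expression_correlation
  for (i in seq_len(cfg$n_families)) {
    if (classes[[i]] != "FULL") next
    z <- stats::rnorm(cfg$n_experiments)
    for (m in members[[i]])
      expr[m, ] <- sqrt(rho) * z +
        sqrt(1 - rho) * stats::rnorm(cfg$n_experiments)
  }
  expr[matrix(stats::runif(length(expr)) < cfg$missing_rate,
              nrow = nrow(expr))] <- NA

  structure(list(
    reactions = reactions, proteome = proteome, families = families,
    expression = expr, complexes = complexes,
    truth = list(family_class = stats::setNames(classes, fam_id),
                 pairs = pairs,
                 scaffold_metabolites = mets,
                 config = cfg)),
    class = "synthetic_study")
}

# Pick k scaffold metabolites pairwise >= min_sep apart (rejection).
place_none_anchors <- function(dsc, k, min_sep) {
  n <- nrow(dsc)
  for (attempt in seq_len(500L)) {
    cand <- sample.int(n, k)
    if (k == 1L || min(dsc[cand, cand][upper.tri(diag(k))]) >= min_sep)
      return(cand)
  }
  stop("could not place divergent-family reactions ", min_sep,
       " scaffold steps apart; scaffold too small", call. = FALSE)
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study> ", length(x$reactions), " reactions, ",
      length(x$families$families), " families, ",
      length(x$proteome), " proteins, ",
      nrow(x$expression), "x", ncol(x$expression), " expression\n",
      sep = "")
  invisible(x)
}

#' Write a synthetic study to disk in every supported format
#'
#' Emits the BioCyc-style bundle (`biocyc/pathways.dat`,
#' `biocyc/enzrxns.dat`, `biocyc/protcplxs.col`), the KEGG-style bundle
#' (`kegg/reaction.lst` plus one KGML file per pathway under `kegg/`),
#' `proteome.fasta`, family tables in both dialects
#' (`families_groups.tsv`, `families_pairs.tsv`), `expression.tsv` and
#' `truth.json`. Every reaction also carries a planted non-primary
#' (non-"main") currency pair ATP/ADP, which a correct reader must
#' discard. Output is byte-deterministic for a given study.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return Named list of the written file paths, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(file.path(dir, "biocyc"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "kegg"), recursive = TRUE,
             showWarnings = FALSE)
  paths <- list(
    pathways = file.path(dir, "biocyc", "pathways.dat"),
    enzrxns = file.path(dir, "biocyc", "enzrxns.dat"),
    complexes = file.path(dir, "biocyc", "protcplxs.col"),
    reaction_list = file.path(dir, "kegg", "reaction.lst"),
    proteome = file.path(dir, "proteome.fasta"),
    groups = file.path(dir, "families_groups.tsv"),
    pairs = file.path(dir, "families_pairs.tsv"),
    expression = file.path(dir, "expression.tsv"),
    truth = file.path(dir, "truth.json"))

  ## BioCyc dialect
  pw_lines <- character(); ez_lines <- character()
  for (rec in study$reactions) {
    cplx <- attr(rec, "complex")
    pw_lines <- c(pw_lines,
      paste0("UNIQUE-ID - ", rec$reaction_id),
      paste0("REACTION-DIRECTION - ",
             if (rec$reversible) "REVERSIBLE" else "LEFT-TO-RIGHT"),
      unlist(lapply(rec$substrates, function(s)
        c(paste0("LEFT - ", s), "^PRIMARY - T"))),
      paste0("LEFT - ", CURRENCY[[1L]]),
      unlist(lapply(rec$products, function(p)
        c(paste0("RIGHT - ", p), "^PRIMARY - T"))),
      paste0("RIGHT - ", CURRENCY[[2L]]),
      paste0("IN-PATHWAY - ", rec$pathways),
      "//")
    cats <- if (is.null(cplx)) rec$enzymes else cplx
    ez_lines <- c(ez_lines, unlist(lapply(seq_along(cats), function(k)
      c(paste0("UNIQUE-ID - ENZRXN-", rec$reaction_id, "-", k),
        paste0("ENZYME - ", cats[[k]]),
        paste0("REACTION - ", rec$reaction_id),
        "//"))))
  }
  writeLines(pw_lines, paths$pathways)
  writeLines(ez_lines, paths$enzrxns)
  writeLines(c("# complex table",
               vapply(names(study$complexes), function(cid)
                 paste(cid, cid,
                       paste(study$complexes[[cid]], collapse = ","),
                       sep = "\t"), character(1))),
             paths$complexes)

  ## KEGG dialect
  rl <- unlist(lapply(study$reactions, function(rec) {
    arrow <- if (rec$reversible) "<=>" else "=>"
    c(paste0("ENTRY       ", rec$reaction_id),
      paste0("EQUATION    ", rec$substrates[[1L]], " + ", CURRENCY[[1L]],
             " ", arrow, " ", rec$products[[1L]], " + ", CURRENCY[[2L]]),
      paste0("RPAIR       RP_", rec$reaction_id, "_1  ",
             rec$substrates[[1L]], "_", rec$products[[1L]], "  main"),
      paste0("RPAIR       RP_", rec$reaction_id, "_2  ",
             CURRENCY[[1L]], "_", CURRENCY[[2L]], "  cofac"),
      "///")
  }))
  writeLines(rl, paths$reaction_list)
  by_pwy <- split(study$reactions,
                  vapply(study$reactions, function(r) r$pathways[[1L]], ""))
  kgml_paths <- character()
  for (pwy in names(by_pwy)) {
    p <- file.path(dir, "kegg", paste0(pwy, ".xml"))
    kgml_paths <- c(kgml_paths, p)
    write_kgml(by_pwy[[pwy]], pwy, p)
  }
  paths$kgml <- kgml_paths

  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(study$proteome), paths$proteome, width = 60L)
  write_family_table(study$families, paths$groups)
  tp <- study$truth$pairs
  writeLines(paste(tp$gene1, tp$gene2, tp$age, sep = "\t"), paths$pairs)
  write_expression_matrix(study$expression, paths$expression)
  jsonlite::write_json(
    list(family_class = as.list(study$truth$family_class),
         pairs = study$truth$pairs,
         scaffold_metabolites = study$truth$scaffold_metabolites,
         config = study$truth$config[setdiff(names(study$truth$config),
                                             "family_size_distribution")]),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

write_kgml <- function(recs, pathway, path) {
  ent <- character(); rxn <- character()
  eid <- 0L
  for (rec in recs) {
    eid <- eid + 1L
    ent <- c(ent, sprintf(
      '  <entry id="%d" name="%s" type="gene" reaction="rn:%s"/>',
      eid, paste0("sce:", rec$enzymes, collapse = " "),
      rec$reaction_id))
    rxn <- c(rxn, sprintf(
      '  <reaction id="%d" name="rn:%s" type="%s"/>',
      eid, rec$reaction_id,
      if (rec$reversible) "reversible" else "irreversible"))
  }
  writeLines(c(
    '<?xml version="1.0"?>',
    sprintf('<pathway name="path:%s" org="syn" number="0">', pathway),
    ent, rxn, "</pathway>"), path)
}

#' A fixed worked toy bundle
#'
#' A deterministic six-metabolite, five-reaction linear pathway split
#' into two pathway annotations, carrying: a FULL isozyme pair (E1, E2
#' both catalysing M1 -> M2, family FA, WGD age), a NONE divergent pair
#' (E3: M2 -> M3 versus E5: M4 -> M5 -> M6, family FB, oldest age) and
#' a contiguous non-paralogous enzyme pair (E3, E4) whose mean
#' metabolite shortest path is exactly 1. Used throughout the
#' documentation and the acceptance checks.
#'
#' @return A list with `reactions`, `network` (prebuilt), `families`,
#'   `proteome`, and the named pairs `full_pair`, `none_pair`,
#'   `contiguous_pair`.
#' @examples
#' toy <- generate_worked_toy()
#' enzyme_dice_m(toy$network, "E1", "E2")   # 1
#' enzyme_dice_m(toy$network, "E3", "E5")   # 0
#' @export
generate_worked_toy <- function() {
  reactions <- list(
    reaction_record("R1", "M1", "M2", enzymes = c("E1", "E2"),
                    pathways = "P1"),
    reaction_record("R2", "M2", "M3", enzymes = "E3", pathways = "P1"),
    reaction_record("R3", "M3", "M4", enzymes = "E4", pathways = "P1"),
    reaction_record("R4", "M4", "M5", enzymes = "E5", pathways = "P2"),
    reaction_record("R5", "M5", "M6", enzymes = "E5", pathways = "P2"))
  families <- new_family_set(
    list(FA = c("E1", "E2"), FB = c("E3", "E5"), FC = "E4"),
    stats::setNames(c("WGD", OLDEST_AGE),
                    c(pair_key("E1", "E2"), pair_key("E3", "E5"))))
  base <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQAPILSRVG"
  proteome <- c(
    E1 = base,
    E2 = sub("AKQ", "GKQ", sub("SHF", "THF", base)),
    E3 = "MSDNLKEQFRAWLLEHPEVLNQYGVNTTRESLAGAILNEWG",
    E4 = "MPLSEQTIRLWAAGKDVNEAFYQHHQEALTRFGISPEQVRK",
    E5 = "MGIDTKELARRAVELSGGQAPAFLHNLSPEEAYKVVTQWNA")
  list(reactions = reactions,
       network = build_metabolic_network(reactions),
       families = families,
       proteome = proteome,
       full_pair = c("E1", "E2"),
       none_pair = c("E3", "E5"),
       contiguous_pair = c("E3", "E4"))
}
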