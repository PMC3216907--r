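#' Assemble and validate a pipeline configuration
#'
#' @param networks Named list of `metabolic_network` objects (or lists
#'   of [reaction_record()]s, which are built into networks), e.g. one
#'   per pathway-database dialect.
#' @param paralogy Named list of `family_set` objects, one per paralogy
#'   definition (sequence-derived and/or externally supplied).
#' @param ages Optional pair-age map (named character keyed by sorted
#'   pair, or a `family_set` carrying `pair_ages`).
#' @param expression Optional raw expression matrix (genes x
#'   experiments, `NA` = missing); it is filtered with
#'   [filter_expression_matrix()] before use.
#' @param collapse_replicates Number of collapsed networks per
#'   (network, paralogy) combination; must be >= 1.
#' @param null_samples Random enzyme pairs for the Dice_M null
#'   distribution; 0 skips the null.
#' @param distances Compute per-pair mean metabolite shortest paths.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param out_dir Optional directory: result TSVs and a JSON manifest
#'   are written there.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(networks, paralogy, ages = NULL,
                            expression = NULL,
                            collapse_replicates = 1000L,
                            null_samples = 0L, distances = TRUE,
                            seed = 1L, out_dir = NULL) {
  if (length(networks) == 0L || is.null(names(networks)))
    stop("at least one named network source is required", call. = FALSE)
  if (length(paralogy) == 0L || is.null(names(paralogy)))
    stop("at least one named paralogy source is required", call. = FALSE)
  networks <- lapply(networks, function(n)
    if (inherits(n, "metabolic_network")) n else build_metabolic_network(n))
  ok <- vapply(paralogy, inherits, TRUE, "family_set")
  if (!all(ok)) stop("paralogy sources must be family_set objects",
                     call. = FALSE)
  if (collapse_replicates < 1L)
    stop("collapse_replicates must be >= 1", call. = FALSE)
  structure(list(networks = networks, paralogy = paralogy, ages = ages,
                 expression = expression,
                 collapse_replicates = as.integer(collapse_replicates),
                 null_samples = as.integer(null_samples),
                 distances = isTRUE(distances),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full paralog-overlap analysis
#'
#' For every paralogy definition: enumerates the within-family pairs
#' present in each network, computes per-network Dice_M (plus Dice_P,
#' mean metabolite paths, ages and expression correlations), summarises
#' the FULL/PARTIAL/NONE class fractions and the duplication-age
#' enrichment among zero-overlap pairs, and runs the randomized family
#' collapse ensemble for every (network, paralogy) combination.
#' Identical configuration and seed reproduce the bundle exactly.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `report_bundle`: `pair_tables` and
#'   `summaries` (one per paralogy definition), `collapse` (one
#'   `collapse_summary` per network x paralogy combination), `null`
#'   (per network, when requested), `agreement` (cross-network class
#'   agreement per paralogy definition) and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  nets <- config$networks
  expr <- config$expression
  if (!is.null(expr)) expr <- filter_expression_matrix(expr)
  pair_tables <- list(); summaries <- list()
  collapse_res <- list(); agreement <- list()
  combo_seed <- config$seed
  for (pname in names(config$paralogy)) {
    fams <- config$paralogy[[pname]]
    ages <- config$ages
    if (is.null(ages) && length(fams$pair_ages)) ages <- fams$pair_ages
    # pairs present in any network, Dice per network
    pairs <- unique(do.call(rbind, lapply(nets, function(net)
      enumerate_network_pairs(fams, net))))
    tab <- overlap_table(pairs, nets, ages = ages, expression = expr,
                         distances = config$distances)
    pair_tables[[pname]] <- tab
    summaries[[pname]] <- summarise_overlap(tab)
    for (nname in names(nets)) {
      combo_seed <- combo_seed + 1L
      collapse_res[[paste(nname, pname, sep = ".")]] <-
        collapse_ensemble(nets[[nname]], fams,
                          n_replicates = config$collapse_replicates,
                          seed = combo_seed, keep_distributions = FALSE)
    }
    if (length(nets) >= 2L) {
      cls <- lapply(names(nets), function(nm) tab[[paste0("class_", nm)]])
      both <- !is.na(cls[[1L]]) & !is.na(cls[[2L]])
      agreement[[pname]] <- data.frame(
        networks = paste(names(nets)[1:2], collapse = " vs "),
        n_pairs = sum(both),
        n_agree = sum(cls[[1L]][both] == cls[[2L]][both]))
    }
  }
  null_res <- NULL
  if (config$null_samples > 0L) {
    null_res <- lapply(seq_along(nets), function(i)
      random_pair_null(nets[[i]], config$null_samples,
                       seed = config$seed + 1000L + i))
    names(null_res) <- names(nets)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("metgrowth")),
    seed = config$seed,
    collapse_replicates = config$collapse_replicates,
    null_samples = config$null_samples,
    networks = lapply(nets, function(n)
      list(nodes = length(n$nodes), edges = nrow(n$edges),
           enzymes = length(network_enzymes(n)))),
    paralogy = lapply(config$paralogy, function(f)
      list(families = length(f$families),
           multi_member = sum(lengths(f$families) > 1L))),
    expression = if (is.null(expr)) NULL else dim(expr))
  bundle <- structure(list(pair_tables = pair_tables,
                           summaries = summaries,
                           collapse = collapse_res, null = null_res,
                           agreement = agreement, manifest = manifest),
                      class = "report_bundle")
  if (!is.null(config$out_dir)) write_report_bundle(bundle, config$out_dir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle> ", length(x$pair_tables),
      " paralogy definition(s), ", length(x$collapse),
      " collapse ensemble(s)\n", sep = "")
  for (nm in names(x$summaries)) {
    cat("--", nm, "--\n")
    print(x$summaries[[nm]])
  }
  invisible(x)
}

#' Write a report bundle's tables to a directory
#'
#' Emits, per paralogy definition, `pairs_<name>.tsv` (the full pair
#' table), `enrichment_<name>.tsv`, `divergent_<name>.tsv` and
#' `fractions_<name>.tsv`; per combination, `collapse_<combo>.tsv`
#' (one row per replicate); per network, `dice_null_<name>.tsv`; plus
#' `manifest.json`.
#'
#' @param bundle A `report_bundle`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(bundle$pair_tables)) {
    write_tsv(bundle$pair_tables[[nm]],
              file.path(dir, paste0("pairs_", nm, ".tsv")))
    write_tsv(bundle$summaries[[nm]]$enrichment,
              file.path(dir, paste0("enrichment_", nm, ".tsv")))
    write_tsv(bundle$summaries[[nm]]$divergent,
              file.path(dir, paste0("divergent_", nm, ".tsv")))
    write_tsv(bundle$summaries[[nm]]$fractions,
              file.path(dir, paste0("fractions_", nm, ".tsv")))
  }
  for (nm in names(bundle$collapse)) {
    s <- bundle$collapse[[nm]]
    write_tsv(s$replicates, file.path(dir, paste0("collapse_", nm, ".tsv")))
  }
  for (nm in names(bundle$null))
    write_tsv(bundle$null[[nm]]$histogram,
              file.path(dir, paste0("dice_null_", nm, ".tsv")))
  jsonlite::write_json(bundle$manifest,
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
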