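#' Dice overlap of two canonical metabolite-pair profiles
#'
#' `Dice_M = 2 |X1 n X2| / (|X1| + |X2|)` where `X1`, `X2` are the sets
#' of canonical (substrate, product) metabolite pairs processed by two
#' enzymes (see [enzyme_metabolite_pairs()]). It is 1 for totally
#' functionally overlapping enzymes (isozymes) and 0 for enzymes with
#' no shared transformation.
#'
#' @param pairs1,pairs2 Data frames with `from`/`to` columns.
#' @return Numeric in \[0, 1\], or `NA` when both sets are empty.
#' @export
dice_m <- function(pairs1, pairs2) {
  k1 <- unique(met_pair_keys(pairs1))
  k2 <- unique(met_pair_keys(pairs2))
  if (length(k1) + length(k2) == 0L) return(NA_real_)
  2 * length(intersect(k1, k2)) / (length(k1) + length(k2))
}

#' Dice overlap of two pathway-membership sets
#'
#' `Dice_P = 2 |P1 n P2| / (|P1| + |P2|)`: 1 when two enzymes are
#' annotated to exactly the same pathways, 0 when they share none.
#'
#' @param pathways1,pathways2 Character vectors of pathway ids.
#' @return Numeric in \[0, 1\], or `NA` when either enzyme has no
#'   pathway annotation.
#' @export
dice_p <- function(pathways1, pathways2) {
  p1 <- unique(pathways1); p2 <- unique(pathways2)
  if (length(p1) == 0L || length(p2) == 0L) return(NA_real_)
  2 * length(intersect(p1, p2)) / (length(p1) + length(p2))
}

#' Dice_M between two enzymes of a network
#'
#' @param network A `metabolic_network`.
#' @param enzyme1,enzyme2 Enzyme ids.
#' @return Numeric in \[0, 1\], or `NA` when either enzyme labels no
#'   network edge (the "N/A" case).
#' @export
enzyme_dice_m <- function(network, enzyme1, enzyme2) {
  enz <- network$edges$enzyme
  if (!(enzyme1 %in% enz) || !(enzyme2 %in% enz)) return(NA_real_)
  dice_m(enzyme_metabolite_pairs(network, enzyme1),
         enzyme_metabolite_pairs(network, enzyme2))
}

#' Classify a Dice coefficient into overlap classes
#'
#' @param dice Numeric vector of Dice values (NA allowed).
#' @return Factor with levels `FULL` (= 1), `PARTIAL` (0 < d < 1),
#'   `NONE` (= 0); `NA` propagates.
#' @export
classify_overlap <- function(dice) {
  cls <- ifelse(is.na(dice), NA_character_,
                ifelse(dice == 1, "FULL",
                       ifelse(dice == 0, "NONE", "PARTIAL")))
  factor(cls, levels = c("FULL", "PARTIAL", "NONE"))
}

#' Null distribution of Dice_M over random enzyme pairs
#'
#' Samples unordered pairs of distinct enzymes uniformly with
#' replacement and computes their Dice_M, emulating the random-pair
#' background against which the paralog Dice distribution is judged.
#'
#' @param network A `metabolic_network` with >= 2 enzymes.
#' @param n_samples Number of sampled pairs.
#' @param seed Integer seed.
#' @param breaks Histogram bin breaks over \[0, 1\].
#' @param exclude_pairs Optional data frame with `gene1`/`gene2`
#'   columns (e.g. paralog pairs); sampled pairs in it are rejected and
#'   redrawn.
#' @return List with `dice` (numeric vector of sampled Dice values) and
#'   `histogram` (data frame: `bin_low`, `bin_high`, `count`,
#'   `fraction`).
#' @export
random_pair_null <- function(network, n_samples = 1e5L, seed = 1L,
                             breaks = seq(0, 1, by = 0.1),
                             exclude_pairs = NULL) {
  enz <- network_enzymes(network)
  n <- length(enz)
  stopifnot(n >= 2L)
  profiles <- lapply(enz, function(e)
    unique(met_pair_keys(enzyme_metabolite_pairs(network, e))))
  sizes <- lengths(profiles)
  excl <- if (!is.null(exclude_pairs))
    pair_key(exclude_pairs$gene1, exclude_pairs$gene2) else character()
  draw <- function(k) {
    i <- sample.int(n, k, replace = TRUE)
    j <- sample.int(n - 1L, k, replace = TRUE)
    j <- ifelse(j >= i, j + 1L, j)
    cbind(i, j)
  }
  dice <- with_local_seed(seed, {
    ij <- draw(n_samples)
    if (length(excl)) {
      bad <- pair_key(enz[ij[, 1L]], enz[ij[, 2L]]) %in% excl
      while (any(bad)) {
        ij[bad, ] <- draw(sum(bad))
        bad <- pair_key(enz[ij[, 1L]], enz[ij[, 2L]]) %in% excl
      }
    }
    vapply(seq_len(n_samples), function(s) {
      a <- ij[s, 1L]; b <- ij[s, 2L]
      2 * sum(profiles[[a]] %in% profiles[[b]]) / (sizes[[a]] + sizes[[b]])
    }, 0)
  })
  h <- graphics::hist(dice, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = FALSE)
  list(dice = dice,
       histogram = data.frame(
         bin_low = utils::head(h$breaks, -1L),
         bin_high = utils::tail(h$breaks, -1L),
         count = h$counts,
         fraction = h$counts / n_samples))
}

#' Mean shortest path between the metabolites of two enzymes
#'
#' Takes M1 and M2, the metabolites incident to each enzyme's edges,
#' and averages the undirected shortest-path length over all ordered
#' cross pairs (m1, m2) in M1 x M2. Identical metabolites contribute
#' distance 0; unreachable pairs are excluded from the mean and
#' counted. A pair of enzymes catalysing contiguous reactions (the
#' products of one are the substrates of the other) scores at or near
#' 1; divergent paralogs in distant network regions score much higher.
#'
#' @param network A `metabolic_network`.
#' @param enzyme1,enzyme2 Enzyme ids.
#' @param directed Use directed distances instead of the undirected
#'   default.
#' @return List with `mean_path`, `sd_path`, `n_pairs_used`,
#'   `n_unreachable`; `mean_path` is `NA` when either enzyme is absent
#'   or no pair is reachable.
#' @export
pair_metabolite_distance <- function(network, enzyme1, enzyme2,
                                     directed = FALSE) {
  enz <- network$edges$enzyme
  if (!(enzyme1 %in% enz) || !(enzyme2 %in% enz))
    return(list(mean_path = NA_real_, sd_path = NA_real_,
                n_pairs_used = 0L, n_unreachable = 0L))
  m1 <- enzyme_incident_metabolites(network, enzyme1)
  m2 <- enzyme_incident_metabolites(network, enzyme2)
  d <- shortest_path_matrix(network, m1, m2, directed = directed)
  vals <- as.numeric(d)
  finite <- vals[is.finite(vals)]
  list(mean_path = if (length(finite)) mean(finite) else NA_real_,
       sd_path = if (length(finite) > 1L) stats::sd(finite) else NA_real_,
       n_pairs_used = length(finite),
       n_unreachable = sum(!is.finite(vals)))
}

# Metabolites incident to any edge (forward or reverse) of an enzyme.
enzyme_incident_metabolites <- function(network, enzyme_id) {
  e <- network$edges[network$edges$enzyme == enzyme_id, , drop = FALSE]
  sort(unique(c(e$from, e$to)))
}

#' Hypergeometric enrichment (upper tail)
#'
#' Probability of observing at least `k` successes when drawing `n`
#' items without replacement from a population of `N` items of which
#' `K` are successes.
#'
#' @param k Successes in the selection.
#' @param n Selection size.
#' @param K Successes in the population.
#' @param N Population size.
#' @return List of class `enrichment_result` with `k`, `n`, `K`, `N`
#'   and `p_value` = P(X >= k).
#' @examples
#' hypergeometric_enrichment(3, 3, 4, 10)$p_value  # 4/120
#' @export
hypergeometric_enrichment <- function(k, n, K, N) {
  if (!(k <= min(n, K) && n <= N && K <= N && k >= 0))
    stop("inconsistent counts: need k <= min(n, K), n <= N, K <= N",
         call. = FALSE)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  structure(list(k = k, n = n, K = K, N = N, p_value = p),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> k=%d of n=%d drawn, K=%d of N=%d; P(X >= k) = %.4g\n",
              x$k, x$n, x$K, x$N, x$p_value))
  invisible(x)
}

#' Filter an expression matrix by missing-data fractions
#'
#' Columns (experiments) whose missing fraction exceeds
#' `col_missing_max` are removed first; then rows (genes) whose missing
#' fraction over the surviving columns exceeds `row_missing_max` are
#' removed. The fixed columns-then-rows order matters: a gene can be
#' rescued by the removal of the experiments it was missing in.
#'
#' @param m Numeric matrix (genes x experiments) with `NA` for missing.
#' @param col_missing_max,row_missing_max Maximum tolerated missing
#'   fractions (defaults 0.05).
#' @return The filtered matrix (possibly with zero rows or columns, in
#'   which case a warning is raised).
#' @export
filter_expression_matrix <- function(m, col_missing_max = 0.05,
                                     row_missing_max = 0.05) {
  stopifnot(is.matrix(m))
  keep_col <- colMeans(is.na(m)) <= col_missing_max
  m2 <- m[, keep_col, drop = FALSE]
  keep_row <- if (ncol(m2)) rowMeans(is.na(m2)) <= row_missing_max
              else rep(FALSE, nrow(m2))
  m2 <- m2[keep_row, , drop = FALSE]
  if (nrow(m2) == 0L || ncol(m2) == 0L)
    warning("expression matrix empty after missing-data filtering",
            call. = FALSE)
  m2
}

#' Pearson correlation of two genes' expression profiles
#'
#' Correlation over pairwise-complete experiments, with the two-sided
#' p value from the t transform on n - 2 degrees of freedom.
#'
#' @param m Numeric matrix (genes x experiments), typically already
#'   passed through [filter_expression_matrix()].
#' @param gene1,gene2 Row ids.
#' @return List with `r`, `p_value` and `n_used`; `r` is `NA` when
#'   fewer than 3 complete pairs exist, either gene is absent, or a
#'   profile has zero variance.
#' @export
expression_correlation <- function(m, gene1, gene2) {
  na <- list(r = NA_real_, p_value = NA_real_, n_used = 0L)
  if (!(gene1 %in% rownames(m)) || !(gene2 %in% rownames(m))) return(na)
  x <- m[gene1, ]; y <- m[gene2, ]
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3L) return(na)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(na)
  r <- stats::cor(x, y)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  list(r = r, p_value = p, n_used = n)
}

#' Overlap, distance, age and expression statistics for paralog pairs
#'
#' Computes, for every paralog pair, the Dice_M in each supplied
#' network, Dice_P over pathway annotations, the mean metabolite
#' shortest path, the age group, and (optionally) the expression
#' correlation.
#'
#' @param pairs Data frame from [enumerate_network_pairs()] (the pairs
#'   of one reference network; pairs with `in_network = FALSE` get NA
#'   statistics).
#' @param networks Named list of `metabolic_network` objects; Dice_M is
#'   computed per network and class columns are named after them.
#' @param ages Optional pair-age map (named character or `family_set`).
#' @param expression Optional filtered expression matrix.
#' @param distances Compute mean shortest paths (can be slow on large
#'   networks); default `TRUE`.
#' @return Data frame with one row per pair: `dice_m_<net>` and
#'   `class_<net>` per network, `dice_p` (from the first network's
#'   pathway annotations), `mean_path`/`sd_path`/`n_unreachable` (first
#'   network), `age`, `pearson_r`, `pearson_p`.
#' @export
overlap_table <- function(pairs, networks, ages = NULL,
                          expression = NULL, distances = TRUE) {
  stopifnot(is.list(networks), length(networks) >= 1L,
            !is.null(names(networks)))
  out <- pairs
  for (nm in names(networks)) {
    net <- networks[[nm]]
    dv <- vapply(seq_len(nrow(pairs)), function(i)
      enzyme_dice_m(net, pairs$gene1[i], pairs$gene2[i]), 0)
    out[[paste0("dice_m_", nm)]] <- dv
    out[[paste0("class_", nm)]] <- classify_overlap(dv)
  }
  ref <- networks[[1L]]
  out$dice_p <- vapply(seq_len(nrow(pairs)), function(i)
    dice_p(ref$pathways[[pairs$gene1[i]]] %||% character(),
           ref$pathways[[pairs$gene2[i]]] %||% character()), 0)
  if (distances) {
    dist <- lapply(seq_len(nrow(pairs)), function(i)
      pair_metabolite_distance(ref, pairs$gene1[i], pairs$gene2[i]))
    out$mean_path <- vapply(dist, `[[`, 0, "mean_path")
    out$sd_path <- vapply(dist, `[[`, 0, "sd_path")
    out$n_unreachable <- vapply(dist, `[[`, 0L, "n_unreachable")
  }
  out <- if (!is.null(ages)) assign_age_group(out, ages) else
    transform(out, age = "UNKNOWN")
  if (!is.null(expression)) {
    ex <- lapply(seq_len(nrow(pairs)), function(i)
      expression_correlation(expression, pairs$gene1[i], pairs$gene2[i]))
    out$pearson_r <- vapply(ex, `[[`, 0, "r")
    out$pearson_p <- vapply(ex, `[[`, 0, "p_value")
  } else {
    out$pearson_r <- NA_real_
    out$pearson_p <- NA_real_
  }
  out
}

#' Summarise overlap classes and duplication-age enrichment
#'
#' Tabulates the FULL/PARTIAL/NONE fractions per network, tests each
#' age group for enrichment among the zero-overlap (NONE) pairs with
#' the upper-tail hypergeometric test (population = all pairs with a
#' defined Dice_M in that network; selection = its NONE pairs), and
#' extracts the divergent-pair table: pairs classified NONE in at least
#' `min_networks_none` network(s).
#'
#' @param tab Data frame from [overlap_table()].
#' @param min_networks_none Minimum number of networks in which a pair
#'   must be NONE to enter the divergent table (default 1).
#' @return List of class `overlap_summary` with `fractions` (data
#'   frame: network, class, count, fraction), `enrichment` (data frame:
#'   network, age, k, n, K, N, p_value, p_bonferroni) and `divergent`
#'   (row subset of `tab`).
#' @export
summarise_overlap <- function(tab, min_networks_none = 1L) {
  class_cols <- grep("^class_", names(tab), value = TRUE)
  stopifnot(length(class_cols) >= 1L)
  nets <- sub("^class_", "", class_cols)
  fractions <- do.call(rbind, lapply(nets, function(nm) {
    cls <- tab[[paste0("class_", nm)]]
    cls <- cls[!is.na(cls)]
    cnt <- table(cls)
    data.frame(network = nm, class = names(cnt),
               count = as.integer(cnt),
               fraction = as.integer(cnt) / max(1L, length(cls)))
  }))
  enrichment <- do.call(rbind, lapply(nets, function(nm) {
    cls <- tab[[paste0("class_", nm)]]
    ok <- !is.na(cls)
    N <- sum(ok); n <- sum(cls[ok] == "NONE")
    do.call(rbind, lapply(setdiff(age_groups(), "UNKNOWN"), function(ag) {
      K <- sum(tab$age[ok] == ag)
      k <- sum(tab$age[ok] == ag & cls[ok] == "NONE")
      p <- if (N > 0L && n > 0L && K > 0L)
        hypergeometric_enrichment(k, n, K, N)$p_value else 1
      data.frame(network = nm, age = ag, k = k, n = n, K = K, N = N,
                 p_value = p)
    }))
  }))
  n_tests <- sum(!duplicated(enrichment$age))
  enrichment$p_bonferroni <- pmin(1, enrichment$p_value * n_tests)
  none_counts <- rowSums(
    sapply(class_cols, function(cc) !is.na(tab[[cc]]) & tab[[cc]] == "NONE"),
    na.rm = TRUE)
  divergent <- tab[none_counts >= min_networks_none, , drop = FALSE]
  structure(list(fractions = fractions, enrichment = enrichment,
                 divergent = divergent),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat("<overlap_summary>\n")
  print(x$fractions, row.names = FALSE)
  cat(nrow(x$divergent), "divergent pair(s)\n")
  invisible(x)
}
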