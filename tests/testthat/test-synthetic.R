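small_cfg <- function(...) {
  synthetic_config(n_scaffold_reactions = 40, n_families = 12,
                   n_experiments = 20, seq_length = 60, ...)
}

test_that("study generation is a deterministic function of the seed", {
  a <- generate_study(small_cfg(seed = 17))
  b <- generate_study(small_cfg(seed = 17))
  expect_identical(a$proteome, b$proteome)
  expect_identical(a$expression, b$expression)
  expect_identical(a$truth$pairs, b$truth$pairs)
  c <- generate_study(small_cfg(seed = 18))
  expect_false(identical(a$proteome, c$proteome))

  # byte-identical emission
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_study(a, d1); p2 <- write_study(b, d2)
  for (nm in c("pathways", "reaction_list", "proteome", "groups",
               "expression")) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]))
  }
})

test_that("planted classes force the promised Dice values and ages", {
  st <- generate_study(small_cfg(f_full = 1, f_partial = 0, f_none = 0,
                                 seed = 3))
  net <- build_metabolic_network(st$reactions)
  pairs <- enumerate_network_pairs(st$families, net)
  dv <- mapply(function(a, b) enzyme_dice_m(net, a, b),
               pairs$gene1, pairs$gene2)
  expect_true(all(dv == 1))

  st0 <- generate_study(small_cfg(f_full = 0, f_partial = 0, f_none = 1,
                                  p_none_given_oldest = 1, seed = 4))
  net0 <- build_metabolic_network(st0$reactions)
  pairs0 <- assign_age_group(enumerate_network_pairs(st0$families, net0),
                             st0$families)
  dv0 <- mapply(function(a, b) enzyme_dice_m(net0, a, b),
                pairs0$gene1, pairs0$gene2)
  expect_true(all(dv0 == 0))
  expect_true(all(pairs0$age == "PRE_WGD_EUASCOMYCETES"))

  # PARTIAL pairs land exactly on 0.5 by construction
  stp <- generate_study(synthetic_config(
    n_scaffold_reactions = 80, n_families = 12, n_experiments = 20,
    seq_length = 60, f_full = 0, f_partial = 1, f_none = 0, seed = 5))
  netp <- build_metabolic_network(stp$reactions)
  pairsp <- enumerate_network_pairs(stp$families, netp)
  dvp <- mapply(function(a, b) enzyme_dice_m(netp, a, b),
                pairsp$gene1, pairsp$gene2)
  expect_true(all(dvp == 0.5))
})

test_that("estimated class fractions equal the planted truth pair by pair", {
  st <- generate_study(synthetic_config(seed = 29))
  net <- build_metabolic_network(st$reactions)
  pairs <- enumerate_network_pairs(st$families, net)
  tab <- overlap_table(pairs, list(net = net), distances = FALSE)
  truth <- st$truth$pairs
  key <- metgrowth:::pair_key(tab$gene1, tab$gene2)
  tkey <- metgrowth:::pair_key(truth$gene1, truth$gene2)
  expect_setequal(key, tkey)
  expect_equal(as.character(tab$class_net),
               truth$class[match(key, tkey)])
})

test_that("divergent-family reactions sit at least the configured distance apart", {
  st <- generate_study(small_cfg(f_full = 0, f_partial = 0, f_none = 1,
                                 seed = 11))
  net <- build_metabolic_network(st$reactions)
  pairs <- enumerate_network_pairs(st$families, net)
  for (i in seq_len(nrow(pairs))) {
    d <- pair_metabolite_distance(net, pairs$gene1[i], pairs$gene2[i])
    expect_gte(d$mean_path, st$truth$config$none_min_separation - 1)
  }
})

test_that("planted sequence identities separate within from between families", {
  st <- generate_study(small_cfg(seed = 21))
  multi <- st$families$families[lengths(st$families$families) > 1L]
  expect_gte(length(multi), 3L)
  take <- multi[1:3]
  prot <- st$proteome[unlist(take)]
  idm <- pairwise_identity(prot)
  for (fi in seq_along(take)) {
    within <- idm[take[[fi]], take[[fi]]]
    expect_gt(min(within), 30)
    for (fj in seq_len(fi - 1L))
      expect_lt(max(idm[take[[fi]], take[[fj]]]), 25)
  }
  # alignment-based family recovery agrees with the planted partition
  fs <- build_paralogy_families(prot, threshold = 30)
  expect_setequal(unname(lapply(fs$families, sort)),
                  unname(lapply(take, sort)))
})

test_that("both dialect emissions parse back to the same network", {
  st <- generate_study(small_cfg(seed = 8))
  dir <- withr::local_tempdir()
  paths <- write_study(st, dir)
  recs_b <- parse_biocyc_bundle(paths$pathways, paths$enzrxns,
                                paths$complexes)
  recs_k <- parse_kegg_bundle(paths$reaction_list, paths$kgml)
  net0 <- build_metabolic_network(st$reactions)
  net_b <- build_metabolic_network(recs_b)
  net_k <- build_metabolic_network(recs_k)
  canon <- function(n) {
    e <- n$edges[order(n$edges$from, n$edges$to, n$edges$enzyme,
                       n$edges$reaction), c("from", "to", "enzyme",
                                            "reaction", "reverse")]
    rownames(e) <- NULL
    e
  }
  expect_equal(canon(net_b), canon(net0))
  expect_equal(canon(net_k), canon(net0))
  # currency metabolites never leak through either reader
  expect_false(any(c("ATP", "ADP") %in% net_b$nodes))
  expect_false(any(c("ATP", "ADP") %in% net_k$nodes))
  # pathway annotations survive both dialects
  expect_setequal(names(net_b$pathways), names(net_k$pathways))
  for (e in names(net_b$pathways))
    expect_setequal(net_b$pathways[[e]], net_k$pathways[[e]])
})

test_that("the worked toy carries its promised structure", {
  toy <- generate_worked_toy()
  expect_length(toy$network$nodes, 6L)
  expect_length(network_enzymes(toy$network), 5L)
  expect_equal(enzyme_dice_m(toy$network, toy$full_pair[1],
                             toy$full_pair[2]), 1)
  expect_equal(enzyme_dice_m(toy$network, toy$none_pair[1],
                             toy$none_pair[2]), 0)
  d <- pair_metabolite_distance(toy$network, toy$contiguous_pair[1],
                                toy$contiguous_pair[2])
  expect_equal(d$mean_path, 1)
  # the FULL pair's sequences are mutually paralogous at 30% identity
  idm <- pairwise_identity(toy$proteome)
  expect_gt(idm["E1", "E2"], 30)
})

test_that("infeasible configurations are rejected up front", {
  expect_error(synthetic_config(f_full = 0.5, f_partial = 0.4,
                                f_none = 0.2), "sum to 1")
  expect_error(synthetic_config(missing_rate = 1.2), "fractions")
  expect_error(generate_study(
    synthetic_config(n_scaffold_reactions = 10, n_families = 40,
                     f_full = 0, f_partial = 1, f_none = 0)),
    "infeasible")
})
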