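mp <- function(...) {
  v <- c(...)
  data.frame(from = v[c(TRUE, FALSE)], to = v[c(FALSE, TRUE)])
}

test_that("Dice_M follows set arithmetic and matches brute-force counting", {
  expect_equal(dice_m(mp("A", "B"), mp("A", "B")), 1)
  expect_equal(dice_m(mp("A", "B"), mp("C", "D")), 0)
  expect_equal(dice_m(mp("A", "B", "C", "D"), mp("A", "B")), 2 / 3)
  expect_true(is.na(dice_m(mp(), mp())))
  # symmetry, bounds, and brute-force agreement on random profiles
  set.seed(8)
  mets <- paste0("M", 1:6)
  for (rep in 1:40) {
    p1 <- mp(sample(mets, 2), sample(mets, 2), sample(mets, 2))
    p2 <- mp(sample(mets, 2), sample(mets, 2))
    d <- dice_m(p1, p2)
    expect_equal(d, dice_m(p2, p1))
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, dice_brute(unique(p1), unique(p2)))
  }
})

test_that("Dice_P handles identical, disjoint and partial pathway sets", {
  expect_equal(dice_p("p1", "p1"), 1)
  expect_equal(dice_p("p1", "p2"), 0)
  expect_equal(dice_p(c("p1", "p2", "p3"), "p1"), 0.5)
  expect_true(is.na(dice_p(character(), "p1")))
})

test_that("per-enzyme Dice_M flags enzymes absent from the network", {
  net <- toy_network()
  expect_equal(enzyme_dice_m(net, "E1", "E2"), 1)
  expect_true(is.na(enzyme_dice_m(net, "E1", "missing")))
  expect_equal(levels(classify_overlap(c(1, 0.4, 0))),
               c("FULL", "PARTIAL", "NONE"))
  expect_equal(as.character(classify_overlap(c(1, 0.4, 0, NA))),
               c("FULL", "PARTIAL", "NONE", NA))
})

test_that("the random-pair null matches exhaustive enumeration", {
  # degenerate networks first
  iso <- build_metabolic_network(list(
    reaction_record("R1", "A", "B", enzymes = c("E1", "E2", "E3"))))
  expect_true(all(random_pair_null(iso, 500, seed = 1)$dice == 1))
  disj <- build_metabolic_network(lapply(1:4, function(i)
    reaction_record(paste0("R", i), paste0("A", i), paste0("B", i),
                    enzymes = paste0("E", i))))
  expect_true(all(random_pair_null(disj, 500, seed = 1)$dice == 0))

  # planted overlap structure: sampled histogram vs all-pairs enumeration
  set.seed(14)
  recs <- random_records(8, 25)
  net <- build_metabolic_network(recs)
  enz <- network_enzymes(net)
  exact <- unlist(lapply(seq_along(enz), function(i)
    lapply(seq_len(i - 1L), function(j)
      enzyme_dice_m(net, enz[i], enz[j]))))
  null <- random_pair_null(net, 2e4, seed = 99)
  expect_equal(mean(null$dice), mean(exact), tolerance = 0.05)
  expect_equal(mean(null$dice == 0), mean(exact == 0), tolerance = 0.05)
  expect_equal(sum(null$histogram$count), 2e4)
  expect_equal(sum(null$histogram$fraction), 1, tolerance = 1e-9)
})

test_that("pair metabolite distances follow the stated conventions", {
  chain <- build_metabolic_network(list(
    reaction_record("R1", "A", "B", enzymes = "E1"),
    reaction_record("R2", "B", "C", enzymes = "E2")))
  d <- pair_metabolite_distance(chain, "E1", "E2")
  expect_equal(d$mean_path, 1)          # distances 1, 2, 0, 1
  expect_equal(d$n_pairs_used, 4L)

  both <- build_metabolic_network(list(
    reaction_record("R1", "A", "B", enzymes = c("E1", "E2"))))
  expect_equal(pair_metabolite_distance(both, "E1", "E2")$mean_path, 0.5)

  disc <- build_metabolic_network(list(
    reaction_record("R1", "A", "B", enzymes = "E1"),
    reaction_record("R2", "C", "D", enzymes = "E2")))
  dd <- pair_metabolite_distance(disc, "E1", "E2")
  expect_true(is.na(dd$mean_path))
  expect_equal(dd$n_unreachable, 4L)

  # invariance under metabolite relabelling (graph isomorphism)
  set.seed(44)
  recs <- random_records(9, 14)
  net1 <- build_metabolic_network(recs)
  perm <- setNames(paste0("Z", seq_along(net1$nodes)), net1$nodes)
  recs2 <- lapply(recs, function(r) {
    r$substrates <- unname(perm[r$substrates])
    r$products <- unname(perm[r$products])
    r
  })
  net2 <- build_metabolic_network(recs2)
  enz <- network_enzymes(net1)
  for (i in 1:3) {
    pr <- sample(enz, 2)
    expect_equal(pair_metabolite_distance(net1, pr[1], pr[2])$mean_path,
                 pair_metabolite_distance(net2, pr[1], pr[2])$mean_path)
  }
})

test_that("hypergeometric upper tail matches full enumeration for all N <= 12", {
  expect_equal(hypergeometric_enrichment(0, 3, 4, 10)$p_value, 1)
  expect_equal(hypergeometric_enrichment(3, 3, 10, 10)$p_value, 1)
  expect_equal(hypergeometric_enrichment(3, 3, 4, 10)$p_value, 4 / 120)
  expect_error(hypergeometric_enrichment(5, 3, 4, 10), "inconsistent")
  tab <- hyper_oracle_table(8)
  expect_equal(tab$p_impl, tab$p_enum, tolerance = 1e-12)
})

test_that("expression filtering removes columns before rows", {
  set.seed(2)
  m <- matrix(rnorm(400), 20, 20,
              dimnames = list(paste0("g", 1:20), paste0("e", 1:20)))
  expect_equal(filter_expression_matrix(m), m)   # complete: unchanged
  m1 <- m
  m1[1:6, 1] <- NA                      # column e1 30% missing
  m1[c(1, 7:11), 2] <- NA               # column e2 30% missing
  f1 <- filter_expression_matrix(m1)
  expect_equal(ncol(f1), 18L)
  expect_false(any(c("e1", "e2") %in% colnames(f1)))
  # g1 is 10% missing overall, but only inside the removed columns, so
  # the columns-then-rows order rescues it
  expect_gt(mean(is.na(m1["g1", ])), 0.05)
  expect_true("g1" %in% rownames(f1))
  m2 <- m1
  m2[3, 5:7] <- NA                      # >5% missing in surviving columns
  expect_false("g3" %in% rownames(filter_expression_matrix(m2)))
  expect_warning(filter_expression_matrix(matrix(NA_real_, 2, 2)), "empty")
})

test_that("expression correlation matches the closed-form t transform", {
  m <- rbind(g1 = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
             g2 = c(2.1, 3.9, 6.2, 8.1, 9.9, 12.2, 13.8, 16.1, 18.0, 20.2),
             g3 = -c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
             g4 = rep(1, 10))
  colnames(m) <- paste0("e", 1:10)
  self <- expression_correlation(rbind(m, g1b = m["g1", ]), "g1", "g1b")
  expect_equal(self$r, 1)
  expect_equal(expression_correlation(m, "g1", "g3")$r, -1)
  expect_true(is.na(expression_correlation(m, "g1", "g4")$r)) # zero var
  # hand computation of the sums for g1 vs g2
  x <- m["g1", ]; y <- m["g2", ]
  n <- 10
  r_hand <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  got <- expression_correlation(m, "g1", "g2")
  expect_equal(got$r, r_hand)
  ct <- cor.test(x, y)
  expect_equal(got$r, unname(ct$estimate))
  expect_equal(got$p_value, ct$p.value)
  # pairwise-complete handling and the < 3 pairs contract
  m2 <- m
  m2["g2", 1:8] <- NA
  expect_true(is.na(expression_correlation(m2, "g1", "g2")$r))
  m2["g2", 1:6] <- 0
  expect_equal(expression_correlation(m2, "g1", "g2")$n_used, 8L)
})

test_that("overlap tables and summaries tabulate classes, ages and divergent pairs", {
  toy <- generate_worked_toy()
  fs <- toy$families
  pairs <- enumerate_network_pairs(fs, toy$network)
  tab <- overlap_table(pairs, list(ybp = toy$network), ages = fs)
  expect_equal(nrow(tab), 2L)
  full_row <- tab[tab$gene1 == "E1", ]
  expect_equal(full_row$dice_m_ybp, 1)
  expect_equal(as.character(full_row$class_ybp), "FULL")
  expect_equal(full_row$age, "WGD")
  none_row <- tab[tab$gene1 == "E3", ]
  expect_equal(none_row$dice_m_ybp, 0)
  expect_equal(none_row$age, "PRE_WGD_EUASCOMYCETES")
  expect_equal(none_row$dice_p, 0)     # P1 vs P2
  expect_gte(none_row$mean_path, 2)    # distant in the chain

  s <- summarise_overlap(tab)
  fr <- s$fractions
  expect_equal(fr$fraction[fr$class == "FULL"], 0.5)
  expect_equal(fr$fraction[fr$class == "NONE"], 0.5)
  expect_equal(nrow(s$divergent), 1L)
  en <- s$enrichment
  oldest <- en[en$age == "PRE_WGD_EUASCOMYCETES", ]
  expect_equal(oldest$k, 1L)
  expect_equal(oldest$p_value,
               hyper_upper_enum(1, 1, 1, 2))    # = 0.5
  expect_true(all(en$p_bonferroni >= en$p_value))
})
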