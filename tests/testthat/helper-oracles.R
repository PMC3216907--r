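# Independent oracles used to cross-check the package implementations.

# Floyd-Warshall all-pairs shortest paths on the undirected simple view
# of an edge data frame (columns from/to). Independent of igraph.
fw_distances <- function(edges, nodes) {
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]
    if (a != b) d[a, b] <- d[b, a] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# Iterative Gotoh three-state affine-gap global alignment returning the
# optimal score only. Written directly from the recurrences, separately
# from the compiled implementation; validated below against full
# alignment enumeration on tiny inputs.
gotoh_score <- function(s1, s2, submat, gap_open, gap_extend) {
  a1 <- strsplit(s1, "")[[1]]; a2 <- strsplit(s2, "")[[1]]
  n <- length(a1); m <- length(a2)
  NEG <- -1e30
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(gap_open + i * gap_extend)
  for (j in seq_len(m)) Y[1, j + 1] <- -(gap_open + j * gap_extend)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- submat[a1[i], a2[j]]
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                             X[i, j + 1] - gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                             Y[i + 1, j] - gap_extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Exhaustive enumeration of every global alignment (as a sequence of
# match/insert/delete columns), scoring gaps with the same affine rule;
# returns the best score. Exponential: only for very short sequences.
enum_best_score <- function(s1, s2, submat, gap_open, gap_extend) {
  a1 <- strsplit(s1, "")[[1]]; a2 <- strsplit(s2, "")[[1]]
  best <- -Inf
  # state: 0 none, 1 in gap consuming s1, 2 in gap consuming s2
  rec <- function(i, j, score, state) {
    if (i > length(a1) && j > length(a2)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(a1) && j <= length(a2))
      rec(i + 1, j + 1, score + submat[a1[i], a2[j]], 0)
    if (i <= length(a1))
      rec(i + 1, j, score - gap_extend -
            if (state == 1) 0 else gap_open, 1)
    if (j <= length(a2))
      rec(i, j + 1, score - gap_extend -
            if (state == 2) 0 else gap_open, 2)
  }
  rec(1, 1, 0, 0)
  best
}

# Score an already-aligned pair of gapped strings under the affine rule.
score_gapped <- function(g1, g2, submat, gap_open, gap_extend) {
  c1 <- strsplit(g1, "")[[1]]; c2 <- strsplit(g2, "")[[1]]
  stopifnot(length(c1) == length(c2))
  score <- 0; state <- 0
  for (k in seq_along(c1)) {
    if (c1[k] == "-") {
      score <- score - gap_extend - if (state == 2) 0 else gap_open
      state <- 2
    } else if (c2[k] == "-") {
      score <- score - gap_extend - if (state == 1) 0 else gap_open
      state <- 1
    } else {
      score <- score + submat[c1[k], c2[k]]
      state <- 0
    }
  }
  score
}

# Upper-tail hypergeometric probability by exhaustive enumeration of
# all C(N, n) draws from a population with K successes.
hyper_upper_enum <- function(k, n, K, N) {
  if (n == 0) return(if (k <= 0) 1 else 0)
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# Brute-force Dice over two explicit pair lists: double loop counting.
dice_brute <- function(p1, p2) {
  shared <- 0L
  seen <- character()
  for (i in seq_len(nrow(p1))) {
    key1 <- paste(p1$from[i], p1$to[i])
    if (key1 %in% seen) next
    seen <- c(seen, key1)
    for (j in seq_len(nrow(p2))) {
      if (p1$from[i] == p2$from[j] && p1$to[i] == p2$to[j]) {
        shared <- shared + 1L
        break
      }
    }
  }
  u1 <- nrow(unique(p1)); u2 <- nrow(unique(p2))
  2 * shared / (u1 + u2)
}

# All sequences of a given length over an alphabet.
all_seqs <- function(len, alphabet) {
  if (len == 0) return(character())
  grid <- do.call(expand.grid, rep(list(alphabet), len))
  apply(grid, 1, paste0, collapse = "")
}

# Batch check of the compiled aligner against the independent oracle:
# for each sequence pair, the emitted alignment must score exactly the
# Gotoh-oracle optimum and identity must recompute from the emitted
# alignment. Returns a data frame of observed vs expected vectors.
alignment_oracle_table <- function(s1s, s2s, gap_open = 5,
                                   gap_extend = 0.5) {
  sub <- blosum62_acd()
  params <- alignment_params(gap_open = gap_open,
                             gap_extend = gap_extend)
  out <- vapply(seq_along(s1s), function(i) {
    res <- global_percent_identity(s1s[i], s2s[i], params)
    c1 <- strsplit(res$aligned1, "")[[1]]
    c2 <- strsplit(res$aligned2, "")[[1]]
    aligned <- c1 != "-" & c2 != "-"
    c(score_emitted = score_gapped(res$aligned1, res$aligned2, sub,
                                   gap_open, gap_extend),
      score_oracle = gotoh_score(s1s[i], s2s[i], sub, gap_open,
                                 gap_extend),
      identity = res$identity,
      identity_recount = 100 * sum(aligned & c1 == c2) / length(c1))
  }, numeric(4))
  as.data.frame(t(out))
}

# Implementation vs enumeration oracle for every hypergeometric
# parameter combination with N <= n_max.
hyper_oracle_table <- function(n_max) {
  rows <- list()
  for (N in 1:n_max) for (K in 0:N) for (n in 0:N)
    for (k in 0:min(n, K)) {
      rows[[length(rows) + 1L]] <- data.frame(
        N = N, K = K, n = n, k = k,
        p_impl = hypergeometric_enrichment(k, n, K, N)$p_value,
        p_enum = hyper_upper_enum(k, n, K, N))
    }
  do.call(rbind, rows)
}
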