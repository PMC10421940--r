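# Independent oracles and small builders shared across the suite.

# two alignment rows forming one read pair; dummy sequence unless given
make_pair <- function(id, chrom1, pos1, chrom2, pos2, len = 100,
                      seq1 = NULL, seq2 = NULL,
                      strand1 = "+", strand2 = "-") {
  seq1 <- seq1 %||% strrep("A", len)
  seq2 <- seq2 %||% strrep("A", len)
  data.frame(read_id = id,
             chrom = c(chrom1, chrom2), pos = as.integer(c(pos1, pos2)),
             strand = c(strand1, strand2), seq = c(seq1, seq2),
             mate_chrom = c(chrom2, chrom1),
             mate_pos = as.integer(c(pos2, pos1)),
             first_in_pair = c(TRUE, FALSE), stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force single-linkage clustering: pairwise distance graph plus
# connected components by breadth-first search
oracle_cluster <- function(pairs, d = 500) {
  n <- nrow(pairs)
  if (n == 0) return(integer(0))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      adj[i, j] <- pairs$chromA[i] == pairs$chromA[j] &&
        pairs$chromB[i] == pairs$chromB[j] &&
        pairs$strandA[i] == pairs$strandA[j] &&
        pairs$strandB[i] == pairs$strandB[j] &&
        abs(pairs$posA[i] - pairs$posA[j]) < d &&
        abs(pairs$posB[i] - pairs$posB[j]) < d
    }
  }
  comp <- rep(NA_integer_, n)
  cc <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cc <- cc + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cc
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# clusters as canonical sets of read ids, for order-independent comparison
cluster_id_sets <- function(clusters) {
  sets <- lapply(clusters, function(cl) sort(cl$members$read_id))
  sets[order(vapply(sets, paste, character(1), collapse = ","))]
}

# two-sided Fisher p by full hypergeometric enumeration over all tables
# with the observed margins: sum of P(table) for P(table) <= P(observed)
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact two-sided rank-sum p by enumeration of all group assignments
oracle_ranksum_p <- function(x, y) {
  all_v <- c(x, y)
  nx <- length(x)
  idx <- utils::combn(length(all_v), nx)
  obs <- sum(rank(all_v)[seq_len(nx)])
  stats_all <- apply(idx, 2, function(i) sum(rank(all_v)[i]))
  mu <- nx * (length(all_v) + 1) / 2
  mean(abs(stats_all - mu) >= abs(obs - mu) - 1e-9)
}

# expected in-frame state from exon lengths: retained partner coding
# length and the coding length the kinase gene loses must agree mod 3
oracle_in_frame <- function(partner_lens, k_partner, ntrk_lens, k_ntrk) {
  sum(partner_lens[seq_len(k_partner)]) %% 3 ==
    sum(ntrk_lens[seq_len(k_ntrk)]) %% 3
}

# a planted event in the same canonical form call_fusions reports
canonical_event <- function(event) {
  canonical_call(list(chromA = event$chromA, posA = event$posA,
                      strandA = event$strandA, chromB = event$chromB,
                      posB = event$posB, strandB = event$strandB))
}

expect_call_matches <- function(call_row, event, tol = 5) {
  truth <- canonical_event(event)
  expect_equal(call_row$chromA, truth$chromA)
  expect_equal(call_row$chromB, truth$chromB)
  expect_lte(abs(call_row$posA - truth$posA), tol)
  expect_lte(abs(call_row$posB - truth$posB), tol)
  expect_equal(call_row$strandA, truth$strandA)
  expect_equal(call_row$strandB, truth$strandB)
}
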