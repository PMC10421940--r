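test_that("discordance uses mate chromosomes and the strict insert boundary", {
  inter <- make_pair("r1", "chr1", 1000, "chr2", 5000)
  disc <- collect_discordant(inter)
  expect_equal(nrow(disc), 1)
  expect_equal(disc$reason, "interchromosomal")
  expect_true(is.na(disc$insert))

  # outer insert 2001 is discordant, 2000 is not (strict > 2000)
  over <- make_pair("r2", "chr1", 1000, "chr1", 2901)
  at <- make_pair("r3", "chr1", 1000, "chr1", 2900)
  expect_equal(collect_discordant(over)$reason, "long-insert")
  expect_equal(collect_discordant(over)$insert, 2001)
  expect_equal(nrow(collect_discordant(at)), 0)

  expect_equal(nrow(collect_discordant(empty_records())), 0)

  # unpaired ids are skipped with a warning
  orphan <- rbind(inter, make_pair("r4", "chr1", 1, "chr1", 5000)[1, ])
  expect_warning(out <- collect_discordant(orphan), "skipped")
  expect_equal(nrow(out), 1)
})

test_that("clustering chains pairs under the distance rule, order-independently", {
  p <- rbind(make_pair("a", "chr1", 100, "chr2", 1000),
             make_pair("b", "chr1", 550, "chr2", 1100))
  cl <- cluster_discordant(collect_discordant(p))
  expect_length(cl, 1)
  expect_equal(cl[[1]]$unique_pairs, 2)

  q <- rbind(make_pair("a", "chr1", 100, "chr2", 1000),
             make_pair("b", "chr1", 700, "chr2", 1000))
  expect_length(cluster_discordant(collect_discordant(q)), 2)

  # exact boundary: 499 links, 500 does not
  near <- rbind(make_pair("a", "chr1", 100, "chr2", 1000),
                make_pair("b", "chr1", 599, "chr2", 1000))
  far <- rbind(make_pair("a", "chr1", 100, "chr2", 1000),
               make_pair("b", "chr1", 600, "chr2", 1000))
  expect_length(cluster_discordant(collect_discordant(near)), 1)
  expect_length(cluster_discordant(collect_discordant(far)), 2)

  # permutation invariance
  set.seed(1)
  many <- do.call(rbind, lapply(1:20, function(i) {
    make_pair(sprintf("r%02d", i), "chr1",
              sample(c(1000, 1400, 5000), 1) + sample(0:300, 1),
              "chr2", sample(c(2000, 9000), 1) + sample(0:300, 1))
  }))
  pairs <- collect_discordant(many)
  shuffled <- pairs[sample(nrow(pairs)), ]
  expect_identical(cluster_id_sets(cluster_discordant(pairs)),
                   cluster_id_sets(cluster_discordant(shuffled)))
})

test_that("clustering equals the brute-force single-linkage oracle", {
  for (s in 1:5) {
    set.seed(s)
    n <- 40
    pairs <- do.call(rbind, lapply(seq_len(n), function(i) {
      make_pair(sprintf("r%03d", i),
                sample(c("chr1", "chr2"), 1), sample(1:4000, 1),
                "chr3", sample(1:4000, 1))
    }))
    pairs <- collect_discordant(pairs)
    comp <- oracle_cluster(pairs, 500)
    got <- cluster_discordant(pairs, 500)
    oracle_sets <- lapply(split(pairs$read_id, comp), sort)
    oracle_sets <- unname(oracle_sets[order(vapply(oracle_sets, paste,
                                                   character(1),
                                                   collapse = ","))])
    expect_identical(cluster_id_sets(got), oracle_sets)
  }
})

test_that("greedy assembly reconstructs a tiled junction sequence", {
  set.seed(7)
  truth <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                 collapse = "")
  starts <- seq(1, 201, by = 10)
  reads <- substring(truth, starts, starts + 99)
  contig <- assemble_contig(reads, min_overlap = 20)
  expect_true(grepl(truth, contig, fixed = TRUE) ||
                grepl(ntrkscan:::revcomp(truth), contig, fixed = TRUE))

  expect_equal(assemble_contig(c(reads[1], reads[1])), reads[1])
  expect_null(assemble_contig(c(strrep("A", 50), strrep("C", 50))))
  expect_error(assemble_contig("ACGT"), "two reads")
})

test_that("split realignment confirms planted junctions and rejects chimeras", {
  ref <- make_reference(2, 50000, seed = 7)
  ev <- planted_fusion("chr1", 20000, "+", "chr2", 30000, "+", 8)
  contig <- ntrkscan:::fused_segment(ref, ev, -80L, 80L)
  res <- confirm_breakpoint(contig, ref)
  expect_true(res$confirmed)
  expect_lte(abs(res$posA - 20000), 5)
  expect_lte(abs(res$posB - 30000), 5)
  expect_equal(c(res$chromA, res$chromB), c("chr1", "chr2"))

  # same left flank, random right flank: unconfirmed
  set.seed(9)
  fake <- paste0(substring(contig, 1, 80),
                 paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
                       collapse = ""))
  expect_false(confirm_breakpoint(fake, ref)$confirmed)

  # reverse-strand 3' segment is recovered with strandB = "-"
  evm <- planted_fusion("chr1", 20000, "+", "chr2", 30000, "-", 8)
  cm <- ntrkscan:::fused_segment(ref, evm, -80L, 80L)
  resm <- confirm_breakpoint(cm, ref)
  expect_true(resm$confirmed)
  expect_equal(resm$strandB, "-")
  expect_lte(abs(resm$posB - 30000), 5)

  # a fully reference-concordant contig is not a fusion
  plain <- as.character(Biostrings::subseq(ref[["chr1"]], 1000, 1200))
  expect_false(confirm_breakpoint(plain, ref)$confirmed)
})

test_that("support filter applies the five-pair rule after deduplication", {
  calls <- data.frame(unique_pairs = c(5, 4, 7))
  expect_equal(filter_support(calls)$unique_pairs, c(5, 7))
  expect_equal(nrow(filter_support(calls[0, , drop = FALSE])), 0)

  # 8 pairs collapsing to 3 distinct start tuples count as 3
  dup <- do.call(rbind, lapply(1:8, function(i) {
    make_pair(sprintf("d%d", i), "chr1", c(100, 100, 150)[i %% 3 + 1],
              "chr2", c(900, 900, 950)[i %% 3 + 1])
  }))
  cl <- cluster_discordant(collect_discordant(dup))
  expect_length(cl, 1)
  expect_equal(cl[[1]]$unique_pairs, 2)  # tuples (100,900) and (150,950)
  expect_equal(nrow(filter_support(
    data.frame(unique_pairs = cl[[1]]$unique_pairs), 5)), 0)
})

test_that("pipeline recovers every well-supported planted event within 5 bp", {
  for (s in 1:20) {
    ref <- make_reference(2, 30000, seed = s)
    ev <- planted_fusion("chr1", 5000 + 997 * (s %% 20), "+",
                         "chr2", 6000 + 883 * (s %% 22), "+",
                         n_support_pairs = 5 + s %% 6)
    rec <- simulate_fusion_reads(ref, ev, background_pairs = 200, seed = s)
    calls <- suppressMessages(call_fusions(rec, ref))
    expect_equal(nrow(calls), 1)
    expect_call_matches(calls[1, ], ev)
    expect_equal(calls$unique_pairs, ev$n_support_pairs)
  }
})

test_that("background-only read sets yield zero calls", {
  for (s in 1:20) {
    ref <- make_reference(2, 30000, seed = 100 + s)
    rec <- simulate_fusion_reads(ref, NULL, background_pairs = 2000,
                                 seed = s)
    expect_equal(nrow(suppressMessages(call_fusions(rec, ref))), 0)
  }
})

test_that("relaxing thresholds never shrinks the call set", {
  ref <- make_reference(2, 30000, seed = 3)
  ev1 <- planted_fusion("chr1", 8000, "+", "chr2", 9000, "+", 6)
  ev2 <- planted_fusion("chr1", 20000, "+", "chr2", 21000, "+", 3)
  r1 <- simulate_fusion_reads(ref, ev1, background_pairs = 100, seed = 1)
  r2 <- simulate_fusion_reads(ref, ev2, seed = 2)
  r2$read_id <- paste0("e2_", r2$read_id)
  rec <- rbind(r1, r2)
  strict <- suppressMessages(call_fusions(rec, ref, min_support = 5))
  loose <- suppressMessages(call_fusions(rec, ref, min_support = 3))
  expect_equal(nrow(strict), 1)
  expect_equal(nrow(loose), 2)
  key <- function(x) paste(x$chromA, x$posA, x$chromB, x$posB)
  expect_true(all(key(strict) %in% key(loose)))
  wide <- suppressMessages(call_fusions(rec, ref, min_support = 3,
                                        cluster_distance = 800))
  expect_true(all(key(loose) %in% key(wide)))
})
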