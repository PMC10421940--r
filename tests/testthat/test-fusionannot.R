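models <- toy_gene_models()

mk_call <- function(cA, pA, sA, cB, pB, sB) {
  list(chromA = cA, posA = pA, strandA = sA,
       chromB = cB, posB = pB, strandB = sB)
}

intron_pos <- function(gene, k, offset = 150) {
  ex <- models[[gene]]$exons
  # midpoint-ish position inside transcript intron k (plus-strand genes)
  as.integer(ex$end[ex$ordinal == k] + offset)
}

test_that("breakpoints map to genes with clinical exon-composition labels", {
  ann <- annotate_fusion(mk_call("chr12", intron_pos("ETV6", 5), "+",
                                 "chr15", intron_pos("NTRK3", 14), "+"),
                         models)
  expect_equal(ann$fusion, "ETV6 exon1-5-NTRK3 exon15-19")
  expect_equal(ann$classification, "Definite")
  expect_equal(ann$rearrangement_type, "interchromosomal")
  expect_equal(ann$novelty, "Reported")

  ann2 <- annotate_fusion(mk_call("chr1", intron_pos("LMNA", 2), "+",
                                  "chr1", intron_pos("NTRK1", 10), "+"),
                          models)
  expect_equal(ann2$fusion, "LMNA exon1-2-NTRK1 exon11-17")
  expect_equal(ann2$rearrangement_type, "intrachromosomal")

  # one base before the gene span is intergenic, call not reportable
  before <- models$ETV6$span[1] - 1L
  ann3 <- annotate_fusion(mk_call("chr12", before, "+",
                                  "chr15", intron_pos("NTRK3", 14), "+"),
                          models)
  expect_equal(ann3$classification, "NotReportable")
  expect_true(is.na(ann3$partner))
})

test_that("exon and intron positions get transcript-order ordinals", {
  m <- models$NTRK3
  ex5 <- m$exons[m$exons$ordinal == 5, ]
  expect_equal(locate_in_gene(m, ex5$start), list(region = "exon",
                                                  ordinal = 5))
  expect_equal(locate_in_gene(m, ex5$end)$region, "intron")
  expect_null(locate_in_gene(m, m$span[2]))
  # minus-strand gene: ordinals count from the genomic right
  tm <- models$TPM3
  first <- tm$exons[tm$exons$ordinal == 1, ]
  expect_equal(max(tm$exons$end), first$end)
  expect_equal(locate_in_gene(tm, first$start), list(region = "exon",
                                                     ordinal = 1))
})

test_that("in-strand requires exactly one transcription start across the junction", {
  pA <- intron_pos("ETV6", 5)
  pB <- intron_pos("NTRK3", 14)
  for (sA in c("+", "-")) for (sB in c("+", "-")) {
    mapping <- map_breakpoints_to_genes(mk_call("chr12", pA, sA,
                                                "chr15", pB, sB), models)
    frame <- junction_frame(mapping)
    # both genes on +: (+,+) fuses ETV6 5' to NTRK3 3'; (-,-) is the
    # reciprocal in-strand chimera with NTRK3 donating its 5' end; the
    # mixed orientations join two 5' or two 3' ends and cannot transcribe
    expect_equal(frame$in_strand, sA == sB,
                 info = paste(sA, sB))
    if (!frame$in_strand) expect_false(frame$in_frame)
    if (sA == "+" && sB == "+") expect_equal(mapping$five$gene, "ETV6")
    if (sA == "-" && sB == "-") expect_equal(mapping$five$gene, "NTRK3")
  }
  # minus-strand partner contributes its 5' end from above the breakpoint
  tp <- models$TPM3$exons
  tpos <- as.integer(tp$end[tp$ordinal == 8] + 50)  # transcript intron 7
  m2 <- map_breakpoints_to_genes(mk_call("chr1", tpos, "-", "chr1",
                                         intron_pos("NTRK1", 8), "+"),
                                 models)
  expect_true(junction_frame(m2)$in_strand)
  expect_equal(m2$five$gene, "TPM3")
})

test_that("frame state matches the modular-arithmetic oracle over all introns", {
  lmna <- models$LMNA; ntrk1 <- models$NTRK1
  for (kp in 1:(nrow(lmna$exons) - 1)) {
    for (kn in c(7, 8, 10, 12)) {
      call <- mk_call("chr1", intron_pos("LMNA", kp), "+",
                      "chr1", intron_pos("NTRK1", kn), "+")
      frame <- junction_frame(map_breakpoints_to_genes(call, models))
      expect_equal(frame$in_frame,
                   oracle_in_frame(lmna$exon_lens, kp,
                                   ntrk1$exon_lens, kn),
                   info = sprintf("LMNA intron %d, NTRK1 intron %d", kp, kn))
    }
  }
})

test_that("frame is unchanged by exons downstream of the kinase domain", {
  with_extra <- c(models, list(
    NTRK1X = gene_model("NTRK1X", "chr9", "+", 30000,
                        c(models$NTRK1$exon_lens, 400),
                        kinase_exons = 13:17, hot_exons = 8:17)))
  p5 <- intron_pos("LMNA", 2)
  base <- junction_frame(map_breakpoints_to_genes(
    mk_call("chr1", p5, "+", "chr1", intron_pos("NTRK1", 10), "+"),
    models))
  ex <- with_extra$NTRK1X$exons
  posx <- as.integer(ex$end[ex$ordinal == 10] + 150)
  extended <- junction_frame(map_breakpoints_to_genes(
    mk_call("chr1", p5, "+", "chr9", posx, "+"), with_extra))
  expect_equal(extended$in_frame, base$in_frame)
})

test_that("classification follows the definite/likely decision rules", {
  expect_equal(classify_fusion(TRUE, TRUE, TRUE, FALSE, FALSE), "Definite")
  expect_equal(classify_fusion(TRUE, FALSE, TRUE, FALSE, TRUE), "Likely")
  expect_equal(classify_fusion(TRUE, FALSE, TRUE, TRUE, FALSE), "Likely")
  expect_equal(classify_fusion(TRUE, TRUE, FALSE, TRUE, TRUE),
               "NotReportable")
  expect_equal(classify_fusion(FALSE, TRUE, TRUE, FALSE, FALSE),
               "NotReportable")
  expect_equal(classify_fusion(TRUE, FALSE, TRUE, FALSE, FALSE),
               "NotReportable")
})

test_that("kinase-domain loss and non-coding partners are classified down", {
  # NTRK1 breakpoint inside the kinase domain (intron 14) loses part of it
  ann <- annotate_fusion(mk_call("chr1", intron_pos("LMNA", 2), "+",
                                 "chr1", intron_pos("NTRK1", 14), "+"),
                         models)
  expect_false(ann$kinase_retained)
  expect_equal(ann$classification, "NotReportable")

  # non-coding partner: frame undefined, rescued only by the hot exon
  lp <- models$LINC01197$exons$end[1] + 50
  ann2 <- annotate_fusion(mk_call("chr15", lp, "+",
                                  "chr15", intron_pos("NTRK3", 14), "+"),
                          models)
  expect_false(ann2$in_frame)
  expect_equal(ann2$classification, "Likely")
  expect_equal(ann2$novelty, "Novel")
})

test_that("rearrangement type depends only on chromosome identity", {
  expect_equal(rearrangement_type("chr1", "chr1"), "intrachromosomal")
  expect_equal(rearrangement_type("chr12", "chr15"), "interchromosomal")
  expect_equal(rearrangement_type("chr1", "chr1"), "intrachromosomal")
})

test_that("novelty lookup is case-insensitive against the knowledge base", {
  expect_equal(call_novelty("ETV6"), "Reported")
  expect_equal(call_novelty("etv6"), "Reported")
  expect_equal(call_novelty("INSRR"), "Novel")
  expect_error(call_novelty(""), "empty gene symbol")
})

test_that("published per-fusion records classify to 34 definite and 7 likely", {
  tab <- table2_patients()
  flags <- data.frame(
    in_strand = TRUE,
    in_frame = tab$classification == "Definite",
    kinase = TRUE,
    known = tab$novelty == "Reported",
    hot = tab$classification == "Likely" & tab$novelty == "Novel")
  got <- mapply(classify_fusion, flags$in_strand, flags$in_frame,
                flags$kinase, flags$known, flags$hot)
  expect_equal(sum(got == "Definite"), 34)
  expect_equal(sum(got == "Likely"), 7)
})

test_that("simulated reads round-trip through calling and annotation", {
  ref <- toy_model_reference(5)
  specs <- list(
    list(g5 = "ETV6", i5 = 5, g3 = "NTRK3", i3 = 14,
         want = "ETV6 exon1-5-NTRK3 exon15-19"),
    list(g5 = "LMNA", i5 = 2, g3 = "NTRK1", i3 = 10,
         want = "LMNA exon1-2-NTRK1 exon11-17"))
  for (sp in specs) {
    m5 <- models[[sp$g5]]; m3 <- models[[sp$g3]]
    ev <- planted_fusion(m5$chrom, intron_pos(sp$g5, sp$i5), "+",
                         m3$chrom, intron_pos(sp$g3, sp$i3), "+", 8)
    rec <- simulate_fusion_reads(ref, ev, background_pairs = 150, seed = 7)
    calls <- suppressMessages(call_fusions(rec, ref))
    expect_equal(nrow(calls), 1)
    ann <- annotate_fusion(as.list(calls[1, ]), models)
    expect_equal(ann$fusion, sp$want)
    expect_equal(ann$classification, "Definite")
  }
})

test_that("gene models survive a GFF3 round-trip", {
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gene_models(models, path)
  back <- read_gene_models(path)
  expect_setequal(names(back), names(models))
  for (g in names(models)) {
    expect_equal(unclass(back[[g]]), unclass(models[[g]]), info = g)
  }
  packaged <- read_gene_models(system.file("extdata", "toy_genes.gff3",
                                           package = "ntrkscan"))
  expect_equal(unclass(packaged$NTRK1), unclass(models$NTRK1))
})
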