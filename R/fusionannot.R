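#' Locate a genomic position within a gene model
#'
#' @param model a [gene_model()]
#' @param pos 0-based genomic coordinate
#' @return `NULL` when outside the gene span, otherwise a list with
#'   `region` ("exon" or "intron") and `ordinal` (transcript-order,
#'   1-based; intron k lies between exons k and k+1)
#' @export
locate_in_gene <- function(model, pos) {
  if (pos < model$span[1] || pos >= model$span[2]) return(NULL)
  ex <- model$exons[order(model$exons$start), ]
  hit <- which(pos >= ex$start & pos < ex$end)
  n <- nrow(ex)
  if (length(hit)) {
    return(list(region = "exon", ordinal = ex$ordinal[hit[1]]))
  }
  gi <- max(which(pos >= ex$end))  # genomic index of the exon to the left
  ord <- if (model$strand == "+") gi else n - gi
  list(region = "intron", ordinal = ord)
}

# genomic interval retained by one side of a call. The two sides of a
# call are oriented towards each other: side A with strand "+" retains
# the coordinates below its breakpoint, while side B with strand "+"
# retains the coordinates above its breakpoint ("-" flips either).
retained_interval <- function(model, pos, retains_lower) {
  if (retains_lower) c(model$span[1], pos) else c(pos, model$span[2])
}

# TRUE when the retained segment contains the gene's transcription start
retains_five_prime <- function(model, retains_lower) {
  (retains_lower && model$strand == "+") ||
    (!retains_lower && model$strand == "-")
}

overlap_len <- function(iv, starts, ends) {
  sum(pmax(0L, pmin(ends, iv[2]) - pmax(starts, iv[1])))
}

#' Assign a fusion call's breakpoints to genes
#'
#' Each breakpoint is assigned to the unique gene model overlapping it and
#' labelled exon-k or intron-k by transcript ordinal. The 5' partner is
#' the side whose retained segment carries its gene's transcription start
#' given the call orientation; the other side must contribute a gene 3'
#' end. Calls with an intergenic breakpoint are flagged not reportable;
#' breakpoints in overlapping genes raise an error listing the
#' candidates.
#'
#' @param call fusion call (row of [call_fusions()] output or list with
#'   `chromA, posA, strandA, chromB, posB, strandB`)
#' @param models named list of [gene_model()]s
#' @return list with `five` and `three` elements (`gene`, `model`,
#'   `region`, `ordinal`, `retained_exons`), plus `in_strand`; or a list
#'   with `intergenic = TRUE` when a breakpoint hits no gene
#' @export
map_breakpoints_to_genes <- function(call, models) {
  side <- function(chrom, pos, strand, is_a_side) {
    cand <- Filter(function(m) m$chrom == chrom && pos >= m$span[1] &&
                     pos < m$span[2], models)
    if (!length(cand)) return(NULL)
    if (length(cand) > 1) {
      stop("breakpoint ", chrom, ":", pos, " overlaps multiple genes: ",
           paste(vapply(cand, function(m) m$gene, character(1)),
                 collapse = ", "))
    }
    m <- cand[[1]]
    loc <- locate_in_gene(m, pos)
    retains_lower <- if (is_a_side) strand == "+" else strand == "-"
    list(gene = m$gene, model = m, region = loc$region,
         ordinal = loc$ordinal, pos = pos, retains_lower = retains_lower,
         five_prime = retains_five_prime(m, retains_lower))
  }
  a <- side(call$chromA, call$posA, call$strandA, TRUE)
  b <- side(call$chromB, call$posB, call$strandB, FALSE)
  if (is.null(a) || is.null(b)) {
    return(list(intergenic = TRUE))
  }
  # orientation-consistent chimera: exactly one side donates its 5' end
  in_strand <- xor(a$five_prime, b$five_prime)
  five <- if (a$five_prime) a else b
  three <- if (a$five_prime) b else a
  if (!in_strand) {
    # fall back to naming the NTRK gene as the 3' side for reporting
    is_ntrk <- function(s) grepl("^NTRK[123]$", s$gene)
    if (is_ntrk(a) && !is_ntrk(b)) { five <- b; three <- a }
    else { five <- a; three <- b }
  }
  n5 <- nrow(five$model$exons)
  k5 <- five$ordinal
  five$retained_exons <- seq_len(min(k5, n5))
  n3 <- nrow(three$model$exons)
  k3 <- if (three$region == "intron") three$ordinal + 1L else three$ordinal
  three$retained_exons <- seq(min(k3, n3), n3)
  list(five = five, three = three, in_strand = in_strand)
}

# coding bases of `model` inside the retained interval of one side
retained_cds_len <- function(model, pos, retains_lower) {
  if (!model$coding) return(NA_integer_)
  iv <- retained_interval(model, pos, retains_lower)
  overlap_len(iv, model$exons$start, model$exons$end)
}

#' Reading-frame and orientation state of a fusion junction
#'
#' In-strand means the genomic strands orient both transcripts 5' to 3'
#' contiguously across the junction. In-frame means the retained 5'
#' partner coding length is congruent (mod 3) to the coding length the
#' NTRK gene lost upstream of its breakpoint, so the kinase-domain codons
#' read through in register. Junctions in a non-coding partner have
#' undefined frame and are reported out-of-frame.
#'
#' @param mapping output of [map_breakpoints_to_genes()]
#' @return list with logicals `in_strand` and `in_frame`
#' @export
junction_frame <- function(mapping) {
  if (isTRUE(mapping$intergenic)) {
    return(list(in_strand = FALSE, in_frame = FALSE))
  }
  five <- mapping$five; three <- mapping$three
  if (!mapping$in_strand) {
    return(list(in_strand = FALSE, in_frame = FALSE))
  }
  ret5 <- retained_cds_len(five$model, five$pos, five$retains_lower)
  ret3 <- retained_cds_len(three$model, three$pos, three$retains_lower)
  if (is.na(ret5) || is.na(ret3)) {
    return(list(in_strand = TRUE, in_frame = FALSE))
  }
  skipped3 <- sum(three$model$exon_lens) - ret3
  in_frame <- (ret5 %% 3L) == (skipped3 %% 3L)
  list(in_strand = TRUE, in_frame = in_frame)
}

# the entire annotated kinase-domain interval must lie inside the
# retained portion of the NTRK side
kinase_retained <- function(three) {
  kd <- three$model$kinase_domain
  if (is.null(kd)) return(FALSE)
  iv <- retained_interval(three$model, three$pos, three$retains_lower)
  kd[1] >= iv[1] && kd[2] <= iv[2]
}

# an NTRK breakpoint is "hot" when it falls in a hot exon or in an intron
# adjacent to one
in_hot_exon <- function(three) {
  hot <- three$model$hot_exons
  if (!length(hot)) return(FALSE)
  k <- three$ordinal
  if (three$region == "exon") k %in% hot else (k %in% hot || (k + 1L) %in% hot)
}

#' Functional classification of a fusion
#'
#' Definite: in-strand, in-frame, kinase domain retained. Likely: kinase
#' domain retained with an out-of-frame (or out-of-strand) junction,
#' rescued by a known partner gene or a hot-exon breakpoint. Everything
#' else is not reportable.
#'
#' @param in_strand,in_frame,kinase,partner_known,hot_exon logical flags
#' @return "Definite", "Likely" or "NotReportable"
#' @export
classify_fusion <- function(in_strand, in_frame, kinase, partner_known,
                            hot_exon) {
  if (!kinase) return("NotReportable")
  if (in_strand && in_frame) return("Definite")
  if (partner_known || hot_exon) return("Likely")
  "NotReportable"
}

#' Rearrangement type of a breakpoint pair
#'
#' @param chromA,chromB chromosomes of the two breakpoints
#' @return "interchromosomal" or "intrachromosomal"
#' @export
rearrangement_type <- function(chromA, chromB) {
  ifelse(chromA == chromB, "intrachromosomal", "interchromosomal")
}

#' Reported fusion-partner knowledge base
#'
#' Partner gene symbols with previously reported NTRK fusions, packaged
#' as a TSV (user-extensible via the `path` argument).
#'
#' @param path optional path to a TSV with a `partner` column
#' @return uppercase character vector of partner symbols
#' @export
reported_partners <- function(path = NULL) {
  path <- path %||% system.file("extdata", "reported_partners.tsv",
                                package = "ntrkscan", mustWork = TRUE)
  toupper(utils::read.table(path, header = TRUE,
                            stringsAsFactors = FALSE)$partner)
}

#' Partner novelty
#'
#' @param partner 5' partner gene symbol
#' @param knowledge_base character vector of reported partner symbols
#' @return "Reported" or "Novel" (case-insensitive symbol match)
#' @export
call_novelty <- function(partner, knowledge_base = reported_partners()) {
  if (!nzchar(partner) || is.na(partner)) stop("empty gene symbol")
  if (toupper(partner) %in% toupper(knowledge_base)) "Reported" else "Novel"
}

format_exon_range <- function(r) {
  if (min(r) == max(r)) sprintf("exon%d", min(r))
  else sprintf("exon%d-%d", min(r), max(r))
}

#' Annotate and classify a confirmed fusion call
#'
#' Maps both breakpoints to gene models, resolves exon composition,
#' orientation, frame, kinase-domain retention, hot-exon status, partner
#' novelty and rearrangement type, and applies the definite/likely
#' classification.
#'
#' @param call fusion call (list or one-row data.frame with breakpoint
#'   fields)
#' @param models named list of [gene_model()]s
#' @param knowledge_base reported-partner symbols, see [call_novelty()]
#' @return one-row data.frame with columns `partner, ntrk_gene, fusion,
#'   exons5, exons3, in_strand, in_frame, kinase_retained, hot_exon,
#'   classification, rearrangement_type, novelty`
#' @export
annotate_fusion <- function(call, models,
                            knowledge_base = reported_partners()) {
  mapping <- map_breakpoints_to_genes(call, models)
  if (isTRUE(mapping$intergenic)) {
    return(data.frame(partner = NA_character_, ntrk_gene = NA_character_,
                      fusion = NA_character_, exons5 = NA_character_,
                      exons3 = NA_character_, in_strand = FALSE,
                      in_frame = FALSE, kinase_retained = FALSE,
                      hot_exon = FALSE, classification = "NotReportable",
                      rearrangement_type =
                        rearrangement_type(call$chromA, call$chromB),
                      novelty = NA_character_, stringsAsFactors = FALSE))
  }
  frame <- junction_frame(mapping)
  kin <- kinase_retained(mapping$three)
  hot <- in_hot_exon(mapping$three)
  partner <- mapping$five$gene
  known <- toupper(partner) %in% toupper(knowledge_base)
  cls <- classify_fusion(frame$in_strand, frame$in_frame, kin, known, hot)
  e5 <- format_exon_range(mapping$five$retained_exons)
  e3 <- format_exon_range(mapping$three$retained_exons)
  data.frame(
    partner = partner, ntrk_gene = mapping$three$gene,
    fusion = sprintf("%s %s-%s %s", partner, e5, mapping$three$gene, e3),
    exons5 = e5, exons3 = e3,
    in_strand = frame$in_strand, in_frame = frame$in_frame,
    kinase_retained = kin, hot_exon = hot, classification = cls,
    rearrangement_type = rearrangement_type(call$chromA, call$chromB),
    novelty = call_novelty(partner, knowledge_base),
    stringsAsFactors = FALSE)
}
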