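#' Construct a gene model
#'
#' A single canonical transcript per gene. Exon coordinates are 0-based
#' half-open genomic intervals, kept in transcript order (5' to 3'); for a
#' minus-strand gene exon 1 therefore has the highest genomic
#' coordinates. Toy models are fully coding unless `coding = FALSE`, so
#' CDS lengths equal exon lengths.
#'
#' @param gene gene symbol
#' @param chrom chromosome name
#' @param strand "+" or "-"
#' @param tx_start genomic start (0-based) of the gene span
#' @param exon_lens exon lengths in transcript order
#' @param intron_lens intron lengths in transcript order (length
#'   `length(exon_lens) - 1`, recycled)
#' @param kinase_exons exon ordinals spanned by the tyrosine kinase domain
#'   (NTRK genes), or NULL
#' @param hot_exons exon ordinals of recurrently rearranged ("hot") exons
#' @param coding FALSE for non-coding genes (frame undefined)
#' @return an object of class `gene_model`
#' @export
gene_model <- function(gene, chrom, strand, tx_start, exon_lens,
                       intron_lens = 300, kinase_exons = NULL,
                       hot_exons = integer(), coding = TRUE) {
  stopifnot(strand %in% c("+", "-"), length(exon_lens) >= 1)
  n <- length(exon_lens)
  intron_lens <- rep_len(intron_lens, max(1L, n - 1L))
  # lay the transcript out genomically left-to-right, then flip ordinals
  # for minus-strand genes
  lens_g <- if (strand == "+") exon_lens else rev(exon_lens)
  introns_g <- if (strand == "+") intron_lens else rev(intron_lens)
  starts <- integer(n)
  starts[1] <- as.integer(tx_start)
  if (n > 1) {
    for (i in 2:n) starts[i] <- starts[i - 1] + lens_g[i - 1] + introns_g[i - 1]
  }
  ends <- starts + lens_g
  ord_g <- if (strand == "+") seq_len(n) else rev(seq_len(n))
  exons <- data.frame(ordinal = ord_g, start = starts, end = ends)
  exons <- exons[order(exons$ordinal), ]
  rownames(exons) <- NULL
  kd <- NULL
  if (!is.null(kinase_exons)) {
    ki <- exons[exons$ordinal %in% kinase_exons, ]
    kd <- c(min(ki$start), max(ki$end))
  }
  structure(list(gene = gene, chrom = chrom, strand = strand,
                 exons = exons, exon_lens = as.integer(exon_lens),
                 kinase_exons = kinase_exons, kinase_domain = kd,
                 hot_exons = as.integer(hot_exons), coding = coding,
                 span = c(min(exons$start), max(exons$end))),
            class = "gene_model")
}

#' @exportS3Method base::print
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d (%s), %d exons%s\n", x$gene,
              x$chrom, x$span[1], x$span[2], x$strand, nrow(x$exons),
              if (!is.null(x$kinase_domain))
                sprintf(", kinase domain exons %d-%d",
                        min(x$kinase_exons), max(x$kinase_exons)) else ""))
  invisible(x)
}

#' Packaged toy gene models
#'
#' A compact set of gene models on a synthetic genome, mirroring the real
#' genes' chromosome assignments (NTRK1 on a chr1-like contig, NTRK3 on
#' chr15-like, ETV6 on chr12-like, NTRK2 on chr9-like). Exon lengths are
#' chosen so that the recurrent clinical junctions (e.g. ETV6 exon 5 to
#' NTRK3 exon 15, LMNA exon 2 to NTRK1 exon 11) are in frame. The NTRK
#' kinase domains span the 3'-terminal exons; hot-exon sets are NTRK1
#' exons 8-17 and NTRK3 exons 13-15, the recurrently rearranged regions.
#'
#' @return named list of [gene_model()] objects
#' @export
toy_gene_models <- function() {
  models <- list(
    gene_model("LMNA", "chr1", "+", 5000,
               c(110, 90, 120, 100, 95, 110, 120, 90, 100, 110, 120, 130)),
    gene_model("TPM3", "chr1", "-", 15000,
               c(120, 90, 99, 120, 90, 120, 120, 100, 110, 95)),
    gene_model("INSRR", "chr1", "-", 24000,
               c(100, 110, 90, 120, 100, 130)),
    gene_model("NTRK1", "chr1", "+", 30000,
               c(100, 120, 90, 150, 87, 120, 99, 110, 130, 121, 140, 95,
                 160, 130, 145, 120, 200),
               kinase_exons = 13:17, hot_exons = 8:17),
    gene_model("TPR", "chr1", "+", 40000,
               c(rep(90, 20), 92, rep(90, 4)), intron_lens = 150),
    gene_model("NTRK2", "chr9", "+", 5000,
               c(100, 120, 90, 150, 90, 120, 99, 110, 130, 120, 140, 96,
                 160, 130, 145, 120, 200),
               kinase_exons = 13:17, hot_exons = 12:16),
    gene_model("ETV6", "chr12", "+", 5000,
               c(100, 90, 120, 150, 120, 110, 130, 200)),
    gene_model("NTRK3", "chr15", "+", 10000,
               c(95, 120, 90, 150, 120, 99, 87, 120, 130, 110, 140, 121,
                 100, 130, 160, 145, 120, 130, 210),
               kinase_exons = 15:19, hot_exons = 13:15),
    gene_model("LINC01197", "chr15", "+", 30000, c(200, 150, 300),
               coding = FALSE))
  names(models) <- vapply(models, function(m) m$gene, character(1))
  models
}

#' Write gene models as GFF3
#'
#' One gene feature per model carrying `kinase_exons`, `hot_exons` and
#' `coding` attribute tags, followed by exon and CDS features (with phase)
#' in transcript order. Coordinates are converted to GFF's 1-based
#' inclusive convention.
#'
#' @param models named list of gene models
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gene_models <- function(models, path) {
  lines <- "##gff-version 3"
  for (m in models) {
    attrs <- sprintf("ID=%s;Name=%s;coding=%s", m$gene, m$gene,
                     tolower(m$coding))
    if (!is.null(m$kinase_exons)) {
      attrs <- paste0(attrs, ";kinase_exons=", min(m$kinase_exons), "-",
                      max(m$kinase_exons))
    }
    if (length(m$hot_exons)) {
      attrs <- paste0(attrs, ";hot_exons=", min(m$hot_exons), "-",
                      max(m$hot_exons))
    }
    lines <- c(lines, paste(m$chrom, "ntrkscan", "gene", m$span[1] + 1L,
                            m$span[2], ".", m$strand, ".", attrs,
                            sep = "\t"))
    phase <- 0L
    for (k in seq_len(nrow(m$exons))) {
      e <- m$exons[k, ]
      lines <- c(lines, paste(m$chrom, "ntrkscan", "exon", e$start + 1L,
                              e$end, ".", m$strand, ".",
                              sprintf("Parent=%s;exon_number=%d", m$gene,
                                      e$ordinal), sep = "\t"))
      if (m$coding) {
        lines <- c(lines, paste(m$chrom, "ntrkscan", "CDS", e$start + 1L,
                                e$end, ".", m$strand, phase,
                                sprintf("Parent=%s;exon_number=%d", m$gene,
                                        e$ordinal), sep = "\t"))
        phase <- (3L - ((e$end - e$start) - phase) %% 3L) %% 3L
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Reads a GFF3 written by [write_gene_models()] (gene features with
#' `kinase_exons`/`hot_exons`/`coding` attribute tags, exon children with
#' `exon_number`).
#'
#' @param path GFF3 path
#' @return named list of [gene_model()] objects
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  genes <- df[df$type == "gene", ]
  models <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ex <- df[df$type == "exon" &
               vapply(df$Parent, function(p) g$ID %in% p, logical(1)), ]
    ex <- ex[order(as.integer(ex$exon_number)), ]
    lens <- ex$end - ex$start + 1L
    # reconstruct intron lengths in transcript order
    starts0 <- ex$start - 1L
    if (nrow(ex) > 1) {
      o <- order(starts0)
      gaps <- starts0[o][-1] - (ex$end[o])[-nrow(ex)]
      if (as.character(g$strand) == "-") gaps <- rev(gaps)
    } else gaps <- 300L
    parse_range <- function(x) {
      if (is.na(x) || !length(x)) return(NULL)
      p <- as.integer(strsplit(x, "-")[[1]])
      seq(p[1], p[2])
    }
    ke <- if ("kinase_exons" %in% names(df)) parse_range(g$kinase_exons)
          else NULL
    he <- if ("hot_exons" %in% names(df)) parse_range(g$hot_exons)
          else NULL
    tx_start <- min(starts0)
    models[[g$ID]] <- gene_model(
      g$ID, as.character(g$seqnames), as.character(g$strand), tx_start,
      exon_lens = lens, intron_lens = as.integer(gaps),
      kinase_exons = ke, hot_exons = he %||% integer(),
      coding = !identical(g$coding, "false"))
  }
  models
}

#' Reference genome matching the toy gene models
#'
#' Chromosomes named chr1, chr9, chr12 and chr15 (mirroring the real NTRK
#' and partner gene locations), each 60 kb of random sequence.
#'
#' @param seed integer seed
#' @return DNAStringSet
#' @export
toy_model_reference <- function(seed = 1) {
  make_reference(n_chrom = 4, length_bp = 60000, seed = seed,
                 chrom_names = c("chr1", "chr9", "chr12", "chr15"))
}
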