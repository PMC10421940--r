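#' Generate a synthetic reference genome
#'
#' Builds a random uniform-composition reference with at least two
#' chromosomes, so that both intra- and interchromosomal rearrangements can
#' be planted.
#'
#' @param n_chrom number of chromosomes (>= 2, interchromosomal events need
#'   two sequences)
#' @param length_bp length of each chromosome in bp (>= 10000)
#' @param seed integer seed; identical seeds give identical sequences
#' @param chrom_names optional character vector of chromosome names
#'   (defaults to chr1..chrN)
#' @return a [Biostrings::DNAStringSet] with one entry per chromosome
#' @export
#' @examples
#' ref <- make_reference(2, 50000, seed = 7)
make_reference <- function(n_chrom = 2, length_bp = 50000, seed = 1,
                           chrom_names = NULL) {
  if (n_chrom < 2) {
    stop("n_chrom must be >= 2: a single chromosome cannot host ",
         "interchromosomal rearrangements")
  }
  if (length_bp < 10000) {
    stop("length_bp must be >= 10000 so fragments and planted events fit")
  }
  chrom_names <- chrom_names %||% paste0("chr", seq_len(n_chrom))
  stopifnot(length(chrom_names) == n_chrom, !anyDuplicated(chrom_names))
  seqs <- with_seed(derive_seed(seed, "reference"), {
    vapply(seq_len(n_chrom), function(i) {
      paste(sample(c("A", "C", "G", "T"), length_bp, replace = TRUE),
            collapse = "")
    }, character(1))
  })
  ref <- Biostrings::DNAStringSet(seqs)
  names(ref) <- chrom_names
  ref
}

#' Write / read a reference as FASTA
#'
#' @param ref a DNAStringSet as produced by [make_reference()]
#' @param path output FASTA path
#' @return `path`, invisibly (writer); a DNAStringSet (reader)
#' @export
write_reference_fasta <- function(ref, path) {
  Biostrings::writeXStringSet(ref, filepath = path)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Describe a rearrangement to plant into simulated reads
#'
#' Coordinates are 0-based half-open. `posA` is the position just past the
#' last retained base of the 5' segment when `strandA == "+"`; for
#' `strandA == "-"` the retained segment is the reverse complement of the
#' sequence starting at `posA`. Symmetrically, `posB` is the first retained
#' base of the 3' segment for `strandB == "+"`, and the position just past
#' it (read leftwards) for `strandB == "-"`.
#'
#' @param chromA,posA,strandA breakpoint of the 5' segment
#' @param chromB,posB,strandB breakpoint of the 3' segment
#' @param n_support_pairs number of read pairs straddling the junction
#' @return an object of class `planted_fusion`
#' @export
planted_fusion <- function(chromA, posA, strandA = "+",
                           chromB, posB, strandB = "+",
                           n_support_pairs = 8) {
  stopifnot(strandA %in% c("+", "-"), strandB %in% c("+", "-"),
            posA >= 0, posB >= 0, n_support_pairs >= 0)
  structure(list(chromA = chromA, posA = as.integer(posA), strandA = strandA,
                 chromB = chromB, posB = as.integer(posB), strandB = strandB,
                 n_support_pairs = as.integer(n_support_pairs)),
            class = "planted_fusion")
}

# sequence of the fused allele on coordinates where the junction sits at 0:
# negative coordinates are 5'-segment bases, non-negative are 3'-segment
fused_segment <- function(ref, event, from, to) {
  stopifnot(from < to)
  left <- ""
  right <- ""
  if (from < 0) {
    lo <- from
    hi <- min(to, 0L)
    n <- hi - lo
    chr <- ref[[event$chromA]]
    if (event$strandA == "+") {
      s0 <- event$posA + lo  # 0-based
      left <- as.character(Biostrings::subseq(chr, s0 + 1, s0 + n))
    } else {
      # fused coord x (< 0) maps to reference base posA - 1 - x
      s0 <- event$posA - 1 - (hi - 1)   # leftmost ref base, 0-based
      left <- revcomp(as.character(Biostrings::subseq(chr, s0 + 1, s0 + n)))
    }
  }
  if (to > 0) {
    lo <- max(from, 0L)
    n <- to - lo
    chr <- ref[[event$chromB]]
    if (event$strandB == "+") {
      s0 <- event$posB + lo
      right <- as.character(Biostrings::subseq(chr, s0 + 1, s0 + n))
    } else {
      # fused coord y (>= 0) maps to reference base posB - 1 - y
      s0 <- event$posB - 1 - (to - 1)
      right <- revcomp(as.character(Biostrings::subseq(chr, s0 + 1, s0 + n)))
    }
  }
  paste0(left, right)
}

#' Simulate paired-end reads around a planted rearrangement
#'
#' Emits exactly `n_support_pairs` read pairs whose fragments straddle the
#' fusion junction (one end anchored near each breakpoint, so every pair
#' satisfies the discordance predicate used by the caller), plus concordant
#' background pairs whose insert size follows a truncated normal
#' distribution. Read sequences are taken from the fused allele, so reads
#' near the junction carry chimeric sequence and the cluster can be
#' assembled across the breakpoint. Each pair has a unique start
#' coordinate.
#'
#' @param ref reference from [make_reference()]
#' @param event a [planted_fusion()]; pass `NULL` for background-only sets
#' @param background_pairs number of concordant background pairs
#' @param read_length read length in bp
#' @param median_insert,insert_sd background insert-size distribution
#'   (normal, truncated below at `2 * read_length`)
#' @param seed integer seed
#' @param stagger spacing in bp between consecutive supporting-fragment
#'   starts (reduced automatically when many pairs must fit)
#' @return a data.frame of alignment records, one row per read end, with
#'   columns `read_id, chrom, pos` (0-based leftmost), `strand, seq,
#'   mate_chrom, mate_pos, first_in_pair`
#' @export
simulate_fusion_reads <- function(ref, event, background_pairs = 0,
                                  read_length = 100, median_insert = 300,
                                  insert_sd = 30, seed = 1, stagger = 10) {
  rl <- as.integer(read_length)
  ins <- as.integer(median_insert)
  stopifnot(ins > 2 * rl)
  rows <- list()

  if (!is.null(event) && event$n_support_pairs > 0) {
    n <- event$n_support_pairs
    # window of fragment starts (fused coordinates) for which read1 sits
    # mostly on the 5' side and read2 mostly on the 3' side
    a_lo <- as.integer(floor(rl / 2) - ins + 5L)
    a_hi <- as.integer(-ceiling(rl / 2) - 5L)
    avail <- a_hi - a_lo + 1L
    if (n > avail) {
      stop("n_support_pairs = ", n, " exceeds the ", avail,
           " unique fragment starts available within one fragment ",
           "length of the breakpoint")
    }
    stg <- max(1L, min(as.integer(stagger),
                       (a_hi - a_lo) %/% max(1L, n - 1L)))
    a <- a_lo + (seq_len(n) - 1L) * stg
    check_bounds(ref, event, a_lo, ins)
    for (i in seq_len(n)) {
      s1 <- a[i]
      s2 <- a[i] + ins - rl
      seq1 <- fused_segment(ref, event, s1, s1 + rl)
      seq2 <- revcomp(fused_segment(ref, event, s2, s2 + rl))
      m1 <- min(0L, s1 + rl)            # end of read1's 5'-side portion
      mb <- max(0L, s2)                 # start of read2's 3'-side portion
      if (event$strandA == "+") {
        pos1 <- event$posA + s1; str1 <- "+"
      } else {
        pos1 <- event$posA - m1; str1 <- "-"
      }
      if (event$strandB == "+") {
        pos2 <- event$posB + mb; str2 <- "-"
      } else {
        pos2 <- event$posB - (s2 + rl); str2 <- "+"
      }
      id <- sprintf("fus%04d", i)
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = id,
        chrom = c(event$chromA, event$chromB),
        pos = as.integer(c(pos1, pos2)),
        strand = c(str1, str2),
        seq = c(seq1, seq2),
        mate_chrom = c(event$chromB, event$chromA),
        mate_pos = as.integer(c(pos2, pos1)),
        first_in_pair = c(TRUE, FALSE),
        stringsAsFactors = FALSE)
    }
  }

  if (background_pairs > 0) {
    bg <- with_seed(derive_seed(seed, "background"), {
      simulate_background(ref, background_pairs, rl, ins, insert_sd)
    })
    rows[[length(rows) + 1L]] <- bg
  }
  if (length(rows) == 0) {
    return(empty_records())
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

check_bounds <- function(ref, event, a_lo, ins) {
  lenA <- Biostrings::width(ref)[match(event$chromA, names(ref))]
  lenB <- Biostrings::width(ref)[match(event$chromB, names(ref))]
  need <- ins  # bases consumed on each side at most one fragment
  okA <- if (event$strandA == "+") event$posA - need >= 0
         else event$posA + need <= lenA
  okB <- if (event$strandB == "+") event$posB + need <= lenB
         else event$posB - need >= 0
  if (!okA || !okB) {
    stop("planted breakpoint too close to a reference end for the ",
         "requested insert size")
  }
  invisible(TRUE)
}

simulate_background <- function(ref, n_pairs, rl, ins, sd) {
  chroms <- names(ref)
  lens <- Biostrings::width(ref)
  ci <- sample.int(length(chroms), n_pairs, replace = TRUE)
  insert <- as.integer(round(stats::rnorm(n_pairs, ins, sd)))
  # truncate below: concordant fragments must hold two non-overlapping reads
  while (any(bad <- insert <= 2 * rl)) {
    insert[bad] <- as.integer(round(stats::rnorm(sum(bad), ins, sd)))
  }
  start <- integer(n_pairs)
  for (k in seq_along(chroms)) {
    idx <- which(ci == k)
    if (!length(idx)) next
    hi <- lens[k] - max(insert[idx]) - 1L
    start[idx] <- sample.int(hi, length(idx), replace = FALSE)
  }
  rows <- vector("list", length(chroms))
  for (k in seq_along(chroms)) {
    idx <- which(ci == k)
    if (!length(idx)) next
    s <- start[idx]
    iv <- insert[idx]
    v1 <- Biostrings::Views(ref[[k]], start = s + 1L, width = rl)
    v2 <- Biostrings::Views(ref[[k]], start = s + iv - rl + 1L, width = rl)
    seq1 <- as.character(Biostrings::DNAStringSet(v1))
    seq2 <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(v2)))
    id <- sprintf("bg_%s_%07d", chroms[k], s)
    rows[[k]] <- data.frame(
      read_id = rep(id, each = 2L),
      chrom = chroms[k],
      pos = as.vector(rbind(s, s + iv - rl)),
      strand = rep(c("+", "-"), length(idx)),
      seq = as.vector(rbind(seq1, seq2)),
      mate_chrom = chroms[k],
      mate_pos = as.vector(rbind(s + iv - rl, s)),
      first_in_pair = rep(c(TRUE, FALSE), length(idx)),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

empty_records <- function() {
  data.frame(read_id = character(), chrom = character(), pos = integer(),
             strand = character(), seq = character(),
             mate_chrom = character(), mate_pos = integer(),
             first_in_pair = logical(), stringsAsFactors = FALSE)
}

#' Write / read alignment records as a headered SAM-like TSV
#'
#' Positions are converted to 1-based on disk (SAM convention) and back to
#' 0-based in memory.
#'
#' @param records alignment record data.frame
#' @param path TSV path
#' @return `path`, invisibly (writer); a record data.frame (reader)
#' @export
write_alignments <- function(records, path) {
  out <- data.frame(
    qname = records$read_id,
    strand = records$strand,
    first_in_pair = as.integer(records$first_in_pair),
    rname = records$chrom,
    pos = records$pos + 1L,
    mapq = 60L,
    cigar = paste0(nchar(records$seq), "M"),
    rnext = records$mate_chrom,
    pnext = records$mate_pos + 1L,
    tlen = 0L,
    seq = records$seq,
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_alignments
#' @export
read_alignments <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  data.frame(read_id = x$qname, chrom = x$rname, pos = x$pos - 1L,
             strand = x$strand, seq = x$seq, mate_chrom = x$rnext,
             mate_pos = x$pnext - 1L,
             first_in_pair = as.logical(x$first_in_pair),
             stringsAsFactors = FALSE)
}

#' Build a microsatellite marker panel
#'
#' A panel of mononucleotide/dinucleotide repeat loci with reference repeat
#' counts, mirroring the 572-marker panel used for MSI scoring.
#'
#' @param n_loci panel size (default 572)
#' @param chroms chromosome names to place loci on
#' @param seed integer seed
#' @return data.frame with columns `locus_id, chrom, pos, repeat_unit,
#'   ref_repeat_count`
#' @export
msi_panel <- function(n_loci = 572, chroms = c("chr1", "chr2"), seed = 1) {
  stopifnot(n_loci >= 1)
  with_seed(derive_seed(seed, "msipanel"), {
    data.frame(
      locus_id = sprintf("MS%04d", seq_len(n_loci)),
      chrom = sample(chroms, n_loci, replace = TRUE),
      pos = sample.int(10^6, n_loci),
      repeat_unit = sample(c("A", "T", "AC", "AT"), n_loci, replace = TRUE),
      ref_repeat_count = sample(10:25, n_loci, replace = TRUE),
      stringsAsFactors = FALSE)
  })
}

#' Simulate tumor/normal microsatellite allele-length profiles
#'
#' Exactly `round(unstable_fraction * nrow(panel))` loci are planted as
#' unstable: the tumor gains a novel allele length absent from the matched
#' normal, with enough supporting reads to be scored. All remaining loci
#' have identical tumor and normal length distributions.
#'
#' @param panel panel from [msi_panel()]
#' @param unstable_fraction proportion of loci to destabilise, in [0, 1]
#' @param depth reads per locus (> 0)
#' @param seed integer seed
#' @return list with elements `tumor` and `normal` (long data.frames with
#'   columns `locus_id, allele_len, reads`) and attribute
#'   `planted_unstable` holding the destabilised locus ids
#' @export
simulate_msi_profiles <- function(panel, unstable_fraction, depth = 100,
                                  seed = 1) {
  stopifnot(unstable_fraction >= 0, unstable_fraction <= 1)
  if (depth <= 0) stop("depth must be positive")
  n <- nrow(panel)
  n_unstable <- round(unstable_fraction * n)
  unstable_ids <- with_seed(derive_seed(seed, "msi"), {
    sample(panel$locus_id, n_unstable)
  })
  stutter <- min(3L, max(1L, depth %/% 10L))
  novel_reads <- max(3L, as.integer(round(depth * 0.3)))
  normal <- data.frame(
    locus_id = rep(panel$locus_id, each = 2L),
    allele_len = as.vector(rbind(panel$ref_repeat_count,
                                 panel$ref_repeat_count - 1L)),
    reads = rep(c(depth - stutter, stutter), n),
    stringsAsFactors = FALSE)
  tumor <- normal
  if (n_unstable > 0) {
    idx <- panel$locus_id %in% unstable_ids
    extra <- data.frame(
      locus_id = panel$locus_id[idx],
      allele_len = panel$ref_repeat_count[idx] + 2L,
      reads = novel_reads,
      stringsAsFactors = FALSE)
    # novel allele reads displace reference-allele reads, total depth kept
    tumor$reads[tumor$locus_id %in% unstable_ids &
                  tumor$allele_len %in% panel$ref_repeat_count[idx]] <-
      pmax(1L, depth - stutter - novel_reads)
    tumor <- rbind(tumor, extra)
    tumor <- tumor[order(tumor$locus_id, tumor$allele_len), ]
    rownames(tumor) <- NULL
  }
  structure(list(tumor = tumor, normal = normal),
            planted_unstable = sort(unstable_ids))
}

#' Simulate a pan-cancer screening cohort
#'
#' Draws per-patient fusion and MSI status independently from the stated
#' rates, with tumor types drawn from the packaged pan-cancer tumor-type
#' frequency table.
#'
#' @param n_patients cohort size
#' @param fusion_rate marginal probability a patient is fusion-positive
#' @param msih_rate_given_fusion P(MSI-H | fusion-positive)
#' @param msih_rate_given_no_fusion P(MSI-H | fusion-negative)
#' @param seed integer seed
#' @return data.frame with columns `patient_id, tumor_type, fusion, msi`
#' @export
simulate_cohort <- function(n_patients, fusion_rate,
                            msih_rate_given_fusion,
                            msih_rate_given_no_fusion, seed = 1) {
  rates <- c(fusion_rate, msih_rate_given_fusion, msih_rate_given_no_fusion)
  stopifnot(all(rates >= 0), all(rates <= 1), n_patients >= 1)
  tt <- tumor_type_frequencies()
  with_seed(derive_seed(seed, "cohort"), {
    fusion <- stats::runif(n_patients) < fusion_rate
    p_msih <- ifelse(fusion, msih_rate_given_fusion,
                     msih_rate_given_no_fusion)
    msi <- ifelse(stats::runif(n_patients) < p_msih, "MSI-H", "MSS")
    data.frame(
      patient_id = sprintf("P%06d", seq_len(n_patients)),
      tumor_type = sample(tt$tumor_type, n_patients, replace = TRUE,
                          prob = tt$n_total),
      fusion = fusion,
      msi = msi,
      stringsAsFactors = FALSE)
  })
}
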