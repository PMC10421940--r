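#' Tumor mutational burden on a targeted panel
#'
#' TMB is the count of coding somatic SNVs and indels divided by the
#' panel's coding footprint in megabases, reported to one decimal
#' (half-up). Synonymous and non-synonymous variants count alike;
#' non-coding variants are excluded.
#'
#' @param variants data.frame with columns `class` (one of "SNV",
#'   "insertion", "deletion") and `coding` (logical)
#' @param panel_coding_mb panel coding footprint in Mb (> 0); the panel
#'   footprint is assay-specific, so there is no default
#' @return TMB in mutations per megabase, one decimal
#' @export
compute_tmb <- function(variants, panel_coding_mb) {
  if (!is.numeric(panel_coding_mb) || panel_coding_mb <= 0) {
    stop("panel_coding_mb must be a positive number of megabases")
  }
  n <- sum(variants$coding &
             variants$class %in% c("SNV", "insertion", "deletion"))
  round_half_up(n / panel_coding_mb, 1)
}

#' Read somatic variants from a minimal VCF
#'
#' Expects CHROM/POS/REF/ALT plus an INFO flag `CODING` on coding
#' variants. Variant class is derived from allele lengths: equal-length
#' single-base alleles are SNVs, longer ALT is an insertion, longer REF a
#' deletion.
#'
#' @param path VCF path (uncompressed or bgzipped)
#' @return data.frame with columns `chrom, pos, ref, alt, class, coding`
#' @export
read_somatic_variants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  ref <- fx[, "REF"]
  alt <- fx[, "ALT"]
  cls <- ifelse(nchar(ref) == nchar(alt), "SNV",
                ifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))
  coding <- grepl("(^|;)CODING(;|$|=)", vcfR::getINFO(v))
  data.frame(chrom = fx[, "CHROM"], pos = as.integer(fx[, "POS"]),
             ref = ref, alt = alt, class = cls, coding = coding,
             stringsAsFactors = FALSE)
}

#' Score one microsatellite locus for instability
#'
#' A locus is unstable when the tumor carries at least one allele length,
#' supported by `min_allele_reads` reads or more, that is absent from the
#' matched normal; uncovered when either sample has fewer than
#' `min_locus_depth` reads.
#'
#' @param tumor,normal named numeric vectors mapping allele length to read
#'   count for one locus (names are allele lengths)
#' @param min_allele_reads minimum reads supporting a novel tumor allele
#' @param min_locus_depth minimum per-sample depth for evaluation
#' @return "stable", "unstable" or "uncovered"
#' @export
score_locus_instability <- function(tumor, normal, min_allele_reads = 3,
                                    min_locus_depth = 10) {
  if (any(c(tumor, normal) < 0)) stop("negative read counts")
  if (sum(tumor) < min_locus_depth || sum(normal) < min_locus_depth) {
    return("uncovered")
  }
  novel <- setdiff(names(tumor)[tumor >= min_allele_reads], names(normal))
  if (length(novel)) "unstable" else "stable"
}

#' Call microsatellite status from per-locus results
#'
#' MSI-H when strictly more than `threshold` (default 15%) of evaluated
#' loci are unstable; Unknown when fewer than `min_evaluated` loci could
#' be evaluated (uncovered loci are excluded from the denominator);
#' otherwise MSS.
#'
#' @param statuses character vector of per-locus statuses from
#'   [score_locus_instability()]
#' @param min_evaluated minimum evaluated loci for a definitive call
#' @param threshold unstable fraction above which the sample is MSI-H
#'   (strict inequality)
#' @return list with `n_evaluated, n_unstable, unstable_fraction, status`
#' @export
call_msi <- function(statuses, min_evaluated = 20, threshold = 0.15) {
  n_eval <- sum(statuses != "uncovered")
  n_unst <- sum(statuses == "unstable")
  frac <- if (n_eval > 0) n_unst / n_eval else NA_real_
  status <- if (n_eval < min_evaluated) "Unknown"
            else if (frac > threshold) "MSI-H" else "MSS"
  list(n_evaluated = n_eval, n_unstable = n_unst,
       unstable_fraction = frac, status = status)
}

#' MSI status of a tumor/normal profile pair
#'
#' Scores every locus of a long-format profile pair (as produced by
#' [simulate_msi_profiles()] or read with [read_msi_profiles()]) and
#' applies the panel-level call.
#'
#' @param tumor,normal long data.frames with columns `locus_id,
#'   allele_len, reads`
#' @param min_allele_reads,min_locus_depth per-locus rule, see
#'   [score_locus_instability()]
#' @param min_evaluated,threshold panel rule, see [call_msi()]
#' @return list as returned by [call_msi()]
#' @export
msi_sample_status <- function(tumor, normal, min_allele_reads = 3,
                              min_locus_depth = 10, min_evaluated = 20,
                              threshold = 0.15) {
  loci <- union(tumor$locus_id, normal$locus_id)
  pull <- function(df, id) {
    x <- df[df$locus_id == id, ]
    stats::setNames(x$reads, x$allele_len)
  }
  statuses <- vapply(loci, function(id) {
    score_locus_instability(pull(tumor, id), pull(normal, id),
                            min_allele_reads, min_locus_depth)
  }, character(1))
  call_msi(statuses, min_evaluated, threshold)
}

#' Write / read microsatellite profiles as TSV
#'
#' Long format: `locus_id, sample, allele_len, reads` with sample in
#' {tumor, normal}.
#'
#' @param profiles list with `tumor` and `normal` data.frames
#' @param path TSV path
#' @return `path`, invisibly (writer); profile list (reader)
#' @export
write_msi_profiles <- function(profiles, path) {
  long <- rbind(cbind(sample = "tumor", profiles$tumor),
                cbind(sample = "normal", profiles$normal))
  utils::write.table(long[, c("locus_id", "sample", "allele_len", "reads")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_msi_profiles
#' @export
read_msi_profiles <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  list(tumor = x[x$sample == "tumor",
                 c("locus_id", "allele_len", "reads")],
       normal = x[x$sample == "normal",
                  c("locus_id", "allele_len", "reads")])
}
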