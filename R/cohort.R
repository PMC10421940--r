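#' Packaged cohort fixtures
#'
#' Accessors for the versioned TSV transcriptions of the published cohort
#' tables: per-stratum marginal counts for the full screening cohort
#' (`table1_marginals`), the per-fusion records of the 40 fusion-positive
#' patients carrying 41 fusions (`table2_patients`), and the 13-patient
#' DNA/RNA/IHC concordance set (`table3_concordance`).
#'
#' @param path optional path overriding the packaged file
#' @return a data.frame
#' @export
table1_marginals <- function(path = NULL) {
  path <- path %||% system.file("extdata", "table1_marginals.tsv",
                                package = "ntrkscan", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, quote = "")
}

#' @rdname table1_marginals
#' @export
table2_patients <- function(path = NULL) {
  path <- path %||% system.file("extdata", "table2_patients.tsv",
                                package = "ntrkscan", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, quote = "")
}

#' @rdname table1_marginals
#' @export
table3_concordance <- function(path = NULL) {
  path <- path %||% system.file("extdata", "table3_concordance.tsv",
                                package = "ntrkscan", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, quote = "")
}

#' Pan-cancer tumor-type frequencies
#'
#' Tumor-type totals of the screening cohort, used as the sampling
#' distribution by [simulate_cohort()].
#'
#' @return data.frame with `tumor_type` and `n_total`
#' @export
tumor_type_frequencies <- function() {
  m <- table1_marginals()
  tt <- m[m$variable == "tumor_type", ]
  data.frame(tumor_type = tt$level, n_total = tt$overall,
             stringsAsFactors = FALSE)
}

#' Assemble a cohort object from fixtures
#'
#' Combines the per-fusion records of the fusion-positive patients with
#' the marginal counts of the full cohort (fusion-negative patients are
#' only available as aggregates).
#'
#' @param patients per-fusion records, default [table2_patients()]
#' @param marginals stratum counts, default [table1_marginals()]
#' @return object of class `ntrk_cohort`
#' @export
ntrk_cohort <- function(patients = table2_patients(),
                        marginals = table1_marginals()) {
  total <- marginals$overall[marginals$variable == "overall"]
  pos <- length(unique(patients$case_id))
  structure(list(patients = patients, marginals = marginals,
                 n_total = total, n_positive = pos),
            class = "ntrk_cohort")
}

#' @exportS3Method base::print
print.ntrk_cohort <- function(x, ...) {
  cat(sprintf("<ntrk_cohort> %d patients, %d fusion-positive (%s%%), %d fusions\n",
              x$n_total, x$n_positive,
              round_half_up(100 * x$n_positive / x$n_total, 1),
              nrow(x$patients)))
  invisible(x)
}

#' Fusion prevalence by stratum
#'
#' Positive and total counts per stratum with the percentage recomputed
#' (half-up, one decimal). Strata with zero totals are omitted.
#'
#' @param cohort an [ntrk_cohort()]
#' @param stratify_by one of "overall", "tumor_type", "subtype",
#'   "age_group", "msi"
#' @return data.frame with `stratum, n_positive, n_total, percent`
#' @export
prevalence <- function(cohort, stratify_by = "overall") {
  m <- cohort$marginals
  ok <- c("overall", "tumor_type", "subtype", "age_group", "msi")
  if (!stratify_by %in% ok) {
    stop("unknown stratifier '", stratify_by, "'; expected one of ",
         paste(ok, collapse = ", "))
  }
  s <- m[m$variable == stratify_by & m$overall > 0, ]
  out <- data.frame(stratum = s$level, n_positive = s$positive,
                    n_total = s$overall,
                    percent = round_half_up(100 * s$positive / s$overall, 1),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Fusion pattern accounting
#'
#' Partner diversity, novelty and rearrangement-type tallies over the
#' per-fusion records. Per-fusion denominators use the fusion count (one
#' patient may carry two fusions); per-patient denominators use distinct
#' case ids.
#'
#' @param patients per-fusion records, default [table2_patients()]
#' @return list of summary counts and percentages
#' @export
fusion_pattern_summary <- function(patients = table2_patients()) {
  n_fusions <- nrow(patients)
  n_patients <- length(unique(patients$case_id))
  partners <- unique(toupper(patients$partner))
  per_gene <- split(patients, patients$ntrk_gene)
  partner_div <- vapply(per_gene, function(d) length(unique(toupper(d$partner))),
                        integer(1))
  rearr <- lapply(per_gene, function(d) {
    tab <- table(factor(d$fusion_type,
                        levels = c("intrachromosomal", "interchromosomal")))
    pct <- round_half_up(100 * as.vector(tab) / nrow(d), 1)
    data.frame(type = names(tab), n = as.vector(tab), of = nrow(d),
               percent = pct, stringsAsFactors = FALSE)
  })
  cls <- table(patients$classification)
  novel <- sum(patients$novelty == "Novel")
  list(n_fusions = n_fusions, n_patients = n_patients,
       n_unique_partners = length(partners),
       partner_diversity = partner_div,
       n_definite = as.integer(cls["Definite"] %||% 0),
       n_likely = as.integer(cls["Likely"] %||% 0),
       n_novel = novel,
       novel_pct_per_fusion = round_half_up(100 * novel / n_fusions, 1),
       rearrangement = rearr)
}

#' Exact association test on a 2x2 (or r x c) contingency table
#'
#' Fisher's exact test (two-sided: the sum of all table probabilities not
#' exceeding the observed table's) by default; chi-square on request.
#' Cohort inputs build the fusion-by-MSI table with Unknown levels
#' excluded pairwise.
#'
#' @param x a contingency matrix, an [ntrk_cohort()] (fusion x MSI from
#'   the marginals) or a simulated cohort data.frame with `fusion` and
#'   `msi` columns
#' @param method "fisher" (exact, default) or "chisq"
#' @return list with `table`, `odds_ratio` (2x2 Fisher only), `p_value`,
#'   `method`
#' @export
association_test <- function(x, method = c("fisher", "chisq")) {
  method <- match.arg(method)
  tab <- if (is.matrix(x)) {
    x
  } else if (inherits(x, "ntrk_cohort")) {
    fusion_msi_table(x)
  } else if (is.data.frame(x) && all(c("fusion", "msi") %in% names(x))) {
    as.matrix(table(factor(x$msi, levels = c("MSI-H", "MSS")),
                    factor(x$fusion, levels = c(TRUE, FALSE))))
  } else {
    stop("x must be a matrix, ntrk_cohort, or cohort data.frame")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate margin: a row or column of the table is all zero; ",
         "odds ratio undefined")
  }
  if (method == "fisher") {
    ft <- stats::fisher.test(tab, alternative = "two.sided")
    or <- if (all(dim(tab) == 2)) unname(ft$estimate) else NA_real_
    list(table = tab, odds_ratio = or, p_value = ft$p.value,
         method = "fisher")
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(table = tab, odds_ratio = NA_real_, p_value = ct$p.value,
         method = "chisq")
  }
}

#' Fusion-by-MSI contingency table from cohort marginals
#'
#' Rows MSI-H/MSS, columns fusion-positive/negative; the Unknown MSI
#' stratum is excluded.
#'
#' @param cohort an [ntrk_cohort()]
#' @return 2x2 integer matrix
#' @export
fusion_msi_table <- function(cohort = ntrk_cohort()) {
  m <- cohort$marginals
  msi <- m[m$variable == "msi" & m$level %in% c("MSI-H", "MSS"), ]
  pos <- msi$positive
  neg <- msi$overall - msi$positive
  matrix(c(pos, neg), nrow = 2,
         dimnames = list(msi = msi$level,
                         fusion = c("positive", "negative")))
}

#' Compare a continuous variable between two groups
#'
#' Wilcoxon rank-sum test with midrank ties; medians and ranges reported
#' to one decimal.
#'
#' @param x,y numeric observations for the two groups (both non-empty)
#' @return list with `median_x, median_y, range_x, range_y, p_value`
#' @export
group_compare_continuous <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups need observations")
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = length(x) < 50 &&
                                              length(y) < 50))
  list(median_x = round_half_up(stats::median(x), 1),
       median_y = round_half_up(stats::median(y), 1),
       range_x = round_half_up(range(x), 1),
       range_y = round_half_up(range(y), 1),
       p_value = wt$p.value)
}

#' Cross-assay concordance among DNA-positive cases
#'
#' Counts positives per assay with NotEvaluated entries excluded from
#' that assay's denominator.
#'
#' @param records concordance records, default [table3_concordance()]
#' @return data.frame with `assay, n_positive, n_evaluated, fraction`
#'   (`fraction` is NA when nothing was evaluated)
#' @export
concordance_summary <- function(records = table3_concordance()) {
  stopifnot(nrow(records) > 0)
  assays <- c("rna_seq", "dna_seq", "ihc")
  out <- lapply(assays, function(a) {
    v <- records[[a]]
    ev <- sum(v != "NotEvaluated")
    np <- sum(v == "Positive")
    data.frame(assay = a, n_positive = np, n_evaluated = ev,
               fraction = if (ev > 0) np / ev else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Co-occurrence counts of binary alteration flags
#'
#' Generic per-gene co-occurrence counter over a patient-by-gene logical
#' matrix (usable with simulated cohorts).
#'
#' @param flags logical matrix, patients in rows, alterations in columns
#' @return data.frame with `alteration, n, of, percent`
#' @export
cooccurrence_counts <- function(flags) {
  stopifnot(is.matrix(flags) || is.data.frame(flags))
  flags <- as.matrix(flags)
  n <- colSums(flags)
  data.frame(alteration = colnames(flags), n = as.integer(n),
             of = nrow(flags),
             percent = round_half_up(100 * n / nrow(flags), 1),
             stringsAsFactors = FALSE)
}

#' Headline cohort statistics
#'
#' Recomputes every printed cohort-level statistic from the packaged
#' fixtures: overall and stratified prevalence, fusion-pattern counts,
#' MSI-H enrichment (Fisher exact), MSI-H fraction among positives, and
#' cross-assay concordance.
#'
#' @param cohort an [ntrk_cohort()]
#' @param concordance concordance records, default [table3_concordance()]
#' @return named list of statistics
#' @export
cohort_report <- function(cohort = ntrk_cohort(),
                          concordance = table3_concordance()) {
  prev_overall <- prevalence(cohort, "overall")
  prev_tt <- prevalence(cohort, "tumor_type")
  prev_sub <- prevalence(cohort, "subtype")
  pat <- fusion_pattern_summary(cohort$patients)
  msi_test <- association_test(cohort)
  msih_pos <- cohort$marginals[cohort$marginals$variable == "msi" &
                                 cohort$marginals$level == "MSI-H",
                               "positive"]
  conc <- concordance_summary(concordance)
  ages <- stats::aggregate(age ~ case_id, cohort$patients, function(a) a[1])
  tmbs <- stats::aggregate(tmb ~ case_id, cohort$patients, function(a) a[1])
  list(prevalence_overall = prev_overall,
       prevalence_by_tumor_type = prev_tt,
       prevalence_by_subtype = prev_sub,
       pattern = pat,
       msih_fusion_rate_pct = round_half_up(
         100 * msi_test$table["MSI-H", "positive"] /
           sum(msi_test$table["MSI-H", ]), 1),
       mss_fusion_rate_pct = round_half_up(
         100 * msi_test$table["MSS", "positive"] /
           sum(msi_test$table["MSS", ]), 2),
       msi_fisher_p = msi_test$p_value,
       msi_odds_ratio = msi_test$odds_ratio,
       msih_fraction_positives_pct = round_half_up(
         100 * msih_pos / cohort$n_positive, 1),
       median_age_positives = round_half_up(stats::median(ages$age), 1),
       median_tmb_positives = round_half_up(stats::median(tmbs$tmb), 1),
       concordance = conc)
}
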