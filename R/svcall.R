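#' Collect discordant read pairs
#'
#' A pair is discordant when its two ends map to different chromosomes, or
#' to the same chromosome with an outer insert size strictly greater than
#' `insert_threshold` (default 2000 bp). The outer insert is the distance
#' from the leftmost mapped base to the rightmost mapped base of the pair.
#' Sides are stored canonically: side A is the lexicographically smaller
#' (chromosome, position) end, so downstream clustering is independent of
#' read order.
#'
#' @param records alignment record data.frame (see
#'   [simulate_fusion_reads()] for the column contract)
#' @param insert_threshold insert size in bp above which a same-chromosome
#'   pair is discordant (strict inequality)
#' @return data.frame of discordant pairs with columns `read_id, chromA,
#'   posA, strandA, seqA, chromB, posB, strandB, seqB, reason, insert`
#' @export
collect_discordant <- function(records, insert_threshold = 2000) {
  if (nrow(records) == 0) return(empty_pairs())
  cnt <- table(records$read_id)
  bad <- names(cnt)[cnt != 2L]
  if (length(bad)) {
    warning(length(bad), " read id(s) without exactly two ends skipped")
    records <- records[!records$read_id %in% bad, , drop = FALSE]
  }
  keep <- !is.na(records$mate_chrom) & !is.na(records$mate_pos)
  records <- records[keep, , drop = FALSE]
  if (nrow(records) == 0) return(empty_pairs())
  ord <- order(records$read_id, records$chrom, records$pos)
  records <- records[ord, , drop = FALSE]
  i1 <- seq(1L, nrow(records), by = 2L)
  i2 <- i1 + 1L
  r1 <- records[i1, ]
  r2 <- records[i2, ]
  same <- r1$chrom == r2$chrom
  outer_ins <- ifelse(same,
                      pmax(r1$pos + nchar(r1$seq), r2$pos + nchar(r2$seq)) -
                        pmin(r1$pos, r2$pos),
                      NA_integer_)
  disc <- !same | (same & outer_ins > insert_threshold)
  if (!any(disc)) return(empty_pairs())
  r1 <- r1[disc, ]; r2 <- r2[disc, ]
  outer_ins <- outer_ins[disc]
  # canonical ordering already guaranteed by the (chrom, pos) sort above
  data.frame(read_id = r1$read_id,
             chromA = r1$chrom, posA = r1$pos, strandA = r1$strand,
             seqA = r1$seq,
             chromB = r2$chrom, posB = r2$pos, strandB = r2$strand,
             seqB = r2$seq,
             reason = ifelse(r1$chrom == r2$chrom, "long-insert",
                             "interchromosomal"),
             insert = outer_ins,
             stringsAsFactors = FALSE)
}

empty_pairs <- function() {
  data.frame(read_id = character(), chromA = character(), posA = integer(),
             strandA = character(), seqA = character(),
             chromB = character(), posB = integer(), strandB = character(),
             seqB = character(), reason = character(), insert = integer(),
             stringsAsFactors = FALSE)
}

#' Cluster discordant pairs by breakpoint proximity
#'
#' Single-linkage clustering within groups that share both chromosomes and
#' both strand orientations: two pairs are linked when their A-side
#' positions and their B-side positions each differ by less than
#' `cluster_distance` (default 500 bp), and clusters are the connected
#' components of that graph, so the result does not depend on input order.
#'
#' @param pairs discordant pairs from [collect_discordant()]
#' @param cluster_distance linkage distance in bp (strict `<`)
#' @return list of clusters, each a list with `chromA, chromB, strandA,
#'   strandB, members` (the pair rows), `locusA`/`locusB` (min/max
#'   positions per side) and `unique_pairs` (distinct (posA, posB) start
#'   tuples), ordered by (chromA, min posA)
#' @export
cluster_discordant <- function(pairs, cluster_distance = 500) {
  if (nrow(pairs) == 0) return(list())
  key <- paste(pairs$chromA, pairs$chromB, pairs$strandA, pairs$strandB,
               sep = "\r")
  out <- list()
  for (k in unique(key)) {
    grp <- pairs[key == k, , drop = FALSE]
    grp <- grp[order(grp$posA, grp$posB, grp$read_id), , drop = FALSE]
    n <- nrow(grp)
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    for (i in seq_len(n)) {
      j <- i + 1L
      while (j <= n && grp$posA[j] - grp$posA[i] < cluster_distance) {
        if (abs(grp$posB[j] - grp$posB[i]) < cluster_distance) {
          parent[find(j)] <- find(i)
        }
        j <- j + 1L
      }
    }
    comp <- vapply(seq_len(n), find, integer(1))
    for (cc in unique(comp)) {
      m <- grp[comp == cc, , drop = FALSE]
      out[[length(out) + 1L]] <- list(
        chromA = m$chromA[1], chromB = m$chromB[1],
        strandA = m$strandA[1], strandB = m$strandB[1],
        members = m,
        locusA = c(min(m$posA), max(m$posA)),
        locusB = c(min(m$posB), max(m$posB)),
        unique_pairs = nrow(unique(m[, c("posA", "posB")])))
    }
  }
  ord <- order(vapply(out, function(cl) cl$chromA, character(1)),
               vapply(out, function(cl) cl$locusA[1], numeric(1)),
               vapply(out, function(cl) cl$chromB, character(1)),
               vapply(out, function(cl) cl$locusB[1], numeric(1)))
  out[ord]
}

# best exact suffix(x)-prefix(y) overlap length in [min_overlap, min(nx,ny))
suffix_prefix_overlap <- function(x, y, min_overlap) {
  nx <- nchar(x); ny <- nchar(y)
  top <- min(nx, ny) - 1L
  if (top < min_overlap) return(0L)
  for (k in seq(top, min_overlap)) {
    if (substring(x, nx - k + 1L, nx) == substring(y, 1L, k)) return(k)
  }
  0L
}

# best merge between two sequences over strand orientations; combo codes:
# 1 suffix(x)+y, 2 suffix(x)+rc(y), 3 suffix(rc(x))+y,
# 4 y contained in x, 5 x contained in y
best_overlap <- function(x, y, min_overlap) {
  nx <- nchar(x); ny <- nchar(y)
  yr <- revcomp(y)
  if (ny <= nx && (grepl(y, x, fixed = TRUE) || grepl(yr, x, fixed = TRUE)))
    return(c(k = ny, combo = 4L))
  if (nx < ny) {
    xr <- revcomp(x)
    if (grepl(x, y, fixed = TRUE) || grepl(xr, y, fixed = TRUE))
      return(c(k = nx, combo = 5L))
  }
  k1 <- suffix_prefix_overlap(x, y, min_overlap)
  k2 <- suffix_prefix_overlap(x, yr, min_overlap)
  k3 <- suffix_prefix_overlap(revcomp(x), y, min_overlap)
  k <- c(k1, k2, k3)
  best <- which.max(k)
  c(k = k[best], combo = best)
}

merge_overlap <- function(x, y, k, combo) {
  switch(combo,
         paste0(x, substring(y, k + 1L)),
         paste0(x, substring(revcomp(y), k + 1L)),
         paste0(revcomp(x), substring(y, k + 1L)),
         x,
         y)
}

#' Greedy overlap assembly of clustered reads
#'
#' Merges reads by exact suffix-prefix overlap (both orientations
#' considered, longest overlap first) until no merge of at least
#' `min_overlap` bases remains, and returns the longest assembled contig.
#' Reads identical to or contained in another read are absorbed.
#'
#' @param seqs character vector of read sequences (>= 2)
#' @param min_overlap minimum exact overlap in bp
#' @param all when TRUE, return every terminal contig (longest first)
#'   instead of only the longest; clusters whose reads do not tile across
#'   the junction assemble into one contig per locus, and the
#'   junction-spanning one need not be the longest
#' @return the longest contig as a character scalar (or all terminal
#'   contigs when `all = TRUE`), or `NULL` when no two reads overlap
#'   (assembly failed)
#' @export
assemble_contig <- function(seqs, min_overlap = 20, all = FALSE) {
  if (length(seqs) < 2) {
    stop("assembly needs at least two reads")
  }
  seqs <- unique(as.character(seqs))
  if (length(seqs) == 1) return(seqs)  # identical reads: idempotent merge
  n0 <- length(seqs)
  n <- length(seqs)
  K <- matrix(0L, n, n)
  Cm <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      b <- best_overlap(seqs[i], seqs[j], min_overlap)
      K[i, j] <- b[["k"]]; Cm[i, j] <- b[["combo"]]
    }
  }
  merged_any <- FALSE
  while (length(seqs) > 1 && max(K) >= min_overlap) {
    idx <- which(K == max(K), arr.ind = TRUE)[1, ]
    i <- idx[[1]]; j <- idx[[2]]
    newseq <- merge_overlap(seqs[i], seqs[j], K[i, j], Cm[i, j])
    merged_any <- TRUE
    keep <- setdiff(seq_along(seqs), c(i, j))
    seqs <- c(seqs[keep], newseq)
    K <- K[keep, keep, drop = FALSE]
    Cm <- Cm[keep, keep, drop = FALSE]
    m <- length(seqs)
    K2 <- matrix(0L, m, m); K2[seq_len(m - 1L), seq_len(m - 1L)] <- K
    C2 <- matrix(0L, m, m); C2[seq_len(m - 1L), seq_len(m - 1L)] <- Cm
    K <- K2; Cm <- C2
    for (i2 in seq_len(m - 1L)) {
      b <- best_overlap(seqs[i2], newseq, min_overlap)
      K[i2, m] <- b[["k"]]; Cm[i2, m] <- b[["combo"]]
      b <- best_overlap(newseq, seqs[i2], min_overlap)
      K[m, i2] <- b[["k"]]; Cm[m, i2] <- b[["combo"]]
    }
  }
  if (!merged_any && length(seqs) == n0) return(NULL)
  seqs <- seqs[order(nchar(seqs), decreasing = TRUE)]
  if (all) seqs else seqs[1]
}

# place a seed (with <= max_mm mismatches) from one end of the contig in
# the reference; side = "prefix" anchors the contig start, side = "suffix"
# anchors its end. For each candidate placement the whole contig is
# projected onto the reference, giving per-position reference coordinates
# and match flags; the best placement is the one whose anchored end
# extends furthest at <= max_mm mismatches. regions restricts the search.
place_flank <- function(contig, ref, side, min_flank, max_mm,
                        regions = NULL) {
  L <- nchar(contig)
  k <- min_flank
  seed <- if (side == "prefix") substring(contig, 1L, k)
          else substring(contig, L - k + 1L, L)
  cvec <- strsplit(contig, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  best <- NULL
  search_space <- if (is.null(regions)) {
    lapply(names(ref), function(ch) {
      list(chrom = ch, lo = 1L,
           hi = Biostrings::width(ref)[match(ch, names(ref))])
    })
  } else regions
  j <- seq_len(L)
  for (sp in search_space) {
    chr <- ref[[sp$chrom]]
    lo <- max(1L, as.integer(sp$lo)); hi <- min(length(chr), as.integer(sp$hi))
    sub <- Biostrings::subseq(chr, lo, hi)
    svec <- strsplit(as.character(sub), "")[[1]]
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") seed else revcomp(seed)
      hits <- Biostrings::matchPattern(pat, sub, max.mismatch = max_mm)
      for (s in Biostrings::start(hits)) {
        # 0-based reference coordinate of every contig position under
        # this placement (within the search window)
        refpos0 <- if (side == "prefix") {
          if (strand == "+") (s - 1L) + (j - 1L) else (s - 1L) + (k - j)
        } else {
          if (strand == "+") (s - 1L) + (j - (L - k + 1L))
          else (s - 1L) + (L - j)
        }
        valid <- refpos0 >= 0L & refpos0 < length(svec)
        base <- rep(NA_character_, L)
        base[valid] <- svec[refpos0[valid] + 1L]
        if (strand == "-") base <- unname(comp[base])
        match <- !is.na(base) & base == cvec
        # anchored-end extension length at <= max_mm mismatches
        mm_cum <- if (side == "prefix") cumsum(!match)
                  else rev(cumsum(rev(!match)))
        within <- which(mm_cum <= max_mm & match)
        if (!length(within)) next
        aligned <- if (side == "prefix") max(within) else L - min(within) + 1L
        cand <- list(chrom = sp$chrom, strand = strand,
                     refpos0 = refpos0 + (lo - 1L), match = match,
                     aligned = aligned)
        if (is.null(best) || cand$aligned > best$aligned) best <- cand
      }
    }
  }
  best
}

#' Confirm a candidate breakpoint by split realignment of the contig
#'
#' Seeds the first and last `min_flank` bases of the contig in the
#' reference (both strands, up to `max_mismatch` mismatches each),
#' projects the whole contig onto the reference under each placement, and
#' picks the junction offset that minimises the total mismatches of the
#' split alignment (left part on the 5' locus, right part on the 3'
#' locus; leftmost junction on ties, so microhomology resolves
#' deterministically). The call is confirmed when each side aligns with
#' at most `max_mismatch` mismatches over at least `min_flank` bases.
#' Breakpoints are reported as the alignment edges at the junction, in
#' the 0-based half-open convention of [planted_fusion()], canonically
#' ordered so that side A is the smaller (chromosome, position).
#'
#' @param contig assembled contig from [assemble_contig()]
#' @param ref reference DNAStringSet
#' @param max_mismatch maximum mismatches tolerated per flank alignment
#' @param min_flank minimum aligned bases required on each side of the
#'   junction
#' @param regions optional list of search windows, each
#'   `list(chrom, lo, hi)` (1-based inclusive), to restrict realignment
#' @return a list with `chromA, posA, strandA, chromB, posB, strandB,
#'   contig, confirmed`; `confirmed = FALSE` (with NA breakpoints) when
#'   either flank fails to realign consistently
#' @export
confirm_breakpoint <- function(contig, ref, max_mismatch = 2,
                               min_flank = 25, regions = NULL) {
  L <- nchar(contig)
  unconfirmed <- list(chromA = NA_character_, posA = NA_integer_,
                      strandA = NA_character_, chromB = NA_character_,
                      posB = NA_integer_, strandB = NA_character_,
                      contig = contig, confirmed = FALSE)
  if (L <= 2 * min_flank) return(unconfirmed)
  left <- place_flank(contig, ref, "prefix", min_flank, max_mismatch,
                      regions)
  right <- place_flank(contig, ref, "suffix", min_flank, max_mismatch,
                       regions)
  if (is.null(left) || is.null(right)) return(unconfirmed)
  # candidate junction after contig position j: mismatches of the left
  # part under the prefix placement plus the right part under the suffix
  # placement
  mm_left <- cumsum(!left$match)
  mm_right <- rev(cumsum(rev(!right$match)))       # mismatches in j..L
  js <- seq(min_flank, L - min_flank)
  total <- mm_left[js] + mm_right[js + 1L]
  feasible <- mm_left[js] <= max_mismatch & mm_right[js + 1L] <= max_mismatch
  if (!any(feasible)) return(unconfirmed)
  j <- js[feasible][which.min(total[feasible])]
  # a true fusion splits across two placements; a contig that aligns
  # contiguously to one locus end-to-end is not one
  if (left$chrom == right$chrom && left$strand == right$strand &&
      all(abs(left$refpos0 - right$refpos0) <= 2L)) {
    return(unconfirmed)
  }
  posA <- if (left$strand == "+") left$refpos0[j] + 1L else left$refpos0[j]
  posB <- if (right$strand == "+") right$refpos0[j + 1L]
          else right$refpos0[j + 1L] + 1L
  call <- list(chromA = left$chrom, posA = as.integer(posA),
               strandA = left$strand, chromB = right$chrom,
               posB = as.integer(posB), strandB = right$strand,
               contig = contig, confirmed = TRUE)
  canonical_call(call)
}

#' Canonical description of a breakpoint pair
#'
#' A fused junction can be described from either strand; the two
#' descriptions are related by swapping sides and flipping both strands.
#' This helper returns the description whose A side is the smaller
#' (chromosome, position), so calls are comparable.
#'
#' @param call list with `chromA, posA, strandA, chromB, posB, strandB`
#' @return the call, possibly side-swapped
#' @export
canonical_call <- function(call) {
  swap <- (call$chromB < call$chromA) ||
    (call$chromB == call$chromA && call$posB < call$posA)
  if (!swap) return(call)
  flip <- function(s) if (s == "+") "-" else "+"
  out <- call
  out$chromA <- call$chromB; out$posA <- call$posB
  out$strandA <- flip(call$strandB)
  out$chromB <- call$chromA; out$posB <- call$posA
  out$strandB <- flip(call$strandA)
  out
}

#' Filter fusion calls by unique supporting pairs
#'
#' Retains calls supported by at least `min_pairs` unique read pairs,
#' where uniqueness means distinct (A-start, B-start) coordinate tuples
#' after duplicate removal.
#'
#' @param calls data.frame of calls with a `unique_pairs` column
#' @param min_pairs minimum unique supporting pairs (default 5)
#' @return the retained rows
#' @export
filter_support <- function(calls, min_pairs = 5) {
  if (nrow(calls) == 0) return(calls)
  calls[calls$unique_pairs >= min_pairs, , drop = FALSE]
}

#' Run the DNA fusion-detection pipeline on alignment records
#'
#' Collects discordant pairs, clusters them by breakpoint proximity, keeps
#' clusters with at least `min_support` unique pairs, assembles each
#' cluster's reads into a contig and confirms the breakpoint by split
#' realignment. Only confirmed, sufficiently supported calls are emitted.
#'
#' @param records alignment record data.frame
#' @param ref reference DNAStringSet
#' @param insert_threshold discordance insert-size cutoff in bp (strict >)
#' @param cluster_distance clustering distance in bp (strict <)
#' @param min_support minimum unique supporting pairs
#' @param min_overlap assembly overlap in bp
#' @param min_flank,max_mismatch confirmation parameters, see
#'   [confirm_breakpoint()]
#' @param search_pad bp added around each cluster locus when realigning
#' @return data.frame of confirmed calls: `chromA, posA, strandA, chromB,
#'   posB, strandB, unique_pairs, contig, confirmed`
#' @export
call_fusions <- function(records, ref, insert_threshold = 2000,
                         cluster_distance = 500, min_support = 5,
                         min_overlap = 20, min_flank = 25,
                         max_mismatch = 2, search_pad = 1000) {
  pairs <- collect_discordant(records, insert_threshold)
  clusters <- cluster_discordant(pairs, cluster_distance)
  out <- list()
  for (cl in clusters) {
    if (cl$unique_pairs < min_support) next
    seqs <- unique(c(cl$members$seqA, cl$members$seqB))
    if (length(seqs) > 120) seqs <- seqs[seq_len(120)]
    contigs <- assemble_contig(seqs, min_overlap, all = TRUE)
    if (is.null(contigs)) {
      message("cluster ", cl$chromA, ":", cl$locusA[1], "-", cl$chromB,
              ":", cl$locusB[1], ": assembly failed, dropped")
      next
    }
    regions <- list(
      list(chrom = cl$chromA, lo = cl$locusA[1] - search_pad,
           hi = cl$locusA[2] + search_pad),
      list(chrom = cl$chromB, lo = cl$locusB[1] - search_pad,
           hi = cl$locusB[2] + search_pad))
    call <- NULL
    for (contig in utils::head(contigs, 6L)) {
      call <- confirm_breakpoint(contig, ref, max_mismatch = max_mismatch,
                                 min_flank = min_flank, regions = regions)
      if (call$confirmed) break
    }
    if (!call$confirmed) {
      message("cluster ", cl$chromA, ":", cl$locusA[1],
              ": breakpoint not confirmed, dropped")
      next
    }
    out[[length(out) + 1L]] <- data.frame(
      chromA = call$chromA, posA = call$posA, strandA = call$strandA,
      chromB = call$chromB, posB = call$posB, strandB = call$strandB,
      unique_pairs = cl$unique_pairs, contig = call$contig,
      confirmed = TRUE, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(chromA = character(), posA = integer(),
                      strandA = character(), chromB = character(),
                      posB = integer(), strandB = character(),
                      unique_pairs = integer(), contig = character(),
                      confirmed = logical(), stringsAsFactors = FALSE))
  }
  calls <- do.call(rbind, out)
  filter_support(calls, min_support)
}

#' Write fusion calls as TSV
#'
#' Positions are emitted 1-based: for a `+` side this is the last retained
#' base, for a `-` side the first retained base, both equal to the
#' internal 0-based half-open junction coordinate (+1 for `-` sides).
#'
#' @param calls call data.frame from [call_fusions()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fusion_calls <- function(calls, path) {
  out <- calls
  out$posA <- ifelse(out$strandA == "+", out$posA, out$posA + 1L)
  out$posB <- ifelse(out$strandB == "+", out$posB + 1L, out$posB)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
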