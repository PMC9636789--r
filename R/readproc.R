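# Quantification of proximal/distal isoform usage from 3'-end MPRA paired
# reads: anchor mapping with mismatch tolerance, poly(A)-run cleavage-site
# calling, UMI collapsing with replicate pooling, and the internal-priming
# sequence filter.

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Map a read to a reference by its upstream anchor
#'
#' The read's prefix is compared against the anchor (first `anchor_len`
#' bases) of every reference; a unique best hit with at most `max_mismatch`
#' substitutions maps the read, ties at the best distance leave it unmapped.
#'
#' @param read1 read sequence (>= anchor_len nt).
#' @param references named character vector of reference sequences.
#' @param anchor_len anchor length (default 30).
#' @param max_mismatch maximum substitutions (default 2).
#' @return reference name, or NA if unmapped/ambiguous.
#' @export
mapRead <- function(read1, references, anchor_len = 30L, max_mismatch = 2L) {
  if (nchar(read1) < anchor_len) return(NA_character_)
  prefix <- substr(read1, 1L, anchor_len)
  anchors <- substr(references, 1L, anchor_len)
  d <- vapply(anchors, hamming, numeric(1), a = prefix)
  best <- min(d)
  if (best > max_mismatch || sum(d == best) > 1L) return(NA_character_)
  names(references)[which.min(d)]
}

# Vectorized mapping of many reads (anchor comparison as a base-wise matrix).
mapReads <- function(reads, references, anchor_len = 30L, max_mismatch = 2L) {
  anchors <- substr(references, 1L, anchor_len)
  A <- do.call(rbind, strsplit(anchors, ""))
  out <- rep(NA_character_, length(reads))
  ok <- nchar(reads) >= anchor_len
  if (!any(ok)) return(out)
  P <- do.call(rbind, strsplit(substr(reads[ok], 1L, anchor_len), ""))
  nm <- names(references)
  d <- matrix(0L, nrow(P), nrow(A))
  for (r in seq_len(nrow(A))) {
    d[, r] <- rowSums(P != matrix(A[r, ], nrow(P), anchor_len, byrow = TRUE))
  }
  best <- apply(d, 1L, min)
  uniq <- rowSums(d == best) == 1L
  hit <- best <= max_mismatch & uniq
  out[ok][hit] <- nm[apply(d[hit, , drop = FALSE], 1L, which.min)]
  out
}

#' Locate the cleavage site in a mapped read
#'
#' Searches 5' to 3' for the first window of 20 consecutive bases with at
#' most `max_mismatch` non-A bases. Leading non-A bases of the matched
#' window are trimmed (a poly(A) run cannot start with a mismatch: those
#' bases are templated reference sequence captured by the tolerance, not
#' sequencing errors). The resulting 0-based offset equals the number of
#' templated reference bases, i.e. the cleavage position in reference
#' coordinates. Reads with no qualifying window are called distal (NA).
#'
#' @param read1 mapped read sequence.
#' @param run_len poly(A) run length (default 20).
#' @param max_mismatch tolerated non-A bases in the run (default 2).
#' @return 0-based cleavage offset, or NA for distal.
#' @export
findCleavageSite <- function(read1, run_len = 20L, max_mismatch = 2L) {
  n <- nchar(read1)
  if (n < run_len) return(NA_integer_)
  isa <- as.integer(strsplit(read1, "")[[1]] == "A")
  cs <- c(0L, cumsum(isa))
  counts <- cs[(run_len + 1L):(n + 1L)] - cs[1L:(n - run_len + 1L)]
  hit <- which(counts >= run_len - max_mismatch)
  if (length(hit) == 0L) return(NA_integer_)
  j <- hit[1L]
  while (j <= n && isa[j] == 0L) j <- j + 1L
  j - 1L
}

#' Collapse cleavage calls over UMIs
#'
#' Identical (reference, UMI, replicate) tuples are counted once; the site
#' of the first occurrence is kept and conflicting duplicate sites are
#' logged. Replicates can be pooled into a single table.
#'
#' @param calls data.frame with columns `reference`, `site` (0-based offset
#'   or NA for distal), `umi`, and optionally `replicate` (default 1).
#' @param pool_replicates sum counts across replicates (default FALSE).
#' @return list(table = data.frame(reference, site, replicate, count),
#'   conflicts = logged UMI collisions with divergent sites).
#' @export
collapseUmis <- function(calls, pool_replicates = FALSE) {
  if (is.null(calls$replicate)) calls$replicate <- 1L
  key <- paste(calls$reference, calls$umi, calls$replicate, sep = "\r")
  first <- !duplicated(key)
  dup <- calls[!first, , drop = FALSE]
  kept <- calls[first, , drop = FALSE]
  conflicts <- merge(
    dup,
    kept[, c("reference", "umi", "replicate", "site")],
    by = c("reference", "umi", "replicate"), suffixes = c("_dup", "_kept"))
  conflicts <- conflicts[
    is.na(conflicts$site_dup) != is.na(conflicts$site_kept) |
      (!is.na(conflicts$site_dup) &
         conflicts$site_dup != conflicts$site_kept), , drop = FALSE]
  agg <- stats::aggregate(
    list(count = rep(1L, nrow(kept))),
    by = list(reference = kept$reference, site = ifelse(is.na(kept$site),
                                                        -1L, kept$site),
              replicate = if (pool_replicates) rep(1L, nrow(kept))
                          else kept$replicate),
    FUN = sum)
  agg$site[agg$site == -1L] <- NA_integer_
  list(table = agg[order(agg$reference, agg$site), , drop = FALSE],
       conflicts = conflicts)
}

#' Process paired reads into a cleavage call table
#'
#' Maps each read to a reference, calls its cleavage site and collapses over
#' UMIs.
#'
#' @param read1,umis character vectors (reads and matching UMIs).
#' @param references named character vector of reference sequences.
#' @param replicate replicate label(s) (default 1).
#' @param anchor_len,max_mismatch mapping parameters (see [mapRead()]).
#' @param run_mismatch tolerated non-A bases in the poly(A) run (default 2;
#'   use 0 for exact site calls on error-free reads, since the tolerant rule
#'   shifts calls up to `run_mismatch` nt 5' of the junction when the last
#'   templated bases are not adenines).
#' @return as [collapseUmis()], plus `n_unmapped`.
#' @export
processReads <- function(read1, umis, references, replicate = 1L,
                         anchor_len = 30L, max_mismatch = 2L,
                         run_mismatch = 2L) {
  stopifnot(length(read1) == length(umis))
  refs <- mapReads(read1, references, anchor_len, max_mismatch)
  mapped <- !is.na(refs)
  sites <- rep(NA_integer_, length(read1))
  sites[mapped] <- vapply(read1[mapped], findCleavageSite, integer(1),
                          max_mismatch = run_mismatch, USE.NAMES = FALSE)
  calls <- data.frame(reference = refs[mapped], site = sites[mapped],
                      umi = umis[mapped],
                      replicate = rep_len(replicate, length(read1))[mapped])
  out <- collapseUmis(calls)
  out$n_unmapped <- sum(!mapped)
  out
}

#' Isoform proportions (and variant LORs) from a cleavage call table
#'
#' The proximal isoform of a reference is the UMI count with cleavage sites
#' 0-50 nt downstream of the CSE start; the proportion is taken against all
#' counted molecules. Wildtype/variant pairs are scored by [lor()] after
#' applying the replicate filter: both members need a mean per-replicate UMI
#' count above `min_mean_umi` from at least `min_replicates` replicates.
#'
#' @param table cleavage call table from [collapseUmis()].
#' @param cse_offset 0-based CSE start (default 69).
#' @param window inclusive site window relative to the CSE start (default
#'   c(0, 50)).
#' @param pairs optional data.frame with columns `wt` and `var` naming
#'   references to score as pairs.
#' @param min_mean_umi,min_replicates replicate filter (defaults 200 and 5;
#'   relax for small designs).
#' @return list(proportions = per-reference data.frame, pairs = scored pair
#'   data.frame with excluded pairs flagged).
#' @export
estimateIsoforms <- function(table, cse_offset = 69L, window = c(0L, 50L),
                             pairs = NULL, min_mean_umi = 200,
                             min_replicates = 5L) {
  refs <- unique(table$reference)
  stats <- lapply(refs, function(r) {
    rows <- table[table$reference == r, , drop = FALSE]
    prox <- sum(rows$count[!is.na(rows$site) &
                             rows$site >= cse_offset + window[1L] &
                             rows$site <= cse_offset + window[2L]])
    total <- sum(rows$count)
    reps <- tapply(rows$count, rows$replicate, sum)
    data.frame(reference = r, proximal = prox, total = total,
               proportion = if (total > 0) prox / total else NA_real_,
               n_replicates = length(reps),
               mean_umi = mean(reps))
  })
  stats <- do.call(rbind, stats)
  scored <- NULL
  if (!is.null(pairs)) {
    scored <- pairs
    scored$lor <- NA_real_
    scored$excluded <- FALSE
    for (i in seq_len(nrow(pairs))) {
      a <- stats[stats$reference == pairs$wt[i], , drop = FALSE]
      b <- stats[stats$reference == pairs$var[i], , drop = FALSE]
      if (nrow(a) == 0L || nrow(b) == 0L ||
          a$mean_umi <= min_mean_umi || b$mean_umi <= min_mean_umi ||
          a$n_replicates < min_replicates ||
          b$n_replicates < min_replicates) {
        scored$excluded[i] <- TRUE
        next
      }
      scored$lor[i] <- lor(a$proportion, b$proportion)
    }
  }
  list(proportions = stats, pairs = scored)
}

#' Internal-priming sequence filter
#'
#' Removes sequences with strictly more than 75% adenine in any window of
#' 12-20 bp (spurious oligo(dT) priming sites mimic cleavage).
#'
#' @param sequences character vector.
#' @return list(retained, removed) character vectors.
#' @export
internalPrimingFilter <- function(sequences) {
  bad <- vapply(sequences, hasRichWindow, logical(1), USE.NAMES = FALSE)
  list(retained = sequences[!bad], removed = sequences[bad])
}
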