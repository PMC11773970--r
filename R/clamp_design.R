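#' Enumerate candidate k-mer clamps from target sequences
#'
#' Every distinct `k`-length ACGT-only substring of every target sequence
#' becomes one candidate. Windows containing ambiguity codes are excluded:
#' a synthesized clamp has a definite sequence, so degenerate windows are
#' not usable candidates. Output order is deterministic (first occurrence
#' across the input, scanning each sequence left to right).
#'
#' @param targets A [record_set()] of clamp target sequences.
#' @param k Clamp length in nt (default 17, the length of published
#'   organelle clamps; allowed 8-25).
#' @return A `ClampCandidate` data frame with columns `seq`, `k` and empty
#'   hit-set list columns, to be populated by [screen_candidates()].
#' @export
enumerate_kmers <- function(targets, k = 17L) {
  stopifnot(inherits(targets, "RecordSet"))
  k <- as.integer(k)
  if (k < 8L || k > 25L) stop("k must be between 8 and 25")
  if (nrow(targets) == 0) stop("empty target set")
  kmers <- unlist(lapply(targets$seq, seq_kmers, k = k), use.names = FALSE)
  kmers <- kmers[!duplicated(kmers)]
  if (length(kmers) == 0) stop("no candidates: every target is shorter than k or ambiguous")
  candidate_frame(kmers, k)
}

candidate_frame <- function(seqs, k) {
  n <- length(seqs)
  out <- data.frame(seq = seqs, k = rep.int(as.integer(k), n), stringsAsFactors = FALSE)
  out$target_hits <- rep(list(character(0)), n)
  out$offtarget_hits <- rep(list(character(0)), n)
  out$orientations <- rep(list(character(0)), n)
  class(out) <- c("ClampCandidate", "data.frame")
  out
}

# all ACGT-only k windows of one sequence, in scan order
seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  win <- substring(seq, starts, starts + k - 1L)
  win[!grepl("[^ACGT]", win)]
}

#' Exact-match hits of a clamp against a record set
#'
#' A record is a hit iff the clamp occurs as an exact substring of the
#' record in forward orientation, or the reverse complement of the clamp
#' does (a clamp binds either strand of the template). Ambiguity codes in
#' records never match: only literal ACGT equality counts, so specificity
#' is never overstated for degenerate positions.
#'
#' @param clamp An ACGT-only clamp sequence.
#' @param records A [record_set()].
#' @return A list with `hits` (character vector of record ids, in record
#'   order) and `orientations` (named character vector, one of `"forward"`,
#'   `"revcomp"`, `"both"` per hit).
#' @examples
#' rs <- record_set(c("r1", "r2"), c("TTACGTTT", "TTCCTT"))
#' count_exact_hits("ACGT", rs)$hits
#' @export
count_exact_hits <- function(clamp, records) {
  clamp <- normalize_clamp(clamp)
  stopifnot(inherits(records, "RecordSet"))
  rc <- revcomp(clamp)
  fwd <- grepl(clamp, records$seq, fixed = TRUE)
  rev <- grepl(rc, records$seq, fixed = TRUE)
  hit <- fwd | rev
  orientations <- ifelse(fwd & rev, "both", ifelse(fwd, "forward", "revcomp"))[hit]
  names(orientations) <- records$id[hit]
  list(hits = records$id[hit], orientations = orientations)
}

normalize_clamp <- function(clamp) {
  clamp <- normalize_dna(clamp, what = "clamp")
  if (length(clamp) != 1L) stop("exactly one clamp sequence expected")
  if (grepl("[^ACGT]", clamp)) stop("clamp must contain only A, C, G, T")
  clamp
}

#' Minimum-mismatch profile of a clamp against one record
#'
#' Slides the clamp along the record in both orientations and reports the
#' minimum ungapped Hamming distance over all k-length windows, with the
#' offset and orientation of the best window. Ambiguity codes in the record
#' count as mismatches. Ties are broken by smallest offset, forward before
#' reverse complement. Offsets are 0-based.
#'
#' @param clamp An ACGT-only clamp sequence.
#' @param record A single-row [record_set()] or one row of one.
#' @return A list of class `MismatchProfile` with fields `clamp_seq`,
#'   `record_id`, `min_mismatches`, `best_offset`, `best_orientation`.
#' @export
min_mismatch_profile <- function(clamp, record) {
  clamp <- normalize_clamp(clamp)
  if (inherits(record, "RecordSet") || is.data.frame(record)) {
    if (nrow(record) != 1L) stop("exactly one record expected")
    rec_id <- record$id
    rec_seq <- record$seq
  } else {
    stop("'record' must be a single-row RecordSet")
  }
  k <- nchar(clamp)
  if (nchar(rec_seq) < k) {
    stop(sprintf("record '%s' (%d nt) is shorter than the clamp (%d nt)", rec_id, nchar(rec_seq), k))
  }
  best <- window_mismatch_scan(clamp, rec_seq)
  structure(
    list(
      clamp_seq = clamp, record_id = rec_id,
      min_mismatches = best$mm, best_offset = best$offset,
      best_orientation = best$orientation
    ),
    class = "MismatchProfile"
  )
}

# Hamming distance of clamp (and its revcomp) to every window; returns the
# (mm, offset, orientation) triple minimal under the documented tie order.
window_mismatch_scan <- function(clamp, seq) {
  k <- nchar(clamp)
  s <- utf8ToInt(seq)
  n <- length(s)
  offs <- 0:(n - k)
  mm_for <- function(pat) {
    p <- utf8ToInt(pat)
    vapply(offs, function(o) sum(s[(o + 1L):(o + k)] != p), integer(1))
  }
  f <- mm_for(clamp)
  r <- mm_for(revcomp(clamp))
  cand <- data.frame(
    mm = c(f, r),
    offset = c(offs, offs),
    rank = rep(c(0L, 1L), each = length(offs))
  )
  i <- order(cand$mm, cand$offset, cand$rank)[1L]
  list(
    mm = cand$mm[i], offset = cand$offset[i],
    orientation = c("forward", "revcomp")[cand$rank[i] + 1L]
  )
}

#' Screen candidate clamps for target coverage and off-target exclusion
#'
#' Enumerates all k-mer candidates from the targets, populates their exact
#' perfect-match hit sets against both sequence sets (both orientations),
#' and retains a candidate only if its minimum mismatch distance to every
#' off-target record is at least `d_min`. With the default `d_min = 1` this
#' reduces to "no exact off-target match in either orientation", the usual
#' design criterion; `d_min >= 2` additionally discards candidates within
#' Hamming distance `d_min - 1` of any bacterial sequence, a stricter
#' safeguard since even single mismatches can leave residual clamp binding.
#'
#' Retained candidates are ranked by number of target hits (descending),
#' then abundance-weighted hit sum (descending), then sequence
#' (lexicographic), so reruns are reproducible.
#'
#' @param targets Target [record_set()] (host organelle ASVs).
#' @param offtargets Off-target [record_set()] (bacterial ASVs); may have 0
#'   rows, in which case no candidate is excluded.
#' @param k Clamp length, see [enumerate_kmers()].
#' @param d_min Minimum allowed mismatch distance to any off-target.
#' @return A ranked `ClampCandidate` data frame.
#' @export
screen_candidates <- function(targets, offtargets, k = 17L, d_min = 1L) {
  stopifnot(inherits(targets, "RecordSet"), inherits(offtargets, "RecordSet"))
  d_min <- as.integer(d_min)
  if (d_min < 1L) stop("d_min must be >= 1")
  if (any(targets$id %in% offtargets$id)) {
    stop("target and off-target sets share record id(s)")
  }
  cand <- enumerate_kmers(targets, k)
  cand <- populate_hits(cand, targets, offtargets)

  keep <- lengths(cand$offtarget_hits) == 0L
  if (d_min > 1L && nrow(offtargets) > 0) {
    long_enough <- nchar(offtargets$seq) >= k
    keep <- keep & vapply(seq_len(nrow(cand)), function(i) {
      if (!keep[i]) return(FALSE)
      for (j in which(long_enough)) {
        mm <- window_mismatch_scan(cand$seq[i], offtargets$seq[j])$mm
        if (mm < d_min) return(FALSE)
      }
      TRUE
    }, logical(1))
  }
  cand <- cand[keep, , drop = FALSE]

  wsum <- vapply(cand$target_hits, function(ids) {
    sum(targets$abundance[match(ids, targets$id)])
  }, numeric(1))
  ord <- order(-lengths(cand$target_hits), -wsum, cand$seq)
  cand <- cand[ord, , drop = FALSE]
  rownames(cand) <- NULL
  class(cand) <- c("ClampCandidate", "data.frame")
  cand
}

# Populate exact-hit sets for many candidates at once via k-mer hashing:
# candidate c hits record r forward iff c is among r's k-mers, and in
# revcomp orientation iff revcomp(c) is. Equivalent to per-candidate
# substring search but linear in total sequence length.
populate_hits <- function(cand, targets, offtargets) {
  k <- cand$k[1L]
  index_of <- function(records) {
    if (nrow(records) == 0) {
      return(list(fwd = list(), rc = list()))
    }
    km <- lapply(records$seq, seq_kmers, k = k)
    ids <- rep(records$id, lengths(km))
    km <- unlist(km, use.names = FALSE)
    km_rc <- if (length(km)) revcomp(km) else character(0)
    list(
      fwd = split(ids, factor(km, levels = unique(km))),
      rc = split(ids, factor(km_rc, levels = unique(km_rc)))
    )
  }
  tidx <- index_of(targets)
  oidx <- index_of(offtargets)
  lookup <- function(idx, seqs) {
    f <- idx$fwd[seqs]
    r <- idx$rc[seqs]
    list(fwd = f, rc = r)
  }
  th <- lookup(tidx, cand$seq)
  oh <- lookup(oidx, cand$seq)
  for (i in seq_len(nrow(cand))) {
    fwd_ids <- unique(th$fwd[[i]])
    rc_ids <- unique(th$rc[[i]])
    all_ids <- targets$id[targets$id %in% c(fwd_ids, rc_ids)]
    cand$target_hits[[i]] <- all_ids
    ori <- ifelse(all_ids %in% fwd_ids & all_ids %in% rc_ids, "both",
      ifelse(all_ids %in% fwd_ids, "forward", "revcomp")
    )
    names(ori) <- all_ids
    cand$orientations[[i]] <- ori
    off_ids <- unique(c(oh$fwd[[i]], oh$rc[[i]]))
    cand$offtarget_hits[[i]] <- offtargets$id[offtargets$id %in% off_ids]
  }
  cand
}
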