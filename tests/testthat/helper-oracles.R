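# Naive reference implementations used as independent oracles. They share
# no code with the package: everything is explicit character-level looping.

ORACLE_COMP <- c(
  A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S", W = "W",
  K = "M", M = "K", B = "V", D = "H", H = "D", V = "B", N = "N"
)

oracle_revcomp <- function(s) {
  chars <- strsplit(s, "")[[1]]
  paste(rev(unname(ORACLE_COMP[chars])), collapse = "")
}

# exact containment of pattern in subject, literal character equality
oracle_contains <- function(subject, pattern) {
  n <- nchar(subject)
  k <- nchar(pattern)
  if (k > n) return(FALSE)
  p <- strsplit(pattern, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  for (o in 0:(n - k)) {
    if (all(s[(o + 1):(o + k)] == p)) return(TRUE)
  }
  FALSE
}

# hit ids of clamp against sequences (either orientation)
oracle_hits <- function(clamp, ids, seqs) {
  rc <- oracle_revcomp(clamp)
  hit <- vapply(seqs, function(s) {
    oracle_contains(s, clamp) || oracle_contains(s, rc)
  }, logical(1))
  ids[hit]
}

# min mismatches over both orientations with (mm, offset, fwd-first) ties
oracle_min_mismatch <- function(clamp, seq) {
  k <- nchar(clamp)
  n <- nchar(seq)
  s <- strsplit(seq, "")[[1]]
  best <- list(mm = Inf, offset = NA, orientation = NA)
  for (orient in c("forward", "revcomp")) {
    pat <- if (orient == "forward") clamp else oracle_revcomp(clamp)
    p <- strsplit(pat, "")[[1]]
    for (o in 0:(n - k)) {
      mm <- sum(s[(o + 1):(o + k)] != p)
      better <- mm < best$mm ||
        (mm == best$mm && o < best$offset) ||
        (mm == best$mm && o == best$offset &&
          orient == "forward" && best$orientation == "revcomp")
      if (better) best <- list(mm = mm, offset = o, orientation = orient)
    }
  }
  best
}

# exhaustive best cover: largest covered union over all subsets of size
# <= max_panel
oracle_best_cover <- function(hit_sets, max_panel) {
  n <- length(hit_sets)
  best <- 0L
  for (size in 0:min(max_panel, n)) {
    if (size == 0) next
    combos <- utils::combn(n, size, simplify = FALSE)
    for (cc in combos) {
      u <- length(unique(unlist(hit_sets[cc])))
      if (u > best) best <- u
    }
  }
  best
}

# brute-force hairpin: any fold-back stem of length >= min_stem with loop
# >= min_loop; returns the longest stem length found (0 if none)
oracle_hairpin_stem <- function(seq, min_stem, min_loop) {
  n <- nchar(seq)
  longest <- 0L
  for (s in min_stem:n) {
    for (i in 0:(n - s)) {
      stem1 <- substr(seq, i + 1, i + s)
      for (j in 0:(n - s)) {
        if (j >= i + s + min_loop &&
          substr(seq, j + 1, j + s) == oracle_revcomp(stem1)) {
          longest <- max(longest, s)
        }
      }
    }
  }
  longest
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small RecordSet of random sequences
random_record_set <- function(n, len_range = c(20, 60), role = "unlabeled", prefix = "r") {
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  record_set(
    paste0(prefix, seq_len(n)),
    vapply(lens, random_dna_str, character(1)),
    role = role
  )
}
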