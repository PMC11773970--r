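IUPAC_DNA <- "ACGTRYSWKMBDHVN"
IUPAC_DNA_COMPLEMENT <- "TGCAYRSWMKVHDBN"

#' Construct a set of labelled sequence records
#'
#' A `RecordSet` is the basic container shared by all pnaclamp operations: a
#' data frame with one row per sequence and columns `id`, `seq`, `role` and
#' `abundance`. Roles distinguish clamp *targets* (host organelle ASVs) from
#' *off-targets* (bacterial ASVs) during specificity screening.
#'
#' @param id Character vector of unique record identifiers.
#' @param seq Character vector of DNA sequences (IUPAC codes; lowercase and
#'   `U` are normalised to uppercase `T`).
#' @param role One of `"target"`, `"offtarget"`, `"unlabeled"`; recycled.
#' @param abundance Non-negative read-count weights, default 1.
#' @return A data frame of class `RecordSet`.
#' @examples
#' record_set(c("a", "b"), c("ACGT", "ggcu"), role = "target")
#' @export
record_set <- function(id, seq, role = "unlabeled", abundance = 1) {
  id <- as.character(id)
  seq <- normalize_dna(seq)
  role <- match.arg(role, c("target", "offtarget", "unlabeled"), several.ok = TRUE)
  if (length(id) != length(seq)) {
    stop("'id' and 'seq' must have the same length")
  }
  dup <- id[duplicated(id)]
  if (length(dup) > 0) {
    stop("duplicate record id(s): ", paste(unique(dup), collapse = ", "))
  }
  rs <- data.frame(
    id = id,
    seq = seq,
    role = rep_len(role, length(id)),
    abundance = rep_len(as.numeric(abundance), length(id)),
    stringsAsFactors = FALSE
  )
  if (any(rs$abundance < 0)) stop("abundance must be non-negative")
  class(rs) <- c("RecordSet", "data.frame")
  rs
}

#' @export
print.RecordSet <- function(x, ...) {
  cat(sprintf(
    "RecordSet with %d record(s): %s\n", nrow(x),
    paste(sprintf("%s=%d", names(role_counts(x)), role_counts(x)), collapse = ", ")
  ))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Count records per role
#'
#' @param records A [record_set()].
#' @return Named integer vector over roles target/offtarget/unlabeled.
#' @export
role_counts <- function(records) {
  stopifnot(inherits(records, "RecordSet"))
  roles <- factor(records$role, levels = c("target", "offtarget", "unlabeled"))
  table_to_int(table(roles))
}

table_to_int <- function(tb) {
  out <- as.integer(tb)
  names(out) <- names(tb)
  out
}

# Uppercase, U->T, and validate against the IUPAC DNA alphabet. Reports the
# 1-based position of the first offending character so malformed FASTA input
# is easy to locate.
normalize_dna <- function(seq, what = "sequence") {
  seq <- chartr("u", "t", toupper(as.character(seq)))
  seq <- chartr("U", "T", seq)
  bad <- regexpr(sprintf("[^%s]", IUPAC_DNA), seq)
  hit <- which(bad > 0)
  if (length(hit) > 0) {
    i <- hit[1L]
    stop(sprintf(
      "non-IUPAC character '%s' in %s %d at position %d",
      substr(seq[i], bad[i], bad[i]), what, i, bad[i]
    ))
  }
  if (any(!nzchar(seq))) stop("empty sequence not allowed")
  seq
}

#' Read a FASTA file into a RecordSet
#'
#' Sequences are uppercased, `U` is mapped to `T` (rRNA sequences are
#' sometimes deposited as RNA), and every record receives the given role.
#' Multi-line FASTA is supported; soft-masking (lowercase) carries no meaning
#' here and is discarded.
#'
#' @param path Path to a FASTA file.
#' @param role Role applied to all records: `"target"`, `"offtarget"` or
#'   `"unlabeled"`.
#' @return A [record_set()].
#' @export
read_fasta <- function(path, role = "unlabeled") {
  if (!file.exists(path)) stop("file not found: ", path)
  xs <- Biostrings::readBStringSet(path)
  if (length(xs) == 0) stop("no records in ", path)
  ids <- sub("\\s.*$", "", names(xs))
  record_set(ids, as.character(xs), role = role)
}

#' Write a RecordSet to FASTA
#'
#' @param records A [record_set()].
#' @param path Output path.
#' @param width Line width for wrapping sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(inherits(records, "RecordSet"))
  xs <- Biostrings::DNAStringSet(records$seq)
  names(xs) <- records$id
  Biostrings::writeXStringSet(xs, path, width = width)
  invisible(path)
}

#' Reverse complement of an IUPAC DNA string
#'
#' Ambiguity codes are complemented to their IUPAC counterparts (e.g. `R`
#' to `Y`, `B` to `V`); `revcomp(revcomp(s))` is always `s`.
#'
#' @param seq Character vector of IUPAC DNA strings.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("AAGG") # "CCTT"
#' @export
revcomp <- function(seq) {
  seq <- normalize_dna(seq)
  comp <- chartr(IUPAC_DNA, IUPAC_DNA_COMPLEMENT, seq)
  vapply(comp, function(s) {
    intToUtf8(rev(utf8ToInt(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' Write a clamp panel report
#'
#' Emits a deterministic TSV with one row per selected clamp: sequence,
#' synthesis string, covered targets, off-target hits, Tm estimates and gate
#' verdicts. Byte-identical across runs on identical input.
#'
#' @param panel A `PanelSolution` from [greedy_cover()].
#' @param qc A list of `ThermoQCReport` objects from [thermo_report()], one
#'   per clamp in `panel`, in the same order.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_report <- function(panel, qc, path) {
  stopifnot(inherits(panel, "PanelSolution"))
  seqs <- panel$clamps$seq
  qc_seqs <- vapply(qc, function(r) r$clamp_seq, character(1))
  if (!identical(unname(seqs), unname(qc_seqs))) {
    stop("panel and qc refer to different clamp sequences")
  }
  header <- paste(
    c(
      "clamp_seq", "synthesis", "n_targets_covered", "targets_covered",
      "n_offtarget_hits", "tm_dna_c", "tm_pna_c", "clamp_temp_c",
      "tm_pass", "hairpin", "gate"
    ),
    collapse = "\t"
  )
  rows <- character(0)
  if (length(seqs) > 0) {
    rows <- vapply(seq_along(seqs), function(i) {
      r <- qc[[i]]
      hits <- sort(panel$clamps$target_hits[[i]])
      off <- panel$clamps$offtarget_hits[[i]]
      paste(
        c(
          seqs[i], r$synthesis, length(hits), paste(hits, collapse = ","),
          length(off), num_str(r$tm_dna), num_str(r$tm_pna),
          ifelse(is.na(r$clamp_temp), "infeasible", num_str(r$clamp_temp)),
          r$tm_pass, r$hairpin$has_hairpin,
          if (isTRUE(r$gate_pass)) "pass" else "fail"
        ),
        collapse = "\t"
      )
    }, character(1))
  }
  writeLines(c(header, rows), path, sep = "\n")
  invisible(path)
}

# fixed-format numbers so report bytes never depend on options(digits)
num_str <- function(x) formatC(x, format = "f", digits = 3)
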