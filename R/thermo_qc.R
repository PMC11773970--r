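# Nearest-neighbor thermodynamic parameter sets for DNA/DNA duplexes.
# Values are (dH kcal/mol, dS cal/(mol K)) per stacked dinucleotide, plus
# initiation/terminal terms. "breslauer1986" is the classic set whose
# reference condition is 1 M NaCl; "santalucia2004" is the unified set.
NN_TABLES <- list(
  breslauer1986 = list(
    stack = matrix(
      c(
        -9.1, -24.0, # AA/TT
        -8.6, -23.9, # AT/AT
        -6.0, -16.9, # TA/TA
        -5.8, -12.9, # CA/GT
        -6.5, -17.3, # GT/CA
        -7.8, -20.8, # CT/GA
        -5.6, -13.5, # GA/CT
        -11.9, -27.8, # CG/CG
        -11.1, -26.7, # GC/GC
        -11.0, -26.6 # GG/CC
      ),
      ncol = 2, byrow = TRUE,
      dimnames = list(c(
        "AA/TT", "AT/AT", "TA/TA", "CA/GT", "GT/CA",
        "CT/GA", "GA/CT", "CG/CG", "GC/GC", "GG/CC"
      ), c("dh", "ds"))
    ),
    init = c(dh = 0, ds = 0),
    init_at_end = c(dh = 0, ds = 0),
    init_gc_end = c(dh = 0, ds = 0),
    init_one_gc = c(dh = 0, ds = -16.8),
    init_all_at = c(dh = 0, ds = -20.1),
    sym = c(dh = 0, ds = -1.3)
  ),
  santalucia2004 = list(
    stack = matrix(
      c(
        -7.9, -22.2,
        -7.2, -20.4,
        -7.2, -21.3,
        -8.5, -22.7,
        -8.4, -22.4,
        -7.8, -21.0,
        -8.2, -22.2,
        -10.6, -27.2,
        -9.8, -24.4,
        -8.0, -19.9
      ),
      ncol = 2, byrow = TRUE,
      dimnames = list(c(
        "AA/TT", "AT/AT", "TA/TA", "CA/GT", "GT/CA",
        "CT/GA", "GA/CT", "CG/CG", "GC/GC", "GG/CC"
      ), c("dh", "ds"))
    ),
    init = c(dh = 0, ds = 0),
    init_at_end = c(dh = 2.3, ds = 4.1),
    init_gc_end = c(dh = 0.1, ds = -2.8),
    init_one_gc = c(dh = 0, ds = 0),
    init_all_at = c(dh = 0, ds = 0),
    sym = c(dh = 0, ds = -1.4)
  )
)

#' Default duplex conditions for melting-temperature estimation
#'
#' The defaults pin the DNA/DNA nearest-neighbor calculation to the
#' Breslauer parameter set at its 1 M Na+ reference condition with 0.25 uM
#' of each strand. This is the regime in which the linear PNA/DNA Tm
#' correlation used by [pna_tm()] was calibrated, so the two stages are
#' consistent; lowering `na_m` (with the salt correction this enables)
#' would shift the DNA Tm out of the correlation's calibration range.
#'
#' @param conc_uM Concentration of each strand, in uM.
#' @param na_m Monovalent cation concentration, mol/L. At 1.0 no salt
#'   correction is applied (reference condition); other values apply the
#'   entropic correction `dS + 0.368 (N-1) ln[Na+]`.
#' @param nn_table `"breslauer1986"` or `"santalucia2004"`.
#' @return A list of class `tm_conditions`.
#' @export
tm_conditions <- function(conc_uM = 0.25, na_m = 1.0,
                          nn_table = c("breslauer1986", "santalucia2004")) {
  nn_table <- match.arg(nn_table)
  if (conc_uM <= 0 || na_m <= 0) stop("concentrations must be positive")
  structure(
    list(conc_uM = conc_uM, na_m = na_m, nn_table = nn_table),
    class = "tm_conditions"
  )
}

#' Pyrimidine fraction of a sequence
#'
#' Fraction of C and T bases; a covariate in the PNA/DNA Tm correlation
#' (purine-rich PNAs melt higher than pyrimidine-rich ones of equal DNA
#' Tm).
#'
#' @param seq ACGT-only DNA string.
#' @return Numeric in \[0, 1\].
#' @examples
#' fraction_pyrimidine("CCTT") # 1
#' @export
fraction_pyrimidine <- function(seq) {
  seq <- normalize_clamp(seq)
  n <- nchar(seq)
  (n - nchar(gsub("[CT]", "", seq))) / n
}

#' Nearest-neighbor DNA/DNA duplex melting temperature
#'
#' Two-state nearest-neighbor model:
#' `Tm = 1000 dH / (dS + R ln k) - 273.15`, with `dH`/`dS` summed over
#' stacked dinucleotides plus initiation and terminal terms of the chosen
#' parameter set, `R = 1.987 cal/(mol K)` and `k = cA - cB/2` for
#' non-self-complementary duplexes at strand concentrations `cA = cB`
#' (`k = cA`, with a symmetry entropy term, for self-complementary ones).
#' Away from the 1 M reference the entropic salt correction
#' `dS + 0.368 (N-1) ln[Na+]` is applied.
#'
#' @param seq ACGT-only DNA string, length >= 8.
#' @param conditions A [tm_conditions()] object.
#' @return Tm in degrees Celsius.
#' @export
nn_dna_tm <- function(seq, conditions = tm_conditions()) {
  seq <- normalize_clamp(seq)
  stopifnot(inherits(conditions, "tm_conditions"))
  n <- nchar(seq)
  if (n < 8L) stop("sequence must be at least 8 nt")
  tab <- NN_TABLES[[conditions$nn_table]]

  dh <- tab$init[["dh"]]
  ds <- tab$init[["ds"]]

  gc_count <- n - nchar(gsub("[GC]", "", seq))
  if (gc_count == 0L) {
    dh <- dh + tab$init_all_at[["dh"]]
    ds <- ds + tab$init_all_at[["ds"]]
  } else {
    dh <- dh + tab$init_one_gc[["dh"]]
    ds <- ds + tab$init_one_gc[["ds"]]
  }
  ends <- c(substr(seq, 1L, 1L), substr(seq, n, n))
  n_at_end <- sum(ends %in% c("A", "T"))
  n_gc_end <- sum(ends %in% c("G", "C"))
  dh <- dh + n_at_end * tab$init_at_end[["dh"]] + n_gc_end * tab$init_gc_end[["dh"]]
  ds <- ds + n_at_end * tab$init_at_end[["ds"]] + n_gc_end * tab$init_gc_end[["ds"]]

  di <- substring(seq, 1:(n - 1L), 2:n)
  keys <- dinucleotide_keys(di)
  dh <- dh + sum(tab$stack[keys, "dh"])
  ds <- ds + sum(tab$stack[keys, "ds"])

  selfcomp <- identical(seq, revcomp(seq))
  conc <- conditions$conc_uM * 1e-6
  if (selfcomp) {
    dh <- dh + tab$sym[["dh"]]
    ds <- ds + tab$sym[["ds"]]
    k <- conc
  } else {
    k <- conc / 2
  }
  if (conditions$na_m != 1.0) {
    ds <- ds + 0.368 * (n - 1L) * log(conditions$na_m)
  }
  1000 * dh / (ds + 1.987 * log(k)) - 273.15
}

# map each dinucleotide to the canonical NN table key (itself or the key
# whose reverse-complement reading it is)
dinucleotide_keys <- function(di) {
  canon <- rownames(NN_TABLES[[1]]$stack)
  alias <- stats::setNames(canon, substr(canon, 1L, 2L))
  out <- alias[di]
  miss <- is.na(out)
  if (any(miss)) {
    out[miss] <- alias[revcomp(di[miss])]
  }
  unname(out)
}

#' Default coefficients of the linear PNA/DNA Tm correlation
#'
#' `tm_pna = c0 + c1 * tm_dna + c2 * fpyr + c3 * length`, the Giesen-style
#' correlation relating the PNA/DNA duplex Tm to the nearest-neighbor
#' DNA/DNA Tm of the same sequence, its pyrimidine fraction and its length.
#' The coefficients are configuration, not code: pass a modified set to
#' [pna_tm()] to recalibrate against melting data for a given chemistry.
#'
#' @return Named numeric vector `c0`, `c1`, `c2`, `c3`.
#' @export
pna_tm_coefficients <- function() {
  c(c0 = 20.79, c1 = 0.83, c2 = -26.13, c3 = 0.44)
}

#' Estimated PNA/DNA duplex melting temperature
#'
#' @param seq ACGT-only clamp sequence (read as the DNA sequence the PNA
#'   mimics).
#' @param conditions [tm_conditions()] for the underlying DNA/DNA Tm.
#' @param coef Correlation coefficients, see [pna_tm_coefficients()].
#' @return Estimated PNA/DNA Tm in degrees Celsius.
#' @examples
#' pna_tm("GTGAATTGGTTTCGAGA")
#' @export
pna_tm <- function(seq, conditions = tm_conditions(), coef = pna_tm_coefficients()) {
  seq <- normalize_clamp(seq)
  stopifnot(all(c("c0", "c1", "c2", "c3") %in% names(coef)))
  tm_dna <- nn_dna_tm(seq, conditions)
  unname(
    coef[["c0"]] + coef[["c1"]] * tm_dna +
      coef[["c2"]] * fraction_pyrimidine(seq) + coef[["c3"]] * nchar(seq)
  )
}

#' Recommended PCR clamping temperature
#'
#' The clamping step of the cycle must sit 5-10 degrees C below the clamp
#' Tm (so the clamp is bound while primers are not displaced) and above the
#' primer Tm (so primers do not anneal during clamping). The recommended
#' value is `max(tm_pna - 10, primer_tm + 2)` when that lies within the
#' feasible window `[tm_pna - 10, tm_pna - 5]`, rounded to the nearest
#' degree; otherwise the window is empty above the primers and `NA` is
#' returned with a message. The +2 degree guard band above the primer Tm is
#' a heuristic margin against primer annealing during the clamping step.
#'
#' @param tm_pna Clamp PNA/DNA Tm, degrees C.
#' @param primer_tm Primer Tm, degrees C (default 66, typical for V4
#'   primers 515F/806R).
#' @return Recommended temperature in degrees C, or `NA_real_` if
#'   infeasible.
#' @examples
#' recommend_clamping_temp(76, 66) # 68
#' @export
recommend_clamping_temp <- function(tm_pna, primer_tm = 66) {
  stopifnot(is.finite(tm_pna), is.finite(primer_tm))
  rec <- max(tm_pna - 10, primer_tm + 2)
  if (rec > tm_pna - 5) {
    message(sprintf(
      "no feasible clamping temperature: need %.1f C (primer Tm %.1f + 2) but window tops out at %.1f C (clamp Tm %.1f - 5)",
      rec, primer_tm, tm_pna - 5, tm_pna
    ))
    return(NA_real_)
  }
  round(rec)
}

#' Screen a clamp for hairpin self-structure
#'
#' Exhaustively scans all pairs of non-overlapping intervals where the
#' second interval is the reverse complement of the first (a fold-back
#' stem) separated by at least `min_loop` unpaired bases, and reports the
#' longest such stem. Intervals are 0-based, half-open.
#'
#' @param seq ACGT-only clamp sequence.
#' @param min_stem Minimum stem length to call a hairpin (default 4).
#' @param min_loop Minimum loop length between the stem halves (default 3,
#'   about the smallest loop a nucleic acid backbone can close).
#' @return List of class `HairpinReport`: `has_hairpin`, `stem_len`,
#'   `loop_len`, `stem_positions` (list of two `c(start, end)` intervals,
#'   0-based half-open; `NULL` if none).
#' @examples
#' hairpin_scan("GGGGAAATTTTCCCC")$has_hairpin
#' @export
hairpin_scan <- function(seq, min_stem = 4L, min_loop = 3L) {
  seq <- normalize_clamp(seq)
  min_stem <- as.integer(min_stem)
  min_loop <- as.integer(min_loop)
  if (min_stem < 2L) stop("min_stem must be >= 2")
  if (min_loop < 0L) stop("min_loop must be >= 0")
  n <- nchar(seq)
  best <- NULL
  for (s in seq.int(min_stem, max(min_stem, n))) {
    if (2L * s + min_loop > n) break
    for (i in 0:(n - 2L * s - min_loop)) {
      stem1 <- substr(seq, i + 1L, i + s)
      rc1 <- revcomp(stem1)
      for (j in seq.int(i + s + min_loop, n - s)) {
        if (substr(seq, j + 1L, j + s) == rc1) {
          loop <- j - (i + s)
          if (is.null(best) || s > best$stem_len) {
            best <- list(
              stem_len = s, loop_len = loop,
              stem_positions = list(c(i, i + s), c(j, j + s))
            )
          }
          break
        }
      }
    }
  }
  structure(
    c(list(has_hairpin = !is.null(best)), if (is.null(best)) {
      list(stem_len = 0L, loop_len = NA_integer_, stem_positions = NULL)
    } else {
      best
    }),
    class = "HairpinReport"
  )
}

#' Synthesis string for a clamp
#'
#' PNA clamps are routinely synthesized with N-terminal lysines to improve
#' aqueous solubility; the N terminus of a PNA corresponds to the 5' end of
#' the DNA sequence it mimics. Rendered `"KK-<seq>"` for the default two
#' lysines; with `lysine_count = 0` the bare sequence is returned.
#'
#' @param seq ACGT-only clamp sequence.
#' @param lysine_count Number of N-terminal lysines (default 2).
#' @return Synthesis string.
#' @examples
#' synthesis_spec("GTGAATTGGTTTCGAGA") # "KK-GTGAATTGGTTTCGAGA"
#' @export
synthesis_spec <- function(seq, lysine_count = 2L) {
  seq <- normalize_clamp(seq)
  lysine_count <- as.integer(lysine_count)
  if (lysine_count < 0L) stop("lysine_count must be >= 0")
  if (lysine_count == 0L) {
    return(seq)
  }
  paste0(strrep("K", lysine_count), "-", seq)
}

#' Protocol defaults for clamp QC and PCR use
#'
#' @param pcr_conc Clamp concentration in the PCR, uM.
#' @param conc_range Typical working range, uM.
#' @param conc_max_suggested Upper concentration worth titrating, uM.
#' @param primer_tm Primer Tm, degrees C.
#' @param tm_threshold Minimum effective clamp PNA/DNA Tm, degrees C.
#' @param lysine_count Solubility lysines prepended at synthesis.
#' @param min_stem,min_loop Hairpin screen thresholds, nt.
#' @return List of class `ProtocolDefaults`.
#' @export
protocol_defaults <- function(pcr_conc = 1, conc_range = c(0.4, 2),
                              conc_max_suggested = 5, primer_tm = 66,
                              tm_threshold = 72, lysine_count = 2L,
                              min_stem = 4L, min_loop = 3L) {
  if (pcr_conc <= 0 || pcr_conc > conc_max_suggested) {
    stop("pcr_conc must be in (0, conc_max_suggested]")
  }
  if (conc_range[1] >= conc_range[2]) stop("conc_range must be increasing")
  structure(
    list(
      pcr_conc = pcr_conc, conc_range = conc_range,
      conc_max_suggested = conc_max_suggested, primer_tm = primer_tm,
      tm_threshold = tm_threshold, lysine_count = as.integer(lysine_count),
      min_stem = as.integer(min_stem), min_loop = as.integer(min_loop)
    ),
    class = "ProtocolDefaults"
  )
}

#' Full thermodynamic/structural QC report for one clamp
#'
#' @param seq ACGT-only clamp sequence.
#' @param defaults [protocol_defaults()].
#' @param conditions [tm_conditions()] for the DNA Tm stage.
#' @param coef PNA Tm correlation coefficients.
#' @return List of class `ThermoQCReport` with `clamp_seq`, `fpyr`,
#'   `tm_dna`, `tm_pna`, `tm_pass`, `hairpin`, `clamp_temp` (`NA` when
#'   infeasible), `synthesis`.
#' @export
thermo_report <- function(seq, defaults = protocol_defaults(),
                          conditions = tm_conditions(),
                          coef = pna_tm_coefficients()) {
  seq <- normalize_clamp(seq)
  stopifnot(inherits(defaults, "ProtocolDefaults"))
  tm_dna <- nn_dna_tm(seq, conditions)
  tm_pna <- pna_tm(seq, conditions, coef)
  hairpin <- hairpin_scan(seq, defaults$min_stem, defaults$min_loop)
  clamp_temp <- suppressMessages(
    recommend_clamping_temp(tm_pna, defaults$primer_tm)
  )
  structure(
    list(
      clamp_seq = seq,
      fpyr = fraction_pyrimidine(seq),
      tm_dna = tm_dna,
      tm_pna = tm_pna,
      tm_pass = tm_pna >= defaults$tm_threshold,
      hairpin = hairpin,
      clamp_temp = clamp_temp,
      synthesis = synthesis_spec(seq, defaults$lysine_count)
    ),
    class = "ThermoQCReport"
  )
}

#' @export
print.ThermoQCReport <- function(x, ...) {
  cat(sprintf(
    "ThermoQCReport %s\n  Tm(DNA) %.1f C, Tm(PNA) %.1f C [%s], clamping at %s, hairpin: %s\n  synthesis: %s\n",
    x$clamp_seq, x$tm_dna, x$tm_pna,
    if (x$tm_pass) "pass" else "below threshold",
    if (is.na(x$clamp_temp)) "infeasible" else sprintf("%d C", as.integer(x$clamp_temp)),
    if (x$hairpin$has_hairpin) sprintf("stem %d", x$hairpin$stem_len) else "none",
    x$synthesis
  ))
  invisible(x)
}

#' Combined pass/fail gate for a screened candidate
#'
#' A candidate passes iff its estimated PNA Tm clears the threshold, no
#' hairpin self-structure was found, and it has zero off-target hits. Every
#' failed gate is named in `reasons`.
#'
#' @param candidate One row of a `ClampCandidate` data frame.
#' @param report The [thermo_report()] computed for the same sequence.
#' @return List with `pass` (logical) and `reasons` (character vector,
#'   empty when passing).
#' @export
qc_gate <- function(candidate, report) {
  stopifnot(inherits(report, "ThermoQCReport"))
  if (nrow(candidate) != 1L) stop("exactly one candidate row expected")
  if (!identical(candidate$seq, report$clamp_seq)) {
    stop("report was not computed for this candidate")
  }
  reasons <- character(0)
  if (!report$tm_pass) reasons <- c(reasons, "Tm below threshold")
  if (report$hairpin$has_hairpin) reasons <- c(reasons, "hairpin self-structure")
  if (length(candidate$offtarget_hits[[1]]) > 0) {
    reasons <- c(reasons, "off-target exact match")
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}
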