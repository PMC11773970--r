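#' Published clamp sequences for host organelle depletion in oak
#'
#' The five clamp sequences used or proposed for suppressing chloroplast
#' and mitochondrial 16S co-amplification in *Quercus* microbiome surveys:
#' the universal plastid clamp (`pPNA`), the universal mitochondrial clamp
#' (`mPNA_universal`), the oak-specific mitochondrial clamp (`qmPNA`) and
#' two additional oak mitochondrial variants (`qmPNAv2`, `qmPNAv3`). All
#' are 17-mers, written 5' to 3' of the DNA sequence the PNA mimics.
#'
#' @return Named character vector of 5 sequences.
#' @examples
#' oak_clamps()[["qmPNA"]]
#' @export
oak_clamps <- function() {
  c(
    pPNA = "GGCTCAACCCTGGACAG",
    mPNA_universal = "GGCAAGTGTTCTTCGGA",
    qmPNA = "GTGAATTGGTTTCGAGA",
    qmPNAv2 = "GTGGAATTTCGTGTGTA",
    qmPNAv3 = "GGTTGAAAGTGAAAGTC"
  )
}

#' Specification for a synthetic ASV fixture
#'
#' Describes a synthetic pair of target (host organelle) and off-target
#' (bacterial) ASV sets in which known clamp k-mers are planted into a
#' chosen fraction of targets and are guaranteed absent from all
#' off-targets. Defaults emulate the scale of an oak V4 survey: 93
#' mitochondrial target ASVs, the 20 most abundant bacterial ASVs as
#' off-targets, ~250 bp sequences, and the three oak mitochondrial clamps
#' planted at carrier fractions 18/93, 27/93 and 33/93 — the coverage
#' counts of the published three-clamp panel.
#'
#' @param n_target Number of target ASVs.
#' @param n_offtarget Number of off-target ASVs.
#' @param seq_len Sequence length, nt.
#' @param planted_kmers Named numeric vector: planted k-mer sequences as
#'   names, per-k-mer carrier fractions as values.
#' @param mutation_rate Per-carrier probability that the planted site
#'   receives one substitution (making it an inexact site).
#' @param seed Integer seed; fixed seed gives identical output.
#' @return List of class `FixtureSpec`.
#' @export
fixture_spec <- function(n_target = 93L, n_offtarget = 20L, seq_len = 250L,
                         planted_kmers = stats::setNames(
                           c(18, 27, 33) / 93,
                           unname(oak_clamps()[c("qmPNA", "qmPNAv2", "qmPNAv3")])
                         ),
                         mutation_rate = 0, seed = 1L) {
  kmers <- normalize_dna(names(planted_kmers))
  if (any(grepl("[^ACGT]", kmers))) stop("planted k-mers must be ACGT-only")
  frac <- as.numeric(planted_kmers)
  if (any(frac < 0 | frac > 1)) stop("carrier fractions must be in [0, 1]")
  if (any(nchar(kmers) > seq_len)) stop("seq_len shorter than a planted k-mer")
  if (mutation_rate < 0 || mutation_rate > 1) stop("mutation_rate must be in [0, 1]")
  structure(
    list(
      n_target = as.integer(n_target), n_offtarget = as.integer(n_offtarget),
      seq_len = as.integer(seq_len),
      planted_kmers = stats::setNames(frac, kmers),
      mutation_rate = mutation_rate, seed = as.integer(seed)
    ),
    class = "FixtureSpec"
  )
}

#' Simulate target and off-target ASV sets with planted clamp sites
#'
#' Backgrounds are i.i.d. uniform ACGT. Any background (target or
#' off-target) that happens to contain a planted k-mer in either
#' orientation is rejection-sampled away, so the truth map is exact: a
#' planted k-mer occurs in precisely the targets it was planted into, and
#' never in an off-target. Carrier counts are deterministic
#' (`round(fraction * n_target)`), carriers are drawn without replacement
#' under the seed, and each carrier's site is overwritten at a fixed slot
#' per k-mer (slots spaced so multiple planted k-mers never overlap).
#' With `mutation_rate > 0` a carrier's site receives one substitution
#' with that probability; only intact (unmutated) sites enter the truth
#' map. Insertions are re-checked after writing: if overwriting created a
#' stray occurrence of any planted k-mer, the sequence is redrawn.
#'
#' @param spec A [fixture_spec()].
#' @return List with `targets` and `offtargets` ([record_set()]s, roles
#'   set) and `truth`: per-k-mer character vectors of target ids carrying
#'   an intact site, plus `union` (ids covered by any intact site).
#' @export
simulate_asv_set <- function(spec) {
  stopifnot(inherits(spec, "FixtureSpec"))
  kmers <- names(spec$planted_kmers)
  ks <- nchar(kmers)
  withr_seed <- set_local_seed(spec$seed)
  on.exit(withr_seed(), add = TRUE)

  # fixed, non-overlapping insertion slots: k-mer j occupies
  # [slot_j, slot_j + k_j)
  slots <- cumsum(c(10L, utils::head(ks, -1L) + 5L))
  if (length(kmers) > 0 && max(slots + ks) > spec$seq_len) {
    stop("seq_len too short to host all planted k-mers at disjoint slots")
  }

  n_carry <- round(spec$planted_kmers * spec$n_target)
  carriers <- list()
  for (j in seq_along(kmers)) {
    carriers[[j]] <- sort(sample(seq_len(spec$n_target), n_carry[j]))
  }

  target_ids <- sprintf("mt_asv_%03d", seq_len(spec$n_target))
  offtarget_ids <- sprintf("bact_asv_%03d", seq_len(spec$n_offtarget))

  clean_background <- function() {
    repeat {
      s <- random_dna(spec$seq_len)
      if (!contains_any(s, kmers)) {
        return(s)
      }
    }
  }

  truth <- stats::setNames(rep(list(character(0)), length(kmers)), kmers)
  targets_seq <- character(spec$n_target)
  for (i in seq_len(spec$n_target)) {
    mine <- which(vapply(carriers, function(cs) i %in% cs, logical(1)))
    repeat {
      s <- clean_background()
      intact <- logical(length(mine))
      for (m in seq_along(mine)) {
        j <- mine[m]
        site <- kmers[j]
        mutate <- spec$mutation_rate > 0 && stats::runif(1) < spec$mutation_rate
        if (mutate) {
          pos <- sample.int(ks[j], 1L)
          base <- substr(site, pos, pos)
          sub <- sample(setdiff(c("A", "C", "G", "T"), base), 1L)
          substr(site, pos, pos) <- sub
        }
        substr(s, slots[j] + 1L, slots[j] + ks[j]) <- site
        intact[m] <- !mutate
      }
      # accept only if final occurrences match intent exactly
      ok <- TRUE
      for (j in seq_along(kmers)) {
        expected <- (j %in% mine[intact])
        if (occurs_either(s, kmers[j]) != expected) {
          ok <- FALSE
          break
        }
      }
      if (ok) {
        for (m in seq_along(mine)) {
          if (intact[m]) {
            j <- mine[m]
            truth[[j]] <- c(truth[[j]], target_ids[i])
          }
        }
        targets_seq[i] <- s
        break
      }
    }
  }

  offtargets_seq <- vapply(seq_len(spec$n_offtarget), function(i) clean_background(), character(1))

  list(
    targets = record_set(target_ids, targets_seq, role = "target"),
    offtargets = record_set(offtarget_ids, offtargets_seq, role = "offtarget"),
    truth = c(truth, list(union = sort(unique(unlist(truth, use.names = FALSE)))))
  )
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

occurs_either <- function(seq, kmer) {
  grepl(kmer, seq, fixed = TRUE) || grepl(revcomp(kmer), seq, fixed = TRUE)
}

contains_any <- function(seq, kmers) {
  for (k in kmers) {
    if (occurs_either(seq, k)) {
      return(TRUE)
    }
  }
  FALSE
}

# save/restore the global RNG state around seeded simulation
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Simulate an ASV count table with known category fractions
#'
#' Draws per-sample read counts from a multinomial over (category, ASV)
#' cells. Each category holds `n_asv` synthetic ASVs whose within-category
#' weights default to a strongly dominated profile (0.97/0.02/0.01),
#' emulating the single-ASV dominance typical of host organelle read
#' pools. Taxonomy labels follow the SILVA convention used by
#' [classify_taxonomy()].
#'
#' @param fractions Numeric matrix, samples in rows (rownames = sample
#'   ids), categories `chloroplast`, `mitochondria`, `bacteria` in
#'   columns; each row sums to 1.
#' @param depth Total reads per sample.
#' @param metadata Optional data frame (sample, tree, tissue, species,
#'   treatment); default is single-tissue, one tree per sample, no_clamp.
#' @param n_asv ASVs per category.
#' @param within_weights Within-category abundance weights, length
#'   `n_asv`.
#' @param seed Integer seed.
#' @return List with `counts` (ASV x sample integer matrix), `taxonomy`
#'   (named lineage vector) and `metadata`.
#' @export
simulate_count_table <- function(fractions, depth = 100000L, metadata = NULL,
                                 n_asv = 3L, within_weights = c(0.97, 0.02, 0.01),
                                 seed = 1L) {
  fractions <- as.matrix(fractions)
  if (is.null(rownames(fractions))) {
    rownames(fractions) <- sprintf("sample_%02d", seq_len(nrow(fractions)))
  }
  cats <- c("chloroplast", "mitochondria", "bacteria")
  if (is.null(colnames(fractions))) colnames(fractions) <- cats
  if (!all(colnames(fractions) %in% cats)) {
    stop("fraction columns must be: ", paste(cats, collapse = ", "))
  }
  if (any(abs(rowSums(fractions) - 1) > 1e-9)) stop("fractions must sum to 1 per sample")
  if (depth <= 0) stop("depth must be positive")
  n_asv <- as.integer(n_asv)
  within_weights <- rep_len(within_weights, n_asv)
  within_weights <- within_weights / sum(within_weights)

  restore <- set_local_seed(seed)
  on.exit(restore(), add = TRUE)

  lineages <- c(
    chloroplast = "Bacteria;Cyanobacteria;Cyanobacteriia;Chloroplast",
    mitochondria = "Bacteria;Proteobacteria;Alphaproteobacteria;Rickettsiales;Mitochondria",
    bacteria = "Bacteria;Actinobacteriota;Actinobacteria;Micrococcales"
  )
  asv_ids <- unlist(lapply(cats, function(cc) sprintf("%s_asv_%02d", cc, seq_len(n_asv))))
  taxonomy <- stats::setNames(rep(lineages[cats], each = n_asv), asv_ids)

  counts <- vapply(seq_len(nrow(fractions)), function(i) {
    # column-major vec of the n_asv x category weight grid matches asv_ids
    p <- as.vector(outer(within_weights, fractions[i, cats]))
    as.integer(stats::rmultinom(1, size = depth, prob = p))
  }, integer(length(asv_ids)))
  rownames(counts) <- asv_ids
  colnames(counts) <- rownames(fractions)

  if (is.null(metadata)) {
    metadata <- data.frame(
      sample = rownames(fractions),
      tree = rownames(fractions),
      tissue = "leaf",
      species = "Q_petraea",
      treatment = "no_clamp",
      stringsAsFactors = FALSE
    )
  }
  list(counts = counts, taxonomy = taxonomy, metadata = metadata)
}

#' Synthetic stand-ins for the most abundant host organelle ASVs
#'
#' Constructs two synthetic ~250 bp V4-like reference sequences that
#' emulate the documented structure of the dominant oak organelle ASVs:
#'
#' * `chloro_ref_synthetic` carries the pPNA clamp site in reverse
#'   complement orientation (the plastid clamp matches the chloroplast ASV
#'   through its complement), and
#' * `mito_ref_synthetic` carries the qmPNA clamp verbatim while the
#'   universal mitochondrial clamp (`mPNA_universal`) sits at exactly 6
#'   ungapped mismatches from its best window — the mismatch load that
#'   motivates a host-specific clamp.
#'
#' These are synthetic surrogates, not the real ASV sequences; they let
#' the match/mismatch machinery be exercised end to end without the
#' study's deposited data. Construction rejection-samples deterministic
#' random backgrounds until all planted properties hold exactly.
#'
#' @param seed Integer seed for the deterministic construction.
#' @return A [record_set()] with records `chloro_ref_synthetic` (role
#'   target) and `mito_ref_synthetic` (role target).
#' @export
synthetic_reference_asvs <- function(seed = 20L) {
  clamps <- oak_clamps()
  restore <- set_local_seed(seed)
  on.exit(restore(), add = TRUE)
  len <- 250L

  clean <- function() {
    repeat {
      s <- random_dna(len)
      if (!contains_any(s, unname(clamps))) {
        return(s)
      }
    }
  }

  # chloroplast stand-in: pPNA binds via its complement only
  chloro <- NULL
  repeat {
    s <- clean()
    substr(s, 61L, 77L) <- revcomp(clamps[["pPNA"]])
    fwd <- grepl(clamps[["pPNA"]], s, fixed = TRUE)
    rc <- grepl(revcomp(clamps[["pPNA"]]), s, fixed = TRUE)
    others <- contains_any(s, unname(clamps[names(clamps) != "pPNA"]))
    if (!fwd && rc && !others) {
      chloro <- s
      break
    }
  }

  # mitochondrial stand-in: qmPNA verbatim, universal mPNA at exactly 6
  # ungapped mismatches over both orientations
  m_univ <- clamps[["mPNA_universal"]]
  mito <- NULL
  repeat {
    s <- clean()
    substr(s, 81L, 97L) <- clamps[["qmPNA"]]
    degen <- m_univ
    for (pos in c(2L, 5L, 8L, 11L, 14L, 16L)) {
      base <- substr(degen, pos, pos)
      substr(degen, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"), base), 1L)
    }
    substr(s, 141L, 157L) <- degen
    if (!grepl(clamps[["qmPNA"]], substr(s, 1L, 80L), fixed = TRUE) &&
      window_mismatch_scan(m_univ, s)$mm == 6L &&
      occurs_either(s, clamps[["qmPNA"]]) &&
      !contains_any(s, unname(clamps[c("pPNA", "qmPNAv2", "qmPNAv3")]))) {
      mito <- s
      break
    }
  }

  record_set(
    c("chloro_ref_synthetic", "mito_ref_synthetic"),
    c(chloro, mito),
    role = "target"
  )
}
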