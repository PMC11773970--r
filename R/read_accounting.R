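COMPOSITION_CATEGORIES <- c("chloroplast", "mitochondria", "bacteria", "other")

#' Classify taxonomy lineages into read-accounting categories
#'
#' Organelle detection keys on the strings "Chloroplast" / "Mitochondria"
#' appearing at any rank of the semicolon-delimited lineage
#' (case-insensitive), matching how the SILVA v138 taxonomy places plant
#' organelle 16S sequences inside Cyanobacteria and Rickettsiales.
#' Remaining lineages in domain Bacteria are "bacteria"; anything else
#' (Archaea, unplaced Eukaryota) is kept visible as "other" rather than
#' silently merged.
#'
#' @param lineage Character vector of semicolon-delimited lineages.
#' @param patterns Named list of regular expressions for the `chloroplast`
#'   and `mitochondria` categories.
#' @return Character vector over
#'   `c("chloroplast", "mitochondria", "bacteria", "other")`.
#' @export
classify_taxonomy <- function(lineage,
                              patterns = list(
                                chloroplast = "chloroplast",
                                mitochondria = "mitochondri"
                              )) {
  lineage <- as.character(lineage)
  out <- rep("other", length(lineage))
  out[grepl("^\\s*(d__)?bacteria", lineage, ignore.case = TRUE)] <- "bacteria"
  out[grepl(patterns$mitochondria, lineage, ignore.case = TRUE)] <- "mitochondria"
  out[grepl(patterns$chloroplast, lineage, ignore.case = TRUE)] <- "chloroplast"
  out
}

#' Tally chloroplast / mitochondria / bacteria read composition
#'
#' Partitions the reads of each sample among the host-organelle and
#' bacterial categories and reports counts and fractions per sample, plus
#' pooled totals per (tissue, treatment) group — the bookkeeping used to
#' quantify how much sequencing effort is lost to host organelles with and
#' without clamp treatment.
#'
#' @param counts Integer matrix or data frame, ASVs in rows (rownames =
#'   ASV ids), samples in columns.
#' @param taxonomy Named character vector or two-column data frame mapping
#'   every ASV id to a semicolon-delimited lineage.
#' @param metadata Data frame with columns `sample`, `tree`, `tissue`,
#'   `species`, `treatment` (`no_clamp` / `pna_clamp`); one row per column
#'   of `counts`.
#' @param patterns Passed to [classify_taxonomy()].
#' @return List of class `CompositionTable`: `samples` (long data frame
#'   sample x category with counts and fractions plus metadata) and
#'   `pooled` (tissue x treatment x category).
#' @export
classify_and_tally <- function(counts, taxonomy, metadata, patterns = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have ASV ids as rownames")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  taxonomy <- as_taxonomy_map(taxonomy)
  missing_tax <- setdiff(rownames(counts), names(taxonomy))
  if (length(missing_tax) > 0) {
    stop("ASV(s) without taxonomy label: ", paste(missing_tax, collapse = ", "))
  }
  metadata <- validate_metadata(metadata, colnames(counts))

  args <- list(lineage = taxonomy[rownames(counts)])
  if (!is.null(patterns)) args$patterns <- patterns
  category <- factor(do.call(classify_taxonomy, args), levels = COMPOSITION_CATEGORIES)

  totals <- colSums(counts)
  empty <- totals == 0
  if (any(empty)) {
    warning(
      "excluding sample(s) with zero reads: ",
      paste(colnames(counts)[empty], collapse = ", ")
    )
    counts <- counts[, !empty, drop = FALSE]
    metadata <- metadata[!empty, , drop = FALSE]
    totals <- totals[!empty]
  }

  cat_counts <- rowsum(counts, category) # category x sample
  miss <- setdiff(COMPOSITION_CATEGORIES, rownames(cat_counts))
  if (length(miss) > 0) {
    cat_counts <- rbind(
      cat_counts,
      matrix(0, length(miss), ncol(cat_counts), dimnames = list(miss, colnames(cat_counts)))
    )
  }
  cat_counts <- cat_counts[COMPOSITION_CATEGORIES, , drop = FALSE]

  samples <- do.call(rbind, lapply(seq_len(ncol(cat_counts)), function(j) {
    data.frame(
      sample = colnames(cat_counts)[j],
      tree = metadata$tree[j],
      tissue = metadata$tissue[j],
      species = metadata$species[j],
      treatment = metadata$treatment[j],
      category = COMPOSITION_CATEGORIES,
      count = unname(cat_counts[, j]),
      fraction = unname(cat_counts[, j] / totals[j]),
      stringsAsFactors = FALSE
    )
  }))
  rownames(samples) <- NULL

  pooled <- stats::aggregate(
    count ~ tissue + treatment + category,
    data = samples, FUN = sum
  )
  pooled_tot <- stats::aggregate(count ~ tissue + treatment, data = pooled, FUN = sum)
  names(pooled_tot)[names(pooled_tot) == "count"] <- "total"
  pooled <- merge(pooled, pooled_tot, by = c("tissue", "treatment"))
  pooled$fraction <- ifelse(pooled$total > 0, pooled$count / pooled$total, 0)
  pooled$total <- NULL
  pooled <- pooled[order(pooled$tissue, pooled$treatment, match(pooled$category, COMPOSITION_CATEGORIES)), ]
  rownames(pooled) <- NULL

  structure(
    list(samples = samples, pooled = pooled, asv_category = stats::setNames(as.character(category), rownames(counts))),
    class = "CompositionTable"
  )
}

as_taxonomy_map <- function(taxonomy) {
  if (is.data.frame(taxonomy)) {
    if (ncol(taxonomy) < 2) stop("taxonomy data frame needs id and lineage columns")
    stats::setNames(as.character(taxonomy[[2]]), as.character(taxonomy[[1]]))
  } else {
    if (is.null(names(taxonomy))) stop("taxonomy vector must be named by ASV id")
    taxonomy
  }
}

validate_metadata <- function(metadata, sample_ids) {
  need <- c("sample", "tissue", "species", "treatment")
  if (!all(need %in% names(metadata))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  }
  if (!"tree" %in% names(metadata)) metadata$tree <- metadata$sample
  idx <- match(sample_ids, metadata$sample)
  if (anyNA(idx)) {
    stop("metadata missing sample(s): ", paste(sample_ids[is.na(idx)], collapse = ", "))
  }
  bad <- setdiff(unique(metadata$treatment), c("no_clamp", "pna_clamp"))
  if (length(bad) > 0) {
    stop("unknown treatment value(s): ", paste(bad, collapse = ", "))
  }
  metadata[idx, , drop = FALSE]
}

#' Per-category composition change between clamp treatments
#'
#' Pairs samples across treatments by (tree, tissue) and reports, for each
#' category, the change in its read fraction with clamps relative to
#' without, in percentage points. Two summaries are emitted and labelled,
#' because they answer different questions: `by_tissue` averages the
#' per-pair deltas (mean and sample sd over paired trees, the form that
#' comes with a +/- spread), while `pooled` differences the pooled
#' (tissue, treatment) totals, which weights trees by read depth.
#'
#' @param comp A `CompositionTable` from [classify_and_tally()].
#' @return List of class `TreatmentDelta`: `pairs` (per tree x tissue x
#'   category delta), `by_tissue` (mean, sd, n per tissue x category),
#'   `pooled` (delta of pooled fractions per tissue x category).
#' @export
treatment_delta <- function(comp) {
  stopifnot(inherits(comp, "CompositionTable"))
  s <- comp$samples
  wide <- merge(
    s[s$treatment == "no_clamp", c("tree", "tissue", "category", "fraction")],
    s[s$treatment == "pna_clamp", c("tree", "tissue", "category", "fraction")],
    by = c("tree", "tissue", "category"), suffixes = c("_no", "_with")
  )
  n_no <- sum(s$treatment == "no_clamp") / length(COMPOSITION_CATEGORIES)
  n_with <- sum(s$treatment == "pna_clamp") / length(COMPOSITION_CATEGORIES)
  if (nrow(wide) / length(COMPOSITION_CATEGORIES) < max(n_no, n_with)) {
    warning("unpaired sample(s) excluded from treatment deltas")
  }
  if (nrow(wide) == 0) stop("no (tree, tissue) pair present in both treatments")
  wide$delta_pp <- 100 * (wide$fraction_with - wide$fraction_no)

  by_tissue <- stats::aggregate(
    delta_pp ~ tissue + category,
    data = wide,
    FUN = function(x) c(mean = mean(x), sd = stats::sd(x), n = length(x))
  )
  by_tissue <- cbind(
    by_tissue[c("tissue", "category")],
    as.data.frame(by_tissue$delta_pp)
  )

  p <- comp$pooled
  pw <- merge(
    p[p$treatment == "no_clamp", c("tissue", "category", "fraction")],
    p[p$treatment == "pna_clamp", c("tissue", "category", "fraction")],
    by = c("tissue", "category"), suffixes = c("_no", "_with")
  )
  pw$delta_pp <- 100 * (pw$fraction_with - pw$fraction_no)

  structure(
    list(pairs = wide, by_tissue = by_tissue, pooled = pw),
    class = "TreatmentDelta"
  )
}

#' Dominance of the most abundant ASV within a category
#'
#' Reports which single ASV carries the largest share of a category's
#' reads — host organelle read pools are often dominated by one ASV, which
#' is what makes a single perfect-match clamp effective.
#'
#' @param counts ASV x sample count matrix (rownames = ASV ids).
#' @param taxonomy ASV id to lineage map, as in [classify_and_tally()].
#' @param category One of `"chloroplast"`, `"mitochondria"`, `"bacteria"`,
#'   `"other"`.
#' @param samples Optional character vector restricting to a subset of
#'   sample columns.
#' @param patterns Passed to [classify_taxonomy()].
#' @return List of class `DominanceReport`: `category`, `asv` (id of the
#'   top ASV; ties broken by lexicographic id), `share` in \[0, 1\],
#'   `total_reads`.
#' @export
dominance <- function(counts, taxonomy, category, samples = NULL, patterns = NULL) {
  category <- match.arg(category, COMPOSITION_CATEGORIES)
  counts <- as.matrix(counts)
  if (!is.null(samples)) counts <- counts[, samples, drop = FALSE]
  taxonomy <- as_taxonomy_map(taxonomy)
  args <- list(lineage = taxonomy[rownames(counts)])
  if (!is.null(patterns)) args$patterns <- patterns
  cats <- do.call(classify_taxonomy, args)
  sub <- counts[cats == category, , drop = FALSE]
  reads <- rowSums(sub)
  total <- sum(reads)
  if (total == 0) stop("category '", category, "' has zero reads")
  ord <- order(-reads, names(reads))
  structure(
    list(
      category = category,
      asv = names(reads)[ord[1L]],
      share = unname(reads[ord[1L]] / total),
      total_reads = total
    ),
    class = "DominanceReport"
  )
}

#' Read an ASV count table from TSV
#'
#' First column = ASV id, remaining columns = samples.
#' @param path TSV path.
#' @return Integer matrix with ASV rownames.
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Read an ASV taxonomy table from TSV
#'
#' Two columns: ASV id, semicolon-delimited lineage.
#' @param path TSV path.
#' @return Named character vector.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_taxonomy_map(df)
}

#' Read a sample metadata table from TSV
#'
#' Columns: sample, tree, tissue, species, treatment.
#' @param path TSV path.
#' @return Data frame.
#' @export
read_metadata <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
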