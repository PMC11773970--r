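#' Select a clamp panel by greedy set cover
#'
#' Builds a small panel of clamps that together cover as many target (host
#' organelle) sequences as possible: at each step the candidate covering
#' the most not-yet-covered targets is chosen, until `max_panel` clamps are
#' selected or no candidate adds coverage. With `weighted = TRUE` the step
#' criterion is the abundance sum of newly covered targets instead of their
#' count, which prioritises depleting reads rather than unique ASVs.
#'
#' Ties are broken by lexicographically smallest clamp sequence, so the
#' result is invariant under permutation of the candidate input order.
#'
#' @param candidates A `ClampCandidate` data frame from
#'   [screen_candidates()] (hit sets populated, off-targets already
#'   excluded).
#' @param targets The target [record_set()] the hit sets were computed
#'   against.
#' @param max_panel Maximum panel size (default 3, the size of a practical
#'   multi-clamp mitochondrial cocktail).
#' @param weighted Use abundance-weighted coverage gain.
#' @return A list of class `PanelSolution` with `clamps` (chosen candidate
#'   rows in selection order), `covered` (target ids), `coverage_fraction`
#'   and `trace` (per-step clamp and newly covered count).
#' @examples
#' ts <- record_set(paste0("s", 1:3), c("AAAACCCC", "CCCCGGGG", "GGGGTTTT"))
#' cand <- screen_candidates(ts, record_set(character(0), character(0)), k = 8)
#' greedy_cover(cand, ts, max_panel = 2)
#' @export
greedy_cover <- function(candidates, targets, max_panel = 3L, weighted = FALSE) {
  stopifnot(inherits(targets, "RecordSet"))
  max_panel <- as.integer(max_panel)
  if (max_panel < 1L) stop("max_panel must be >= 1")
  n_targets <- nrow(targets)
  hit_sets <- if (nrow(candidates)) candidates$target_hits else list()
  abund <- stats::setNames(targets$abundance, targets$id)

  chosen <- integer(0)
  covered <- character(0)
  trace <- data.frame(
    clamp = character(0), new_covered = integer(0),
    stringsAsFactors = FALSE
  )
  pool <- seq_along(hit_sets)
  while (length(chosen) < max_panel && length(pool) > 0) {
    gain_n <- vapply(pool, function(i) {
      length(setdiff(hit_sets[[i]], covered))
    }, integer(1))
    score <- if (weighted) {
      vapply(pool, function(i) {
        sum(abund[setdiff(hit_sets[[i]], covered)])
      }, numeric(1))
    } else {
      as.numeric(gain_n)
    }
    if (max(score) <= 0) break
    best <- pool[order(-score, candidates$seq[pool])][1L]
    bi <- match(best, pool)
    chosen <- c(chosen, best)
    trace <- rbind(trace, data.frame(
      clamp = candidates$seq[best],
      new_covered = gain_n[bi], stringsAsFactors = FALSE
    ))
    covered <- union(covered, hit_sets[[best]])
    pool <- setdiff(pool, best)
  }

  clamps <- candidates[chosen, , drop = FALSE]
  rownames(clamps) <- NULL
  structure(
    list(
      clamps = clamps,
      covered = covered,
      coverage_fraction = if (n_targets > 0) length(covered) / n_targets else 0,
      trace = trace
    ),
    class = "PanelSolution"
  )
}

#' @export
print.PanelSolution <- function(x, ...) {
  cat(sprintf(
    "PanelSolution: %d clamp(s), coverage %d target(s) (%.1f%%)\n",
    nrow(x$clamps), length(x$covered), 100 * x$coverage_fraction
  ))
  if (nrow(x$trace) > 0) {
    for (i in seq_len(nrow(x$trace))) {
      cat(sprintf("  %d. %s (+%d)\n", i, x$trace$clamp[i], x$trace$new_covered[i]))
    }
  }
  invisible(x)
}

#' Coverage of a clamp panel over a target set
#'
#' Pure set union over the clamps' target hit sets; independent of clamp
#' order. Also reports the ids left uncovered, so the residual host
#' sequences a panel cannot suppress are visible.
#'
#' @param panel A `ClampCandidate` data frame (e.g. `solution$clamps`) or a
#'   `PanelSolution`.
#' @param targets The target [record_set()].
#' @return List with `covered` (ids), `uncovered` (ids) and
#'   `coverage_fraction`.
#' @export
coverage <- function(panel, targets) {
  stopifnot(inherits(targets, "RecordSet"))
  if (inherits(panel, "PanelSolution")) panel <- panel$clamps
  covered_ids <- unique(unlist(panel$target_hits, use.names = FALSE))
  covered_ids <- targets$id[targets$id %in% covered_ids]
  list(
    covered = covered_ids,
    uncovered = setdiff(targets$id, covered_ids),
    coverage_fraction = if (nrow(targets) > 0) length(covered_ids) / nrow(targets) else 0
  )
}
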