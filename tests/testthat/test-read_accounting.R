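# small hand-built table: 3 ASVs x samples, SILVA-style lineages
toy_taxonomy <- c(
  chl1 = "Bacteria;Cyanobacteria;Cyanobacteriia;Chloroplast",
  mit1 = "Bacteria;Proteobacteria;Alphaproteobacteria;Rickettsiales;Mitochondria",
  bac1 = "Bacteria;Actinobacteriota;Actinobacteria",
  bac2 = "Bacteria;Proteobacteria;Gammaproteobacteria",
  arc1 = "Archaea;Crenarchaeota"
)

toy_metadata <- function(samples, treatment = "no_clamp", tissue = "leaf") {
  data.frame(
    sample = samples, tree = sub("_.*$", "", samples),
    tissue = tissue, species = "Q_petraea", treatment = treatment,
    stringsAsFactors = FALSE
  )
}

test_that("classify_taxonomy keys on organelle strings at any rank", {
  expect_identical(
    classify_taxonomy(unname(toy_taxonomy)),
    c("chloroplast", "mitochondria", "bacteria", "bacteria", "other")
  )
  expect_identical(classify_taxonomy("bacteria;cyanobacteria;CHLOROPLAST"), "chloroplast")
})

test_that("classify_and_tally reproduces hand-computed fractions", {
  counts <- matrix(c(880, 110, 10, 0, 0), ncol = 1,
    dimnames = list(names(toy_taxonomy), "t1_leaf")
  )
  comp <- classify_and_tally(counts, toy_taxonomy, toy_metadata("t1_leaf"))
  s <- comp$samples
  expect_equal(s$fraction[s$category == "chloroplast"], 0.88)
  expect_equal(s$fraction[s$category == "mitochondria"], 0.11)
  expect_equal(s$fraction[s$category == "bacteria"], 0.01)
  expect_equal(sum(s$fraction), 1, tolerance = 1e-9)

  only_bact <- matrix(c(0, 0, 5, 7, 0), ncol = 1,
    dimnames = list(names(toy_taxonomy), "t1_leaf")
  )
  comp2 <- classify_and_tally(only_bact, toy_taxonomy, toy_metadata("t1_leaf"))
  expect_equal(
    comp2$samples$fraction[comp2$samples$category == "bacteria"], 1.0
  )
})

test_that("pooled fractions are count-weighted means across samples", {
  counts <- matrix(
    c(
      100, 0, 0, 0, 0, # t1: all chloroplast
      0, 0, 100, 0, 0 # t2: all bacteria
    ),
    ncol = 2, dimnames = list(names(toy_taxonomy), c("t1_leaf", "t2_leaf"))
  )
  comp <- classify_and_tally(counts, toy_taxonomy, toy_metadata(c("t1_leaf", "t2_leaf")))
  p <- comp$pooled
  expect_equal(p$fraction[p$category == "chloroplast"], 0.5)
  expect_equal(p$fraction[p$category == "bacteria"], 0.5)
})

test_that("zero-read samples are excluded with a warning; unlabeled ASVs error", {
  counts <- matrix(c(10, 0, 0, 0, 0, 0, 0, 0, 0, 0), ncol = 2,
    dimnames = list(names(toy_taxonomy), c("t1_leaf", "t2_leaf"))
  )
  expect_warning(
    comp <- classify_and_tally(counts, toy_taxonomy, toy_metadata(c("t1_leaf", "t2_leaf"))),
    "zero reads.*t2_leaf"
  )
  expect_identical(unique(comp$samples$sample), "t1_leaf")

  bad_tax <- toy_taxonomy[-1]
  expect_error(
    classify_and_tally(counts[, 1, drop = FALSE], bad_tax, toy_metadata("t1_leaf")),
    "without taxonomy label: chl1"
  )
})

test_that("classify_and_tally is invariant under ASV row permutation", {
  set.seed(5)
  counts <- matrix(rpois(10, 50), ncol = 2,
    dimnames = list(names(toy_taxonomy), c("t1_leaf", "t2_leaf"))
  )
  comp_a <- classify_and_tally(counts, toy_taxonomy, toy_metadata(c("t1_leaf", "t2_leaf")))
  perm <- sample(nrow(counts))
  comp_b <- classify_and_tally(counts[perm, ], toy_taxonomy, toy_metadata(c("t1_leaf", "t2_leaf")))
  expect_equal(comp_a$samples, comp_b$samples)
})

test_that("treatment_delta computes paired percentage-point changes", {
  # three trees, leaf tissue, bacteria fraction rising by 70/72/74 points
  mk_counts <- function(bact_frac) {
    vapply(bact_frac, function(f) {
      c(chl1 = round(1000 * (1 - f)), mit1 = 0, bac1 = round(1000 * f), bac2 = 0, arc1 = 0)
    }, numeric(5))
  }
  no <- mk_counts(c(0.05, 0.05, 0.05))
  with <- mk_counts(c(0.75, 0.77, 0.79))
  colnames(no) <- paste0("t", 1:3, "_no")
  colnames(with) <- paste0("t", 1:3, "_with")
  counts <- cbind(no, with)
  metadata <- rbind(
    toy_metadata(colnames(no), treatment = "no_clamp"),
    toy_metadata(colnames(with), treatment = "pna_clamp")
  )
  comp <- classify_and_tally(counts, toy_taxonomy, metadata)
  delta <- treatment_delta(comp)
  bt <- delta$by_tissue
  row <- bt[bt$category == "bacteria" & bt$tissue == "leaf", ]
  expect_equal(row$mean, 72)
  expect_equal(row$sd, 2)
  expect_equal(row$n, 3)

  # pooled view: 5% -> 77% bacteria = +72 points
  pooled_row <- delta$pooled[delta$pooled$category == "bacteria", ]
  expect_equal(pooled_row$delta_pp, 72, tolerance = 0.2)
})

test_that("treatment_delta of a table against itself is identically zero", {
  set.seed(9)
  counts <- matrix(rpois(20, 40), ncol = 4, dimnames = list(
    names(toy_taxonomy)[1:5],
    c("t1_no", "t2_no", "t1_with", "t2_with")
  ))
  counts[, "t1_with"] <- counts[, "t1_no"]
  counts[, "t2_with"] <- counts[, "t2_no"]
  metadata <- rbind(
    toy_metadata(c("t1_no", "t2_no"), treatment = "no_clamp"),
    toy_metadata(c("t1_with", "t2_with"), treatment = "pna_clamp")
  )
  comp <- classify_and_tally(counts, toy_taxonomy, metadata)
  delta <- treatment_delta(comp)
  expect_true(all(abs(delta$pairs$delta_pp) < 1e-12))
  expect_true(all(abs(delta$pooled$delta_pp) < 1e-12))
})

test_that("dominance reports the top ASV share with deterministic ties", {
  counts <- matrix(c(990, 10, 0, 0, 0), ncol = 1,
    dimnames = list(c("chl1", "chl2", "mit1", "bac1", "arc1"), "t1_leaf")
  )
  tax <- c(toy_taxonomy["chl1"], chl2 = unname(toy_taxonomy["chl1"]),
    toy_taxonomy[c("mit1", "bac1", "arc1")]
  )
  rep <- dominance(counts, tax, "chloroplast")
  expect_identical(rep$asv, "chl1")
  expect_equal(rep$share, 0.99)

  solo <- dominance(counts[c("chl1", "mit1", "bac1", "arc1"), , drop = FALSE] + c(0, 1, 0, 0), tax, "mitochondria")
  expect_equal(solo$share, 1.0)

  tie_counts <- matrix(c(50, 50, 0, 0, 0), ncol = 1,
    dimnames = list(c("chl2", "chl1", "mit1", "bac1", "arc1"), "t1_leaf")
  )
  tie <- dominance(tie_counts, tax, "chloroplast")
  expect_identical(tie$asv, "chl1") # lexicographic winner
  expect_equal(tie$share, 0.5)

  expect_error(dominance(counts, tax, "bacteria"), "zero reads")
})
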