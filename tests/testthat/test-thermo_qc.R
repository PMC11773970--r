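test_that("fraction_pyrimidine counts C and T", {
  expect_equal(fraction_pyrimidine("CCTT"), 1.0)
  expect_equal(fraction_pyrimidine("GGCTCAACCCTGGACAG"), 8 / 17)
  expect_equal(fraction_pyrimidine("GTGAATTGGTTTCGAGA"), 7 / 17)
  expect_error(fraction_pyrimidine(""), "empty")
})

test_that("nn_dna_tm reproduces an independent nearest-neighbor implementation", {
  for (i in seq_len(nrow(tm_reference_cases))) {
    case <- tm_reference_cases[i, ]
    tm <- nn_dna_tm(
      case$seq,
      tm_conditions(conc_uM = 0.25, na_m = case$na_m, nn_table = case$table)
    )
    expect_equal(tm, case$tm, tolerance = 1e-8)
  }
})

test_that("nn_dna_tm is strand-symmetric and deterministic", {
  set.seed(13)
  for (i in 1:40) {
    s <- random_dna_str(sample(8:25, 1))
    expect_equal(nn_dna_tm(s), nn_dna_tm(revcomp(s)), tolerance = 1e-12)
  }
  s <- "GTGAATTGGTTTCGAGA"
  expect_identical(nn_dna_tm(s), nn_dna_tm(s))
  expect_error(nn_dna_tm("ACGTACG"), "at least 8")
  expect_error(nn_dna_tm("ACGTNACGT"), "A, C, G, T")
})

test_that("higher GC content raises the nearest-neighbor Tm directionally", {
  base <- "ATATATATATATATATA"
  gc <- "GCGCGCGCGCGCGCGCG"
  expect_gt(nn_dna_tm(gc), nn_dna_tm(base))
  one_sub <- "ATATATATGTATATATA" # one A->G
  expect_gt(nn_dna_tm(one_sub), nn_dna_tm(base) - 10)
})

test_that("pna_tm is the configured linear form of its three inputs", {
  coef <- pna_tm_coefficients()
  # closed form at synthetic inputs: 20.79 + 0.83*60 - 26.13*0.5 + 0.44*17
  expect_equal(
    coef[["c0"]] + coef[["c1"]] * 60 + coef[["c2"]] * 0.5 + coef[["c3"]] * 17,
    65.005
  )
  set.seed(17)
  for (i in 1:30) {
    s <- random_dna_str(sample(10:25, 1))
    expect_equal(
      pna_tm(s),
      coef[["c0"]] + coef[["c1"]] * nn_dna_tm(s) +
        coef[["c2"]] * fraction_pyrimidine(s) + coef[["c3"]] * nchar(s),
      tolerance = 1e-12
    )
  }
  # linearity: +0.1 pyrimidine fraction at fixed tm_dna/length shifts by c2/10
  custom <- c(c0 = 0, c1 = 0, c2 = -26.13, c3 = 0)
  s1 <- "GGGGGGGGGG" # fpyr 0
  s2 <- "CGGGGGGGGG" # fpyr 0.1, same length
  expect_equal(
    pna_tm(s2, coef = custom) - pna_tm(s1, coef = custom),
    -2.613,
    tolerance = 1e-9
  )
})

test_that("published clamp sequences clear the 72 C effectiveness rule at defaults", {
  clamps <- oak_clamps()
  tm_p <- pna_tm(clamps[["pPNA"]])
  tm_q <- pna_tm(clamps[["qmPNA"]])
  expect_gte(tm_p, 72)
  expect_gte(tm_q, 72)
  # soft cross-check against the reported vendor-tool values 82 and 76
  expect_lt(abs(tm_p - 82), 5)
  expect_lt(abs(tm_q - 76), 5)
})

test_that("recommend_clamping_temp lands in the 5-10 C window above the primer Tm", {
  expect_equal(recommend_clamping_temp(76, 66), 68)
  expect_equal(recommend_clamping_temp(82, 66), 72)
  expect_true(is.na(suppressMessages(recommend_clamping_temp(70, 66))))

  set.seed(19)
  for (i in 1:100) {
    tm_pna <- runif(1, 60, 95)
    primer <- runif(1, 50, 80)
    rec <- suppressMessages(recommend_clamping_temp(tm_pna, primer))
    if (!is.na(rec)) {
      expect_gte(rec, round(tm_pna - 10))
      expect_lte(rec, round(tm_pna - 5))
      expect_gt(rec, primer)
    }
  }
})

test_that("hairpin_scan finds fold-back stems and respects thresholds", {
  rep1 <- hairpin_scan("GGGGAAATTTTCCCC", min_stem = 4, min_loop = 3)
  expect_true(rep1$has_hairpin)
  expect_gte(rep1$stem_len, 4L)
  # reported intervals really are reverse complements of each other
  s <- "GGGGAAATTTTCCCC"
  iv <- rep1$stem_positions
  stem1 <- substr(s, iv[[1]][1] + 1, iv[[1]][2])
  stem2 <- substr(s, iv[[2]][1] + 1, iv[[2]][2])
  expect_identical(stem2, revcomp(stem1))
  expect_gte(rep1$loop_len, 3L)

  expect_false(hairpin_scan("AAAAAAAAAAAAAAAAA")$has_hairpin)
  expect_false(hairpin_scan("GGGAAACCC", min_stem = 4)$has_hairpin)
  expect_error(hairpin_scan("ACGTACGT", min_stem = 1), "min_stem")
})

test_that("hairpin_scan agrees with the brute-force oracle on random short sequences", {
  set.seed(29)
  for (i in 1:150) {
    s <- random_dna_str(sample(8:25, 1))
    rep <- hairpin_scan(s, min_stem = 3, min_loop = 3)
    oracle_stem <- oracle_hairpin_stem(s, min_stem = 3, min_loop = 3)
    expect_equal(rep$stem_len, oracle_stem)
    expect_identical(rep$has_hairpin, oracle_stem >= 3)
  }
})

test_that("synthesis_spec prepends solubility lysines at the N terminus", {
  expect_identical(synthesis_spec("GTGAATTGGTTTCGAGA", 2), "KK-GTGAATTGGTTTCGAGA")
  expect_identical(synthesis_spec("ACGTACGT", 0), "ACGTACGT")
  set.seed(43)
  for (i in 1:20) {
    s <- random_dna_str(12)
    n <- sample(0:4, 1)
    out <- synthesis_spec(s, n)
    expect_identical(sub("^K*-?", "", out), s)
  }
})

test_that("qc_gate combines Tm, hairpin and off-target verdicts with reasons", {
  ts <- record_set("t1", "AAAGGCTCAACCCTGGACAGAAA", role = "target")
  os <- record_set("o1", "TTTTTTTTTTTTTTTTTTTT", role = "offtarget")
  cand <- screen_candidates(ts, os, k = 17)
  good <- cand[cand$seq == "GGCTCAACCCTGGACAG", , drop = FALSE]
  rep_good <- thermo_report(good$seq)
  expect_true(qc_gate(good, rep_good)$pass)

  # low-Tm AT-rich clamp fails the threshold gate
  weak <- record_set("t1", "AATATTATATATTATAATAAT", role = "target")
  cand_w <- screen_candidates(weak, os[0, ], k = 17)
  rep_w <- thermo_report(cand_w$seq[1])
  gate_w <- qc_gate(cand_w[1, , drop = FALSE], rep_w)
  expect_false(gate_w$pass)
  expect_true("Tm below threshold" %in% gate_w$reasons)

  # an off-target exact hit fails regardless of thermodynamics
  bad <- good
  bad$offtarget_hits[[1]] <- "o1"
  gate_b <- qc_gate(bad, rep_good)
  expect_false(gate_b$pass)
  expect_true("off-target exact match" %in% gate_b$reasons)
})

test_that("thermo_report assembles a consistent QC record", {
  rep <- thermo_report("GTGAATTGGTTTCGAGA")
  expect_s3_class(rep, "ThermoQCReport")
  expect_equal(rep$fpyr, 7 / 17)
  expect_identical(rep$tm_pass, rep$tm_pna >= protocol_defaults()$tm_threshold)
  expect_identical(rep$synthesis, "KK-GTGAATTGGTTTCGAGA")
  expect_equal(rep$clamp_temp, recommend_clamping_temp(rep$tm_pna, 66))
})
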