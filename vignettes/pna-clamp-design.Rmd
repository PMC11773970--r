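---
title: "Designing PNA clamps against host organelle 16S co-amplification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing PNA clamps against host organelle 16S co-amplification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pnaclamp)
```

## Why clamp, and what the package computes

Plant 16S rRNA amplicon surveys with universal V4 primers co-amplify the
host's chloroplast and mitochondrial rRNA genes, because organelles are of
bacterial ancestry and carry the same conserved primer sites. In
photosynthetic tissue the organelle fraction can reach ~99% of reads. A
peptide nucleic acid (PNA) clamp — a 17-mer nucleobase oligomer on an
amide backbone — binds a perfectly matching template with higher affinity
than DNA/DNA and blocks either primer binding or polymerase elongation,
suppressing amplification of the matching host sequence while leaving
mismatched (bacterial) templates untouched. Even a single mismatch
substantially weakens clamping, which cuts both ways: a host clamp loses
power against diverged host ASVs, and a bacterial sequence one mismatch
away is, conversely, mostly safe.

pnaclamp treats clamp design as four separable computations, each a module
with a small surface: candidate generation and specificity screening
(`clamp_design`), panel selection (`panel_select`), thermodynamic and
structural gating (`thermo_qc`), and read-composition accounting
(`read_accounting`), over shared sequence containers (`sequence_io`) and a
ground-truth simulator (`synthetic_fixtures`).

## Specificity screening

`enumerate_kmers()` generates every distinct ACGT-only k-length window of
the target (host organelle) ASVs; windows containing IUPAC ambiguity codes
are excluded because a synthesized clamp has a definite sequence.
`count_exact_hits()` declares a record hit when the clamp occurs verbatim
in the record or the record contains the clamp's reverse complement — both
orientations are always searched, since published organelle clamps bind
in either sense (the plastid clamp matches its ASV through the
complement; the oak mitochondrial clamp is present verbatim). Ambiguity
codes in records never match anything: matching is literal equality on
ACGT, so degenerate positions cannot inflate apparent coverage.

Mismatch profiling (`min_mismatch_profile()`) uses an **ungapped**
sliding-window Hamming distance, minimized over windows and orientations,
with deterministic tie-breaking (smallest offset, forward before reverse
complement). A gapped aligner can report different mismatch counts for
the same pair; the ungapped metric was chosen because it is deterministic,
cheap, oracle-checkable by brute force, and conservative for 17-mers,
where a gap would imply a bulged — and already ineffective — clamp
duplex. Mismatch counts quoted elsewhere from gapped multiple alignments
may therefore differ from this metric.

`screen_candidates()` retains a candidate only if its minimum mismatch
distance to **every** off-target (bacterial) record is at least `d_min`.
The default `d_min = 1` is exact-match exclusion — the standard design
criterion. Because single mismatches can still leave residual clamp
activity, `d_min = 2` is exposed as a stricter option that also discards
candidates within Hamming distance 1 of any bacterial sequence. Raising
`d_min` can only shrink the candidate set (tested as an invariant).
Retained candidates are ranked by host ASVs hit, then abundance-weighted
hits, then sequence, so reruns are byte-reproducible.

## Panel selection

One clamp rarely covers a diverse mitochondrial ASV population, so panels
are selected by greedy maximum-coverage: repeatedly take the clamp
covering the most uncovered targets (`weighted = TRUE` sums target
abundances instead, prioritising read depletion over unique ASVs; the
default counts unique ASVs). Greedy was chosen over exact set cover
because it generalizes deterministically the manual
pick-the-biggest-coverage procedure a designer follows, runs in
O(panel × candidates), and carries the classical (1 − 1/e) approximation
guarantee; on every small random instance in the test suite (≤10
candidates, ≤15 targets, exhaustive oracle) it attained the true optimum.
`max_panel` defaults to 3, a practical cocktail size. Ties are broken by
lexicographically smallest sequence, making the solution invariant under
candidate order. Uncovered target ids are reported explicitly so the
residual host fraction a panel cannot suppress stays visible.

## Thermodynamic model

The package estimates the PNA/DNA duplex Tm with the linear correlation

Tm_PNA = c0 + c1 · Tm_DNA + c2 · f_pyr + c3 · L,  (c0, c1, c2, c3) =
(20.79, 0.83, −26.13, 0.44),

on the DNA/DNA nearest-neighbor Tm of the same sequence, its pyrimidine
fraction f_pyr and length L. The coefficients live in configuration
(`pna_tm_coefficients()`), not code, so they can be recalibrated against
melting data for a particular chemistry.

`nn_dna_tm()` implements the two-state model Tm = 1000·ΔH / (ΔS + R ln k)
− 273.15 with stacked-dinucleotide ΔH/ΔS sums, initiation and terminal
terms, a symmetry correction for self-complementary sequences (detected
automatically), and k = c/2 for equal strand concentrations c. Two
parameter sets are provided: Breslauer 1986 (default) and the unified
SantaLucia 2004 set. **Default conditions are the Breslauer set at its
1 M Na⁺ reference (no salt correction) with 0.25 µM per strand.** This is
a deliberate choice: the linear PNA correlation above was calibrated
against nearest-neighbor DNA Tm values computed in exactly that regime,
so feeding it a 50 mM-corrected Tm would systematically underestimate
PNA Tm by 15–20 °C. At these defaults the model reproduces the vendor-
reported melting temperatures of the published plastid and oak
mitochondrial clamps to within ~1.5 °C (80.5 vs 82 °C; 75.4 vs 76 °C),
and both clear the ≥72 °C effectiveness rule. Vendor tools do not publish
their models, so printed values are treated as a ±5 °C cross-check, never
an exact target. Away from 1 M the entropic correction
ΔS + 0.368·(N−1)·ln[Na⁺] is applied; the implementation is verified in
the test suite against 108 frozen values from an independent
nearest-neighbor implementation, to 10⁻⁸ °C.

The PCR **clamping step** must sit where the clamp is bound but primers
are not annealing: 5–10 °C below the clamp Tm and above the primer Tm.
`recommend_clamping_temp()` returns max(Tm_PNA − 10, primer_Tm + 2)
when that lies within [Tm_PNA − 10, Tm_PNA − 5] (rounded to the degree),
else "infeasible". The +2 °C guard band above the primer Tm is a
heuristic margin; with a clamp Tm of 76 °C and primer Tm of 66 °C it
yields the conventional 68 °C clamping step.

**Hairpin screening** (`hairpin_scan()`) does an exhaustive scan for
fold-back stems: two non-overlapping intervals, the second the reverse
complement of the first, separated by at least `min_loop` bases. Defaults
`min_stem = 4`, `min_loop = 3` follow common oligo-QC convention (three
unpaired bases is about the tightest loop a nucleic-acid backbone
closes); vendor hairpin tools do not publish their thresholds, so these
are package choices. For ≤25-mers the cubic scan is instantaneous and is
property-tested against an independent brute-force oracle.

`synthesis_spec()` renders the order string with N-terminal lysines
(default 2), the standard solubility handle for PNA synthesis; the PNA N
terminus corresponds to the 5′ end of the mimicked DNA strand. Protocol
defaults (`protocol_defaults()`) record 1 µM in-PCR concentration with a
typical 0.4–2 µM working range and up to 4–5 µM worth titrating for
heavily contaminated templates.

## Read accounting

`classify_and_tally()` keys organelle categories on the lineage strings
"Chloroplast" / "Mitochondria" at any rank (case-insensitive, patterns
configurable), the placement convention of SILVA v138; remaining Bacteria
are "bacteria" and anything else is kept as an explicit "other" category
rather than silently merged. Per-sample fractions always sum to 1;
zero-read samples are dropped with a warning; unlabeled ASVs are an
error naming the ASV.

"The bacterial fraction increased by X points" is ambiguous between
per-sample and pooled views, and the two genuinely differ when read depth
varies across trees. `treatment_delta()` therefore emits both, labelled:
`by_tissue` averages per-pair percentage-point deltas over trees (mean ±
sample sd, the form that carries a spread), while `pooled` differences
the read-weighted pooled fractions. Relative changes (ratios) are not
asserted anywhere; deltas are always percentage points. `dominance()`
reports the single most abundant ASV's share within a category — organelle
read pools are typically dominated by one ASV, which is exactly what
makes a single perfect-match clamp worth designing.

## The synthetic data generator

`simulate_asv_set()` emulates the structure that matters to the
screening problem and nothing more: uniform i.i.d. ACGT backgrounds of
~250 bp (V4-like) in which planted clamp k-mers occur in an exact,
deterministic number of targets (`round(fraction × n_target)`, sampled
without replacement under the seed) and — by rejection sampling — in no
off-target and no unintended position. Defaults mirror a realistic oak
survey: 93 mitochondrial targets, 20 abundant bacterial off-targets, and
the three oak mitochondrial clamps planted at carrier fractions 18/93,
27/93, 33/93, the coverage arithmetic of the published three-clamp
panel. An optional per-carrier mutation rate plants single-substitution
(inexact) sites; only intact sites enter the truth map.

What the generator does **not** emulate: 16S phylogenetic structure
(real ASVs are highly similar to each other, so real candidate k-mers
are shared among related bacteria far more often than under a uniform
background), GC skew, chimeras and sequencing error. Passing the
end-to-end recovery tests therefore demonstrates the correctness of the
screening/cover machinery under exact ground truth, not the expected
coverage attainable on real organelle data. Likewise
`simulate_count_table()` draws clean multinomial reads at known category
fractions (with a 0.97/0.02/0.01 within-category dominance profile), so
accounting tests verify estimator correctness within 3 multinomial
standard deviations at depth 10⁶, not robustness to compositional
artifacts.

Because the real most-abundant organelle ASV sequences are not
redistributable, `synthetic_reference_asvs()` provides clearly labelled
synthetic stand-ins that plant the documented match structure — the
plastid clamp matching through its complement, the oak clamp verbatim,
and the universal mitochondrial clamp at exactly 6 ungapped mismatches —
so those relationships are exercised end to end.

## Numerical and design choices

* Coordinates are 0-based, half-open everywhere (offsets, hairpin stems).
* All tie-breaks are deterministic and documented: candidate ranking
  (hits ↓, weighted hits ↓, sequence ↑), greedy selection (gain ↓,
  sequence ↑), mismatch profiles (mismatches ↑, offset ↑, forward first),
  dominance (reads ↓, ASV id ↑).
* `U` is mapped to `T` on input and lowercase is uppercased; soft-masking
  carries no meaning for clamp design. Degenerate windows are excluded
  from candidates but count as mismatches when matched against.
* Reports are written with fixed numeric formatting so identical inputs
  give byte-identical files.
* Problem sizes in the test suite (≤93 × 250 bp fixtures, 1000-instance
  oracle sweeps, depth-10⁶ count tables) were chosen so the full suite
  runs in a couple of minutes on one core while still exercising the
  study-scale defaults.

## Known limitations

* The PNA Tm correlation is linear and sequence-composition based; it
  ignores position-dependent and terminal effects, PNA-specific mismatch
  thermodynamics, and clamp–primer heterodimers. Full secondary-structure
  folding (partition-function) is out of scope; the hairpin scan is a
  combinatorial screen, not a free-energy model.
* Mismatch effects on clamping efficiency are handled combinatorially
  (exact vs ≥ d_min mismatches), not thermodynamically.
* Greedy cover is a heuristic; for panels larger than a few clamps an ILP
  could recover a provably optimal panel. Clamp–clamp interactions in a
  cocktail are not modeled.
* The simulator's uniform background understates k-mer sharing among real
  related 16S sequences; coverage numbers from synthetic runs are upper
  bounds on what equally sized real data would yield.
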