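Package: pnaclamp
Title: Design and Quality Control of PNA Clamps for Host Organelle
    Depletion in 16S rRNA Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs peptide nucleic acid (PNA) clamps that suppress
    co-amplification of host chloroplast and mitochondrial 16S rRNA gene
    sequences in plant microbiome amplicon studies. Candidate k-mer clamps
    are enumerated from host organelle amplicon sequence variants (ASVs),
    screened for perfect-match coverage of the host set and absence of
    binding to bacterial ASVs, assembled into a minimal clamp panel by
    greedy set cover, and gated on PNA/DNA duplex melting temperature and
    hairpin self-structure. Also provides per-sample read accounting of
    chloroplast, mitochondrial and bacterial fractions in ASV count tables,
    a synthetic ASV simulator with planted clamp sites for validation, and
    a command-line interface over the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
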