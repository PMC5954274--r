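Package: granulome
Title: Resolution Effects in Synteny-Block Ancestral Genome Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how the resolution (granularity) of synteny
    blocks distorts comparative-genomic inference.  Builds three-way synteny
    blocks from pairwise block tables, degrades resolution by deleting small
    blocks and merging nearby same-colour neighbours, computes exact DCJ and
    breakpoint medians of three genomes, decomposes rearrangement scenarios
    into translocations, reversals, fusions and fissions, measures breakpoint
    reuse (r = 2d/b), and estimates translocation counts from conserved
    syntenies via a probabilistic model.  A ground-truthed synthetic-genome
    simulator emulates SynMap-style block data so every stage is testable
    without external genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
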