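Package: nd3shift
Title: Evolutionary Analysis of a +1 Frameshift Insertion in Mitochondrial ND3
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study single-nucleotide frameshift insertions in
    protein-coding mitochondrial genes, built around the +1 insertion at
    position 174 of NADH dehydrogenase subunit 3 (ND3) found in some birds
    and turtles. Calls insertion states from a multiple alignment,
    reconstructs ancestral states under an equal-rates Mk model (Felsenstein
    pruning, maximum-likelihood rate fitting, rerooting-method marginal
    posteriors) and by Sankoff maximum parsimony, counts gain/loss and
    nucleotide-substitution events along a phylogeny under an evidence
    threshold, profiles per-site Shannon entropy and information content,
    tabulates codon usage in the shifted (0) and corrected (+1) reading
    frames under the vertebrate mitochondrial code, scans codon-aware
    alignments for frame-breaking indels, and simulates trees, traits and
    ND3-like alignments with known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    seqinr,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix,
    phangorn
Config/testthat/edition: 3
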