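Package: dendroblast
Title: Alignment-Free Phylogenetic Trees from Pairwise Local-Alignment Bit Scores
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers approximate phylogenetic trees for protein families
    without a multiple sequence alignment. All-vs-all local-alignment bit
    scores (computed internally under BLOSUM62, or parsed from external
    blastp tabular output) are transformed into a symmetric distance matrix
    via normalisation by per-query score extrema, hit-profile overlap
    weighting, and a negative-log transform. Trees are inferred from the
    distances by neighbour-joining or balanced minimum evolution. Weakly
    supported bipartitions are identified and removed by perturbing the
    input sequences under a Gamma-weighted BLOSUM62 replacement model,
    re-inferring a tree per perturbed replicate, and taking the
    majority-rule consensus. Includes bipartition-based tree comparison
    (Robinson-Foulds distance, false-positive and false-negative splits,
    precision, recall), a calibration routine for the Gamma scale of the
    replacement model, and a synthetic protein-family simulator that evolves
    sequences along known random trees for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
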