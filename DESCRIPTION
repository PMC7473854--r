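Package: mosaicKO
Title: Modeling and Maximizing CRISPR/Cas9 Knockout Penetrance in Mosaic F0 Embryos
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for designing CRISPR/Cas9 guide RNAs that maximize
    loss-of-function phenotype penetrance in mosaic F0 embryos. Provides a
    canonical representation of Cas9 editing outcomes (deletions, insertions,
    wildtype) with microhomology-aware canonicalization, the curation and
    normalization rules used to compare predicted and experimentally observed
    indel spectra, a concordance harness (per-guide, pooled and
    frameshift-frequency Pearson correlations, residual analyses, Sanger/ICE
    averaging), analytic and Monte-Carlo models of mosaic embryos including
    the knockout score (squared frameshift frequency) and the pushforward of
    a frameshift-frequency prior to the distribution of biallelic-frameshift
    cell fractions, a guide scanning and scoring pipeline (position-specific
    activity regression, microhomology stand-in outcome predictor, MMEJ
    fraction, per-gene highest/lowest-in-class calls), synthetic-data
    generators with known ground truth, and grayscale eye-pigmentation
    quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    png,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
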