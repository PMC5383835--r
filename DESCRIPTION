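Package: codonsym
Title: Group-Theoretic Symmetries of the Standard Genetic Code
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the standard genetic code as a
    six-dimensional hypercube acted on by the Klein four-group. Implements
    the component-wise action of K4^3 on codons under the admissible Cayley
    variants, the codon metric and hypercube graph with its full
    automorphism group, the piecewise isometries that interconvert the
    Rodin-Ohno arrangement of the aminoacyl-tRNA synthetase classes and the
    RNY-based code, quotient-group renderings of Delarue's differentiation
    genealogy, and a general symmetry scanner that scores how exceptional an
    amino-acid classification is against permutation null models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
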