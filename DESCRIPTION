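Package: dcgr
Title: Alignment-Free Protein Sequence Features from Chaos Game
    Representation Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Extracts alignment-free numerical features from protein
    sequences with the DCGR method: each sequence is encoded as a chaos
    game representation (CGR) curve inside the unit circle, one curve per
    physicochemical amino-acid scale, with the 20 amino acids arranged on
    the circumference in ascending order of the scale.  Each curve is
    summarised by the leading eigenvalues of the pairwise point-distance
    matrices of its four quadrants, yielding 4 features per scale (632 for
    a 158-scale catalog).  Downstream tools reduce the feature matrix by
    principal component analysis, compute inter-sequence distances under
    four metrics (Euclidean, Manhattan, cosine, standardized Euclidean),
    and build UPGMA or neighbor-joining trees exported as Newick.  Includes
    an AAindex1 flat-file parser with a redundancy filter, a frequency-only
    baseline (FCGR ablation), and a synthetic protein-family generator for
    end-to-end validation without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
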