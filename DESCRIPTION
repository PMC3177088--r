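Package: cysmapr
Title: Disulfide-Bond Abundance Estimation by Sequence-Structure Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the fraction of cysteine residues engaged in
    intramolecular disulfide bonds across whole proteomes by mapping protein
    sequences onto homologous three-dimensional structures. Provides the
    proteome-scale disulfide abundance parameter f (fraction of
    structure-mapped cysteines whose C-alpha lies within a distance cutoff of
    another mapped cysteine), the structure-database control fraction f'
    derived from SSBOND records with metal-site exclusion, an even-versus-odd
    cysteine parity analysis, eligibility filters for metal motifs and
    secreted proteins, a semi-global Needleman-Wunsch realignment engine, and
    a synthetic proteome/structure generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    bio3d,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
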