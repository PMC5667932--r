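Package: commitnet
Title: Switching Boolean Network Analysis of Phosphatase-Driven Cell Commitment
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for inferring signed phosphatase-phosphatase interaction
    networks from gene-knockdown time courses and for formal reasoning over
    Abstract Boolean Networks (ABNs) whose topology switches along a
    differentiation trajectory.  Provides a synthetic-data generator for
    knockdown RT-qPCR tables and SILAC phosphoproteomics tables with known
    ground truth; two-way ANOVA edge inference with Holm-Sidak correction and
    inverse-p edge weights; Boolean discretisation of expression profiles;
    synchronous Boolean network simulation; complete enumeration-based
    satisfiability checking of single and switching ABNs, including
    required/disallowed interaction classification; and SILAC phospho-site
    ranking with a protein-abundance exclusion rule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
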