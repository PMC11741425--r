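Package: repeatflux
Title: Evolution of Genome-Wide Simple Repeat Length Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the mutational dynamics of simple tandem
    repeats (microsatellites). Assembles genome-wide contiguous repeat
    length distributions per motif equivalence class from sequence
    assemblies; estimates context-classified substitution rates and
    length-stratified expansion, contraction and non-motif insertion
    rates from de novo trio mutation tables and popSTR-style locus
    tables; evolves the joint repeat/non-repeat length distribution
    under an explicit deterministic (or stochastic) mutation kernel with
    progressive time rescaling; infers instability-rate parameters by
    grid search against an empirical distribution; and characterizes
    steady states analytically through a geometric short-length solution
    and nested steady-state ordinary differential equations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    BiocGenerics,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
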