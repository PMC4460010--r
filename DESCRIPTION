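Package: ferromap
Title: Profile-Based Screening of Iron-Metabolism Gene Families in
    Transcriptome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A self-contained pipeline for surveying iron-metabolism gene
    families (ferric reductase, multicopper oxidase, iron permease, ferritin,
    flavodoxin, ferredoxin, plastocyanin, cytochrome c6 and the four
    superoxide dismutase metalloforms) across transcriptome assemblies.
    Contigs are six-frame translated and screened with internally built,
    extreme-value-calibrated profile models; candidates pass span, insertion
    and within-strain duplicate filters; functional identity is assigned by
    degenerate motif and diagnostic-residue rules; plastid transit peptides
    and ubiquitin fusion architectures are detected; and per-strain paralog
    copy numbers are derived by collapsing same-species clades on
    neighbor-joining trees. A synthetic-community generator with a complete
    truth manifest makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    phangorn,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
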