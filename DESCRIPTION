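Package: pepdigest
Title: In Silico Gastrointestinal Release and Characterization of Bioactive
    Di- and Tripeptides from Plant Antimicrobial Oligopeptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates simultaneous proteolysis of plant antimicrobial
    oligopeptides by gastrointestinal proteases (pepsin, trypsin,
    chymotrypsin) under configurable bond-cleavage specificity rules,
    annotates the released di- and tripeptides with bioactivity classes
    (ACE, DPP-IV and related peptidase inhibitors, antioxidative and
    neuropeptides), screens the fragments for resistance to microbial
    proteases (oligopeptidase F, proteinase P1/lactocepin), and computes
    physicochemical descriptors: Boman index, Henderson-Hasselbalch net
    charge and theoretical isoelectric point, Guruprasad instability index,
    Ikai aliphatic index, Kyte-Doolittle GRAVY and a water-solubility class,
    together with the standard interpretation thresholds. Ships the
    57-record reference dataset of plant antimicrobial peptides with
    anticancer properties and a seeded synthetic-peptide generator with
    motif embedding for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
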