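Package: neovax
Title: Individualized Neoantigen Vaccine Design and Immune Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs individualized mRNA neoantigen vaccines from somatic
    variant calls and monitors the induced T cell response. Somatic SNVs and
    indels are turned into mutated peptide sequences (27-mer windows for
    substitutions, novel reading frame to the next stop for frameshifts) with
    germline phasing, expression and variant-allele-frequency annotation;
    candidates are scored against the patient HLA genotype through a pluggable
    percentile-rank binding interface, reduced to a prioritized list of at
    most 46 peptides by tiered rules, and at most 20 selected targets are
    assembled into up to two concatamer mRNA constructs with a secretory
    signal peptide, glycine/serine linkers and an MHC class I trafficking
    domain. Downstream assay analytics cover overlapping-peptide pool design,
    ELISpot response calling by a permutation test, peptide-HLA multimer
    candidate selection, and CDR3-beta clonotype tracking across blood and
    tumor bulk TCR repertoires. A deterministic synthetic-cohort generator
    emulates all required inputs so the full pipeline runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
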