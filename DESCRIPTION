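Package: beoutcome
Title: Base-Editing Outcome Classification and Fidelity Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies the outcomes of CRISPR base editing experiments from
    resolved allele sequences. Alleles are globally aligned to the target
    locus, substitution and indel events are called with left-normalized
    coordinates, and every event is labelled by genomic region (on-target
    editing window, bystander positions within the protospacer, proximal
    off-target flanks) and by product purity (anticipated transitions,
    opposite-strand deamination, other substitutions, indels) for cytosine
    (CBE) and adenine (ABE) base editors. Cohort-level summaries reproduce
    per-editor category frequencies, the 5'-TC-3' APOBEC sequence-context
    fraction of proximal off-target cytosine mutations, and chi-squared
    editor comparisons with Bonferroni correction and noncentral chi-squared
    power analysis. Includes a synthetic-cohort simulator with ground truth
    and deterministic fixture builders.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
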