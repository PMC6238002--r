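# beoutcome

Classification of base-editing outcomes and editing-fidelity statistics in R.

## The problem

Cytosine base editors (CBEs: BE2/HF2-BE2, BE3, SaBE3, VQR-BE3, BE4) and the
adenine base editor (ABE 7.10) install point mutations without double-strand
breaks, but not every edited allele carries only the intended change. Given
Sanger-resolved allele sequences from edited founders or embryos, a
consistent accounting is needed of *where* each mutation fell and *what*
product it is:

- **On-target** — within the ~5-bp editing window (protospacer positions
  4–8, counting the first PAM base as position 21).
- **Bystander** — inside the protospacer but outside the window.
- **Proximal off-target** — outside the protospacer but within 200 bp of it.
- **Anticipated product** — C•G→T•A for a CBE, A•T→G•C for ABE, on the
  protospacer strand.
- **Opposite-strand edit** — the same deamination chemistry on the
  non-protospacer strand, seen as G→A (CBE) or T→C (ABE).
- **Unanticipated products** — everything else: other substitutions and
  indels.

`beoutcome` implements this taxonomy as a reusable pipeline for anyone
genotyping base-edited animals or cell clones: global affine-gap alignment
of each allele against the target locus, mutation calling with canonical
left-normalized indel coordinates, per-mutation and per-allele
classification, per-editor category frequencies (denominator = mutant
alleles, multi-membership categories), the 5′-TC-3′ APOBEC sequence-context
fraction of proximal off-target cytosine mutations, and a chi-squared
CBE-vs-ABE comparison with Bonferroni correction and noncentral chi-squared
power analysis (Cohen's *w*, power = P(χ²(df, λ = n·w²) > χ²₁₋α(df))).

It also ships a synthetic-cohort simulator with ground truth and
deterministic fixture builders that reconstruct published per-editor cohort
counts as concrete sequences, so the whole pipeline is testable end to end.

## Worked example

Classify the built-in BE4 fixture cohort (27 mutant alleles on a 423-bp
locus) and compare it with the 214-allele ABE cohort:

```r
library(beoutcome)
library(dplyr)

fx  <- make_printed_fixture("BE4")
res <- classify_cohort(fx$alleles, fx$locus, fx$editor)

res$mutations |>
  select(allele_id, kind, ps_pos, ref, alt, region, product) |>
  head(3)
#>   allele_id kind         ps_pos ref   alt   region    product
#> 1 BE4/a001  substitution      4 C     T     on_target anticipated
#> 2 BE4/a002  substitution      4 C     T     on_target anticipated
#> 3 BE4/a003  substitution      4 C     T     on_target anticipated

summarize_cohort(res$alleles) |>
  filter(category %in% c("on_target", "bystander", "indel",
                         "unanticipated_sub", "anticipated_only_on_target"))
#>   editor_name n_mutant_alleles category                   count percent
#> 1 BE4                       27 on_target                     26      96
#> 2 BE4                       27 bystander                      4      15
#> 3 BE4                       27 indel                          5      19
#> 4 BE4                       27 unanticipated_sub              3      11
#> 5 BE4                       27 anticipated_only_on_target    17      63
```

Read: 96% of BE4 mutant alleles carry an edit in the editing window, 15%
carry a bystander edit, 19% a deletion, 11% an unanticipated substitution,
and 63% carry *only* anticipated on-target edits (product purity).
Categories are multi-membership, so percentages need not sum to 100.

```r
abe <- make_printed_fixture("ABE")
cmp <- compare_editors(bind_rows(
  res$alleles,
  classify_cohort(abe$alleles, abe$locus, abe$editor)$alleles
))
tidy(cmp)
#>   category            abe_count cbe_count statistic    df  p_value p_adjusted
#> 1 on_target                 214        26      7.96     1 4.79e- 3   1.91e- 2
#> 2 bystander                  69         4      3.45     1 6.33e- 2   2.53e- 1
#> 3 proximal_off_target         0         1      7.96     1 4.79e- 3   1.91e- 2
#> 4 indel                       0         5     40.5      1 2.00e-10   7.99e-10
```

Each row is a 2×2 test (allele in/not in category, ABE vs pooled CBE);
`p_adjusted` is Bonferroni over the four planned comparisons. `glance(cmp)`
adds the omnibus statistic and the power of the design at *w* = 0.15,
α = 0.05. `autoplot(summarize_cohort(...))` draws the per-editor frequency
panels.

File-based runs (`run_pipeline()`, or `inst/scripts/beoutcome.R` from a
shell) take a reference FASTA, an allele multi-FASTA, a TSV sample sheet
and a YAML editor config, and write per-mutation TSV, per-allele flags,
cohort summary TSV/JSON, comparison stats JSON and the context JSON.

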