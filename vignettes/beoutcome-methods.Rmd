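---
title: "Classifying base-editing outcomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying base-editing outcomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beoutcome)
library(dplyr)
```

## The analysis in one paragraph

Given a reference locus, a guide's protospacer, and a set of resolved
allele sequences from base-edited founders or embryos, `beoutcome` aligns
every allele globally against the reference window (protospacer ± 200 bp),
calls substitution and indel events with canonical coordinates, labels
every event by genomic region (on-target editing window, bystander
protospacer positions, proximal off-target flanks) and product purity
(anticipated transition, opposite-strand edit, other substitution, indel),
rolls the labels up to per-allele category flags, and summarizes per-editor
frequencies together with a sequence-context statistic and a CBE-versus-ABE
chi-squared comparison with power analysis.

## Coordinate model

All rules are written in protospacer coordinates on the
protospacer-containing strand: position 1 is the protospacer's 5′-most
base, so for a 20-nt SpCas9 protospacer the PAM starts at position 21;
upstream flank positions are 0, −1, −2, …. Internally, reference positions
are 1-based (`ref_pos`), the R/Bioconductor convention, and
`protospacer_position()`/`ref_position()` convert losslessly between the
two systems. Loci whose protospacer lies on the genomic minus strand must
be reverse-complemented at ingestion; every downstream rule then sees the
protospacer strand, which is also the strand the "opposite-strand edit"
vocabulary is relative to.

Region boundaries, with `w = [window_start, window_end]` (default 4–8),
`L` the protospacer length and `r` the proximal radius (default 200 bp):

| region | condition on protospacer position p |
|---|---|
| on_target | `window_start ≤ p ≤ window_end` |
| bystander | `1 ≤ p ≤ L`, outside the window |
| proximal_off_target | `−r < p ≤ 0` or `L < p ≤ L + r` |
| out_of_range | otherwise |

PAM bases sit outside the protospacer and are therefore proximal
off-target territory. An indel spanning several positions takes the
highest-priority region it overlaps (on-target > bystander > proximal);
an insertion is judged by the two bases flanking its junction.

## Alignment and mutation calling

Alignment is global Needleman–Wunsch/Gotoh with affine gaps over the full
reference window, so flank mutations are never silently dropped by local
alignment. Default scores: match +2, mismatch −2, gap open −8, gap extend
−1 (a length-k gap costs 8 + k). The enforced ordering
`gap_open < mismatch < 0 < match` guarantees a point change is always
represented as a substitution rather than an adjacent
insertion–deletion pair. The dynamic programming itself is delegated to
`Biostrings::pairwiseAlignment()`; terminal gap columns that the aligned
views clip are restored so deletions or insertions at the window ends are
still called.

Aligner tracebacks are not unique, so event coordinates are made
deterministic by a canonicalization pass: every gap run is re-placed at
the left-most position that maximizes the number of matching aligned
columns within the window bounded by its neighboring gap runs. This
subsumes classic VCF left-alignment of indels in repeats (sliding through
equal bases) and additionally slides gaps across substitution columns,
which is always score-neutral — the displaced mismatch reappears on the
other side of the gap. The practical consequence is that a deletion
flanked by substitutions has one well-defined description, whichever
traceback the aligner happened to return. Adjacent mismatch columns are
always emitted as separate length-1 substitutions (transitions are
counted per base, never merged into MNVs). The operative contract, tested
on thousands of random alleles, is the round trip
`apply_mutations(ref, call_mutations(align_allele(locus, x))) == x`.

Partial Sanger reads are supported through `partial = TRUE`, which makes
end gaps free and records the uncovered reference range instead of calling
spurious terminal deletions. This is an explicit argument rather than an
automatic switch on length: any allele carrying a deletion is also
"shorter than the reference", and auto-switching would turn real terminal
deletions into uncovered spans.

IUPAC ambiguity codes anywhere in a reference or allele are a hard error.
An unresolved heterozygous trace would corrupt per-allele counts; the
analysis assumes alleles are resolved upstream.

## Product purity and strand inference

For an editor with target base `B` and product base `P` (C→T for CBEs,
A→G for ABE), a substitution is:

- `anticipated` if it is `B→P` on the protospacer strand;
- `opposite_strand` if it is `comp(B)→comp(P)` (G→A for CBE, T→C for
  ABE) — the same deamination chemistry acting on the exposed opposite
  strand;
- `other_substitution` otherwise, with the edited strand annotated when
  the reference base is `B` or `comp(B)`. Under a CBE, G→T is flagged
  `possible_opposite_edit` (it could arise from C→A on the opposite
  strand);
- every insertion or deletion is product class `indel`.

Product is evaluated per mutation irrespective of region: an
anticipated-type C→T in the proximal flank is an off-target *event* but
not an unanticipated *product*. The symmetric opposite-strand rule for ABE
(T→C) follows from the chemistry; it is adopted for consistency even
though such events are rare in practice.

## Allele-level categories

Per allele, the package reports multi-membership flags; the cohort
denominators are mutant alleles only (alleles with zero called mutations
are wild-type sentinels and never counted):

- `has_on_target`, `has_bystander`, `has_proximal` — where base
  substitutions fell. A deletion or insertion additionally sets
  `has_on_target` when it overlaps the editing window (the target site is
  itself destroyed); indels elsewhere do **not** set the bystander or
  proximal flags. This split reflects how location categories are used in
  practice: they describe base-editing events, while indels are reported
  as their own outcome class. It is also the only reading under which
  published per-editor counts of the location categories, the indel
  category and the allele totals are simultaneously consistent.
- `has_indel` — any insertion or deletion.
- `anticipated_only_on_target` — every mutation is an anticipated product
  inside the window; the product-purity figure of merit.
- `has_unanticipated` — any non-anticipated product, indels included;
  `has_unanticipated_sub` — unanticipated substitutions only
  (opposite-strand or other). Both are reported because "alleles with
  unanticipated products" and "alleles with unanticipated mutations
  (substitution types)" are distinct published quantities: a cohort can
  have five deletion-carrying alleles yet only three alleles with
  unanticipated substitutions.
- `off_target_or_indel_only` — (proximal or indel) and no on-target edit:
  the allele was mutagenized without the intended edit.

Percentages are `100 × count / n_mutant_alleles`, rounded half away from
zero to integers — the rounding that reproduces published figures
(54/91 → 59%, 4/27 → 15%, 5/23 → 22%), where R's default banker's
rounding would not.

## Sequence context (5′-TC-3′)

APOBEC-family deaminases prefer a cytosine preceded by thymidine. For
every proximal off-target substitution at a cytosine — on either strand:
`ref == C`, or `ref == G` read as a C on the opposite strand —
`tc_fraction()` reads the 5′ neighbor from the *reference* (deamination
acted on the pre-edit sequence), taking the complement of the 3′ neighbor
for opposite-strand events. The statistic is `n_tc / n_total`, reported as
`NA` (not zero) when no eligible mutation exists. Both strands are
eligible because opposite-strand deamination is part of the product model.

## Cohort statistics

The editor-class comparison treats the four planned categories
(on-target, bystander, proximal off-target, indel) one at a time: a 2×2
Pearson chi-squared test (no continuity correction) of allele membership,
ABE versus all CBE variants pooled, with Bonferroni correction over m = 4
comparisons. Per-category 2×2 tables are used because the categories are
multi-membership — a single omnibus 2×4 table would count some alleles
several times. The omnibus Pearson statistic on the count table is still
reported for reference. A category absent from both arms carries no
information and yields `NA` rather than a degenerate test.

Power uses Cohen's *w* for chi-squared tests: under the alternative the
statistic is noncentral chi-squared with λ = n·w², and

power = P( χ²(df, λ) > χ²₁₋α(df) ).

At *w* = 0 the function returns α exactly (the central case by
definition, avoiding floating-point noise from the quantile round trip).
The *w* convention is a deliberate choice: effect sizes for chi-squared
designs are sometimes quoted as Cohen's d, but d applies to mean
differences; for a 4-category allele-count design *w* is the coherent
measure, and the default `effect_size_w = 0.15` with α = 0.05 and
n = 436 alleles (df = 3) gives power ≈ 0.75, computed — never hard-coded —
by `chisq_power()`. A Monte-Carlo rejection-rate oracle in the test suite
confirms the closed form to within 0.02.

## The synthetic-data generator

`simulate_cohort()` emulates the statistical structure of an edited-zygote
cohort: independent per-position Bernoulli edits at target bases (separate
rates for window, bystander and flank positions, default 0.5 / 0.05 /
0.002 per position — roughly an efficient editor with rare proximal
events), a product-purity mixture (default 90% anticipated, 5%
opposite-strand, 5% other), a per-allele deletion probability (default
0.1) with a geometric length distribution over 1–10 bp placed inside the
protospacer, and a 5′-TC-3′ rate multiplier in the flanks (default 3).
Opposite-strand events are realized at the nearest complement-base
position in the same region. Events are applied 3′→5′ so coordinates stay
valid, and injected indels are rewritten in the same canonical form the
caller emits, so ground truth and calls are comparable coordinate by
coordinate.

What the simulator does *not* model: founder mosaicism, Sanger basecall
noise, PCR chimeras, large structural variants, and any correlation
between edits beyond shared alleles. Passing recovery tests therefore
demonstrates that the pipeline inverts its own generative model — a
necessary, not sufficient, condition for correctness on real traces.

The fixture builders (`make_printed_fixture()`, `make_tc_fixture()`) are
the deterministic counterpart: hand-laid allele blueprints on a
constructed 423-bp locus whose edit sites have fixed sequence context and
whose indel sites are flanked so that no alternative gap placement exists
(asserted at construction). Fixture classification is therefore exact, and
the preset cohorts reproduce published per-editor counts through the full
pipeline. A custom counts specification is allocated greedily
(cover alleles lacking on-target edits first, then break the purity of the
remaining on-target alleles) and rejected with an `InfeasibleSpec` error
when logically inconsistent, e.g. more anticipated-only than on-target
alleles. The pooled ABE preset keeps its three sub-cohorts (8 + 39 + 167
alleles) addressable via the `cohort` column; the three unanticipated C→T
alleles are placed among the bystander-carrying alleles because the
on-target-only alleles are published as carrying nothing else.

## Numerical and degenerate-input choices

- Ties among equal-scoring alignments: canonical left-most gap placement
  (above); deterministic across platforms since only integer match counts
  are compared.
- Aligned identity < 80% raises a structured warning (`be_low_identity`),
  not an error: a mislabeled sample should surface, but the decision to
  drop it belongs to the analyst.
- `tc_fraction` with an empty denominator returns `NA`; chi-squared on a
  table with an all-zero margin raises `be_degenerate_table`; a cohort in
  which an editor has zero mutant alleles raises `be_empty_cohort`.
- `bonferroni_adjust(p, m)` allows `m > length(p)` (planned comparisons
  that could not all be run still discount the ones that were).
- SaCas9 editors use a 21-nt protospacer and NNGRRT PAM; the "PAM at
  position 21" convention generalizes to "PAM starts at protospacer_len
  + 1". Their editing window is not separately established here and
  defaults to 4–8, configurable in `editor_spec()`.

## Problem sizes in the test suite

The suites run on one CPU in a few minutes: exhaustive alignment-oracle
comparison over all 2-letter sequence pairs up to length 4 plus 120 random
pairs up to length 12; a 1000-allele round-trip suite on a 103-bp locus;
1000 simulated alleles for label recovery (≥ 99% required; residual
disagreements are genuinely ambiguous re-descriptions of compound events
in repeats); 10⁵-replicate multinomial oracles for chi-squared p-values;
2×10⁴-replicate rejection-rate oracles for power.

## Known limitations

- Alleles are taken as resolved sequences; chromatogram deconvolution and
  diploid phasing are out of scope.
- Distal off-target analysis (away from the protospacer) is explicitly
  out of scope; the model covers ±200 bp.
- The per-mutation strand call for `other_substitution` events at bases
  other than the target or its complement is `not_applicable`; no attempt
  is made to infer their origin.
- Compound alleles whose deletion and substitutions admit several
  equal-scoring descriptions are reported in canonical form, which may
  differ from the mutational history; only the resulting sequence is
  knowable from data.
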