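# APOBEC sequence-context analysis. Cytosine deaminases prefer a thymidine
# immediately 5' of the substrate cytosine (5'-TC-3'); the fraction of
# proximal off-target cytosine mutations in that context is the summary
# statistic. The reference base, not the allele's possibly mutated
# neighbor, defines the context: deamination acted on the pre-edit
# sequence.

#' Base 5' of an edited cytosine
#'
#' For a substitution at a cytosine on the protospacer strand (`ref == C`)
#' this is the reference base immediately 5' of it. For a cytosine edited
#' on the opposite strand (seen as `ref == G` on the protospacer strand)
#' it is the complement of the reference base immediately 3' of the G.
#'
#' @param locus a [target_locus()].
#' @param ref_pos 1-based reference position of the edited base.
#' @param edited_strand `"protospacer_strand"` or `"opposite_strand"`.
#' @return single base.
#' @export
preceding_base <- function(locus, ref_pos, edited_strand) {
  stopifnot(inherits(locus, "target_locus"), length(ref_pos) == 1L)
  n <- nchar(locus$reference_seq)
  if (edited_strand == "protospacer_strand") {
    if (ref_pos - 1L < 1L) {
      rlang::abort("5' neighbor falls outside the covered reference",
                   class = "be_out_of_window")
    }
    ref_base_at(locus, ref_pos - 1L)
  } else {
    if (ref_pos + 1L > n) {
      rlang::abort("3' neighbor falls outside the covered reference",
                   class = "be_out_of_window")
    }
    complement_base(ref_base_at(locus, ref_pos + 1L))
  }
}

# vectorized context read-off used by classify_mutations(): NA for
# non-eligible events (non-substitutions, bases other than C/G) or when
# the neighbor is off the reference
preceding_base_vec <- function(locus, kind, ref_pos, ref) {
  n <- nchar(locus$reference_seq)
  refseq <- locus$reference_seq
  dplyr::case_when(
    kind != "substitution" ~ NA_character_,
    ref == "C" & ref_pos > 1L ~ substring(refseq, ref_pos - 1L, ref_pos - 1L),
    ref == "G" & ref_pos < n ~ unname(DNA_COMPLEMENT[substring(refseq, ref_pos + 1L, ref_pos + 1L)]),
    TRUE ~ NA_character_
  )
}

#' 5'-TC-3' context fraction of off-target cytosine mutations
#'
#' Among region-filtered substitutions at cytosines (on either strand:
#' `ref == C`, or `ref == G` read as a C on the opposite strand), counts
#' how many occurred at a C preceded by T.
#'
#' @param classified tibble from [classify_mutations()].
#' @param region_filter regions to keep (default proximal off-target, the
#'   reported statistic).
#' @return one-row tibble with `n_tc`, `n_total` and `fraction`
#'   (`NA` -- not zero -- when no eligible mutation exists).
#' @export
tc_fraction <- function(classified, region_filter = "proximal_off_target") {
  stopifnot(is.data.frame(classified))
  elig <- classified |>
    dplyr::filter(.data$kind == "substitution",
                  .data$region %in% region_filter,
                  .data$ref %in% c("C", "G"),
                  !is.na(.data$preceding_base))
  n_total <- nrow(elig)
  n_tc <- sum(elig$preceding_base == "T")
  tibble::tibble(
    n_tc = n_tc, n_total = n_total,
    fraction = if (n_total == 0) NA_real_ else n_tc / n_total
  )
}
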