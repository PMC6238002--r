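# Outcome taxonomy. Every called event receives a region label relative to
# the protospacer coordinate system (on-target editing window > bystander
# protospacer positions > proximal off-target flanks) and a product label
# (anticipated transition, opposite-strand deamination, other substitution,
# indel). Allele-level flags roll these up into the categories reported at
# cohort level.

REGIONS <- c("on_target", "bystander", "proximal_off_target", "out_of_range")
PRODUCTS <- c("anticipated", "opposite_strand", "other_substitution", "indel")

# region of a single protospacer position
region_of_pos <- function(p, editor, protospacer_len, radius) {
  dplyr::case_when(
    p >= editor$window_start & p <= editor$window_end ~ "on_target",
    p >= 1L & p <= protospacer_len ~ "bystander",
    p <= 0L & p > -radius ~ "proximal_off_target",
    p > protospacer_len & p - protospacer_len <= radius ~ "proximal_off_target",
    TRUE ~ "out_of_range"
  )
}

#' Classify the genomic region of a mutation
#'
#' Substitutions are classified by their protospacer position: within the
#' editing window = on-target; elsewhere within the protospacer =
#' bystander; outside the protospacer but within `proximal_radius` bp of
#' either protospacer boundary = proximal off-target; further away =
#' out of range. PAM positions lie outside the protospacer and are
#' therefore proximal off-target territory. An indel spanning several
#' positions takes the highest-priority region it overlaps
#' (on-target > bystander > proximal off-target); an insertion is judged by
#' the two reference bases flanking its junction.
#'
#' @param ref_pos integer vector of 1-based reference positions.
#' @param kind character vector: "substitution", "insertion" or "deletion".
#' @param length integer vector of event lengths.
#' @param locus a [target_locus()].
#' @param editor an [editor_spec()].
#' @return character vector of region labels.
#' @export
classify_region <- function(ref_pos, kind, length, locus, editor) {
  stopifnot(inherits(locus, "target_locus"), inherits(editor, "editor_spec"))
  plen <- locus$protospacer_len
  radius <- locus$proximal_radius
  p <- ref_pos - locus$protospacer_start + 1L
  purrr::pmap_chr(list(p, kind, length), function(pi, ki, li) {
    span <- switch(ki,
      substitution = pi,
      deletion = seq.int(pi, pi + li - 1L),
      insertion = c(pi - 1L, pi)
    )
    regs <- region_of_pos(span, editor, plen, radius)
    REGIONS[min(match(regs, REGIONS))]
  })
}

#' Classify the product purity of a mutation
#'
#' On the protospacer strand, the anticipated product is
#' `target_base -> product_base` (C->T for CBE, A->G for ABE). The
#' complementary change (G->A for CBE, T->C for ABE) is read as the same
#' deamination chemistry acting on the opposite strand. Any other
#' substitution is an "other" (unanticipated) substitution; every indel is
#' its own product class. For CBE, a G->T is additionally flagged as a
#' possible opposite-strand C->A transversion.
#'
#' @param kind,ref,alt character vectors describing the events.
#' @param editor an [editor_spec()].
#' @return tibble with columns `product`, `edited_strand`,
#'   `possible_opposite_edit`.
#' @export
classify_product <- function(kind, ref, alt, editor) {
  stopifnot(inherits(editor, "editor_spec"))
  tb <- editor$target_base; pb <- editor$product_base
  ctb <- complement_base(tb); cpb <- complement_base(pb)
  is_sub <- kind == "substitution"
  product <- dplyr::case_when(
    !is_sub ~ "indel",
    ref == tb & alt == pb ~ "anticipated",
    ref == ctb & alt == cpb ~ "opposite_strand",
    TRUE ~ "other_substitution"
  )
  edited_strand <- dplyr::case_when(
    product == "anticipated" ~ "protospacer_strand",
    product == "opposite_strand" ~ "opposite_strand",
    product == "other_substitution" & ref == tb ~ "protospacer_strand",
    product == "other_substitution" & ref == ctb ~ "opposite_strand",
    TRUE ~ "not_applicable"
  )
  possible_opposite <- is_sub & ref == ctb & alt != cpb
  tibble::tibble(product = product, edited_strand = edited_strand,
                 possible_opposite_edit = possible_opposite)
}

#' Classify every mutation in a cohort table
#'
#' Adds protospacer coordinates, region and product labels, strand calls
#' and (for cytosine-context-eligible substitutions) the 5' preceding base
#' to a called mutation table.
#'
#' @param mutations tibble from [call_mutations()]/[call_cohort()].
#' @param locus a [target_locus()].
#' @param editor an [editor_spec()].
#' @return the input tibble with columns `ps_pos`, `region`, `product`,
#'   `edited_strand`, `possible_opposite_edit`, `overlaps_window`,
#'   `preceding_base` appended.
#' @export
classify_mutations <- function(mutations, locus, editor) {
  stopifnot(is.data.frame(mutations))
  if (nrow(mutations) == 0) {
    return(dplyr::mutate(mutations,
      ps_pos = integer(0), region = character(0), product = character(0),
      edited_strand = character(0), possible_opposite_edit = logical(0),
      overlaps_window = logical(0), preceding_base = character(0)))
  }
  ws <- ref_position(locus, editor$window_start)
  we <- ref_position(locus, editor$window_end)
  prod <- classify_product(mutations$kind, mutations$ref, mutations$alt, editor)
  out <- dplyr::mutate(mutations,
    ps_pos = .data$ref_pos - locus$protospacer_start + 1L,
    region = classify_region(.data$ref_pos, .data$kind, .data$length, locus, editor),
    product = prod$product,
    edited_strand = prod$edited_strand,
    possible_opposite_edit = prod$possible_opposite_edit,
    overlaps_window = dplyr::case_when(
      .data$kind == "substitution" ~ .data$ref_pos >= ws & .data$ref_pos <= we,
      .data$kind == "deletion" ~ .data$ref_pos <= we & (.data$ref_pos + .data$length - 1L) >= ws,
      .data$kind == "insertion" ~ .data$ref_pos - 1L <= we & .data$ref_pos >= ws
    ),
    preceding_base = preceding_base_vec(locus, .data$kind, .data$ref_pos, .data$ref)
  )
  out
}

#' Roll mutation labels up to allele-level categories
#'
#' Computes, per allele, the multi-membership flags that define the cohort
#' categories. Location flags (`has_on_target`, `has_bystander`,
#' `has_proximal`) record where base substitutions occurred; a deletion or
#' insertion additionally sets `has_on_target` when it overlaps the editing
#' window (the target site itself is disrupted), while indels elsewhere are
#' tallied only under `has_indel` -- indels are their own outcome category,
#' not a location category. `anticipated_only_on_target` marks alleles
#' whose every mutation is an anticipated product inside the window
#' (product purity); `has_unanticipated` marks any non-anticipated product
#' including indels, `has_unanticipated_sub` only unanticipated
#' substitutions. Alleles with zero mutations are returned as wild-type
#' sentinels (`is_mutant = FALSE`) and must be excluded from cohort
#' denominators.
#'
#' @param classified tibble from [classify_mutations()].
#' @param alleles tibble with `allele_id` plus metadata columns
#'   (`editor_name`, `cohort`, ...) listing every sequenced allele,
#'   including alleles in which no mutation was called. If `NULL`, the
#'   allele list is taken from the mutation table (wild-type alleles then
#'   cannot be represented).
#' @return one row per allele with logical category flags.
#' @export
classify_alleles <- function(classified, alleles = NULL) {
  stopifnot(is.data.frame(classified))
  if (is.null(alleles)) {
    alleles <- dplyr::distinct(classified, .data$allele_id)
  }
  stopifnot("allele_id" %in% names(alleles))
  if (anyDuplicated(alleles$allele_id)) {
    rlang::abort("duplicated allele_id in allele sheet", class = "be_invalid_spec")
  }
  per <- classified |>
    dplyr::group_by(.data$allele_id) |>
    dplyr::summarise(
      n_mutations = dplyr::n(),
      has_on_target = any(.data$kind == "substitution" & .data$region == "on_target") ||
        any(.data$kind != "substitution" & .data$overlaps_window),
      has_bystander = any(.data$kind == "substitution" & .data$region == "bystander"),
      has_proximal = any(.data$kind == "substitution" & .data$region == "proximal_off_target"),
      has_indel = any(.data$kind != "substitution"),
      anticipated_only_on_target = all(.data$product == "anticipated" &
                                         .data$region == "on_target"),
      has_unanticipated = any(.data$product != "anticipated"),
      has_unanticipated_sub = any(.data$product %in% c("opposite_strand", "other_substitution")),
      .groups = "drop"
    )
  out <- alleles |>
    dplyr::left_join(per, by = "allele_id") |>
    dplyr::mutate(
      n_mutations = dplyr::coalesce(.data$n_mutations, 0L),
      is_mutant = .data$n_mutations > 0L,
      dplyr::across(dplyr::where(is.logical), \(x) dplyr::coalesce(x, FALSE)),
      anticipated_only_on_target = .data$anticipated_only_on_target & .data$is_mutant,
      off_target_or_indel_only = (.data$has_proximal | .data$has_indel) &
        !.data$has_on_target
    )
  tibble::as_tibble(out)
}
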