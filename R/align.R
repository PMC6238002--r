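# Global affine-gap alignment of allele sequences against the locus
# reference, and conversion of alignments into a normalized mutation table.
# Alignment itself is delegated to Biostrings::pairwiseAlignment; event
# extraction and VCF-style left-normalization of indels are done here so
# that event coordinates are deterministic regardless of traceback.

#' Alignment scoring parameters
#'
#' Affine-gap scores used for global alignment. The invariant
#' `gap_open < mismatch < 0 < match` guarantees that a single base change
#' scores better as a substitution than as an adjacent insertion+deletion
#' pair, so point edits are never fragmented into indels. The cost of a
#' gap of length k is `gap_open + k * gap_extend` (both negative).
#'
#' @param match match score (positive).
#' @param mismatch mismatch score (negative).
#' @param gap_open gap opening score (negative).
#' @param gap_extend per-base gap extension score (negative).
#' @return an object of class `alignment_params`.
#' @export
alignment_params <- function(match = 2, mismatch = -2, gap_open = -8,
                             gap_extend = -1) {
  if (!(gap_open < mismatch && mismatch < 0 && 0 < match)) {
    rlang::abort("require gap_open < mismatch < 0 < match",
                 class = "be_invalid_spec")
  }
  if (!(gap_extend < 0)) {
    rlang::abort("gap_extend must be negative", class = "be_invalid_spec")
  }
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "alignment_params")
}

#' Globally align one allele against the locus reference
#'
#' Needleman-Wunsch/Gotoh global alignment with affine gap penalties over
#' the full reference window, so mutations anywhere in the proximal flanks
#' are retained. With `partial = TRUE` end gaps on the reference side are
#' free (for truncated Sanger reads); reference positions outside the
#' covered range are then recorded as uncovered rather than called as
#' terminal deletions.
#'
#' @param locus a [target_locus()].
#' @param allele_seq allele DNA string.
#' @param params an [alignment_params()].
#' @param allele_id optional label carried through to the mutation table.
#' @param partial if `TRUE`, align the allele end-gap free against the
#'   reference (partial read support).
#' @return an object of class `be_alignment` with gapped reference and
#'   allele strings, score, percent identity and covered reference range.
#'   A warning of class `be_low_identity` is raised when aligned identity
#'   falls below 80% (probable sample mix-up); the alignment is still
#'   returned.
#' @export
align_allele <- function(locus, allele_seq, params = alignment_params(),
                         allele_id = NULL, partial = FALSE) {
  stopifnot(inherits(locus, "target_locus"),
            inherits(params, "alignment_params"))
  allele_seq <- check_dna(allele_seq, "allele_seq")
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = params$match, mismatch = params$mismatch, baseOnly = TRUE
  )
  type <- if (partial) "global-local" else "global"
  pa <- Biostrings::pairwiseAlignment(
    pattern = allele_seq, subject = locus$reference_seq,
    substitutionMatrix = mat,
    gapOpening = -params$gap_open, gapExtension = -params$gap_extend,
    type = type
  )
  aligned_allele <- as.character(Biostrings::pattern(pa))
  aligned_ref <- as.character(Biostrings::subject(pa))
  covered <- c(Biostrings::start(Biostrings::subject(pa)),
               Biostrings::end(Biostrings::subject(pa)))
  if (!partial) {
    # restore terminal gap columns clipped from the aligned views, so
    # deletions/insertions at the window ends are still called
    n_ref <- nchar(locus$reference_seq); n_al <- nchar(allele_seq)
    ps <- Biostrings::start(Biostrings::pattern(pa))
    pe <- Biostrings::end(Biostrings::pattern(pa))
    aligned_ref <- paste0(
      substring(locus$reference_seq, 1L, covered[1] - 1L), strrep("-", ps - 1L),
      aligned_ref,
      substring(locus$reference_seq, covered[2] + 1L, n_ref), strrep("-", n_al - pe)
    )
    aligned_allele <- paste0(
      strrep("-", covered[1] - 1L), substring(allele_seq, 1L, ps - 1L),
      aligned_allele,
      strrep("-", n_ref - covered[2]), substring(allele_seq, pe + 1L, n_al)
    )
    covered <- c(1L, n_ref)
  }
  a <- strsplit(aligned_allele, "")[[1]]
  r <- strsplit(aligned_ref, "")[[1]]
  ncol_match <- sum(a == r & a != "-")
  identity <- ncol_match / length(a)
  out <- structure(
    list(aligned_ref = aligned_ref, aligned_allele = aligned_allele,
         score = Biostrings::score(pa), identity = identity,
         covered = as.integer(covered), allele_id = allele_id,
         locus_id = locus$locus_id, partial = partial),
    class = "be_alignment"
  )
  if (identity < 0.80) {
    rlang::warn(sprintf("aligned identity %.1f%% below 80%% for allele %s: probable sample mix-up",
                        100 * identity, allele_id %||% "<unnamed>"),
                class = "be_low_identity")
  }
  out
}

#' @export
print.be_alignment <- function(x, ...) {
  cat(sprintf("<be_alignment> %s vs %s: score %.1f, identity %.1f%%, covers %d-%d\n",
              x$allele_id %||% "<allele>", x$locus_id, x$score,
              100 * x$identity, x$covered[1], x$covered[2]))
  invisible(x)
}

# Canonicalize a gapped alignment: each gap run is re-placed at the
# left-most position that maximizes the number of matching aligned
# columns within the window bounded by the neighboring gap runs. The
# gapped/aligned column counts are unchanged, so among equal-scoring
# tracebacks this selects the 5'-most gap placement deterministically,
# independent of the aligner's traceback; substitution columns displaced
# by the move reappear on the other side of the gap.
canonicalize_alignment <- function(r, a) {
  n <- length(r)
  for (pass in 1:5) {
    changed <- FALSE
    i <- 1L
    while (i <= n) {
      is_del <- a[i] == "-" && r[i] != "-"
      is_ins <- r[i] == "-" && a[i] != "-"
      if (!is_del && !is_ins) { i <- i + 1L; next }
      j <- i
      if (is_del) {
        while (j < n && a[j + 1L] == "-" && r[j + 1L] != "-") j <- j + 1L
      } else {
        while (j < n && r[j + 1L] == "-" && a[j + 1L] != "-") j <- j + 1L
      }
      L <- j - i + 1L
      # window of aligned columns bounded by the adjacent gap runs
      b <- i - 1L
      while (b >= 1L && a[b] != "-" && r[b] != "-") b <- b - 1L
      e <- j + 1L
      while (e <= n && a[e] != "-" && r[e] != "-") e <- e + 1L
      b <- b + 1L; e <- e - 1L           # window is [b..e]
      M <- (e - b + 1L) - L              # aligned chars in the window
      if (M > 0L) {
        if (is_del) {
          long <- r[b:e]                 # M + L reference chars
          short <- a[b:e]; short <- short[short != "-"]
        } else {
          long <- a[b:e]
          short <- r[b:e]; short <- short[short != "-"]
        }
        # matches when the gap sits after short-sequence position t
        pre <- c(0L, cumsum(short == long[seq_len(M)]))
        d <- short == long[seq_len(M) + L]
        suf <- rev(c(0L, cumsum(rev(d))))
        score <- pre + suf
        t_new <- which.max(score) - 1L   # leftmost argmax
        t_cur <- i - b
        if (t_new != t_cur) {
          if (is_del) {
            a[b:e] <- append(short, rep("-", L), after = t_new)
          } else {
            r[b:e] <- append(short, rep("-", L), after = t_new)
          }
          changed <- TRUE
        }
      }
      i <- e + 1L
    }
    if (!changed) break
  }
  list(r = r, a = a)
}

# Gapped alignment implied by an event table (used to push ground-truth
# events through the same canonicalization the caller applies).
alignment_from_events <- function(ev, ref) {
  ev <- dplyr::arrange(ev, .data$ref_pos)
  n <- nchar(ref)
  rcols <- character(0); acols <- character(0)
  pos <- 1L
  emit_ref <- function(from, to) {
    if (from > to) return(invisible())
    seg <- strsplit(substring(ref, from, to), "")[[1]]
    rcols <<- c(rcols, seg); acols <<- c(acols, seg)
  }
  for (k in seq_len(nrow(ev))) {
    emit_ref(pos, ev$ref_pos[k] - 1L)
    if (ev$kind[k] == "substitution") {
      rcols <- c(rcols, ev$ref[k]); acols <- c(acols, ev$alt[k])
      pos <- ev$ref_pos[k] + 1L
    } else if (ev$kind[k] == "deletion") {
      seg <- strsplit(ev$ref[k], "")[[1]]
      rcols <- c(rcols, seg); acols <- c(acols, rep("-", length(seg)))
      pos <- ev$ref_pos[k] + length(seg)
    } else {
      seg <- strsplit(ev$alt[k], "")[[1]]
      rcols <- c(rcols, rep("-", length(seg))); acols <- c(acols, seg)
      pos <- ev$ref_pos[k]
    }
  }
  emit_ref(pos, n)
  list(r = rcols, a = acols)
}

# extract sorted events from gapped columns
events_from_columns <- function(r, a, start_pos) {
  n <- length(r)
  kind <- character(0); ref_pos <- integer(0)
  ref_al <- character(0); alt_al <- character(0)
  pos <- start_pos
  i <- 1L
  while (i <= n) {
    if (r[i] != "-" && a[i] != "-") {
      if (r[i] != a[i]) {
        kind <- c(kind, "substitution"); ref_pos <- c(ref_pos, pos)
        ref_al <- c(ref_al, r[i]); alt_al <- c(alt_al, a[i])
      }
      pos <- pos + 1L; i <- i + 1L
    } else if (a[i] == "-") {        # gap in allele: deletion of ref bases
      j <- i
      while (j <= n && a[j] == "-") j <- j + 1L
      kind <- c(kind, "deletion"); ref_pos <- c(ref_pos, pos)
      ref_al <- c(ref_al, paste0(r[i:(j - 1L)], collapse = ""))
      alt_al <- c(alt_al, "")
      pos <- pos + (j - i); i <- j
    } else {                         # gap in reference: insertion
      j <- i
      while (j <= n && r[j] == "-") j <- j + 1L
      kind <- c(kind, "insertion"); ref_pos <- c(ref_pos, pos)
      ref_al <- c(ref_al, ""); alt_al <- c(alt_al, paste0(a[i:(j - 1L)], collapse = ""))
      i <- j
    }
  }
  tibble::tibble(
    kind = kind, ref_pos = as.integer(ref_pos), ref = ref_al, alt = alt_al,
    length = dplyr::if_else(kind == "insertion", nchar(alt_al), nchar(ref_al))
  ) |> dplyr::arrange(.data$ref_pos)
}

# Rewrite an event table in the caller's canonical form: build the
# implied alignment, canonicalize its gap placements, and re-extract.
canonicalize_events <- function(ev, ref) {
  if (nrow(ev) == 0 || !any(ev$kind != "substitution")) {
    return(dplyr::arrange(ev, .data$ref_pos))
  }
  cols <- alignment_from_events(ev[c("kind", "ref_pos", "ref", "alt")], ref)
  canon <- canonicalize_alignment(cols$r, cols$a)
  events_from_columns(canon$r, canon$a, 1L)
}

#' Call mutations from an alignment
#'
#' Converts a [align_allele()] alignment into a sorted, non-overlapping
#' tibble of events. Each mismatch column becomes a length-1 substitution
#' (adjacent mismatches are never merged into multi-nucleotide variants,
#' because transitions are counted per base). Maximal gap runs become
#' single insertion/deletion events, left-normalized so that an indel in a
#' repeat is always reported at the 5'-most equivalent position. For an
#' insertion, `ref_pos` is the reference base immediately 3' of the
#' inserted sequence.
#'
#' @param alignment a `be_alignment`.
#' @param locus the [target_locus()] the alignment was computed against.
#' @return a tibble with columns `allele_id`, `kind`
#'   (substitution/insertion/deletion), `ref_pos` (1-based), `ref`, `alt`,
#'   `length`, plus attributes `covered` (reference range seen by the
#'   read).
#' @export
call_mutations <- function(alignment, locus) {
  stopifnot(inherits(alignment, "be_alignment"),
            inherits(locus, "target_locus"))
  if (!identical(alignment$locus_id, locus$locus_id)) {
    rlang::abort("alignment was produced against a different locus",
                 class = "be_mixed_locus")
  }
  canon <- canonicalize_alignment(
    strsplit(alignment$aligned_ref, "")[[1]],
    strsplit(alignment$aligned_allele, "")[[1]]
  )
  out <- events_from_columns(canon$r, canon$a, alignment$covered[1])
  out <- dplyr::mutate(out, allele_id = alignment$allele_id %||% NA_character_,
                       .before = 1)
  attr(out, "covered") <- alignment$covered
  out
}

#' Apply a mutation table to a reference sequence
#'
#' Reconstructs the allele sequence implied by a mutation table; the
#' operative round-trip contract is
#' `apply_mutations(ref, call_mutations(align_allele(locus, x))) == x`.
#' Events are applied 3' to 5' so earlier coordinates stay valid.
#'
#' @param reference_seq reference DNA string.
#' @param mutations tibble with columns `kind`, `ref_pos`, `ref`, `alt`.
#' @return the mutated sequence.
#' @export
apply_mutations <- function(reference_seq, mutations) {
  seq <- reference_seq
  if (nrow(mutations) == 0) return(seq)
  # 3' to 5'; at a shared position the insertion goes last, since its
  # junction sits 5' of the base a substitution/deletion refers to
  mutations <- dplyr::arrange(mutations, dplyr::desc(.data$ref_pos),
                              .data$kind == "insertion")
  for (k in seq_len(nrow(mutations))) {
    pos <- mutations$ref_pos[k]
    if (mutations$kind[k] == "substitution") {
      stopifnot(substring(seq, pos, pos) == mutations$ref[k])
      substring(seq, pos, pos) <- mutations$alt[k]
    } else if (mutations$kind[k] == "deletion") {
      L <- nchar(mutations$ref[k])
      stopifnot(substring(seq, pos, pos + L - 1L) == mutations$ref[k])
      seq <- paste0(substring(seq, 1L, pos - 1L), substring(seq, pos + L))
    } else {
      seq <- paste0(substring(seq, 1L, pos - 1L), mutations$alt[k],
                    substring(seq, pos))
    }
  }
  seq
}

#' Align a cohort of alleles and call all mutations
#'
#' Tidy wrapper running [align_allele()] + [call_mutations()] over a tibble
#' of alleles.
#'
#' @param alleles tibble with columns `allele_id`, `seq` (and optionally
#'   `editor_name`, carried through).
#' @param locus a [target_locus()].
#' @param params an [alignment_params()].
#' @param partial passed to [align_allele()].
#' @return tibble of called mutations across alleles (zero-mutation alleles
#'   contribute no rows).
#' @export
call_cohort <- function(alleles, locus, params = alignment_params(),
                        partial = FALSE) {
  stopifnot(is.data.frame(alleles), all(c("allele_id", "seq") %in% names(alleles)))
  purrr::map_dfr(seq_len(nrow(alleles)), function(i) {
    al <- align_allele(locus, alleles$seq[i], params,
                       allele_id = alleles$allele_id[i], partial = partial)
    call_mutations(al, locus)
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x
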