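# Target-locus model: the protospacer coordinate system every classification
# rule is written in. Positions are 1-based on the protospacer-containing
# strand; protospacer position 1 is the 5'-most protospacer base, so the PAM
# starts at protospacer_len + 1 (21 for a 20-nt SpCas9 protospacer).

IUPAC_REGEX <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]",
  B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]"
)

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Validate a DNA string
#'
#' Uppercases and checks that a sequence contains only A/C/G/T. IUPAC
#' ambiguity codes are rejected: unresolved bases would corrupt per-allele
#' event counts, so they are a hard error rather than silently skipped.
#'
#' @param seq character scalar.
#' @param what label used in the error message.
#' @return the validated, uppercased sequence.
#' @export
check_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq)) {
    rlang::abort(paste0(what, " must be a non-empty character scalar"),
                 class = "be_invalid_base")
  }
  seq <- unname(toupper(seq))
  if (grepl("[^ACGT]", seq)) {
    bad <- unique(strsplit(gsub("[ACGT]", "", seq), "")[[1]])
    rlang::abort(
      paste0(what, " contains non-ACGT characters: ", paste(bad, collapse = ", ")),
      class = "be_invalid_base"
    )
  }
  seq
}

#' Reverse-complement a DNA string
#' @param seq character scalar over A/C/G/T.
#' @return character scalar.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

complement_base <- function(base) unname(DNA_COMPLEMENT[base])

iupac_regex <- function(motif) {
  motif <- toupper(motif)
  codes <- strsplit(motif, "")[[1]]
  if (!all(codes %in% names(IUPAC_REGEX))) {
    rlang::abort(paste0("invalid IUPAC code in PAM motif: ", motif),
                 class = "be_invalid_base")
  }
  paste0(IUPAC_REGEX[codes], collapse = "")
}

#' Describe a base editor
#'
#' An editor specification fixes the chemistry (CBE deaminates cytosine,
#' C->T on the protospacer strand; ABE deaminates adenine, A->G), the
#' protospacer length, the PAM motif, and the editing window within which
#' edits count as on-target. Defaults are the SpCas9 conventions: 20-nt
#' protospacer, NGG PAM, editing window at protospacer positions 4-8.
#'
#' @param name editor label, e.g. "BE3", "BE4", "SaBE3", "VQR-BE3", "ABE".
#' @param editor_class "CBE" or "ABE".
#' @param protospacer_len protospacer length in nt (21 for SaCas9 editors).
#' @param pam_motif PAM over IUPAC codes ("NGG", "NGA", "NNGRRT").
#' @param window_start,window_end editing-window bounds in protospacer
#'   coordinates (inclusive).
#' @return an object of class `editor_spec`.
#' @examples
#' editor_spec("BE4", "CBE")
#' editor_spec("SaBE3", "CBE", protospacer_len = 21, pam_motif = "NNGRRT")
#' @export
editor_spec <- function(name, editor_class = c("CBE", "ABE"),
                        protospacer_len = 20L, pam_motif = "NGG",
                        window_start = 4L, window_end = 8L) {
  editor_class <- match.arg(editor_class)
  protospacer_len <- as.integer(protospacer_len)
  window_start <- as.integer(window_start)
  window_end <- as.integer(window_end)
  if (!(window_start >= 1L && window_start <= window_end &&
        window_end <= protospacer_len)) {
    rlang::abort("editing window must satisfy 1 <= window_start <= window_end <= protospacer_len",
                 class = "be_invalid_spec")
  }
  iupac_regex(pam_motif)  # validates the motif
  target_base <- if (editor_class == "CBE") "C" else "A"
  product_base <- if (editor_class == "CBE") "T" else "G"
  structure(
    list(
      name = name, editor_class = editor_class,
      target_base = target_base, product_base = product_base,
      protospacer_len = protospacer_len, pam_motif = toupper(pam_motif),
      pam_len = nchar(pam_motif),
      window_start = window_start, window_end = window_end
    ),
    class = "editor_spec"
  )
}

#' @export
print.editor_spec <- function(x, ...) {
  cat(sprintf("<editor_spec> %s (%s): %s->%s, %d-nt protospacer, PAM %s, window %d-%d\n",
              x$name, x$editor_class, x$target_base, x$product_base,
              x$protospacer_len, x$pam_motif, x$window_start, x$window_end))
  invisible(x)
}

#' Construct a target locus
#'
#' Represents the reference window around one protospacer. The reference
#' must cover the full proximal window (`proximal_radius` bp, default 200)
#' on both sides of the protospacer so that every proximal off-target
#' position is classifiable.
#'
#' @param reference_seq reference DNA covering the protospacer and flanks.
#' @param protospacer_start 1-based position of the protospacer's 5'-most
#'   base within `reference_seq`.
#' @param protospacer_len protospacer length in nt.
#' @param pam_len PAM length in nt (3 for NGG/NGA, 6 for NNGRRT).
#' @param locus_id text label.
#' @param proximal_radius radius in bp of the proximal off-target zone.
#' @param protospacer_seq optional declared protospacer; checked against the
#'   reference substring when supplied.
#' @return an object of class `target_locus`.
#' @seealso [build_locus()] to locate the protospacer automatically.
#' @export
target_locus <- function(reference_seq, protospacer_start, protospacer_len,
                         pam_len = 3L, locus_id = "locus",
                         proximal_radius = 200L, protospacer_seq = NULL) {
  reference_seq <- check_dna(reference_seq, "reference_seq")
  protospacer_start <- as.integer(protospacer_start)
  protospacer_len <- as.integer(protospacer_len)
  proximal_radius <- as.integer(proximal_radius)
  n <- nchar(reference_seq)
  if (protospacer_start <= proximal_radius ||
      protospacer_start + protospacer_len - 1L + proximal_radius > n) {
    rlang::abort(
      sprintf(paste0("reference must cover %d bp on both sides of the ",
                     "protospacer (have %d upstream, %d downstream)"),
              proximal_radius, protospacer_start - 1L,
              n - (protospacer_start + protospacer_len - 1L)),
      class = "be_flank_too_short"
    )
  }
  found <- substr(reference_seq, protospacer_start,
                  protospacer_start + protospacer_len - 1L)
  if (!is.null(protospacer_seq)) {
    protospacer_seq <- check_dna(protospacer_seq, "protospacer_seq")
    if (!identical(found, protospacer_seq)) {
      rlang::abort("declared protospacer does not match the reference substring",
                   class = "be_invalid_spec")
    }
  }
  structure(
    list(
      locus_id = locus_id, reference_seq = reference_seq,
      protospacer_start = protospacer_start,
      protospacer_len = protospacer_len,
      protospacer_seq = found,
      pam_len = as.integer(pam_len),
      proximal_radius = proximal_radius
    ),
    class = "target_locus"
  )
}

#' @export
print.target_locus <- function(x, ...) {
  cat(sprintf("<target_locus> %s: %d bp reference, protospacer %d-%d (%s), proximal radius %d bp\n",
              x$locus_id, nchar(x$reference_seq), x$protospacer_start,
              x$protospacer_start + x$protospacer_len - 1L,
              x$protospacer_seq, x$proximal_radius))
  invisible(x)
}

#' Locate a protospacer on a reference and build the locus
#'
#' Finds the unique occurrence of `protospacer_seq` immediately 5' of a PAM
#' matching the editor's motif, and returns the corresponding
#' [target_locus()]. Loci whose protospacer lies on the genomic minus strand
#' should be reverse-complemented before ingestion: all downstream rules
#' operate on the protospacer-containing strand.
#'
#' @param reference_seq reference DNA string.
#' @param protospacer_seq protospacer sequence (length = editor protospacer_len).
#' @param editor an [editor_spec()].
#' @inheritParams target_locus
#' @return a `target_locus`.
#' @export
build_locus <- function(reference_seq, protospacer_seq, editor,
                        locus_id = "locus", proximal_radius = 200L) {
  stopifnot(inherits(editor, "editor_spec"))
  reference_seq <- check_dna(reference_seq, "reference_seq")
  protospacer_seq <- check_dna(protospacer_seq, "protospacer_seq")
  if (nchar(protospacer_seq) != editor$protospacer_len) {
    rlang::abort(sprintf("protospacer_seq must have length %d for editor %s",
                         editor$protospacer_len, editor$name),
                 class = "be_invalid_spec")
  }
  pat <- paste0(protospacer_seq, iupac_regex(editor$pam_motif))
  hits <- gregexpr(pat, reference_seq)[[1]]
  hits <- hits[hits > 0L]
  if (length(hits) == 0L) {
    rlang::abort("protospacer with matching PAM not found on the reference",
                 class = "be_not_found")
  }
  if (length(hits) > 1L) {
    rlang::abort(sprintf("protospacer with matching PAM occurs %d times on the reference",
                         length(hits)),
                 class = "be_ambiguous")
  }
  target_locus(reference_seq, protospacer_start = hits,
               protospacer_len = editor$protospacer_len,
               pam_len = editor$pam_len, locus_id = locus_id,
               proximal_radius = proximal_radius,
               protospacer_seq = protospacer_seq)
}

#' Convert reference positions to protospacer coordinates
#'
#' Protospacer coordinates count 1 at the protospacer's 5'-most base, so the
#' PAM starts at `protospacer_len + 1` (position 21 for a 20-nt protospacer);
#' positions 5' of the protospacer are 0, -1, -2, ...
#'
#' @param locus a [target_locus()].
#' @param ref_pos integer vector of 1-based reference positions.
#' @return integer vector of protospacer positions.
#' @seealso [ref_position()] for the inverse transform.
#' @export
protospacer_position <- function(locus, ref_pos) {
  stopifnot(inherits(locus, "target_locus"))
  ref_pos <- as.integer(ref_pos)
  if (any(ref_pos < 1L | ref_pos > nchar(locus$reference_seq), na.rm = TRUE)) {
    rlang::abort("ref_pos outside the reference", class = "be_out_of_window")
  }
  ref_pos - locus$protospacer_start + 1L
}

#' Convert protospacer coordinates back to reference positions
#' @param locus a [target_locus()].
#' @param ps_pos integer vector of protospacer positions.
#' @return integer vector of 1-based reference positions.
#' @export
ref_position <- function(locus, ps_pos) {
  stopifnot(inherits(locus, "target_locus"))
  out <- as.integer(ps_pos) + locus$protospacer_start - 1L
  if (any(out < 1L | out > nchar(locus$reference_seq), na.rm = TRUE)) {
    rlang::abort("protospacer position outside the reference",
                 class = "be_out_of_window")
  }
  out
}

#' @rdname protospacer_position
#' @param pos alias of `ref_pos` used by the tidy verbs.
#' @keywords internal
ps_pos_of <- function(locus, pos) pos - locus$protospacer_start + 1L

ref_base_at <- function(locus, ref_pos) {
  substring(locus$reference_seq, ref_pos, ref_pos)
}
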