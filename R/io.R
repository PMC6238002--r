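# File interfaces: FASTA via Biostrings, TSV sample sheets via readr,
# YAML editor configs.

#' Read a FASTA file into a tibble
#'
#' @param path FASTA file; one record per sequence.
#' @return tibble with columns `id`, `seq` (uppercased, validated DNA).
#' @export
read_fasta <- function(path) {
  xs <- Biostrings::readDNAStringSet(path)
  out <- tibble::tibble(id = names(xs), seq = unname(toupper(as.character(xs))))
  purrr::walk2(out$seq, out$id, \(s, i) check_dna(s, paste0("record ", i)))
  out
}

#' Write sequences to a FASTA file
#'
#' @param x tibble with an id column and a `seq` column.
#' @param path output path.
#' @param id_col name of the id column (default `allele_id`, falling back
#'   to `id`).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, id_col = NULL) {
  id_col <- id_col %||% intersect(c("allele_id", "id"), names(x))[1]
  stopifnot(!is.na(id_col), "seq" %in% names(x))
  xs <- Biostrings::DNAStringSet(x$seq)
  names(xs) <- x[[id_col]]
  Biostrings::writeXStringSet(xs, path)
  invisible(path)
}

#' Read a sample sheet
#'
#' Tab-separated, one row per allele, columns `allele_id`, `editor_name`,
#' `locus_id` (and optionally `cohort`).
#'
#' @param path TSV path.
#' @return tibble.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(path, show_col_types = FALSE,
                           progress = FALSE, comment = "#")
  need <- c("allele_id", "editor_name", "locus_id")
  if (!all(need %in% names(sheet))) {
    rlang::abort(paste0("sample sheet needs columns: ",
                        paste(need, collapse = ", ")),
                 class = "be_invalid_spec")
  }
  sheet
}

#' Read an editor configuration file
#'
#' YAML with a top-level `editors:` list; each entry has keys `name`,
#' `class` (CBE/ABE), `protospacer` (the guide-matched sequence), `pam`
#' (IUPAC motif) and optionally `window_start`, `window_end`.
#'
#' @param path YAML path.
#' @return named list (by editor name) of lists with elements `editor`
#'   (an [editor_spec()]) and `protospacer`.
#' @export
read_editor_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  entries <- cfg$editors %||% cfg
  out <- purrr::map(entries, function(e) {
    need <- c("name", "class", "protospacer", "pam")
    if (!all(need %in% names(e))) {
      rlang::abort(paste0("editor config entries need keys: ",
                          paste(need, collapse = ", ")),
                   class = "be_invalid_spec")
    }
    proto <- check_dna(e$protospacer, paste0("protospacer of ", e$name))
    list(
      editor = editor_spec(
        e$name, toupper(e$class), protospacer_len = nchar(proto),
        pam_motif = e$pam,
        window_start = e$window_start %||% 4L,
        window_end = e$window_end %||% 8L
      ),
      protospacer = proto
    )
  })
  names(out) <- purrr::map_chr(out, \(x) x$editor$name)
  out
}
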