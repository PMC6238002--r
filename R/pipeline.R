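# End-to-end pipeline: align + call + classify one cohort, then summarize.

#' Align, call and classify a cohort held in memory
#'
#' Stage function chaining [call_cohort()], [classify_mutations()] and
#' [classify_alleles()] for one locus/editor.
#'
#' @param alleles tibble with `allele_id`, `seq` and metadata columns.
#' @param locus a [target_locus()].
#' @param editor an [editor_spec()].
#' @param params an [alignment_params()].
#' @return list with `mutations` (classified mutation tibble) and
#'   `alleles` (allele-level flags from [classify_alleles()]).
#' @export
classify_cohort <- function(alleles, locus, editor,
                            params = alignment_params()) {
  muts <- call_cohort(alleles, locus, params)
  cls <- classify_mutations(muts, locus, editor)
  flags <- classify_alleles(cls, dplyr::select(alleles, -"seq"))
  list(mutations = cls, alleles = flags)
}

#' Run the full pipeline from files
#'
#' Reads a reference FASTA (records named by locus id), an allele
#' multi-FASTA (record ids matching the sample sheet), a TSV sample sheet
#' (`allele_id`, `editor_name`, `locus_id`) and a YAML editor config;
#' aligns and classifies every allele against its locus; and writes the
#' per-mutation table, per-allele flags, cohort summary, comparison
#' statistics and sequence-context summary to `out_dir`. Re-running with
#' identical inputs produces identical outputs.
#'
#' @param reference_fa path to the reference FASTA.
#' @param alleles_fa path to the allele FASTA.
#' @param sample_sheet path to the sample-sheet TSV.
#' @param editor_config path to the editor YAML.
#' @param out_dir output directory (created if missing).
#' @param params an [alignment_params()].
#' @param proximal_radius proximal off-target radius in bp.
#' @param alpha,effect_size_w,m_comparisons statistics options passed to
#'   [compare_editors()].
#' @param abe_editors editor names forming the ABE arm of the comparison.
#' @return list with `mutations`, `alleles`, `summary`, `context`,
#'   `comparison` (NULL when only one editor class is present), invisibly.
#' @export
run_pipeline <- function(reference_fa, alleles_fa, sample_sheet,
                         editor_config, out_dir,
                         params = alignment_params(),
                         proximal_radius = 200L,
                         alpha = 0.05, effect_size_w = 0.15,
                         m_comparisons = 4L, abe_editors = "ABE") {
  for (f in c(reference_fa, alleles_fa, sample_sheet, editor_config)) {
    if (!file.exists(f)) {
      rlang::abort(paste0("input file not found: ", f), class = "be_not_found")
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  refs <- read_fasta(reference_fa)
  alleles <- read_fasta(alleles_fa)
  if (nrow(alleles) == 0) {
    rlang::abort("allele FASTA contains no records", class = "be_empty_cohort")
  }
  sheet <- read_sample_sheet(sample_sheet)
  editors <- read_editor_config(editor_config)

  missing <- setdiff(alleles$id, sheet$allele_id)
  if (length(missing) > 0) {
    rlang::abort(paste0("alleles absent from sample sheet: ",
                        paste(utils::head(missing, 5), collapse = ", ")),
                 class = "be_invalid_spec")
  }
  dat <- dplyr::inner_join(alleles, sheet, by = c(id = "allele_id")) |>
    dplyr::rename(allele_id = "id")

  groups <- dplyr::group_split(dat, .data$locus_id, .data$editor_name)
  res <- purrr::map(groups, function(g) {
    lid <- g$locus_id[1]; en <- g$editor_name[1]
    if (!en %in% names(editors)) {
      rlang::abort(paste0("editor not in config: ", en), class = "be_not_found")
    }
    if (!lid %in% refs$id) {
      rlang::abort(paste0("locus not in reference FASTA: ", lid),
                   class = "be_not_found")
    }
    ed <- editors[[en]]
    locus <- build_locus(refs$seq[refs$id == lid], ed$protospacer, ed$editor,
                         locus_id = lid, proximal_radius = proximal_radius)
    classify_cohort(g, locus, ed$editor, params)
  })
  mutations <- purrr::map_dfr(res, "mutations")
  allele_flags <- purrr::map_dfr(res, "alleles")

  summary <- summarize_cohort(allele_flags)
  context <- tc_fraction(mutations)
  classes <- purrr::map_chr(editors[unique(dat$editor_name)],
                            \(x) x$editor$editor_class)
  comparison <- if (length(unique(classes)) == 2) {
    compare_editors(allele_flags,
                    abe_editors = intersect(abe_editors, names(classes)),
                    m = m_comparisons, effect_size_w = effect_size_w,
                    alpha = alpha)
  } else NULL

  readr::write_tsv(mutations, file.path(out_dir, "mutations.tsv"))
  readr::write_tsv(allele_flags, file.path(out_dir, "allele_flags.tsv"))
  readr::write_tsv(summary, file.path(out_dir, "cohort_summary.tsv"))
  jsonlite::write_json(summary, file.path(out_dir, "cohort_summary.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  jsonlite::write_json(as.list(context), file.path(out_dir, "context.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  if (!is.null(comparison)) {
    stats <- list(per_category = tidy(comparison),
                  overall = glance(comparison))
    jsonlite::write_json(stats, file.path(out_dir, "stats.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }
  log_lines <- c(
    paste0("beoutcome version: ", as.character(utils::packageVersion("beoutcome"))),
    paste0("alignment: match=", params$match, " mismatch=", params$mismatch,
           " gap_open=", params$gap_open, " gap_extend=", params$gap_extend),
    paste0("proximal_radius=", proximal_radius, " alpha=", alpha,
           " effect_size_w=", effect_size_w, " m=", m_comparisons),
    paste0("alleles=", nrow(alleles), " editors=",
           paste(sort(unique(dat$editor_name)), collapse = ","))
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(list(mutations = mutations, alleles = allele_flags,
                 summary = summary, context = context,
                 comparison = comparison))
}

#' Write a fixture or simulated cohort to pipeline input files
#'
#' Emits the allele FASTA, reference FASTA, sample sheet and editor config
#' for a `be_fixture` so the file-level pipeline can be run on it.
#'
#' @param fixture a `be_fixture` from [make_printed_fixture()] /
#'   [make_tc_fixture()].
#' @param dir output directory.
#' @return named list of the written paths.
#' @export
write_fixture_inputs <- function(fixture, dir) {
  stopifnot(inherits(fixture, "be_fixture"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    reference_fa = file.path(dir, "reference.fa"),
    alleles_fa = file.path(dir, "alleles.fa"),
    sample_sheet = file.path(dir, "samples.tsv"),
    editor_config = file.path(dir, "editors.yaml")
  )
  write_fasta(tibble::tibble(id = fixture$locus$locus_id,
                             seq = fixture$locus$reference_seq),
              paths$reference_fa)
  write_fasta(fixture$alleles, paths$alleles_fa)
  readr::write_tsv(fixture$sample_sheet, paths$sample_sheet)
  ed <- fixture$editor
  yaml::write_yaml(list(editors = list(list(
    name = ed$name, class = ed$editor_class,
    protospacer = fixture$locus$protospacer_seq, pam = ed$pam_motif,
    window_start = ed$window_start, window_end = ed$window_end
  ))), paths$editor_config)
  paths
}
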