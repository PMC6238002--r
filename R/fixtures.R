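# Deterministic fixture cohorts. Each fixture is a concrete reference
# locus plus concrete allele sequences constructed so that running the
# full pipeline (align -> call -> classify -> summarize) reproduces the
# published per-editor category counts. Event positions are placed outside
# homopolymer runs so alignment and left-normalization are unambiguous;
# this is asserted at construction.

FIXTURE_EDITORS <- c("HF2-BE2", "BE3", "SaBE3", "VQR-BE3", "BE4", "ABE")

# fixed linear congruential generator so fixture flanks are byte-stable
# and independent of R's RNG state
lcg_bases <- function(n, seed) {
  x <- as.numeric(seed)
  out <- character(n)
  for (i in seq_len(n)) {
    x <- (69069 * x + 1) %% 2147483648
    out[i] <- c("A", "C", "G", "T")[(x %/% 1048576) %% 4 + 1]
  }
  out
}

#' Editor presets used by the fixture cohorts
#'
#' @param editor_name one of `"HF2-BE2"`, `"BE3"`, `"SaBE3"`, `"VQR-BE3"`,
#'   `"BE4"`, `"ABE"`.
#' @return an [editor_spec()].
#' @export
preset_editor <- function(editor_name) {
  switch(editor_name,
    "HF2-BE2" = editor_spec("HF2-BE2", "CBE"),
    "BE3" = editor_spec("BE3", "CBE"),
    "BE4" = editor_spec("BE4", "CBE"),
    "VQR-BE3" = editor_spec("VQR-BE3", "CBE", pam_motif = "NGA"),
    "SaBE3" = editor_spec("SaBE3", "CBE", protospacer_len = 21L,
                          pam_motif = "NNGRRT"),
    "ABE" = editor_spec("ABE", "ABE"),
    rlang::abort(paste0("no preset editor named ", editor_name),
                 class = "be_not_found")
  )
}

# flank edit-site offsets; negative = bp 5' of the protospacer start,
# positive = bp 3' of the protospacer end
FIXTURE_SITE_OFFSETS <- list(
  c_tc    = c(-40L, -80L, -120L, 40L, 80L, 120L),  # C preceded by T
  c_nontc = c(-50L, -90L, -130L, 50L, 90L, 130L),  # C preceded by A
  g_tc    = c(-60L, 60L),                          # G followed by A (opposite-strand TC)
  g_nontc = c(-70L, 70L),                          # G followed by C
  del     = 25L                                    # 3-bp flank deletion start
)

fixture_protospacer <- function(editor) {
  if (editor$editor_class == "ABE") {
    "GCATACGTAACTGCTGACTG"          # A at 3/5/9/10, C at 6
  } else if (editor$protospacer_len == 21L) {
    "AGTCCCATGCATGACTAGTAC"         # C at 4/5/6/10, G at 9
  } else {
    "AGTCCCATGCATGACTAGTA"
  }
}

fixture_pam <- function(editor) {
  switch(editor$pam_motif,
    NGG = "AGG", NGA = "AGA", NNGRRT = "ATGAGT",
    rlang::abort(paste0("no fixture PAM for motif ", editor$pam_motif),
                 class = "be_not_found")
  )
}

#' Deterministic reference locus for a fixture cohort
#'
#' 200-bp flanks around the editor's preset protospacer+PAM, with cytosine
#' and guanine edit sites of defined 5'-TC-3' context imposed at fixed
#' flank offsets, and indel sites whose flanking bases forbid any
#' alternative gap placement.
#'
#' @param editor an [editor_spec()].
#' @param locus_id locus label.
#' @return a [target_locus()].
#' @export
fixture_locus <- function(editor, locus_id = paste0(editor$name, "_site")) {
  radius <- 200L
  proto <- fixture_protospacer(editor)
  pam <- fixture_pam(editor)
  refv <- c(lcg_bases(radius, seed = 7), strsplit(proto, "")[[1]],
            strsplit(pam, "")[[1]], lcg_bases(radius, seed = 19))
  ps_start <- radius + 1L
  ps_end <- ps_start + editor$protospacer_len - 1L
  at <- function(off) if (off < 0L) ps_start + off else ps_end + off
  for (off in FIXTURE_SITE_OFFSETS$c_tc) {
    refv[at(off)] <- "C"; refv[at(off) - 1L] <- "T"
  }
  for (off in FIXTURE_SITE_OFFSETS$c_nontc) {
    refv[at(off)] <- "C"; refv[at(off) - 1L] <- "A"
  }
  for (off in FIXTURE_SITE_OFFSETS$g_tc) {
    refv[at(off)] <- "G"; refv[at(off) + 1L] <- "A"
  }
  for (off in FIXTURE_SITE_OFFSETS$g_nontc) {
    refv[at(off)] <- "G"; refv[at(off) + 1L] <- "C"
  }
  fd <- at(FIXTURE_SITE_OFFSETS$del)
  refv[(fd - 1L):(fd + 3L)] <- c("A", "C", "G", "T", "A")
  # deletion sites must not be left- or right-shiftable
  stopifnot(refv[fd - 1L] != refv[fd + 2L], refv[fd] != refv[fd + 3L])
  wd <- ps_start + 5L  # window deletion of protospacer positions 6-8
  stopifnot(refv[wd - 1L] != refv[wd + 2L], refv[wd] != refv[wd + 3L])
  target_locus(paste0(refv, collapse = ""), protospacer_start = ps_start,
               protospacer_len = editor$protospacer_len,
               pam_len = editor$pam_len, locus_id = locus_id,
               proximal_radius = radius)
}

fixture_site_positions <- function(locus) {
  ps_start <- locus$protospacer_start
  ps_end <- ps_start + locus$protospacer_len - 1L
  at <- function(off) ifelse(off < 0L, ps_start + off, ps_end + off)
  lapply(FIXTURE_SITE_OFFSETS, at)
}

# default bystander / opposite-strand positions per editor class
fixture_default_pos <- function(editor) {
  if (editor$editor_class == "ABE") {
    list(by = 9L, by_opp = 4L, on = 5L, on_other_alt = "C", on_c = 6L)
  } else {
    list(by = 10L, by_opp = 9L, on = 4L, on_other_alt = "G", on_c = NA)
  }
}

# Turn a vector of event tokens into a concrete mutation table for one
# allele. Tokens: on_ant, on_other, by_ant[@p], by_opp, on_c_other,
# prox_ant_tc, prox_ant_nontc, prox_opp_tc, prox_opp_nontc, prox_gt,
# del_window, del_flank. Repeated flank tokens within one allele draw
# successive sites from the pool.
realize_tokens <- function(tokens, locus, editor) {
  sitepos <- fixture_site_positions(locus)
  defaults <- fixture_default_pos(editor)
  tb <- editor$target_base; pb <- editor$product_base
  ctb <- complement_base(tb); cpb <- complement_base(pb)
  # target-base positions inside the window, consumed in order by
  # on_ant/on_other tokens
  wp <- ref_position(locus, editor$window_start:editor$window_end)
  wtp <- wp[substring(locus$reference_seq, wp, wp) == tb]
  cursor <- new.env(parent = emptyenv())
  nxt <- function(class, pool) {
    k <- (cursor[[class]] %||% 0L) + 1L
    if (k > length(pool)) {
      rlang::abort(paste0("fixture site pool exhausted for ", class),
                   class = "be_infeasible_spec")
    }
    assign(class, k, envir = cursor)
    pool[k]
  }
  sub_row <- function(pos, ref, alt) {
    stopifnot(ref_base_at(locus, pos) == ref)
    tibble::tibble(kind = "substitution", ref_pos = pos, ref = ref, alt = alt,
                   length = 1L)
  }
  del_row <- function(pos, len) {
    tibble::tibble(kind = "deletion", ref_pos = pos,
                   ref = substring(locus$reference_seq, pos, pos + len - 1L),
                   alt = "", length = len)
  }
  rows <- purrr::map(tokens, function(tok) {
    base_tok <- sub("@.*$", "", tok)
    arg <- if (grepl("@", tok)) as.integer(sub("^.*@", "", tok)) else NA_integer_
    switch(base_tok,
      on_ant = sub_row(nxt("window", wtp), tb, pb),
      on_other = sub_row(nxt("window", wtp), tb, defaults$on_other_alt),
      by_ant = sub_row(ref_position(locus, arg %|NA|% defaults$by), tb, pb),
      by_opp = sub_row(ref_position(locus, arg %|NA|% defaults$by_opp), ctb, cpb),
      on_c_other = sub_row(ref_position(locus, defaults$on_c), "C", "T"),
      prox_ant_tc = sub_row(nxt("c_tc", sitepos$c_tc), "C", "T"),
      prox_ant_nontc = sub_row(nxt("c_nontc", sitepos$c_nontc), "C", "T"),
      prox_opp_tc = sub_row(nxt("g_tc", sitepos$g_tc), "G", "A"),
      prox_opp_nontc = sub_row(nxt("g_nontc", sitepos$g_nontc), "G", "A"),
      prox_gt = sub_row(nxt("g_nontc", sitepos$g_nontc), "G", "T"),
      del_window = del_row(ref_position(locus, 6L), 3L),
      del_flank = del_row(sitepos$del, 3L),
      rlang::abort(paste0("unknown fixture token ", tok),
                   class = "be_invalid_spec")
    )
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$ref_pos)
}

`%|NA|%` <- function(x, y) if (is.na(x)) y else x

rep_bp <- function(n, tokens) rep(list(tokens), n)

# Allele blueprints reproducing the published per-editor counts. Each
# element is one mutant allele's event-token vector.
fixture_blueprint <- function(editor_name) {
  switch(editor_name,
    "HF2-BE2" = c(
      rep_bp(17, "on_ant"),
      rep_bp(7, "by_ant"),
      rep_bp(4, "prox_ant_tc"), rep_bp(4, "prox_ant_nontc"),
      rep_bp(5, c("on_ant", "prox_ant_tc")),
      rep_bp(4, c("on_ant", "prox_ant_nontc")),
      rep_bp(2, c("on_ant", "del_window")),
      rep_bp(4, c("on_ant", "on_other"))
    ),
    "BE3" = c(
      rep_bp(54, "on_ant"),
      rep_bp(8, "by_ant"),
      rep_bp(6, "del_flank"),
      rep_bp(5, c("on_ant", "del_window")),
      rep_bp(18, c("on_ant", "on_other"))
    ),
    "SaBE3" = c(
      rep_bp(10, "on_ant"),
      rep_bp(11, "by_ant"),
      rep_bp(2, "by_opp"),
      rep_bp(1, c("prox_ant_tc", "del_flank")),
      rep_bp(1, c("on_ant", "prox_ant_tc")),
      rep_bp(9, c("on_ant", "del_window"))
    ),
    "VQR-BE3" = c(
      rep_bp(17, "on_ant"),
      rep_bp(3, c("prox_opp_tc", "prox_ant_tc")),
      rep_bp(1, "prox_gt"),
      rep_bp(1, c("on_ant", "prox_ant_nontc", "prox_opp_nontc")),
      rep_bp(1, "del_window")
    ),
    "BE4" = c(
      rep_bp(17, "on_ant"),
      rep_bp(4, c("on_ant", "by_ant")),
      rep_bp(1, c("prox_ant_tc", "del_flank")),
      rep_bp(2, c("on_ant", "on_other", "del_window")),
      rep_bp(2, c("on_ant", "del_window")),
      rep_bp(1, c("on_ant", "on_other"))
    ),
    "ABE" = c(
      rep_bp(6, "on_ant"), rep_bp(2, c("on_ant", "by_ant@9")),
      rep_bp(29, "on_ant"), rep_bp(5, c("on_ant", "by_ant@3")),
      rep_bp(5, c("on_ant", "by_ant@10")),
      rep_bp(110, "on_ant"), rep_bp(27, c("on_ant", "by_ant@3")),
      rep_bp(27, c("on_ant", "by_ant@9")),
      rep_bp(3, c("on_ant", "by_ant@3", "on_c_other"))
    ),
    rlang::abort(paste0("no fixture preset for editor ", editor_name),
                 class = "be_not_found")
  )
}

# sub-cohort labels for the pooled ABE fixture (this-study zygotes plus
# the two re-analyzed published cohorts)
fixture_cohorts <- function(editor_name, n) {
  if (editor_name == "ABE") {
    rep(c("thisstudy", "tyr", "arhoxd13"), times = c(8L, 39L, 167L))
  } else {
    rep("thisstudy", n)
  }
}

#' Published per-editor category counts
#'
#' The mutant-allele denominators and category counts reported per editor,
#' used as the construction targets of the preset fixtures.
#'
#' @return tibble with one row per editor.
#' @export
printed_counts <- function() {
  tibble::tribble(
    ~editor_name, ~n_mutant, ~on_target, ~bystander, ~proximal, ~indel, ~anticipated_only, ~unanticipated_sub,
    "HF2-BE2",    47L,  32L,  7L, 17L,  2L, 17L, NA_integer_,
    "BE3",        91L,  77L,  8L,  0L, 11L, 54L, NA_integer_,
    "SaBE3",      34L,  20L, 13L,  2L, 10L, 10L, 2L,
    "VQR-BE3",    23L,  19L,  0L,  5L,  1L, 17L, 5L,
    "BE4",        27L,  26L,  4L,  1L,  5L, 17L, 3L,
    "ABE",       214L, 214L, 69L,  0L,  0L, 145L, 3L
  )
}

blueprint_from_counts <- function(counts_spec) {
  cs <- as.list(counts_spec)
  need <- c("n_mutant", "on_target", "bystander", "proximal", "indel",
            "anticipated_only")
  if (!all(need %in% names(cs))) {
    rlang::abort(paste0("counts_spec needs fields: ", paste(need, collapse = ", ")),
                 class = "be_invalid_spec")
  }
  n <- cs$n_mutant; on <- cs$on_target; by <- cs$bystander
  px <- cs$proximal; ind <- cs$indel; ao <- cs$anticipated_only
  u <- cs$unanticipated_sub %||% NA_integer_
  vals <- c(n, on, by, px, ind, ao)
  if (any(vals < 0) || any(vals[-1] > n)) {
    rlang::abort("counts must be non-negative and at most n_mutant",
                 class = "be_infeasible_spec")
  }
  if (ao > on) {
    rlang::abort("anticipated_only cannot exceed on_target",
                 class = "be_infeasible_spec")
  }
  non_on <- n - on
  if (by + px + ind < non_on) {
    rlang::abort("not enough bystander/proximal/indel alleles to cover alleles without on-target edits",
                 class = "be_infeasible_spec")
  }
  # cover alleles without on-target edits
  b1 <- min(by, non_on)
  p1 <- min(px, non_on - b1)
  d1 <- min(ind, non_on - b1 - p1)
  bp <- c(rep_bp(ao, "on_ant"),
          rep_bp(b1, "by_ant"),
          lapply(seq_len(p1), function(i)
            if (i %% 2L) "prox_ant_tc" else "prox_ant_nontc"),
          rep_bp(d1, "del_flank"))
  # remaining category slots break the purity of impure on-target alleles
  b2 <- by - b1; p2 <- px - p1; d2 <- ind - d1
  impure <- on - ao
  if (b2 + p2 + d2 > impure) {
    rlang::abort("more bystander/proximal/indel alleles requested than on-target alleles can absorb",
                 class = "be_infeasible_spec")
  }
  bp <- c(bp,
          rep_bp(b2, c("on_ant", "by_ant")),
          lapply(seq_len(p2), function(i)
            c("on_ant", if (i %% 2L) "prox_ant_tc" else "prox_ant_nontc")),
          rep_bp(d2, c("on_ant", "del_window")),
          rep_bp(impure - b2 - p2 - d2, c("on_ant", "on_other")))
  if (!is.na(u)) {
    have <- impure - b2 - p2 - d2  # alleles already carrying on_other
    if (u < have) {
      rlang::abort("unanticipated_sub too small for the remaining purity-breaking substitutions",
                   class = "be_infeasible_spec")
    }
    extra <- u - have
    # convert proximal anticipated events to opposite-strand events, which
    # keeps every location flag but adds an unanticipated substitution
    conv <- which(purrr::map_lgl(bp, \(x) any(grepl("^prox_ant", x))))
    if (extra > length(conv)) {
      rlang::abort("unanticipated_sub too large for this category layout",
                   class = "be_infeasible_spec")
    }
    for (i in utils::head(conv, extra)) {
      bp[[i]] <- sub("^prox_ant_tc$", "prox_opp_tc",
                     sub("^prox_ant_nontc$", "prox_opp_nontc", bp[[i]]))
    }
  }
  stopifnot(length(bp) == n)
  bp
}

#' Build a fixture cohort reproducing published category counts
#'
#' Constructs concrete allele sequences for one editor such that the full
#' pipeline yields exactly the requested per-category allele counts. With
#' `counts_spec = NULL` the preset blueprint for the named editor (the
#' published counts, see [printed_counts()]) is used; a custom
#' `counts_spec` (fields `n_mutant`, `on_target`, `bystander`, `proximal`,
#' `indel`, `anticipated_only`, optionally `unanticipated_sub`) is
#' allocated automatically, raising an `be_infeasible_spec` error when the
#' combination is logically inconsistent (e.g. more anticipated-only than
#' on-target alleles).
#'
#' @param editor_name an editor preset name (see [preset_editor()]).
#' @param counts_spec optional named list/row of category counts.
#' @return list of class `be_fixture` with `editor`, `locus`, `alleles`
#'   (tibble `allele_id`, `editor_name`, `cohort`, `seq`) and
#'   `sample_sheet`.
#' @export
make_printed_fixture <- function(editor_name, counts_spec = NULL) {
  editor <- preset_editor(editor_name)
  locus <- fixture_locus(editor)
  bp <- if (is.null(counts_spec)) fixture_blueprint(editor_name)
        else blueprint_from_counts(counts_spec)
  cohorts <- if (is.null(counts_spec)) fixture_cohorts(editor_name, length(bp))
             else rep("custom", length(bp))
  alleles <- purrr::map_dfr(seq_along(bp), function(i) {
    muts <- realize_tokens(bp[[i]], locus, editor)
    tibble::tibble(
      allele_id = sprintf("%s/a%03d", editor_name, i),
      editor_name = editor_name, cohort = cohorts[i],
      seq = apply_mutations(locus$reference_seq, muts)
    )
  })
  structure(
    list(editor = editor, locus = locus, alleles = alleles,
         sample_sheet = dplyr::mutate(
           dplyr::select(alleles, "allele_id", "editor_name", "cohort"),
           locus_id = locus$locus_id),
         blueprint = bp),
    class = "be_fixture"
  )
}

#' Sequence-context fixture for the 5'-TC-3' statistic
#'
#' A CBE cohort whose proximal off-target cytosine mutations number 68
#' across both strands, 44 of them at a C preceded by T: 11 alleles carry
#' four TC-context events each (three protospacer-strand C>T, one
#' opposite-strand G>A), 6 alleles carry four non-TC events each.
#'
#' @return a `be_fixture` (see [make_printed_fixture()]).
#' @export
make_tc_fixture <- function() {
  editor <- preset_editor("BE3")
  locus <- fixture_locus(editor, locus_id = "tc_site")
  bp <- c(
    rep_bp(11, c("prox_ant_tc", "prox_ant_tc", "prox_ant_tc", "prox_opp_tc")),
    rep_bp(6, c("prox_ant_nontc", "prox_ant_nontc", "prox_ant_nontc",
                "prox_opp_nontc"))
  )
  alleles <- purrr::map_dfr(seq_along(bp), function(i) {
    muts <- realize_tokens(bp[[i]], locus, editor)
    tibble::tibble(
      allele_id = sprintf("TC/a%03d", i), editor_name = "BE3",
      cohort = "tc", seq = apply_mutations(locus$reference_seq, muts)
    )
  })
  structure(
    list(editor = editor, locus = locus, alleles = alleles,
         sample_sheet = dplyr::mutate(
           dplyr::select(alleles, "allele_id", "editor_name", "cohort"),
           locus_id = locus$locus_id),
         blueprint = bp),
    class = "be_fixture"
  )
}

#' @export
print.be_fixture <- function(x, ...) {
  cat(sprintf("<be_fixture> %s: %d alleles on %s (%d bp)\n",
              x$editor$name, nrow(x$alleles), x$locus$locus_id,
              nchar(x$locus$reference_seq)))
  invisible(x)
}
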