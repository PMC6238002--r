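mk_mut <- function(kind, ref_pos, ref, alt, allele_id = "a1") {
  tibble::tibble(allele_id = allele_id, kind = kind,
                 ref_pos = as.integer(ref_pos), ref = ref, alt = alt,
                 length = ifelse(kind == "insertion", nchar(alt), nchar(ref)))
}

test_that("substitution regions follow the window/protospacer/200bp rules", {
  ed <- preset_editor("BE3")
  loc <- fixture_locus(ed)
  at_ps <- function(p) ref_position(loc, p)
  expect_equal(classify_region(at_ps(5), "substitution", 1L, loc, ed),
               "on_target")
  expect_equal(classify_region(at_ps(9), "substitution", 1L, loc, ed),
               "bystander")
  expect_equal(classify_region(at_ps(21), "substitution", 1L, loc, ed),
               "proximal_off_target")  # PAM is outside the protospacer
  expect_equal(classify_region(at_ps(-49), "substitution", 1L, loc, ed),
               "proximal_off_target")  # 50 bp upstream
  expect_equal(classify_region(at_ps(-199), "substitution", 1L, loc, ed),
               "proximal_off_target")

  # with a tighter radius, positions beyond it fall out of range
  loc150 <- target_locus(loc$reference_seq, loc$protospacer_start,
                         loc$protospacer_len, pam_len = loc$pam_len,
                         proximal_radius = 150L)
  at2 <- function(p) ref_position(loc150, p)
  expect_equal(classify_region(at2(-149), "substitution", 1L, loc150, ed),
               "proximal_off_target")
  expect_equal(classify_region(at2(-150), "substitution", 1L, loc150, ed),
               "out_of_range")
  expect_equal(classify_region(at2(170), "substitution", 1L, loc150, ed),
               "proximal_off_target")  # 150 bp downstream of the protospacer
  expect_equal(classify_region(at2(171), "substitution", 1L, loc150, ed),
               "out_of_range")
})

test_that("ABE bystander edit at position 9 is adjacent to the window", {
  ed <- preset_editor("ABE")
  loc <- fixture_locus(ed)
  cls <- classify_mutations(mk_mut("substitution", ref_position(loc, 9), "A", "G"),
                            loc, ed)
  expect_equal(cls$region, "bystander")
  expect_equal(cls$product, "anticipated")
})

test_that("indels take the highest-priority region they overlap", {
  ed <- preset_editor("BE3")
  loc <- fixture_locus(ed)
  del_at <- function(p, len) {
    rp <- ref_position(loc, p)
    mk_mut("deletion", rp, substring(loc$reference_seq, rp, rp + len - 1), "")
  }
  expect_equal(classify_region(ref_position(loc, 6), "deletion", 5L, loc, ed),
               "on_target")    # spans window positions
  expect_equal(classify_region(ref_position(loc, 9), "deletion", 3L, loc, ed),
               "bystander")
  expect_equal(classify_region(ref_position(loc, 25), "deletion", 3L, loc, ed),
               "proximal_off_target")
  # deletion starting upstream and ending inside the window
  expect_equal(classify_region(ref_position(loc, -2), "deletion", 8L, loc, ed),
               "on_target")
  cls <- classify_mutations(del_at(6, 5), loc, ed)
  expect_true(cls$overlaps_window)
  expect_equal(cls$product, "indel")
})

test_that("product purity follows the editor chemistry on both strands", {
  cbe <- preset_editor("BE3")
  abe <- preset_editor("ABE")
  p <- classify_product(rep("substitution", 4), c("C", "G", "G", "A"),
                        c("T", "A", "T", "G"), cbe)
  expect_equal(p$product, c("anticipated", "opposite_strand",
                            "other_substitution", "other_substitution"))
  expect_equal(p$edited_strand[1:3],
               c("protospacer_strand", "opposite_strand", "opposite_strand"))
  # G>T under CBE could arise from an opposite-strand C>A transversion
  expect_true(p$possible_opposite_edit[3])
  expect_false(any(p$possible_opposite_edit[c(1, 2, 4)]))

  pa <- classify_product(rep("substitution", 3), c("A", "T", "C"),
                         c("G", "C", "T"), abe)
  expect_equal(pa$product, c("anticipated", "opposite_strand",
                             "other_substitution"))
  pd <- classify_product("deletion", "ACG", "", cbe)
  expect_equal(pd$product, "indel")
  expect_equal(pd$edited_strand, "not_applicable")
})

test_that("every substitution gets exactly one region and counts partition", {
  ed <- preset_editor("BE3")
  loc <- fixture_locus(ed)
  withr::with_seed(21, {
    pos <- sample(nchar(loc$reference_seq), 300, replace = TRUE)
  })
  regs <- classify_region(pos, rep("substitution", 300), rep(1L, 300), loc, ed)
  expect_true(all(regs %in% c("on_target", "bystander", "proximal_off_target",
                              "out_of_range")))
  expect_equal(sum(table(regs)), 300)
})

test_that("allele flags implement purity and multi-membership definitions", {
  ed <- preset_editor("BE3")
  loc <- fixture_locus(ed)
  at_ps <- function(p) ref_position(loc, p)
  alleles <- tibble::tibble(allele_id = c("pure", "mixed", "delonly", "wt"),
                            editor_name = "BE3")
  muts <- dplyr::bind_rows(
    mk_mut("substitution", at_ps(5), "C", "T", "pure"),
    mk_mut("substitution", at_ps(4), "C", "T", "mixed"),
    mk_mut("substitution", at_ps(-40), "C", "T", "mixed"),   # proximal, anticipated-type
    mk_mut("deletion", at_ps(6), substring(loc$reference_seq, at_ps(6), at_ps(6) + 4), "", "delonly")
  )
  flags <- classify_alleles(classify_mutations(muts, loc, ed), alleles)
  flags <- tibble::column_to_rownames(as.data.frame(flags), "allele_id")

  expect_true(flags["pure", "anticipated_only_on_target"])
  expect_false(flags["pure", "has_unanticipated"])

  # an anticipated-type proximal edit breaks purity-of-location but is not
  # an unanticipated product
  expect_false(flags["mixed", "anticipated_only_on_target"])
  expect_false(flags["mixed", "has_unanticipated"])
  expect_true(flags["mixed", "has_proximal"])

  # window-overlapping deletion: indel + on-target, so not off-target-only
  expect_true(flags["delonly", "has_indel"])
  expect_true(flags["delonly", "has_on_target"])
  expect_false(flags["delonly", "off_target_or_indel_only"])
  expect_true(flags["delonly", "has_unanticipated"])
  expect_false(flags["delonly", "has_unanticipated_sub"])

  # zero-mutation allele is a wild-type sentinel, not a mutant
  expect_false(flags["wt", "is_mutant"])
  expect_false(flags["wt", "anticipated_only_on_target"])
})

test_that("pure A-to-G window cohorts are 100% anticipated-only", {
  ed <- preset_editor("ABE")
  loc <- fixture_locus(ed)
  prof <- sim_profile(ed, p_on_target = 1, p_bystander = 0, p_proximal = 0,
                      purity = c(anticipated = 1, opposite_strand = 0,
                                 other_substitution = 0),
                      p_deletion = 0)
  sim <- simulate_cohort(loc, prof, 40, seed = 3)
  flags <- classify_cohort(sim$alleles, loc, ed)$alleles
  expect_true(all(flags$is_mutant))
  expect_true(all(flags$anticipated_only_on_target))
  s <- summarize_cohort(flags)
  expect_equal(s$percent[s$category == "anticipated_only_on_target"], 100L)
})
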