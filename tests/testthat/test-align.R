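test_that("alignment_params enforces score ordering", {
  p <- alignment_params()
  expect_lt(p$gap_open, p$mismatch)
  expect_error(alignment_params(gap_open = -1), class = "be_invalid_spec")
  expect_error(alignment_params(gap_extend = 1), class = "be_invalid_spec")
})

test_that("identity alignment has maximal score and no events", {
  loc <- small_locus()
  al <- align_allele(loc, loc$reference_seq)
  expect_equal(al$score, 2 * nchar(loc$reference_seq))
  expect_equal(al$identity, 1)
  expect_equal(nrow(call_mutations(al, loc)), 0L)
})

test_that("worked 8-mer and gapped examples match the brute-force oracle", {
  # single mismatch: one substitution column, no gaps
  al <- suppressWarnings(align_allele(pair_locus("ACGTACGT"), "ACGAACGT"))
  expect_equal(al$score, oracle_align_score("ACGAACGT", "ACGTACGT"))
  expect_equal(al$score, 7 * 2 - 2)
  ev <- call_mutations(al, pair_locus("ACGTACGT"))
  expect_equal(ev$kind, "substitution")
  expect_equal(ev$ref_pos, 4L)
  expect_equal(c(ev$ref, ev$alt), c("T", "A"))

  # 3-bp deletion in a TTT run, left-most placement
  loc <- pair_locus("ACGTTTACGT")
  al2 <- suppressWarnings(align_allele(loc, "ACGACGT"))
  expect_equal(al2$score, oracle_align_score("ACGACGT", "ACGTTTACGT"))
  ev2 <- call_mutations(al2, loc)
  expect_equal(ev2$kind, "deletion")
  expect_equal(ev2$ref_pos, 4L)  # 5'-most equivalent placement
  expect_equal(ev2$ref, "TTT")
})

test_that("scores equal the oracle on exhaustive short and random 2-letter pairs", {
  # exhaustive over {A,C} up to length 3 x 3
  strs <- unlist(lapply(1:3, function(L) {
    apply(expand.grid(rep(list(c("A", "C")), L)), 1, paste0, collapse = "")
  }))
  for (s1 in strs) {
    for (s2 in strs) {
      al <- suppressWarnings(align_allele(pair_locus(s2), s1))
      expect_equal(al$score, oracle_align_score(s1, s2),
                   label = paste(s1, "vs", s2))
    }
  }
  # random longer pairs up to length 12
  withr::with_seed(4, {
    for (k in 1:60) {
      s1 <- random_dna(sample(4:12, 1), c("A", "C"))
      s2 <- random_dna(sample(4:12, 1), c("A", "C"))
      al <- suppressWarnings(align_allele(pair_locus(s2), s1))
      expect_equal(al$score, oracle_align_score(s1, s2),
                   label = paste(s1, "vs", s2))
    }
  })
})

test_that("homopolymer deletions are reported at the 5'-most placement", {
  # deleting any T of the TTTT run is equivalent; the caller must always
  # report the run's first position
  ref <- "ACGTTTTACG"
  loc <- pair_locus(ref)
  for (drop_at in 4:7) {
    allele <- paste0(substring(ref, 1, drop_at - 1), substring(ref, drop_at + 1))
    ev <- call_mutations(suppressWarnings(align_allele(loc, allele)), loc)
    expect_equal(ev$kind, "deletion")
    expect_equal(ev$ref_pos, 4L, label = paste("drop at", drop_at))
  }
})

test_that("called mutations round-trip random mutated alleles exactly", {
  loc <- small_locus()
  withr::with_seed(99, {
    for (k in 1:150) {
      allele <- mutate_random(loc$reference_seq,
                              n_sub = sample(0:4, 1),
                              n_del = sample(0:1, 1),
                              n_ins = sample(0:1, 1))
      ev <- call_mutations(suppressWarnings(align_allele(loc, allele)), loc)
      expect_equal(apply_mutations(loc$reference_seq, ev), allele)
      base_ev <- ev[ev$kind != "insertion", ]
      if (nrow(base_ev) > 1) {
        # base-consuming events are sorted and non-overlapping
        ends <- base_ev$ref_pos +
          ifelse(base_ev$kind == "deletion", base_ev$length - 1L, 0L)
        expect_true(all(utils::head(ends, -1) < utils::tail(base_ev$ref_pos, -1)))
      }
      ins <- ev[ev$kind == "insertion", ]
      if (nrow(ins) > 0 && any(ev$kind == "deletion")) {
        # an insertion junction never falls inside a deleted segment
        del <- ev[ev$kind == "deletion", ]
        for (ip in ins$ref_pos) {
          expect_false(any(ip > del$ref_pos & ip <= del$ref_pos + del$length - 1L))
        }
      }
    }
  })
})

test_that("calling is deterministic and independent of cohort order", {
  loc <- small_locus()
  withr::with_seed(5, {
    alleles <- tibble::tibble(
      allele_id = sprintf("a%02d", 1:12),
      seq = replicate(12, mutate_random(loc$reference_seq, 2, 1, 0))
    )
  })
  m1 <- call_cohort(alleles, loc)
  m2 <- call_cohort(alleles[sample(12), ], loc)
  expect_equal(dplyr::arrange(m1, allele_id, ref_pos),
               dplyr::arrange(m2, allele_id, ref_pos))
  # idempotence: re-calling the reconstructed alleles gives the same table
  m3 <- call_cohort(alleles, loc)
  expect_identical(m1, m3)
})

test_that("low identity triggers a warning, invalid bases an error", {
  loc <- small_locus()
  expect_warning(align_allele(loc, random_dna(30)), class = "be_low_identity")
  expect_error(align_allele(loc, "ACGTN"), class = "be_invalid_base")
})

test_that("partial reads get free end gaps instead of terminal deletions", {
  loc <- small_locus()
  inner <- substring(loc$reference_seq, 21, nchar(loc$reference_seq) - 25)
  al <- align_allele(loc, inner, partial = TRUE)
  expect_equal(al$covered, c(21L, nchar(loc$reference_seq) - 25L))
  ev <- call_mutations(al, loc)
  expect_equal(nrow(ev), 0L)  # no spurious terminal deletions
})
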