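test_that("percentages round half away from zero like the published figures", {
  expect_equal(round_half_away(100 * 54 / 91), 59L)
  expect_equal(round_half_away(100 * 4 / 27), 15L)
  expect_equal(round_half_away(100 * 5 / 23), 22L)
  expect_equal(round_half_away(c(0.5, 1.5, 2.5, -0.5)), c(1L, 2L, 3L, -1L))
})

test_that("summarize_cohort computes multi-membership counts per mutant allele", {
  flags <- tibble::tibble(
    allele_id = c("a", "b", "c"), editor_name = "E",
    n_mutations = c(1L, 2L, 0L), is_mutant = c(TRUE, TRUE, FALSE),
    has_on_target = c(TRUE, TRUE, FALSE), has_bystander = c(FALSE, TRUE, FALSE),
    has_proximal = FALSE, has_indel = c(FALSE, TRUE, FALSE),
    anticipated_only_on_target = c(TRUE, FALSE, FALSE),
    has_unanticipated = c(FALSE, TRUE, FALSE),
    has_unanticipated_sub = FALSE,
    off_target_or_indel_only = FALSE
  )
  s <- summarize_cohort(flags)
  expect_equal(unique(s$n_mutant_alleles), 2L)  # wild-type excluded
  get <- function(cat) s$count[s$category == cat]
  expect_equal(get("on_target"), 2L)
  expect_equal(get("indel"), 1L)
  expect_equal(get("anticipated_only_on_target"), 1L)
  expect_equal(s$percent[s$category == "on_target"], 100L)
  # category counts can exceed n via multi-membership, never per category
  expect_true(all(s$count <= s$n_mutant_alleles))

  wt_only <- dplyr::mutate(flags, is_mutant = FALSE)
  expect_error(summarize_cohort(wt_only), class = "be_empty_cohort")
})

test_that("single anticipated on-target allele yields 100/0 percentages", {
  ed <- preset_editor("BE3")
  loc <- fixture_locus(ed)
  allele <- loc$reference_seq
  pos <- ref_position(loc, 5)
  substring(allele, pos, pos) <- "T"
  res <- classify_cohort(
    tibble::tibble(allele_id = "one", editor_name = "BE3", seq = allele),
    loc, ed)
  s <- summarize_cohort(res$alleles)
  expect_equal(s$percent[s$category == "on_target"], 100L)
  expect_equal(s$percent[s$category == "anticipated_only_on_target"], 100L)
  expect_true(all(s$percent[!s$category %in%
                              c("on_target", "anticipated_only_on_target")] == 0L))
})

test_that("Pearson chi-squared matches hand computation and properties", {
  same <- rbind(c(10, 20, 5), c(10, 20, 5))
  ht <- chi_squared_compare(same)
  expect_equal(ht$statistic, 0)
  expect_equal(ht$p_value, 1)

  ht2 <- chi_squared_compare(rbind(c(10, 0), c(0, 10)))
  expect_equal(ht2$statistic, 20)
  expect_equal(ht2$df, 1L)

  # homogeneity: scaling all counts by k scales the statistic by k
  tab <- rbind(c(12, 7, 3, 9), c(5, 11, 8, 2))
  expect_equal(chi_squared_compare(tab * 3)$statistic,
               3 * chi_squared_compare(tab)$statistic)

  expect_error(chi_squared_compare(rbind(c(0, 0), c(1, 2))),
               class = "be_degenerate_table")
  expect_error(chi_squared_compare(rbind(c(-1, 2), c(1, 2))),
               class = "be_invalid_spec")
})

test_that("chi-squared p-values agree with a multinomial resampling oracle", {
  tab <- rbind(c(40, 25, 18, 30), c(28, 35, 22, 19))
  ht <- chi_squared_compare(tab)
  n <- sum(tab)
  p0 <- outer(rowSums(tab), colSums(tab)) / n^2
  withr::with_seed(17, {
    reps <- 20000
    draws <- stats::rmultinom(reps, n, as.vector(p0))
    stat1 <- vapply(seq_len(reps), function(i) {
      m <- matrix(draws[, i], 2)
      suppressWarnings(stats::chisq.test(m, correct = FALSE)$statistic)
    }, numeric(1))
  })
  p_mc <- mean(stat1 >= ht$statistic)
  se <- sqrt(p_mc * (1 - p_mc) / 20000)
  expect_lt(abs(p_mc - ht$p_value), 3 * se + 1e-12)
})

test_that("bonferroni adjustment caps at one and allows m beyond length", {
  expect_equal(bonferroni_adjust(c(0.01, 0.2), m = 4), c(0.04, 0.8))
  expect_equal(bonferroni_adjust(0.5, m = 4), 1)
  expect_equal(bonferroni_adjust(numeric(0)), numeric(0))
  expect_equal(bonferroni_adjust(c(0.02, 0.03)), c(0.04, 0.06))
  expect_error(bonferroni_adjust(c(0.5, 1.2)), class = "be_invalid_p")
  expect_error(bonferroni_adjust(c(0.1, 0.2), m = 1), class = "be_invalid_spec")
})

test_that("noncentral chi-squared power is alpha at w = 0 and monotone", {
  expect_identical(chisq_power(0, 0.05, 436, 3), 0.05)
  expect_identical(chisq_power(0, 0.01, 100, 1), 0.01)
  grid_n <- c(50, 100, 200, 436, 1000)
  pw_n <- vapply(grid_n, \(n) chisq_power(0.15, 0.05, n, 3), numeric(1))
  expect_true(all(diff(pw_n) > 0))
  grid_w <- c(0.05, 0.1, 0.15, 0.3, 0.5)
  pw_w <- vapply(grid_w, \(w) chisq_power(w, 0.05, 436, 3), numeric(1))
  expect_true(all(diff(pw_w) > 0))
  expect_true(all(pw_n > 0 & pw_n < 1))
})

test_that("compare_editors builds per-category 2x2 tables with Bonferroni m=4", {
  fxs <- lapply(c("BE3", "ABE"), make_printed_fixture)
  flags <- dplyr::bind_rows(lapply(fxs, function(fx) {
    classify_cohort(fx$alleles, fx$locus, fx$editor)$alleles
  }))
  cmp <- compare_editors(flags)
  td <- tidy(cmp)
  expect_equal(nrow(td), 4L)
  expect_equal(td$abe_count[td$category == "on_target"], 214L)
  expect_equal(td$cbe_count[td$category == "indel"], 11L)
  ok <- !is.na(td$p_value)
  expect_equal(td$p_adjusted[ok], pmin(1, td$p_value[ok] * 4))
  # proximal is zero in both arms here: no signal, NA rather than a test
  expect_true(is.na(td$p_value[td$category == "proximal_off_target"]))
  gl <- glance(cmp)
  expect_equal(gl$n_total, 91L + 214L)
  expect_equal(gl$power, chisq_power(0.15, 0.05, 305, 3))
  expect_error(compare_editors(dplyr::filter(flags, editor_name == "BE3")),
               class = "be_empty_cohort")
})
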