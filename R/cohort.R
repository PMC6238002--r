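# Cohort-level summaries and the editor-class comparison. Percentages use
# the total number of mutant alleles per editor as denominator; categories
# are multi-membership (one allele can carry several kinds of mutation), so
# category counts may sum to more than the number of alleles.

CATEGORIES <- c("on_target", "bystander", "proximal_off_target", "indel",
                "unanticipated_any", "unanticipated_sub",
                "anticipated_only_on_target", "off_target_or_indel_only")

FLAG_OF_CATEGORY <- c(
  on_target = "has_on_target", bystander = "has_bystander",
  proximal_off_target = "has_proximal", indel = "has_indel",
  unanticipated_any = "has_unanticipated",
  unanticipated_sub = "has_unanticipated_sub",
  anticipated_only_on_target = "anticipated_only_on_target",
  off_target_or_indel_only = "off_target_or_indel_only"
)

#' Round half away from zero
#'
#' The rounding used for printed percentages (59.34 -> 59, 14.81 -> 15,
#' 21.74 -> 22), as opposed to R's banker's rounding.
#'
#' @param x numeric vector.
#' @return integer vector.
#' @export
round_half_away <- function(x) as.integer(sign(x) * floor(abs(x) + 0.5))

#' Summarise allele classifications per editor
#'
#' Counts, per editor, the mutant alleles in each outcome category and the
#' corresponding percentage of all mutant alleles (integer, rounded half
#' away from zero). Wild-type alleles (`is_mutant = FALSE`) are excluded
#' from all denominators.
#'
#' @param allele_flags tibble from [classify_alleles()] with an
#'   `editor_name` column.
#' @return object of class `be_cohort_summary`: a tibble with one row per
#'   editor x category (`editor_name`, `n_mutant_alleles`, `category`,
#'   `count`, `percent`).
#' @export
summarize_cohort <- function(allele_flags) {
  stopifnot(is.data.frame(allele_flags),
            "editor_name" %in% names(allele_flags))
  mut <- dplyr::filter(allele_flags, .data$is_mutant)
  empty <- setdiff(unique(allele_flags$editor_name), unique(mut$editor_name))
  if (length(empty) > 0) {
    rlang::abort(paste0("editor(s) with zero mutant alleles: ",
                        paste(empty, collapse = ", ")),
                 class = "be_empty_cohort")
  }
  out <- mut |>
    dplyr::group_by(.data$editor_name) |>
    dplyr::summarise(
      n_mutant_alleles = dplyr::n(),
      dplyr::across(dplyr::all_of(unname(FLAG_OF_CATEGORY)), sum),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(dplyr::all_of(unname(FLAG_OF_CATEGORY)),
                        names_to = "flag", values_to = "count") |>
    dplyr::mutate(
      category = names(FLAG_OF_CATEGORY)[match(.data$flag, FLAG_OF_CATEGORY)],
      percent = round_half_away(100 * .data$count / .data$n_mutant_alleles)
    ) |>
    dplyr::select("editor_name", "n_mutant_alleles", "category", "count", "percent")
  class(out) <- c("be_cohort_summary", class(out))
  out
}

#' Pearson chi-squared test on a contingency table
#'
#' Pearson statistic without continuity correction, with
#' df = (rows-1)(cols-1) and the upper-tail p-value.
#'
#' @param counts matrix of non-negative integer counts (e.g. 2 x k,
#'   editors x categories).
#' @return object of class `be_chisq` (fields `statistic`, `df`,
#'   `p_value`, `observed`, `expected`).
#' @export
chi_squared_compare <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    rlang::abort("counts must be non-negative integers", class = "be_invalid_spec")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    rlang::abort("degenerate table: a margin is all zero", class = "be_degenerate_table")
  }
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  structure(
    list(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = unname(ht$p.value), observed = counts,
         expected = ht$expected),
    class = "be_chisq"
  )
}

#' @export
print.be_chisq <- function(x, ...) {
  cat(sprintf("<be_chisq> X-squared = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Bonferroni adjustment
#'
#' `adjusted_i = min(1, p_i * m)`; `m` may exceed the number of p-values
#' supplied (four planned category comparisons of which fewer were run).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param m number of comparisons (default `length(p)`).
#' @return adjusted p-values, order-preserving.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    rlang::abort("p-values must lie in [0, 1]", class = "be_invalid_p")
  }
  if (m < length(p)) {
    rlang::abort("m must be at least length(p)", class = "be_invalid_spec")
  }
  pmin(1, p * m)
}

#' Power of the chi-squared test at effect size w
#'
#' Cohen's w effect-size convention: the test statistic under the
#' alternative is noncentral chi-squared with noncentrality
#' `lambda = n * w^2`; power is the mass above the central
#' `(1 - alpha)` quantile. At `w = 0` power equals `alpha` exactly.
#'
#' @param effect_size_w Cohen's w (>= 0).
#' @param alpha significance level.
#' @param n total sample size.
#' @param df degrees of freedom.
#' @return power in `(0, 1)`.
#' @export
chisq_power <- function(effect_size_w, alpha = 0.05, n, df) {
  stopifnot(effect_size_w >= 0, alpha > 0, alpha < 1, n >= 1, df >= 1)
  if (effect_size_w == 0) return(alpha)  # central case, exact by definition
  crit <- stats::qchisq(1 - alpha, df = df)
  stats::pchisq(crit, df = df, ncp = n * effect_size_w^2, lower.tail = FALSE)
}

#' Compare ABE against pooled CBE editors
#'
#' Builds, for each of the four planned outcome categories (on-target,
#' bystander, proximal off-target, indel), the 2 x 2 table of mutant
#' alleles in/not in the category for ABE versus all CBE editors pooled,
#' tests each with [chi_squared_compare()] and applies a Bonferroni
#' correction over `m` comparisons. Because the categories are
#' multi-membership, per-category 2 x 2 tables are used rather than one
#' omnibus table that would double-count alleles; the omnibus Pearson test
#' on the 2 x k category-count table is also reported for reference.
#' A power analysis of the omnibus comparison at effect size
#' `effect_size_w` is attached.
#'
#' @param allele_flags tibble from [classify_alleles()] with `editor_name`.
#' @param abe_editors editor names making up the ABE arm.
#' @param categories outcome categories to compare.
#' @param m number of comparisons for the Bonferroni correction.
#' @param effect_size_w Cohen's w for the power analysis.
#' @param alpha significance level.
#' @return object of class `be_comparison`; see [tidy.be_comparison()] and
#'   [glance.be_comparison()].
#' @export
compare_editors <- function(allele_flags, abe_editors = "ABE",
                            categories = c("on_target", "bystander",
                                           "proximal_off_target", "indel"),
                            m = length(categories),
                            effect_size_w = 0.15, alpha = 0.05) {
  stopifnot(is.data.frame(allele_flags), "editor_name" %in% names(allele_flags))
  mut <- dplyr::filter(allele_flags, .data$is_mutant) |>
    dplyr::mutate(arm = dplyr::if_else(.data$editor_name %in% abe_editors,
                                       "ABE", "CBE"))
  if (length(unique(mut$arm)) < 2) {
    rlang::abort("both an ABE arm and a CBE arm are required",
                 class = "be_empty_cohort")
  }
  n_by_arm <- table(mut$arm)

  per_cat <- purrr::map(categories, function(cat) {
    flag <- FLAG_OF_CATEGORY[[cat]]
    tab <- rbind(
      ABE = c(sum(mut[[flag]][mut$arm == "ABE"]),
              sum(!mut[[flag]][mut$arm == "ABE"])),
      CBE = c(sum(mut[[flag]][mut$arm == "CBE"]),
              sum(!mut[[flag]][mut$arm == "CBE"]))
    )
    colnames(tab) <- c("in_category", "not_in_category")
    # a category absent (or universal) in both arms carries no signal
    if (any(colSums(tab) == 0)) {
      list(category = cat, table = tab, statistic = NA_real_, df = NA_integer_,
           p_value = NA_real_)
    } else {
      ht <- chi_squared_compare(tab)
      list(category = cat, table = tab, statistic = ht$statistic,
           df = ht$df, p_value = ht$p_value)
    }
  })
  p_raw <- purrr::map_dbl(per_cat, "p_value")
  ok <- !is.na(p_raw)
  p_adj <- rep(NA_real_, length(p_raw))
  p_adj[ok] <- bonferroni_adjust(p_raw[ok], m = max(m, sum(ok)))

  count_tab <- rbind(
    ABE = purrr::map_int(categories, \(cat) sum(mut[[FLAG_OF_CATEGORY[[cat]]]][mut$arm == "ABE"])),
    CBE = purrr::map_int(categories, \(cat) sum(mut[[FLAG_OF_CATEGORY[[cat]]]][mut$arm == "CBE"]))
  )
  colnames(count_tab) <- categories
  omnibus <- if (all(colSums(count_tab) > 0)) chi_squared_compare(count_tab) else NULL

  n_total <- nrow(mut)
  df_power <- length(categories) - 1L
  structure(
    list(
      per_category = per_cat, p_adjusted = p_adj, m = max(m, sum(ok)),
      omnibus = omnibus, counts = count_tab,
      n_total = n_total, n_by_arm = n_by_arm,
      power = chisq_power(effect_size_w, alpha, n_total, df_power),
      effect_size_w = effect_size_w, alpha = alpha, power_df = df_power
    ),
    class = "be_comparison"
  )
}

#' @export
print.be_comparison <- function(x, ...) {
  cat(sprintf("<be_comparison> ABE (n=%d) vs CBE (n=%d) over %d categories\n",
              x$n_by_arm[["ABE"]], x$n_by_arm[["CBE"]],
              length(x$per_category)))
  print(tidy(x))
  cat(sprintf("power = %.3f at w = %.2f, alpha = %.2f, df = %d, n = %d\n",
              x$power, x$effect_size_w, x$alpha, x$power_df, x$n_total))
  invisible(x)
}

#' Tidy an editor comparison
#'
#' @param x a `be_comparison`.
#' @param ... unused.
#' @return tibble with one row per category: counts per arm, chi-squared
#'   statistic, raw and Bonferroni-adjusted p-values.
#' @exportS3Method generics::tidy
#' @export
tidy.be_comparison <- function(x, ...) {
  tibble::tibble(
    category = purrr::map_chr(x$per_category, "category"),
    abe_count = purrr::map_int(x$per_category, \(pc) as.integer(pc$table["ABE", 1])),
    cbe_count = purrr::map_int(x$per_category, \(pc) as.integer(pc$table["CBE", 1])),
    statistic = purrr::map_dbl(x$per_category, "statistic"),
    df = purrr::map_int(x$per_category, \(pc) as.integer(pc$df)),
    p_value = purrr::map_dbl(x$per_category, "p_value"),
    p_adjusted = x$p_adjusted
  )
}

#' One-row summary of an editor comparison
#'
#' @param x a `be_comparison`.
#' @param ... unused.
#' @return one-row tibble with omnibus statistic, n per arm, and power.
#' @exportS3Method generics::glance
#' @export
glance.be_comparison <- function(x, ...) {
  tibble::tibble(
    n_abe = as.integer(x$n_by_arm[["ABE"]]),
    n_cbe = as.integer(x$n_by_arm[["CBE"]]),
    n_total = x$n_total,
    omnibus_statistic = if (is.null(x$omnibus)) NA_real_ else x$omnibus$statistic,
    omnibus_df = if (is.null(x$omnibus)) NA_integer_ else x$omnibus$df,
    omnibus_p = if (is.null(x$omnibus)) NA_real_ else x$omnibus$p_value,
    effect_size_w = x$effect_size_w, alpha = x$alpha,
    power_df = x$power_df, power = x$power
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
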