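# Cohort-level figures.

#' Bar chart of per-editor outcome frequencies
#'
#' Frequency of mutant alleles in each outcome category, per editor, with
#' the editor's mutant-allele total as 100%.
#'
#' @param summary a `be_cohort_summary` from [summarize_cohort()].
#' @param categories categories to show (default the four location/indel
#'   panels).
#' @return a ggplot object.
#' @export
plot_cohort_frequencies <- function(summary,
                                    categories = c("on_target", "bystander",
                                                   "proximal_off_target",
                                                   "indel")) {
  stopifnot(is.data.frame(summary))
  dat <- dplyr::filter(summary, .data$category %in% categories) |>
    dplyr::mutate(category = factor(.data$category, levels = categories))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$editor_name,
                                    y = .data$percent,
                                    fill = .data$category)) +
    ggplot2::geom_col(position = ggplot2::position_dodge2(preserve = "single")) +
    ggplot2::facet_wrap(ggplot2::vars(.data$category), nrow = 1) +
    ggplot2::labs(x = NULL, y = "% of mutant alleles", fill = NULL) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname plot_cohort_frequencies
#' @param object a `be_cohort_summary`.
#' @param ... passed to [plot_cohort_frequencies()].
#' @importFrom ggplot2 autoplot
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.be_cohort_summary <- function(object, ...) {
  plot_cohort_frequencies(object, ...)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
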