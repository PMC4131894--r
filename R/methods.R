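#' @importFrom ggplot2 autoplot ggplot aes geom_col labs facet_wrap
#'   scale_x_continuous theme_minimal position_dodge
NULL

#' @export
ggplot2::autoplot

#' Length-distribution bar chart of a read library
#'
#' @param object A `mulmir_library`.
#' @param ... Unused.
#' @return A ggplot: fraction of total clean reads per read length.
#' @export
autoplot.mulmir_library <- function(object, ...) {
  d <- length_distribution(object)
  ggplot(d, aes(x = .data$length, y = .data$frac)) +
    geom_col(fill = "steelblue") +
    scale_x_continuous(breaks = d$length) +
    labs(x = "read length (nt)", y = "fraction of clean reads",
         title = paste0("Read length distribution (",
                        library_label(object), ")")) +
    theme_minimal()
}

#' Per-category annotation bar chart
#'
#' @param object A `mulmir_annotation`.
#' @param ... Unused.
#' @return A ggplot of total reads per category.
#' @export
autoplot.mulmir_annotation <- function(object, ...) {
  d <- tidy(object)
  d$category <- factor(d$category, levels = rev(.CASCADE))
  ggplot(d, aes(x = .data$total_reads, y = .data$category)) +
    geom_col(fill = "darkorange") +
    labs(x = "total reads", y = NULL,
         title = paste0("Annotation categories (", attr(object, "label"),
                        ")")) +
    theme_minimal()
}

#' RPM bar chart of an expression matrix
#'
#' @param object A `mulmir_expression`.
#' @param ... Unused.
#' @return A ggplot: RPM per unit, grouped by tissue.
#' @export
autoplot.mulmir_expression <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$unit, y = .data$rpm, fill = .data$tissue)) +
    geom_col(position = position_dodge()) +
    labs(x = NULL, y = "reads per million (RPM)",
         title = "Normalised expression by tissue") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Relative-quantification bar chart of 2^-ddCt results
#'
#' @param object A `mulmir_ddct`.
#' @param ... Unused.
#' @return A ggplot: RQ per sample.
#' @export
autoplot.mulmir_ddct <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$sample, y = .data$rq)) +
    geom_col(fill = "forestgreen") +
    labs(x = NULL, y = expression(2^{-Delta * Delta * Ct}),
         title = paste0("Relative expression of ", object$assay[1],
                        " (calibrator: ", object$calibrator[1], ")")) +
    theme_minimal()
}

#' One-row summary of a ddct result
#'
#' @param x A `mulmir_ddct`.
#' @param ... Unused.
#' @return One-row tibble: assay, calibrator, fold-change range.
#' @export
glance.mulmir_ddct <- function(x, ...) {
  tibble(assay = x$assay[1], calibrator = x$calibrator[1],
         n_samples = nrow(x), rq_min = min(x$rq), rq_max = max(x$rq))
}

#' Bias-call summary counts
#'
#' @param x A `mulmir_bias`.
#' @param ... Unused.
#' @return One row per label with the number of units.
#' @export
tidy.mulmir_bias <- function(x, ...) {
  as_tibble(x) %>%
    group_by(.data$label) %>%
    summarise(n = dplyr::n(), units = paste(.data$unit, collapse = ","),
              .groups = "drop")
}

#' One-row summary of a novel catalog
#'
#' @param x A `mulmir_novel_catalog`.
#' @param ... Unused.
#' @return One-row tibble: entries, loci, star-supported entries.
#' @export
glance.mulmir_novel_catalog <- function(x, ...) {
  tibble(n_novel = nrow(x), n_loci = sum(x$n_loci),
         n_star_observed = sum(x$star_observed))
}
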