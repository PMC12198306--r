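#' Bar chart of control-normalized isoform expression
#'
#' One bar per species and isoform class at height log10(count / Actb
#' count); species without a detectable isoform simply lack that bar (zero
#' counts have no finite log ratio and are omitted).
#'
#' @param expression Long expression tibble ([isoform_expression()] output
#'   with `species_id`), or a `cassette_run` (its presence table is
#'   reshaped).
#' @return A ggplot object.
#' @export
plot_expression_bars <- function(expression) {
  if (inherits(expression, "cassette_run")) {
    expression <- tidyr::pivot_longer(
      expression$presence,
      cols = c("log10_ratio_L", "log10_ratio_S"),
      names_to = "isoform_class", names_prefix = "log10_ratio_",
      values_to = "log10_ratio")
  }
  df <- expression[!is.na(expression$log10_ratio), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$species_id,
                                   y = .data$log10_ratio,
                                   fill = .data$isoform_class)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(preserve = "single"),
                      colour = "grey20") +
    ggplot2::scale_fill_manual(values = c(L = "white", S = "firebrick"),
                               name = "isoform") +
    ggplot2::labs(x = NULL, y = "log10(junction reads / Actb reads)") +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Sequencing depth vs skipping-isoform presence
#'
#' Species ordered by total control-gene (Actb) junction reads; filled
#' points mark species where the skipping isoform was detected. A flat
#' mixture of filled and open points across the depth range indicates that
#' detection is not depth-limited.
#'
#' @param x A [depth_report()] or a tibble with `species_id`, `actb_total`,
#'   `s_present`.
#' @return A ggplot object.
#' @export
plot_depth <- function(x) {
  if (inherits(x, "depth_report")) x <- x$table
  x <- arrange(x, .data$actb_total)
  x$species_id <- factor(x$species_id, levels = x$species_id)
  ggplot2::ggplot(x, ggplot2::aes(x = .data$species_id, y = .data$actb_total,
                                  fill = .data$s_present)) +
    ggplot2::geom_point(shape = 21, size = 3, colour = "black") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "white"),
                               name = "skipping isoform") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "Actb junction reads (depth)") +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @export
autoplot.depth_report <- function(object, ...) plot_depth(object)

#' Plot a local similarity profile
#'
#' Window scores against window-center position, optionally with shaded
#' column intervals (e.g. transmembrane segments) and vertical marks (e.g.
#' cassette-exon boundaries).
#'
#' @param object A [window_scan()] profile.
#' @param shade Optional two-column data frame of column intervals to shade.
#' @param vlines Optional column positions for dashed vertical lines.
#' @param use_ref Plot against `ref_center` (reference-row residue
#'   numbering) instead of alignment columns, when available.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.similarity_profile <- function(object, shade = NULL, vlines = NULL,
                                        use_ref = FALSE, ...) {
  xcol <- if (use_ref && "ref_center" %in% names(object)) "ref_center"
          else "center"
  p <- ggplot2::ggplot(as_tibble(unclass(object)),
                       ggplot2::aes(x = .data[[xcol]], y = .data$score))
  if (!is.null(shade)) {
    p <- p + ggplot2::annotate("rect", xmin = shade[[1]], xmax = shade[[2]],
                               ymin = -Inf, ymax = Inf, alpha = 0.2,
                               fill = "grey40")
  }
  if (!is.null(vlines)) {
    p <- p + ggplot2::geom_vline(xintercept = vlines, linetype = "dashed",
                                 colour = "purple")
  }
  p + ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 3)) +
    ggplot2::labs(x = if (xcol == "center") "alignment column (window center)"
                  else "reference residue (window center)",
                  y = "local similarity (0-3)") +
    ggplot2::theme_classic()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
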