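# ggplot2 views of the main result types.

#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_hline geom_vline
#'   labs theme_minimal scale_y_log10 facet_wrap geom_tile
NULL

#' Plot a meta-profile
#'
#' @param object A `meta_profile` from [tss_metaprofile()] or
#'   [scaled_island_metaprofile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.meta_profile <- function(object, ...) {
  anchor <- attr(object, "anchor")
  xcol <- if (anchor == "TSS") "position" else "x"
  xlab <- if (anchor == "TSS") "distance from TSS (bp)" else
    "scaled island coordinate (island = [0, 1])"
  p <- ggplot(as_tibble(object), aes(x = .data[[xcol]], y = .data$density)) +
    geom_line(color = "#b2182b") +
    labs(x = xlab, y = "mean tag density (fragment-bp / bp / anchor)",
         subtitle = sprintf("%d anchors", attr(object, "n_anchors"))) +
    theme_minimal()
  if (anchor != "TSS") {
    p <- p + geom_vline(xintercept = c(0, 1), linetype = "dashed",
                        color = "grey50")
  }
  p
}

#' Volcano plot of knockdown differential expression
#'
#' @param volcano_tbl Output of [volcano()].
#' @param p_line Significance guide line (default 0.05).
#' @param fc_lines Fold-change guide lines (default 2- and 4-fold).
#' @return A ggplot.
#' @export
plot_volcano <- function(volcano_tbl, p_line = 0.05, fc_lines = c(2, 4)) {
  ggplot(volcano_tbl, aes(x = .data$log2fc, y = -log10(.data$p_value))) +
    geom_point(color = "#b2182b", alpha = 0.6, size = 0.9) +
    geom_vline(xintercept = 0, linetype = "dashed", color = "black") +
    geom_vline(xintercept = c(-log2(fc_lines), log2(fc_lines)),
               linetype = "dashed", color = c("green4", "blue", "green4", "blue")[
                 seq_len(2 * length(fc_lines))]) +
    geom_hline(yintercept = -log10(p_line), linetype = "dashed",
               color = "grey40") +
    labs(x = "log2 fold change (knockdown / control)",
         y = "-log10 p (two-sided t)") +
    theme_minimal()
}

#' @rdname expression_vs_tags
#' @param object A `binding_expression`.
#' @param ... Unused.
#' @export
autoplot.binding_expression <- function(object, ...) {
  ggplot(object$data, aes(x = .data$expr, y = .data$tags)) +
    geom_point(alpha = 0.5, size = 0.9) +
    geom_line(data = object$trend, aes(y = .data$fit), color = "black",
              linewidth = 1) +
    labs(x = "expression (log2)", y = "TSS-proximal tag count",
         subtitle = sprintf("Spearman rho = %s", format(object$rho, digits = 2))) +
    theme_minimal()
}

#' @rdname fit_kinetics
#' @param object A `kinetic_fit`.
#' @export
autoplot.kinetic_fit <- function(object, ...) {
  df <- object$data
  df$fitted <- object$fitted
  ggplot(df, aes(x = .data$time, group = .data$concentration)) +
    geom_point(aes(y = .data$response), size = 0.4, alpha = 0.4) +
    geom_line(aes(y = .data$fitted), color = "#b2182b") +
    labs(x = "time (s)", y = "response (RU)",
         subtitle = sprintf("K_D = %.3g uM", object$kd_uM)) +
    theme_minimal()
}

#' @rdname call_methylation
#' @param object A `clone_set`.
#' @export
autoplot.clone_set <- function(object, ...) {
  df <- tidy(object)
  df$clone <- factor(df$clone, levels = rev(rownames(object$calls)))
  ggplot(df, aes(x = factor(.data$pos), y = .data$clone)) +
    geom_point(aes(fill = .data$call), shape = 21, size = 3) +
    ggplot2::scale_fill_manual(
      values = c(methylated = "black", unmethylated = "white"),
      na.value = "grey80"
    ) +
    labs(x = "CpG position", y = NULL) +
    theme_minimal()
}
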