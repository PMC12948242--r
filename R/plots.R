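#' Delta volcano plot
#'
#' The virtual-sorting analogue of a fold-change volcano: per-gene delta-ARS
#' on the x axis against -log10 adjusted p on the y axis, with the
#' mutual-exclusion / co-existence delta cutoffs and the significance line
#' drawn in. Given an `me_screen`, candidate genes are highlighted.
#'
#' @param x A sorting table from [virtual_sort()] or an `me_screen` object.
#' @param delta_max,coexist_min,padj_max Cutoff lines; taken from the screen
#'   when `x` is an `me_screen`.
#' @return A ggplot object.
#' @export
plot_delta_volcano <- function(x, delta_max = -15, coexist_min = 15,
                               padj_max = 0.01) {
  if (inherits(x, "me_screen")) {
    if (x$status != "ok") rlang::abort("screen has no sorting table (source not analyzable)")
    th <- x$thresholds
    delta_max <- th$delta_max
    coexist_min <- th$coexist_min
    padj_max <- th$padj_max
    dat <- x$candidates
    dat$highlight <- dat$is_candidate
  } else {
    dat <- tibble::as_tibble(x)
    dat$highlight <- dat$delta <= delta_max & dat$p_adj <= padj_max
  }
  # floor p at the smallest double so -log10 stays finite
  dat$neglog_p <- -log10(pmax(dat$p_adj, .Machine$double.xmin))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$delta, y = .data$neglog_p)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$highlight),
                        alpha = 0.6, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55", `TRUE` = "firebrick")) +
    ggplot2::geom_vline(xintercept = c(delta_max, coexist_min), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(padj_max), linetype = "dashed") +
    ggplot2::labs(
      x = "delta ARS (source-high - source-low)",
      y = expression(-log[10] ~ "adjusted p"),
      title = "Delta volcano"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot method for mutual-exclusion screens
#'
#' Draws the delta volcano for the screen with its own thresholds; see
#' [plot_delta_volcano()].
#'
#' @param object An `me_screen` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot me_screen
#' @export
autoplot.me_screen <- function(object, ...) {
  plot_delta_volcano(object) +
    ggplot2::labs(title = paste0("Delta volcano: source ", object$source))
}

#' Scatter plot of a gene pair's expression
#'
#' TPM of one gene against another across samples - the raw view in which
#' bilateral exclusion (an L-shaped cloud hugging the axes), linear negative
#' correlation (a descending band away from the axes) and co-existence are
#' visually distinct.
#'
#' @param m TPM matrix or `gene_id`-keyed data frame.
#' @param gene_x,gene_y Gene identifiers to plot.
#' @param log1p If `TRUE` (default) plot on a log1p scale.
#' @return A ggplot object.
#' @export
plot_gene_pair <- function(m, gene_x, gene_y, log1p = TRUE) {
  m <- as_tpm_matrix(m)
  for (g in c(gene_x, gene_y)) {
    if (!g %in% rownames(m)) rlang::abort(paste0("gene not found in matrix: ", g))
  }
  dat <- tibble::tibble(x = m[gene_x, ], y = m[gene_y, ])
  if (log1p) dat <- dplyr::mutate(dat, x = log1p(.data$x), y = log1p(.data$y))
  unit <- if (log1p) "log1p(TPM)" else "TPM"
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(x = paste0(gene_x, " (", unit, ")"),
                  y = paste0(gene_y, " (", unit, ")")) +
    ggplot2::theme_minimal()
}
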