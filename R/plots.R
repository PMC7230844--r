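#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a comparison result set
#'
#' Histogram of the differential fraction x = D/p across all compared pairs,
#' with the retention threshold marked.
#'
#' @param object An `ssr_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ssr_comparison <- function(object, ...) {
  params <- attr(object, "params")
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$x, fill = .data$verdict)) +
    ggplot2::geom_histogram(bins = 30, boundary = 0) +
    ggplot2::labs(x = "differential fraction x = D/p", y = "fingerprint pairs",
                  fill = NULL, title = "Fingerprint comparison results") +
    ggplot2::theme_minimal()
  if (!is.null(params)) {
    p <- p + ggplot2::geom_vline(xintercept = params$max_diff_fraction,
                                 linetype = "dashed")
  }
  p
}

#' Plot per-locus merge support
#'
#' Bar chart of the winning support fraction per locus, coloured by audit
#' flag, with the effective-data threshold marked.
#'
#' @param object An `ssr_merge`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ssr_merge <- function(object, ...) {
  ggplot2::ggplot(object$loci,
                  ggplot2::aes(x = .data$marker_id, y = .data$support,
                               fill = .data$flag)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "winning support fraction", fill = NULL,
                  title = "Peer-merge locus support") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Plot a noise-tolerance scan
#'
#' Effective-locus count against realised noise fraction, one line per
#' replicate count, with the detected boundary marked.
#'
#' @param object An `ssr_qc_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ssr_qc_scan <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(x = .data$realised_fraction,
                               y = .data$effective_loci,
                               colour = factor(.data$replicate_count))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$threshold_pct / 100,
                        linetype = "dashed") +
    ggplot2::labs(x = "noise fraction", y = "merged effective loci",
                  colour = "replicates",
                  title = "Replicate-audit noise tolerance") +
    ggplot2::theme_minimal()
}

#' Plot a 96-well plate layout
#'
#' @param object An `ssr_plate_layout` from [design_plates()].
#' @param ... Unused.
#' @return A ggplot (one facet per plate).
#' @export
autoplot.ssr_plate_layout <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$row <- factor(substr(df$well, 1, 1), levels = rev(LETTERS[1:8]))
  df$col <- as.integer(substring(df$well, 2))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$role)) +
    ggplot2::geom_tile(colour = "grey40") +
    ggplot2::scale_x_continuous(breaks = 1:12) +
    ggplot2::facet_wrap(~plate_barcode) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL,
                  title = "Electrophoresis plate layout") +
    ggplot2::theme_minimal()
}

#' Plot an allele frequency table
#'
#' @param freq Output of [allele_frequencies()].
#' @return A ggplot: stacked allele frequencies per marker.
#' @export
plot_allele_frequencies <- function(freq) {
  ggplot2::ggplot(freq, ggplot2::aes(x = .data$marker_id, y = .data$freq,
                                     fill = factor(.data$allele))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "allele frequency", fill = "allele (bp)",
                  title = "Allele frequencies by marker") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
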