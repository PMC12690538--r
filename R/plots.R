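#' Plot a 5'-5' overlap spectrum
#'
#' Bar chart of pair counts by overlap distance, one facet per transposon,
#' with the 10-nt ping-pong distance highlighted.
#'
#' @param spectrum Tibble from [overlap_spectrum()].
#' @return A ggplot.
#' @export
plot_overlap_spectrum <- function(spectrum) {
  ggplot2::ggplot(spectrum,
                  ggplot2::aes(x = .data$overlap, y = .data$count,
                               fill = .data$overlap == 10)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "firebrick")) +
    ggplot2::facet_wrap(ggplot2::vars(.data$transposon), scales = "free_y") +
    ggplot2::labs(x = "5'-5' overlap (nt)", y = "pair count") +
    ggplot2::theme_minimal()
}

#' Scatter plot of per-transposon piRNA abundances between two libraries
#'
#' Mirrors the classic mutant-vs-wild-type abundance scatter on log axes; a
#' floor of half the smallest non-zero abundance is applied for display only
#' (zeros stay zeros in the tables).
#'
#' @param wt,mut `abundance_table` tibbles.
#' @param strand Which strand to plot (default `"antisense"`).
#' @return A ggplot.
#' @export
plot_abundance_scatter <- function(wt, mut, strand = "antisense") {
  s <- strand
  d <- inner_join(
    filter(wt, .data$strand == s) |>
      select("transposon", wt = "abundance"),
    filter(mut, .data$strand == s) |>
      select("transposon", mut = "abundance"),
    by = "transposon")
  floor_val <- min(c(d$wt[d$wt > 0], d$mut[d$mut > 0])) / 2
  d <- mutate(d, wt = pmax(.data$wt, floor_val),
              mut = pmax(.data$mut, floor_val))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$wt, y = .data$mut)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "wild-type abundance (per 1e6 siRNAs)",
                  y = "mutant abundance (per 1e6 siRNAs)",
                  subtitle = paste(s, "piRNAs")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname end_signature
#' @param object An `end_signature`.
#' @export
autoplot.end_signature <- function(object, ...) {
  d <- tidy(object)
  d$position <- factor(d$position, levels = unique(object$freq$position))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$frequency,
                                  fill = .data$base)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "position relative to piRNA 3' end",
                  y = "base frequency") +
    ggplot2::theme_minimal()
}

#' @rdname compare_linkage
#' @param object A `pp_linkage_test`.
#' @export
autoplot.pp_linkage_test <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$z10_a, y = .data$z10_b)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = paste("ping-pong z10,", object$labels[1]),
                  y = paste("ping-pong z10,", object$labels[2])) +
    ggplot2::theme_minimal()
}
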