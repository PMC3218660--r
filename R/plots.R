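#' Plot candidate scores
#'
#' DASPER against RESPER for every scored candidate; real fusions stand out
#' in the upper right, random-pairing artifacts sit near (or below) zero
#' DASPER.
#'
#' @param scores A `fusion_scores` tibble.
#' @param label_top Label the top `label_top` candidates by DASPER.
#' @return A ggplot object.
#' @export
plot_scores <- function(scores, label_top = 3L) {
  d <- as_tibble(scores)
  d$pair <- paste0(d$gene_a, "-", d$gene_b)
  top <- head(d[order(-d$dasper), ], label_top)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$resper, y = .data$dasper)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$m_i, colour = .data$type), alpha = 0.8) +
    ggplot2::geom_text(
      data = top, ggplot2::aes(label = .data$pair),
      vjust = -0.8, size = 3
    ) +
    ggplot2::labs(
      x = "RESPER (SPER / mean SPER)",
      y = "DASPER (SPER - expected SPER)",
      size = "supporting pairs", colour = "type"
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.fusion_scores <- function(object, ...) plot_scores(object, ...)

#' Plot per-filter removal percentages
#'
#' @param cascade A `fusion_cascade`.
#' @return A ggplot object.
#' @export
plot_filter_summary <- function(cascade) {
  s <- cascade$summary
  ggplot2::ggplot(s, ggplot2::aes(
    x = stats::reorder(.data$filter, .data$removed_pct),
    y = .data$removed_pct
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% of candidates removed") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.fusion_cascade <- function(object, ...) plot_filter_summary(object)

#' Plot the intra-transcript insert-size distribution
#'
#' Histogram of the normal-transcriptome insert sizes with optional candidate
#' chimeric medians overlaid; abnormal candidates sit far to the right.
#'
#' @param intra An [insert_size_distribution()].
#' @param candidate_medians Optional named numeric vector of chimeric insert
#'   medians to overlay.
#' @return A ggplot object.
#' @export
plot_insert_sizes <- function(intra, candidate_medians = NULL) {
  d <- tibble(insert = intra$values)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$insert)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey60") +
    ggplot2::geom_vline(xintercept = intra$median, linetype = 2) +
    ggplot2::labs(x = "insert size (composite nt)", y = "pairs") +
    ggplot2::theme_minimal()
  if (!is.null(candidate_medians)) {
    p <- p + ggplot2::geom_vline(
      data = tibble(
        m = unname(candidate_medians),
        candidate = names(candidate_medians) %||% as.character(seq_along(candidate_medians))
      ),
      ggplot2::aes(xintercept = .data$m, colour = .data$candidate)
    )
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.insert_size_distribution <- function(object, ...) plot_insert_sizes(object, ...)

#' Plot junction read support
#'
#' Read-start offsets across the best-supported junction element; a real
#' breakpoint shows reads spread uniformly over the valid offsets, a PCR
#' artifact shows a single spike.
#'
#' @param junction A [find_junction()] result.
#' @return A ggplot object.
#' @export
plot_junction_support <- function(junction) {
  calls <- junction$calls
  if (nrow(calls) == 0) {
    return(ggplot2::ggplot() +
      ggplot2::annotate("text", x = 0, y = 0, label = "no junction call") +
      ggplot2::theme_void())
  }
  best <- calls[1, ]
  hits <- junction$hits
  h <- hits[hits$orientation == best$orientation &
    hits$tile_a == best$tile_a & hits$tile_b == best$tile_b, , drop = FALSE]
  ggplot2::ggplot(tibble(offset = h$offset), ggplot2::aes(x = .data$offset)) +
    ggplot2::geom_bar(fill = "firebrick") +
    ggplot2::labs(
      x = "read start offset on junction element",
      y = "reads",
      title = paste0(
        best$gene_a, ":", best$break_a, " | ", best$gene_b, ":",
        best$break_b, " (", best$orientation, ", ", best$support, " reads)"
      )
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.junction_result <- function(object, ...) plot_junction_support(object)
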