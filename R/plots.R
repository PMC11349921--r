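# ggplot2 views of screen results and cohort classification.

#' Plot the filtering waterfall and penetrance of a screen result
#'
#' @param object A `mody_screen` object.
#' @param ... Unused.
#' @return A ggplot: penetrance (or MAF for screens without carrier
#'   reports) per surviving variant.
#' @export
autoplot.mody_screen <- function(object, ...) {
  tb <- tidy(object)
  if (nrow(tb) == 0) {
    stop("no surviving variants to plot", call. = FALSE)
  }
  lab <- if ("gene" %in% names(tb)) tb$gene else tb$variant_id
  tb$label <- make.unique(as.character(lab))
  if ("penetrance_pct" %in% names(tb)) {
    ggplot2::ggplot(tb, ggplot2::aes(
      x = stats::reorder(.data$label, -.data$penetrance_pct),
      y = .data$penetrance_pct)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::labs(x = NULL, y = "Penetrance (%)",
                    title = paste0("MODY ", object$pipeline,
                                   " pipeline survivors")) +
      ggplot2::ylim(0, 100) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(tb, ggplot2::aes(x = .data$label, y = .data$maf)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::labs(x = NULL, y = "Cohort MAF",
                    title = paste0("MODY ", object$pipeline,
                                   " pipeline survivors")) +
      ggplot2::theme_minimal()
  }
}

#' Bar chart of the per-variant spectrum shares
#'
#' @param spectrum Output of [spectrum_report()]; a `gene` column is used
#'   for labels when present.
#' @return A ggplot.
#' @export
plot_spectrum <- function(spectrum) {
  lab <- if ("gene" %in% names(spectrum)) spectrum$gene else
    spectrum$variant_id
  spectrum$label <- make.unique(as.character(lab))
  ggplot2::ggplot(spectrum, ggplot2::aes(
    x = stats::reorder(.data$label, -.data$spectrum_share_pct),
    y = .data$spectrum_share_pct)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = NULL, y = "Share of carriers (%)",
                  title = "MODY genetic spectrum") +
    ggplot2::theme_minimal()
}

#' Bar chart of lifetime glycemic classification counts
#'
#' @param participants Output of [classify_participants()].
#' @return A ggplot.
#' @export
plot_classification <- function(participants) {
  counts <- dplyr::count(participants, .data$lifetime_status)
  counts$lifetime_status <- factor(counts$lifetime_status,
                                   levels = rev(glycemic_levels()))
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$lifetime_status,
                                       y = .data$n)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = NULL, y = "Participants",
                  title = "Lifetime glycemic classification") +
    ggplot2::theme_minimal()
}
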