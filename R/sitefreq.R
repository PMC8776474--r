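#' Per-position frequency of a selected feature set
#'
#' Maps selected features back to the window positions their generating
#' k-mers cover and counts, for every position, how many selected features
#' cover it.  Each feature contributes 1 to each of its k covered
#' positions, so the total count mass is `k * n_features`.  Under the
#' default centre-excluding encoding the centre position always has count
#' zero.
#'
#' @param selected Descriptor rows of the selected features, as from
#'   [feature_descriptors()] (needs the `covered_positions` list column).
#' @param window_len Window length (default 41).
#' @return An object of class `position_frequency`: a `data.frame` with
#'   columns `position` (1..window_len) and `count`; attribute
#'   `n_features` records the selection size.
#' @export
position_frequencies <- function(selected, window_len = 41L) {
  counts <- integer(window_len)
  pos_list <- selected$covered_positions
  if (length(pos_list)) {
    all_pos <- unlist(pos_list)
    if (any(all_pos < 1L | all_pos > window_len)) {
      stop("validation error: descriptor covers positions outside the window",
           call. = FALSE)
    }
    tab <- tabulate(all_pos, nbins = window_len)
    counts <- as.integer(tab)
  }
  out <- data.frame(position = seq_len(window_len), count = counts)
  attr(out, "n_features") <- nrow(selected)
  class(out) <- c("position_frequency", "data.frame")
  out
}

#' Write a position-frequency profile as TSV and bar chart
#'
#' @param freq A [position_frequencies()] result.
#' @param path_prefix Output prefix; writes `<prefix>.tsv` and
#'   `<prefix>.<ext>` for the chart.
#' @param ext Chart format by extension (default `"png"`; anything
#'   [ggplot2::ggsave()] understands, e.g. `"pdf"`).
#' @return Invisibly, the two paths.
#' @export
write_frequency_outputs <- function(freq, path_prefix, ext = "png") {
  stopifnot(inherits(freq, "position_frequency"))
  tsv <- paste0(path_prefix, ".tsv")
  img <- paste0(path_prefix, ".", ext)
  utils::write.table(as.data.frame(freq), tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gg <- ggplot2::ggplot(freq, ggplot2::aes(x = position, y = count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "window position (nt)",
                  y = "selected features covering position") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(img, gg, width = 7, height = 3.5, dpi = 150)
  invisible(c(tsv, img))
}
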