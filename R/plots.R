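#' Plot reliability or information curves
#'
#' @param report The result of [reliability_report()].
#' @param what `"reliability"` or `"information"`.
#' @return A ggplot object.
#' @export
plot_reliability <- function(report, what = c("reliability", "information")) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  what <- match.arg(what)
  d <- report$curves
  d$value <- d[[what]]
  ggplot2::ggplot(d, ggplot2::aes(x = theta, y = value, colour = instrument)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Delirium intensity (common metric, SD units)",
                  y = what) +
    ggplot2::theme_minimal()
}

#' Plot a crosswalk table
#'
#' Expected target-instrument scores against the source instrument's
#' integer scores.
#'
#' @param cw A `crosswalk_table` from [crosswalk()].
#' @return A ggplot object.
#' @export
plot_crosswalk <- function(cw) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  raw_cols <- grep("_raw$", names(cw), value = TRUE)
  long <- do.call(rbind, lapply(raw_cols, function(cl)
    data.frame(source_score = cw$source_score,
               target = sub("_raw$", "", cl), expected = cw[[cl]])))
  ggplot2::ggplot(long, ggplot2::aes(x = source_score, y = expected, colour = target)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = paste0(attr(cw, "source"), " score"),
                  y = "Expected target score") +
    ggplot2::theme_minimal()
}
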