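# Caterpillar-style display of failure differences versus the reference.

.category_colours <- c(
  inferior_100    = "#b2182b",  # dark red
  inferior_20     = "#ef8a62",  # orange-red
  inconclusive    = "#999999",  # grey
  noninferior_100 = "#67a9cf",  # light blue
  noninferior_20  = "#2166ac"   # dark blue
)

#' Caterpillar plot of a benchmark report
#'
#' One point with a CI whisker per comparator, ordered by failure
#' difference (ascending), with vertical lines at the 20\% and 100\%
#' margins. Differences are drawn in percentage points; internal values
#' stay on the probability scale. The legend lists only the categories
#' that actually occur.
#'
#' @param x A `benchmark_report`.
#' @param main Plot title; a default describes the time point.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the plotted row order.
#' @export
plot.benchmark_report <- function(x, main = NULL, ...) {
  rows <- x$rows
  if (is.null(rows) || nrow(rows) == 0L) {
    warning("empty report: nothing to plot")
    return(invisible(NULL))
  }
  # rows are stored ordered by difference; keep that ordering
  n <- nrow(rows)
  pct <- function(v) 100 * v
  xlim <- range(pct(c(rows$ci_low, rows$ci_high, x$margins$m100, 0)))
  if (is.null(main)) {
    main <- sprintf("Failure difference vs %s at %g years (%s)",
                    x$reference, x$t, x$stratum)
  }
  cols <- .category_colours[rows$category]
  graphics::plot(pct(rows$diff), seq_len(n), xlim = xlim,
                 ylim = c(0.5, n + 0.5), pch = 19, col = cols,
                 xlab = "Difference in net failure (percentage points)",
                 ylab = "", yaxt = "n", main = main, ...)
  graphics::axis(2, at = seq_len(n), labels = rows$construct, las = 1,
                 cex.axis = 0.6)
  graphics::segments(pct(rows$ci_low), seq_len(n), pct(rows$ci_high),
                     seq_len(n), col = cols)
  graphics::abline(v = 0, col = "black", lty = 3)
  graphics::abline(v = pct(x$margins$m20), col = "grey30", lty = 2)
  graphics::abline(v = pct(x$margins$m100), col = "grey30", lty = 1)
  present <- intersect(names(.category_colours), unique(rows$category))
  graphics::legend("bottomright", legend = present,
                   col = .category_colours[present], pch = 19, cex = 0.7,
                   bty = "n")
  invisible(rows$construct)
}

#' @export
plot.tkr_benchmark <- function(x, ...) {
  for (r in x$reports) plot(r, ...)
  invisible(x)
}

#' Render a report to files
#'
#' Writes the caterpillar figure (PNG) and the companion tidy CSV for one
#' report. An empty report writes a header-only CSV, no figure, and a
#' warning.
#'
#' @param report A `benchmark_report`.
#' @param path Output stem; `<path>.png` and `<path>.csv` are written.
#' @param width,height Figure size in pixels.
#' @return Invisibly, the paths written.
#' @export
render_report <- function(report, path, width = 900, height = 700) {
  stopifnot(inherits(report, "benchmark_report"))
  csv_path <- paste0(path, ".csv")
  write_benchmark_csv(report, csv_path)
  if (is.null(report$rows) || nrow(report$rows) == 0L) {
    return(invisible(c(csv = csv_path)))
  }
  png_path <- paste0(path, ".png")
  grDevices::png(png_path, width = width, height = height)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(5, 11, 4, 2))
  plot(report)
  invisible(c(csv = csv_path, figure = png_path))
}
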