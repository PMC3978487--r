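# Base-graphics Kaplan-Meier plot in the style biomarker query tools print:
# two step curves with the pooled n, hazard ratio and log-rank p annotated.

#' Plot pooled Kaplan-Meier curves
#'
#' @param x A `km_curve` (from [km_estimate()]).
#' @param result Optional `test_result`; when given, n, HR and log-rank p
#'   are annotated on the plot.
#' @param col Colours for the low and high curves.
#' @param main Plot title.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.km_curve <- function(x, result = NULL, col = c(low = "#2166AC", high = "#B2182B"),
                          main = NULL, ...) {
  endpoint <- attr(x, "endpoint")
  graphics::plot(NA, xlim = c(0, max(x$time)), ylim = c(0, 1),
                 xlab = "Time (months)",
                 ylab = if (is.null(endpoint)) "Survival probability"
                        else paste0(endpoint, " probability"),
                 main = main, ...)
  for (g in unique(x$group)) {
    d <- x[x$group == g, ]
    graphics::lines(c(0, d$time), c(1, d$survival), type = "s",
                    col = col[[g]], lwd = 2)
    cens <- d[d$n_censor > 0, ]
    if (nrow(cens) > 0)
      graphics::points(cens$time, cens$survival, pch = 3, col = col[[g]], cex = 0.7)
  }
  graphics::legend("bottomleft", legend = names(col), col = unlist(col),
                   lwd = 2, bty = "n")
  if (!is.null(result))
    graphics::legend("topright", bty = "n", legend = c(
      sprintf("n = %d", result$n),
      sprintf("HR = %.3g (%.3g-%.3g)", result$hr, result$ci_low, result$ci_high),
      sprintf("log-rank p = %.3g", result$logrank_p)))
  invisible(x)
}

#' @export
plot.marker_result <- function(x, ...) {
  plot.km_curve(x$km, result = x$result,
                main = paste(paste(x$query$gene_ids, collapse = "+"),
                             x$query$endpoint, sep = " - "), ...)
  invisible(x)
}
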