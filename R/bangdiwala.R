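# Bangdiwala observer-agreement chart. Inside the N x N square, category i
# owns the rectangle spanned by the cumulative row marginal (width) and the
# cumulative column marginal (height); the dark square of side n_ii marks
# exact agreement and a lighter band the cells within the partial-agreement
# distance. Marginal bias shows as rectangles drifting off the 45-degree
# diagonal. B = sum(n_ii^2) / sum(n_i. * n_.i) summarises the chart.

#' Bangdiwala agreement chart
#'
#' Computes the chart geometry and the B statistic for a k x k paired ordinal
#' table. `B = 1` exactly when the table is diagonal (all mass in exact
#' agreement); `B = 0` when the diagonal is empty.
#'
#' @param tab a [contingency_table()] or square count matrix (rows = mode A,
#'   columns = mode B).
#' @param partial_band how many categories away still counts as partial
#'   agreement (default 1: "one level away").
#' @return an object of class `bangdiwala_chart`: list with `N`, `B`,
#'   `labels`, and data.frames `rectangles`, `dark`, `partial`, all in count
#'   coordinates on `[0, N]^2`.
#' @examples
#' bangdiwala_chart(contingency_table(diag(c(2, 3, 4, 5))))$B # 1
#' @export
bangdiwala_chart <- function(tab, partial_band = 1) {
  m <- unclass(as.matrix(tab))
  n <- sum(m)
  if (n == 0) stop_computation("chart is undefined for an empty table")
  k <- nrow(m)
  labels <- rownames(m)
  if (is.null(labels)) labels <- as.character(0:(k - 1))
  rm_ <- rowSums(m)
  cm_ <- colSums(m)
  R <- c(0, cumsum(rm_))
  C <- c(0, cumsum(cm_))
  den <- sum(rm_ * cm_)
  B <- if (den == 0) 0 else sum(diag(m)^2) / den

  rect <- data.frame(category = labels,
                     x0 = R[-(k + 1)], y0 = C[-(k + 1)],
                     x1 = R[-1], y1 = C[-1])
  dark <- partial <- vector("list", k)
  for (i in seq_len(k)) {
    # offsets inside rectangle i: row cells left of the diagonal cell shift
    # the dark square right, column cells below shift it up
    off_x <- if (i > 1) sum(m[i, 1:(i - 1)]) else 0
    off_y <- if (i > 1) sum(m[1:(i - 1), i]) else 0
    dark[[i]] <- data.frame(category = labels[i],
                            x0 = R[i] + off_x, y0 = C[i] + off_y,
                            x1 = R[i] + off_x + m[i, i],
                            y1 = C[i] + off_y + m[i, i])
    jr <- max(1, i - partial_band):min(k, i + partial_band)
    px0 <- R[i] + (if (min(jr) > 1) sum(m[i, 1:(min(jr) - 1)]) else 0)
    py0 <- C[i] + (if (min(jr) > 1) sum(m[1:(min(jr) - 1), i]) else 0)
    partial[[i]] <- data.frame(category = labels[i],
                               x0 = px0, y0 = py0,
                               x1 = px0 + sum(m[i, jr]),
                               y1 = py0 + sum(m[jr, i]))
  }
  structure(
    list(N = n, B = B, labels = labels, partial_band = partial_band,
         rectangles = rect, dark = do.call(rbind, dark),
         partial = do.call(rbind, partial)),
    class = "bangdiwala_chart"
  )
}

#' @export
print.bangdiwala_chart <- function(x, ...) {
  cat(sprintf("<bangdiwala_chart> %d categories, N = %d, B = %.3f\n",
              length(x$labels), x$N, x$B))
  invisible(x)
}

#' Plot a Bangdiwala chart
#'
#' Base-graphics rendering: marginal rectangles in light grey, the partial
#' agreement band in mid grey, exact-agreement squares in dark grey, and the
#' 45-degree diagonal.
#'
#' @param x a [bangdiwala_chart()].
#' @param main plot title.
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.bangdiwala_chart <- function(x, main = sprintf("Agreement chart (B = %.2f)", x$B),
                                  ...) {
  N <- x$N
  graphics::plot(NULL, xlim = c(0, N), ylim = c(0, N), asp = 1,
                 xlab = "mode A (cumulative)", ylab = "mode B (cumulative)",
                 main = main)
  with(x$rectangles, graphics::rect(x0, y0, x1, y1,
                                    col = grDevices::grey(0.92), border = "grey40"))
  with(x$partial, graphics::rect(x0, y0, x1, y1,
                                 col = grDevices::grey(0.75), border = NA))
  with(x$dark, graphics::rect(x0, y0, x1, y1,
                              col = grDevices::grey(0.35), border = NA))
  graphics::abline(0, 1, lty = 2)
  graphics::rect(0, 0, N, N, border = "black")
  invisible(x)
}

#' Export a Bangdiwala chart
#'
#' `write_bangdiwala_json()` serialises the chart geometry; the SVG writer
#' emits a self-contained vector rendering (axis-aligned rectangles and the
#' diagonal), suitable for reports.
#'
#' @param chart a [bangdiwala_chart()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bangdiwala_json <- function(chart, path) {
  stopifnot(inherits(chart, "bangdiwala_chart"))
  jsonlite::write_json(unclass(chart), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}

#' @rdname write_bangdiwala_json
#' @export
write_bangdiwala_svg <- function(chart, path) {
  stopifnot(inherits(chart, "bangdiwala_chart"))
  N <- chart$N
  size <- 480
  pad <- 40
  sc <- (size - 2 * pad) / N
  # svg y grows downward; flip
  rect_el <- function(d, fill) {
    sprintf('  <rect x="%.3f" y="%.3f" width="%.3f" height="%.3f" fill="%s" stroke="none"/>',
            pad + d$x0 * sc, pad + (N - d$y1) * sc,
            (d$x1 - d$x0) * sc, (d$y1 - d$y0) * sc, fill)
  }
  lines <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            size, size, size, size),
    sprintf('  <title>Agreement chart, N = %d, B = %.3f</title>', N, chart$B),
    unlist(lapply(seq_len(nrow(chart$rectangles)), function(i)
      rect_el(chart$rectangles[i, ], "#ebebeb"))),
    unlist(lapply(seq_len(nrow(chart$partial)), function(i)
      rect_el(chart$partial[i, ], "#bfbfbf"))),
    unlist(lapply(seq_len(nrow(chart$dark)), function(i)
      rect_el(chart$dark[i, ], "#595959"))),
    sprintf('  <line x1="%d" y1="%d" x2="%d" y2="%d" stroke="black" stroke-dasharray="4 3"/>',
            pad, size - pad, size - pad, pad),
    sprintf('  <rect x="%d" y="%d" width="%d" height="%d" fill="none" stroke="black"/>',
            pad, pad, size - 2 * pad, size - 2 * pad),
    '</svg>'
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
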