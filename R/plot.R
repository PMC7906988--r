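#' @export
plot.ratemap_1d <- function(x, what = c("smoothed", "raw", "normalized"),
                            ...) {
  what <- match.arg(what)
  y <- switch(what, smoothed = x$smoothed_rate, raw = x$raw_rate,
              normalized = x$normalized_rate)
  graphics::plot(x$bin_centers_cm, y, type = "s",
                 xlab = "linearized position (cm)",
                 ylab = sprintf("%s activity rate (dF/F per s)", what), ...)
  invisible(x)
}

#' @export
plot.ratemap_2d <- function(x, what = c("smoothed", "raw", "normalized"),
                            ...) {
  what <- match.arg(what)
  z <- switch(what, smoothed = x$smoothed_rate, raw = x$raw_rate,
              normalized = x$normalized_rate)
  graphics::image(x$bin_centers_cm, x$bin_centers_cm, z,
                  xlab = "x (cm)", ylab = "y (cm)", asp = 1,
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' @export
plot.mds_embedding <- function(x, dims = c(1, 2), ...) {
  if (nrow(x$Y) < max(dims)) stop("not enough components", call. = FALSE)
  col <- if (!is.null(x$theta_deg))
    grDevices::hcl.colors(360, "spectral")[pmax(1L, ceiling(x$theta_deg))]
  else "black"
  graphics::plot(x$Y[dims[1], ], x$Y[dims[2], ], col = col, pch = 16,
                 cex = 0.5, xlab = sprintf("component %d", dims[1]),
                 ylab = sprintf("component %d", dims[2]), ...)
  invisible(x)
}

#' @export
plot.lap_rate_matrix <- function(x, ...) {
  graphics::image(seq_len(x$n_bins) * x$bin_size_cm - x$bin_size_cm / 2,
                  seq_len(nrow(x$rate)), t(x$rate),
                  xlab = "position (cm)", ylab = "lap",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}
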