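#' Render a time-frequency grid as a normalised square image
#'
#' Log-compresses to decibels (with an additive floor), clips the dynamic
#' range to the top `top_db` decibels below the per-image maximum so the
#' near-zero padding floor cannot swamp the in-signal contrast, min-max
#' normalises to \[0, 1\] and bilinearly resizes to `size x size`. A constant
#' grid has no dynamic range to normalise, so it maps to an all-0.5 image.
#'
#' @param grid Non-empty numeric matrix (rows = frequency, cols = time).
#' @param size Output side length (default 128).
#' @param log_floor Additive floor before the log.
#' @param branch Provenance tag (`"mel"` or `"cwt"`).
#' @param top_db Retained dynamic range in dB below the image maximum.
#' @param power Is `grid` a power quantity (10 dB/decade, as for the
#'   magnitude-squared mel grid) rather than a magnitude (20 dB/decade, as
#'   for CWT magnitudes)?
#' @return A `lung_scalogram`: `size x size` matrix in \[0, 1\] with
#'   attributes `branch`, `norm_min`, `norm_max`.
#' @export
to_image <- function(grid, size = 128L, log_floor = 1e-10, branch = "mel",
                     top_db = 60, power = identical(branch, "mel")) {
  if (length(grid) == 0) stop("empty grid")
  g <- (if (power) 10 else 20) * log10(grid + log_floor)
  g <- pmax(g, max(g) - top_db)
  lo <- min(g); hi <- max(g)
  g <- if (hi - lo < 1e-12) matrix(0.5, nrow(g), ncol(g)) else (g - lo) / (hi - lo)
  img <- resize_bilinear(g, size, size)
  structure(img, class = "lung_scalogram", branch = branch,
            norm_min = lo, norm_max = hi)
}

#' Bilinear resize of a matrix
#'
#' Separable linear interpolation on the regular pixel grid; identity when
#' the matrix already has the target shape.
#'
#' @param m Numeric matrix.
#' @param nrow_out,ncol_out Target dimensions.
#' @return Resized matrix.
#' @export
resize_bilinear <- function(m, nrow_out, ncol_out) {
  if (nrow(m) == nrow_out && ncol(m) == ncol_out) return(m)
  interp_axis <- function(mat, n_out) {
    n_in <- nrow(mat)
    if (n_in == n_out) return(mat)
    if (n_in == 1L) return(mat[rep(1L, n_out), , drop = FALSE])
    xout <- seq(1, n_in, length.out = n_out)
    apply(mat, 2, function(col) approx(seq_len(n_in), col, xout = xout)$y)
  }
  m2 <- interp_axis(m, nrow_out)
  t(interp_axis(t(m2), ncol_out))
}

#' @export
print.lung_scalogram <- function(x, ...) {
  cat("<lung_scalogram> ", nrow(x), "x", ncol(x), " ", attr(x, "branch"),
      " image, range [", signif(min(x), 3), ", ", signif(max(x), 3), "]\n",
      sep = "")
  invisible(x)
}

#' Plot a scalogram image
#'
#' @param object A `lung_scalogram`.
#' @param ... Unused.
#' @return A ggplot raster of the image (row 1 at the bottom: low
#'   frequencies down, time left to right).
#' @export
autoplot.lung_scalogram <- function(object, ...) {
  df <- tidyr::expand_grid(freq_bin = seq_len(nrow(object)),
                           time_bin = seq_len(ncol(object)))
  df$intensity <- as.vector(object[cbind(df$freq_bin, df$time_bin)])
  ggplot2::ggplot(df, ggplot2::aes(.data$time_bin, .data$freq_bin,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "time bin", y = "frequency bin",
                  fill = "intensity",
                  title = paste0(attr(object, "branch"), " scalogram")) +
    ggplot2::theme_minimal()
}
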