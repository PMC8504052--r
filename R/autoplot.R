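# tidy()/glance()/autoplot() conveniences for quick, ad-hoc looks at
# fetched data.  The deterministic figure pipeline is render_frame(); these
# ggplot2 views are for interactive exploration of payloads.

#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom generics tidy glance
NULL

#' @rdname tidy_trackkit
#' @export
#' @method tidy score_profile
tidy.score_profile <- function(x, ...) as_tibble(x)

#' @rdname tidy_trackkit
#' @export
#' @method tidy contact_matrix
tidy.contact_matrix <- function(x, ...) as_tibble(x)

#' Tidy and summarize trackkit result objects
#'
#' `tidy()` returns the long per-bin (or per-cell) tibble behind a result;
#' `glance()` a one-row summary.
#'
#' @param x A `score_profile` or `contact_matrix`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy_trackkit
NULL

#' @rdname tidy_trackkit
#' @export
#' @method glance score_profile
glance.score_profile <- function(x, ...) {
  fin <- x$values[is.finite(x$values)]
  tibble::tibble(
    kind = x$kind, n_bins = x$axis$n_bins, n_finite = length(fin),
    min = if (length(fin)) min(fin) else NA_real_,
    max = if (length(fin)) max(fin) else NA_real_,
    mean = if (length(fin)) mean(fin) else NA_real_
  )
}

#' @rdname tidy_trackkit
#' @export
#' @method glance contact_matrix
glance.contact_matrix <- function(x, ...) {
  fin <- x$values[is.finite(x$values)]
  tibble::tibble(
    n_rows = nrow(x$values), n_cols = ncol(x$values),
    resolution = x$resolution,
    symmetric = is_square_matrix(x),
    total = sum(fin), max = if (length(fin)) max(fin) else NA_real_
  )
}

#' @rdname autoplot_trackkit
#' @export
#' @method autoplot score_profile
autoplot.score_profile <- function(object, ...) {
  df <- as_tibble(object)
  mid <- (df$start + df$end) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = mid, y = .data$value)) +
    ggplot2::geom_line(na.rm = TRUE, color = "#2166ac") +
    ggplot2::labs(x = df$chrom[1], y = object$kind) +
    ggplot2::theme_minimal()
}

#' ggplot2 views of trackkit results
#'
#' Quick interactive plots of fetched payloads; the publication pipeline is
#' [render_frame()].
#'
#' @param object A `score_profile` or `contact_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot_trackkit
NULL

#' @rdname autoplot_trackkit
#' @export
#' @method autoplot contact_matrix
autoplot.contact_matrix <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col_start, y = .data$row_start,
                                   fill = log1p(pmax(.data$value, 0)))) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "#ffffff", high = "#67000d",
                                 name = "log1p") +
    ggplot2::labs(x = format(object$col_axis$range),
                  y = format(object$row_axis$range)) +
    ggplot2::theme_minimal()
}

#' Manhattan-style plot of fetched SNPs
#'
#' @param snps Tibble from [read_snps()].
#' @return A ggplot object.
#' @export
plot_snps <- function(snps) {
  ggplot2::ggplot(snps, ggplot2::aes(x = .data$pos, y = .data$neg_log10_p)) +
    ggplot2::geom_point(size = 0.8, color = "#636363") +
    ggplot2::labs(x = "position (bp)", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}
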