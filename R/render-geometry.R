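# Pure geometry used by the renderer.  Numerical tests assert on these
# specs (and on fetch payloads), never on decoded pixels.

#' Assign annotation records to non-overlapping display rows
#'
#' Greedy first-fit packing: each record (sorted by start) is placed in the
#' lowest row whose previous occupant ends at least `min_gap` bases before
#' the record starts.
#'
#' @param genes Tibble with `start`/`end` columns, sorted by `start`.
#' @param min_gap Minimum gap (bp) between same-row neighbours.
#' @return Integer vector of 0-based row indices, one per record.
#' @examples
#' layout_gene_rows(tibble::tibble(start = c(1, 5, 20), end = c(10, 15, 30)))
#' @export
layout_gene_rows <- function(genes, min_gap = 0) {
  n <- nrow(genes)
  if (!n) return(integer())
  if (is.unsorted(genes$start)) {
    stop("records must be sorted by start position", call. = FALSE)
  }
  rows <- integer(n)
  row_last_end <- numeric()
  for (k in seq_len(n)) {
    placed <- FALSE
    for (r in seq_along(row_last_end)) {
      if (genes$start[k] - row_last_end[r] - 1 >= min_gap) {
        rows[k] <- r - 1L
        row_last_end[r] <- genes$end[k]
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      row_last_end <- c(row_last_end, genes$end[k])
      rows[k] <- length(row_last_end) - 1L
    }
  }
  rows
}

#' Arc geometry for interaction pairs
#'
#' Computes the curve specification of an arcs track: each pair is drawn as
#' a half-ellipse from the midpoint of anchor 1 to the midpoint of anchor
#' 2, apex halfway between them, apex height proportional to the genomic
#' span (normalized so the widest pair in view has height 1) and line
#' width proportional to the score when scores are present (equal widths
#' otherwise).
#'
#' @param pairs Tibble as returned by [read_pairs()].
#' @return Tibble with `x0`, `x1` (anchor midpoints), `apex_x`, `span`,
#'   `height` (normalized 0-1) and `lwd`.
#' @export
arc_geometry <- function(pairs) {
  if (!nrow(pairs)) {
    return(tibble::tibble(x0 = double(), x1 = double(), apex_x = double(),
                          span = double(), height = double(), lwd = double()))
  }
  mid1 <- (pairs$start1 + pairs$end1) / 2
  mid2 <- (pairs$start2 + pairs$end2) / 2
  span <- abs(mid2 - mid1)
  height <- if (max(span) > 0) span / max(span) else rep(1, length(span))
  score <- pairs$score
  lwd <- if (all(is.na(score)) || max(score, na.rm = TRUE) <= 0) {
    rep(1, length(span))
  } else {
    s <- ifelse(is.na(score), 0, pmax(score, 0))
    0.5 + 2.5 * s / max(s)
  }
  tibble::tibble(x0 = mid1, x1 = mid2, apex_x = (mid1 + mid2) / 2,
                 span = span, height = height, lwd = lwd)
}

# ---- colormaps -----------------------------------------------------------

tk_palette <- function(name, n = 256L) {
  switch(name,
    reds = grDevices::colorRampPalette(c("#ffffff", "#fee0d2", "#fc9272",
                                         "#de2d26", "#67000d"))(n),
    bwr = grDevices::colorRampPalette(c("#2166ac", "#f7f7f7", "#b2182b"))(n),
    viridis = grDevices::hcl.colors(n, "viridis"),
    stop("unknown colormap '", name, "'", call. = FALSE)
  )
}

#' Map a contact matrix to drawable colors
#'
#' Transforms (`log1p` or identity), clamps (explicitly or at the 2nd/98th
#' percentile of finite values) and color-maps a matrix, and returns the
#' colorbar specification annotated in pre-transform (data) units.  `NaN`
#' cells map to `NA` color (rendered as background).
#'
#' @param matrix A [contact_matrix()].
#' @param style `"square"` or `"triangular"` (recorded for the drawing
#'   layer).
#' @param scale `"log1p"` or `"linear"` value transform.
#' @param cmap Colormap name (`"reds"`, `"bwr"`, `"viridis"`).
#' @param clamp Optional `c(lo, hi)` display clamp in data units;
#'   `NULL` = automatic percentile clamp.
#' @param symmetric Force a clamp symmetric about 0 (differential
#'   matrices).
#' @return List with `colors` (hex matrix, `NA` for `NaN` cells), `style`,
#'   and `colorbar` (list with `palette`, `lo`, `hi` in data units).
#' @export
matrix_panel_transform <- function(matrix, style = c("square", "triangular"),
                                   scale = c("log1p", "linear"),
                                   cmap = "reds", clamp = NULL,
                                   symmetric = FALSE) {
  style <- match.arg(style)
  scale <- match.arg(scale)
  v <- matrix$values
  tf <- function(x) if (scale == "log1p") log1p(pmax(x, -1 + 1e-12)) else x
  fin <- v[is.finite(v)]
  if (is.null(clamp)) {
    clamp <- if (length(fin)) {
      as.numeric(stats::quantile(fin, c(0.02, 0.98), names = FALSE))
    } else c(0, 1)
    if (symmetric) {
      m <- max(abs(clamp))
      clamp <- c(-m, m)
    }
  } else {
    if (length(clamp) != 2L || any(!is.finite(clamp))) {
      stop("`clamp` must be two finite numbers", call. = FALSE)
    }
    clamp <- sort(as.numeric(clamp))
  }
  pal <- tk_palette(cmap)
  t_v <- tf(v)
  t_lo <- tf(clamp[1]); t_hi <- tf(clamp[2])
  norm <- if (t_hi > t_lo) pmin(pmax((t_v - t_lo) / (t_hi - t_lo), 0), 1) else t_v * 0
  idx <- 1L + as.integer(round(norm * (length(pal) - 1L)))
  colors <- matrix(pal[idx], nrow(v), ncol(v))
  colors[!is.finite(v)] <- NA_character_
  list(colors = colors, style = style, scale = scale,
       colorbar = list(palette = pal, lo = clamp[1], hi = clamp[2]))
}

# ---- axis ticks ----------------------------------------------------------

# "nice" round tick positions with a kb/Mb unit suffix shared by the axis
axis_ticks <- function(range, n = 6) {
  ticks <- pretty(c(range$start, range$end), n = n)
  ticks <- ticks[ticks >= range$start & ticks <= range$end]
  if (!length(ticks)) ticks <- c(range$start, range$end)
  unit <- if (max(ticks) >= 1e6) c(1e6, "Mb") else if (max(ticks) >= 1e3) c(1e3, "kb") else c(1, "bp")
  div <- as.numeric(unit[1])
  labels <- formatC(ticks / div, format = "fg", big.mark = ",", digits = 7)
  tibble::tibble(pos = ticks, label = labels, unit = unit[2])
}
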