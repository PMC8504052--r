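# Built-in draw functions.  Each runs inside a panel viewport covering the
# track's region of the page and pushes its own data viewport with the
# shared x scale (bp; an interval [s, e] occupies x in [s, e+1)) and a
# track-specific y scale.  Drawing consumes only the fetched payload.

push_data_vp <- function(range, yscale = c(0, 1)) {
  grid::pushViewport(grid::viewport(
    xscale = c(range$start, range$end + 1), yscale = yscale,
    clip = "on"
  ))
}

pop_vp <- function() grid::popViewport()

alpha_color <- function(color, alpha) {
  if (is.null(alpha) || is.na(alpha) || alpha >= 1) return(color)
  grDevices::adjustcolor(color, alpha.f = alpha)
}

y_limits <- function(values, props, pad = 0.05, include_zero = TRUE) {
  fin <- values[is.finite(values)]
  lo <- props$min_value %||% if (length(fin)) min(if (include_zero) 0 else Inf, fin) else 0
  hi <- props$max_value %||% if (length(fin)) max(fin) else 1
  if (hi <= lo) hi <- lo + 1
  span <- hi - lo
  c(lo - if (lo == 0) 0 else pad * span, hi + pad * span)
}

value_range_label <- function(lims) {
  lab <- function(x) formatC(x, format = "g", digits = 3)
  grid::grid.text(paste0("[", lab(lims[1]), " - ", lab(lims[2]), "]"),
                  x = grid::unit(1, "npc") - grid::unit(2, "pt"),
                  y = grid::unit(1, "npc") - grid::unit(2, "pt"),
                  just = c("right", "top"),
                  gp = grid::gpar(cex = 0.45, col = "#666666"))
}

# ---- decorative tracks ---------------------------------------------------

draw_spacer <- function(payload, track, range) invisible()

draw_xaxis <- function(payload, track, range) {
  push_data_vp(range)
  ticks <- axis_ticks(range)
  col <- track$props$color %||% "#333333"
  grid::grid.lines(x = grid::unit(c(range$start, range$end + 1), "native"),
                   y = grid::unit(c(0.62, 0.62), "npc"),
                   gp = grid::gpar(col = col, lwd = 1))
  for (k in seq_len(nrow(ticks))) {
    grid::grid.lines(x = grid::unit(rep(ticks$pos[k] + 0.5, 2), "native"),
                     y = grid::unit(c(0.52, 0.62), "npc"),
                     gp = grid::gpar(col = col, lwd = 1))
    grid::grid.text(ticks$label[k],
                    x = grid::unit(ticks$pos[k] + 0.5, "native"),
                    y = grid::unit(0.40, "npc"),
                    gp = grid::gpar(cex = 0.55, col = col))
  }
  grid::grid.text(paste0(range$chrom, " (", ticks$unit[1], ")"),
                  x = grid::unit(0.01, "npc"), y = grid::unit(0.85, "npc"),
                  just = "left", gp = grid::gpar(cex = 0.55, col = col))
  pop_vp()
}

# ---- signal tracks -------------------------------------------------------

draw_signal_bars <- function(payload, track, range) {
  lims <- y_limits(payload$value, track$props)
  push_data_vp(range, yscale = lims)
  if (nrow(payload)) {
    s <- pmax(payload$start, range$start)
    e <- pmin(payload$end, range$end)
    keep <- s <= e
    s <- s[keep]; e <- e[keep]
    v <- pmin(pmax(payload$value[keep], lims[1]), lims[2])
    base <- max(lims[1], 0)
    if (length(s)) {
      fill <- alpha_color(track$props$color, track$props$alpha)
      grid::grid.rect(x = grid::unit(s, "native"),
                      y = grid::unit(rep(base, length(s)), "native"),
                      width = grid::unit(e + 1 - s, "native"),
                      height = grid::unit(v - base, "native"),
                      just = c("left", "bottom"),
                      gp = grid::gpar(fill = fill, col = NA))
    }
  }
  value_range_label(lims)
  pop_vp()
}

# score_profile payloads: line (virtual 4C, insulation) or signed bars (DI)
draw_profile_line <- function(payload, track, range) {
  ax <- payload$axis
  vals <- payload$values
  lims <- y_limits(vals, track$props, include_zero = FALSE)
  push_data_vp(range, yscale = lims)
  centers <- (ax$starts + ax$ends + 1) / 2
  runs <- split(seq_along(vals), cumsum(!is.finite(vals)))
  col <- alpha_color(track$props$color, track$props$alpha)
  for (run in runs) {
    run <- run[is.finite(vals[run])]
    if (length(run) >= 2) {
      grid::grid.lines(x = grid::unit(centers[run], "native"),
                       y = grid::unit(vals[run], "native"),
                       gp = grid::gpar(col = col, lwd = 1.4))
    } else if (length(run) == 1) {
      grid::grid.points(x = grid::unit(centers[run], "native"),
                        y = grid::unit(vals[run], "native"),
                        pch = 16, size = grid::unit(1.5, "pt"),
                        gp = grid::gpar(col = col))
    }
  }
  if (lims[1] < 0 && lims[2] > 0) {
    grid::grid.lines(x = grid::unit(c(range$start, range$end + 1), "native"),
                     y = grid::unit(c(0, 0), "native"),
                     gp = grid::gpar(col = "#bbbbbb", lty = 2, lwd = 0.6))
  }
  value_range_label(lims)
  pop_vp()
}

draw_profile_bars <- function(payload, track, range) {
  ax <- payload$axis
  vals <- payload$values
  lims <- y_limits(vals, track$props, include_zero = TRUE)
  if (lims[1] > 0) lims[1] <- 0
  push_data_vp(range, yscale = lims)
  fin <- which(is.finite(vals))
  if (length(fin)) {
    pos_col <- track$props$color_pos %||% "#d6604d"
    neg_col <- track$props$color_neg %||% "#4393c3"
    v <- vals[fin]
    grid::grid.rect(x = grid::unit(ax$starts[fin], "native"),
                    y = grid::unit(pmin(v, 0), "native"),
                    width = grid::unit(ax$ends[fin] + 1 - ax$starts[fin], "native"),
                    height = grid::unit(abs(v), "native"),
                    just = c("left", "bottom"),
                    gp = grid::gpar(fill = ifelse(v >= 0, pos_col, neg_col), col = NA))
  }
  grid::grid.lines(x = grid::unit(c(range$start, range$end + 1), "native"),
                   y = grid::unit(c(0, 0), "native"),
                   gp = grid::gpar(col = "#888888", lwd = 0.6))
  value_range_label(lims)
  pop_vp()
}

# ---- annotation tracks ---------------------------------------------------

draw_bed <- function(payload, track, range) {
  if (!nrow(payload)) {
    push_data_vp(range); pop_vp(); return(invisible())
  }
  payload <- payload[order(payload$start), ]
  rows <- layout_gene_rows(payload, min_gap = as.numeric(track$props$min_gap %||% 0))
  n_rows <- max(rows) + 1L
  push_data_vp(range, yscale = c(0, n_rows))
  col <- alpha_color(track$props$color, track$props$alpha)
  style <- track$props$style %||% "tile"
  for (k in seq_len(nrow(payload))) {
    y0 <- n_rows - rows[k] - 1L  # first row at the top
    s <- payload$start[k]; e <- payload$end[k]
    if (style == "gene" && !is.null(payload$blocks[[k]])) {
      grid::grid.lines(x = grid::unit(c(s, e + 1), "native"),
                       y = grid::unit(rep(y0 + 0.5, 2), "native"),
                       gp = grid::gpar(col = col, lwd = 0.8))
      b <- payload$blocks[[k]]
      grid::grid.rect(x = grid::unit(b$start, "native"),
                      y = grid::unit(rep(y0 + 0.2, nrow(b)), "native"),
                      width = grid::unit(b$end + 1 - b$start, "native"),
                      height = grid::unit(rep(0.6, nrow(b)), "native"),
                      just = c("left", "bottom"),
                      gp = grid::gpar(fill = col, col = NA))
    } else {
      grid::grid.rect(x = grid::unit(s, "native"),
                      y = grid::unit(y0 + 0.15, "native"),
                      width = grid::unit(e + 1 - s, "native"),
                      height = grid::unit(0.7, "native"),
                      just = c("left", "bottom"),
                      gp = grid::gpar(fill = col, col = NA))
    }
  }
  pop_vp()
}

draw_gtf <- function(payload, track, range) {
  if (!nrow(payload)) {
    push_data_vp(range); pop_vp(); return(invisible())
  }
  payload <- payload[order(payload$start), ]
  rows <- layout_gene_rows(payload, min_gap = as.numeric(track$props$min_gap %||% 0))
  n_rows <- max(rows) + 1L
  push_data_vp(range, yscale = c(0, n_rows))
  col <- alpha_color(track$props$color, track$props$alpha)
  for (k in seq_len(nrow(payload))) {
    y0 <- n_rows - rows[k] - 1L
    s <- payload$start[k]; e <- payload$end[k]
    grid::grid.lines(x = grid::unit(c(s, e + 1), "native"),
                     y = grid::unit(rep(y0 + 0.35, 2), "native"),
                     gp = grid::gpar(col = col, lwd = 0.9))
    ex <- payload$exons[[k]]
    grid::grid.rect(x = grid::unit(ex$start, "native"),
                    y = grid::unit(rep(y0 + 0.12, nrow(ex)), "native"),
                    width = grid::unit(ex$end + 1 - ex$start, "native"),
                    height = grid::unit(rep(0.46, nrow(ex)), "native"),
                    just = c("left", "bottom"),
                    gp = grid::gpar(fill = col, col = NA))
    label <- paste0(payload$gene_name[k],
                    if (payload$strand[k] %in% c("+", "-")) paste0(" (", payload$strand[k], ")") else "")
    grid::grid.text(label,
                    x = grid::unit((max(s, range$start) + min(e, range$end)) / 2, "native"),
                    y = grid::unit(y0 + 0.8, "native"),
                    gp = grid::gpar(cex = 0.5, col = "#333333"))
  }
  pop_vp()
}

draw_arcs <- function(payload, track, range) {
  push_data_vp(range, yscale = c(0, 1.05))
  geom <- arc_geometry(payload)
  col <- alpha_color(track$props$color, track$props$alpha)
  theta <- seq(0, pi, length.out = 64)
  for (k in seq_len(nrow(geom))) {
    cx <- geom$apex_x[k]
    a <- geom$span[k] / 2
    grid::grid.lines(x = grid::unit(cx - a * cos(theta), "native"),
                     y = grid::unit(geom$height[k] * sin(theta), "native"),
                     gp = grid::gpar(col = col, lwd = geom$lwd[k]))
  }
  pop_vp()
}

draw_snp <- function(payload, track, range) {
  lims <- y_limits(payload$neg_log10_p, track$props)
  push_data_vp(range, yscale = lims)
  if (nrow(payload)) {
    col <- alpha_color(track$props$color, track$props$alpha)
    grid::grid.points(x = grid::unit(payload$pos + 0.5, "native"),
                      y = grid::unit(payload$neg_log10_p, "native"),
                      pch = 16, size = grid::unit(2.2, "pt"),
                      gp = grid::gpar(col = col))
  }
  value_range_label(lims)
  pop_vp()
}

# ---- matrix tracks -------------------------------------------------------

draw_colorbar_strip <- function(colorbar) {
  pal <- colorbar$palette
  grid::grid.raster(rev(pal), x = grid::unit(0.995, "npc"),
                    y = grid::unit(0.5, "npc"), just = "right",
                    width = grid::unit(0.012, "npc"),
                    height = grid::unit(0.8, "npc"), interpolate = TRUE)
  lab <- function(x) formatC(x, format = "g", digits = 3)
  grid::grid.text(lab(colorbar$hi), x = grid::unit(0.982, "npc"),
                  y = grid::unit(0.9, "npc"), just = c("right", "top"),
                  gp = grid::gpar(cex = 0.4, col = "#555555"))
  grid::grid.text(lab(colorbar$lo), x = grid::unit(0.982, "npc"),
                  y = grid::unit(0.1, "npc"), just = c("right", "bottom"),
                  gp = grid::gpar(cex = 0.4, col = "#555555"))
}

draw_matrix_panel <- function(mat, track, range, symmetric_clamp = FALSE) {
  props <- track$props
  clamp <- if (!is.null(props$min_value) && !is.null(props$max_value)) {
    c(props$min_value, props$max_value)
  } else NULL
  mpt <- matrix_panel_transform(
    mat,
    style = props$style %||% "triangular",
    scale = props$scale %||% "log1p",
    cmap = props$cmap %||% if (symmetric_clamp) "bwr" else "reds",
    clamp = clamp, symmetric = symmetric_clamp
  )
  ax_r <- mat$row_axis; ax_c <- mat$col_axis
  if (mpt$style == "square") {
    push_data_vp(range, yscale = c(0, 1))
    n_r <- ax_r$n_bins
    for (i in seq_len(n_r)) {
      cols <- mpt$colors[i, ]
      ok <- !is.na(cols)
      if (!any(ok)) next
      grid::grid.rect(x = grid::unit(ax_c$starts[ok], "native"),
                      y = grid::unit(1 - i / n_r, "native"),
                      width = grid::unit(ax_c$ends[ok] + 1 - ax_c$starts[ok], "native"),
                      height = grid::unit(rep(1 / n_r, sum(ok)), "native"),
                      just = c("left", "bottom"),
                      gp = grid::gpar(fill = cols[ok], col = NA))
    }
  } else {
    # upper triangle rotated 45 degrees: (i, j) -> ((x_i+x_j)/2, (x_j-x_i)/2)
    depth <- as.numeric(props$depth %||% 0.5) * range_length(range)
    push_data_vp(range, yscale = c(0, depth))
    xs <- c(ax_c$starts, ax_c$ends[ax_c$n_bins] + 1)  # bin edges
    polys_x <- c(); polys_y <- c(); polys_id <- c(); polys_col <- c()
    id <- 0L
    for (i in seq_len(ax_r$n_bins)) {
      for (j in i:ax_c$n_bins) {
        colr <- mpt$colors[i, j]
        if (is.na(colr)) next
        xi0 <- xs[i]; xi1 <- xs[i + 1]; xj0 <- xs[j]; xj1 <- xs[j + 1]
        px <- c((xi0 + xj0) / 2, (xi1 + xj0) / 2, (xi1 + xj1) / 2, (xi0 + xj1) / 2)
        py <- c((xj0 - xi0) / 2, (xj0 - xi1) / 2, (xj1 - xi1) / 2, (xj1 - xi0) / 2)
        if (min(py) > depth) next
        id <- id + 1L
        polys_x <- c(polys_x, px); polys_y <- c(polys_y, py)
        polys_id <- c(polys_id, rep(id, 4L)); polys_col <- c(polys_col, colr)
      }
    }
    if (id > 0L) {
      grid::grid.polygon(x = grid::unit(polys_x, "native"),
                         y = grid::unit(polys_y, "native"),
                         id = polys_id,
                         gp = grid::gpar(fill = polys_col, col = NA))
    }
  }
  draw_colorbar_strip(mpt$colorbar)
  pop_vp()
}

draw_hicmat <- function(payload, track, range) {
  draw_matrix_panel(payload, track, range, symmetric_clamp = FALSE)
}

draw_hicdiff <- function(payload, track, range) {
  draw_matrix_panel(payload, track, range, symmetric_clamp = TRUE)
}

# ---- coverages -----------------------------------------------------------

draw_coverage <- function(cov, track, range) {
  push_data_vp(range)
  p <- cov$params
  col <- p$color %||% "#ffd92f"
  alpha <- p$alpha %||% 0.35
  if (cov$painter_type == "highlight_region") {
    r <- parse_region(p$region)
    if (identical(r$chrom, range$chrom)) {
      grid::grid.rect(x = grid::unit(max(r$start, range$start), "native"),
                      y = grid::unit(0, "npc"),
                      width = grid::unit(min(r$end, range$end) + 1 -
                                           max(r$start, range$start), "native"),
                      height = grid::unit(1, "npc"),
                      just = c("left", "bottom"),
                      gp = grid::gpar(fill = alpha_color(col, alpha), col = NA))
    }
  } else if (cov$painter_type == "vlines") {
    pos <- as.numeric(p$positions)
    pos <- pos[pos >= range$start & pos <= range$end]
    for (x in pos) {
      grid::grid.lines(x = grid::unit(rep(x + 0.5, 2), "native"),
                       y = grid::unit(c(0, 1), "npc"),
                       gp = grid::gpar(col = alpha_color(p$color %||% "#555555",
                                                         p$alpha %||% 0.8),
                                       lty = p$lty %||% 2, lwd = 0.8))
    }
  } else if (cov$painter_type == "arcs_overlay") {
    pairs <- read_pairs(p$path, range, rule = "either")
    fake <- list(props = list(color = p$color %||% "#7570b3",
                              alpha = p$alpha %||% 0.6))
    pop_vp()
    draw_arcs(pairs, fake, range)
    return(invisible())
  } else if (cov$painter_type == "custom") {
    p$fun(track, range)
  }
  pop_vp()
}
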