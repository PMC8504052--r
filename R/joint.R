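#' Joint 2D view specification
#'
#' A joint view places 1D frames on the sides of a (possibly off-diagonal)
#' contact-matrix heatmap over two genomic ranges: the center shows
#' contacts between `range_v` (rows, vertical axis) and `range_h`
#' (columns, horizontal axis); top/bottom frames are plotted along
#' `range_h`, left/right frames along `range_v` with their axes rotated
#' 90 degrees.  With `range_v = range_h` this is the on-diagonal case; with
#' different ranges it magnifies a cis-remote (off-diagonal) block, e.g. a
#' loop region.
#'
#' @param center A matrix track (type `HiCMat`, or a custom type derived
#'   from it).
#' @param range_h Horizontal (column) range, string or [genome_range()].
#' @param range_v Vertical (row) range; defaults to `range_h`.
#' @param top,bottom,left,right Optional side [frame()]s (single tracks are
#'   promoted).
#' @param side_size Scale factor applied to the side frames' natural
#'   heights (default 0.6; the center square is 3.6 in).
#' @return An object of class `tk_joint`.
#' @export
joint_view <- function(center, range_h, range_v = NULL,
                       top = NULL, bottom = NULL, left = NULL, right = NULL,
                       side_size = 0.6) {
  stopifnot(inherits(center, "tk_track"))
  as_frame <- function(x) {
    if (is.null(x)) return(NULL)
    if (inherits(x, "tk_track")) x <- frame(list(x))
    stopifnot(inherits(x, "tk_frame"))
    x
  }
  range_h <- parse_region(range_h)
  range_v <- if (is.null(range_v)) range_h else parse_region(range_v)
  structure(
    list(center = center, range_h = range_h, range_v = range_v,
         side_frames = list(top = as_frame(top), bottom = as_frame(bottom),
                            left = as_frame(left), right = as_frame(right)),
         side_size = side_size),
    class = "tk_joint"
  )
}

#' @export
print.tk_joint <- function(x, ...) {
  sides <- names(purrr::compact(x$side_frames))
  cat("<joint_view> center ", x$center$track_id, "\n",
      "  cols: ", format(x$range_h), "\n",
      "  rows: ", format(x$range_v), "\n",
      "  sides: ", if (length(sides)) paste(sides, collapse = ", ") else "none",
      "\n", sep = "")
  invisible(x)
}

#' Fetch the center matrix of a joint view
#'
#' The exact data the joint view's center heatmap draws: the contact
#' matrix with rows over `range_v` and columns over `range_h`, read from
#' the center track's source with its configured resolution/balancing.
#'
#' @param spec A [joint_view()].
#' @return A [contact_matrix()].
#' @export
joint_center_fetch <- function(spec) {
  stopifnot(inherits(spec, "tk_joint"))
  if (identical(spec$center$track_type, "HiCDiff")) {
    stop("the joint-view center must be a single-matrix track", call. = FALSE)
  }
  props <- spec$center$props
  read_contact_matrix(spec$center$source, spec$range_v, spec$range_h,
                      resolution = props$resolution %||% NULL,
                      balanced = isTRUE(props$balanced))
}

# side frame plan with the standalone-render margin removed
side_plan <- function(fr, scale) {
  if (is.null(fr)) return(NULL)
  plan <- layout_frame(fr)
  plan$panels$y_top <- (plan$panels$y_top - 0.12) * scale
  plan$panels$y_bottom <- (plan$panels$y_bottom - 0.12) * scale
  plan$panels$height <- plan$panels$height * scale
  plan$height <- sum(plan$panels$height)
  plan
}

#' Render a joint 2D view
#'
#' Draws the center heatmap from [joint_center_fetch()] and each side
#' frame from its own [frame_fetch_all()] at the appropriate range; the
#' side-frame payloads are exactly what a standalone render of those
#' frames would draw.
#'
#' @param spec A [joint_view()].
#' @param out_path Output file.
#' @param format,dpi,strict See [render_frame()].
#' @return `out_path`, invisibly.
#' @export
render_joint_view <- function(spec, out_path, format = NULL, dpi = 96,
                              strict = FALSE) {
  stopifnot(inherits(spec, "tk_joint"))
  format <- infer_format(out_path, format)
  center_mat <- if (strict) {
    joint_center_fetch(spec)
  } else {
    tryCatch(joint_center_fetch(spec), error = function(e) e)
  }
  sf <- spec$side_frames
  plans <- lapply(sf, side_plan, scale = spec$side_size)
  fetches <- list(
    top = if (!is.null(sf$top)) frame_fetch_all(sf$top, spec$range_h),
    bottom = if (!is.null(sf$bottom)) frame_fetch_all(sf$bottom, spec$range_h),
    left = if (!is.null(sf$left)) frame_fetch_all(sf$left, spec$range_v),
    right = if (!is.null(sf$right)) frame_fetch_all(sf$right, spec$range_v)
  )
  if (strict) {
    for (side in names(fetches)) {
      errs <- purrr::keep(fetches[[side]] %||% list(), inherits, "tk_fetch_error")
      if (length(errs)) {
        stop("fetch failed in ", side, " frame: ", errs[[1]]$message, call. = FALSE)
      }
    }
  }

  center_in <- 3.6
  top_h <- if (is.null(plans$top)) 0 else plans$top$height
  bottom_h <- if (is.null(plans$bottom)) 0 else plans$bottom$height
  left_w <- if (is.null(plans$left)) 0 else plans$left$height
  right_w <- if (is.null(plans$right)) 0 else plans$right$height
  margin <- 0.15
  fig_w <- left_w + center_in + right_w + 2 * margin
  fig_h <- top_h + center_in + bottom_h + 2 * margin

  open_device(out_path, format, fig_w, fig_h, dpi)
  ok <- FALSE
  on.exit({
    grDevices::dev.off()
    if (!ok && file.exists(out_path)) unlink(out_path)
  })
  grid::grid.newpage()

  # all placement in physical inches; rotated viewports keep their
  # width/height in the rotated (content) coordinates
  place <- function(cx, cy, w, h, angle = 0) {
    grid::viewport(x = grid::unit(cx, "in"), y = grid::unit(fig_h - cy, "in"),
                   width = grid::unit(w, "in"), height = grid::unit(h, "in"),
                   angle = angle)
  }
  cx0 <- margin + left_w
  cy0 <- margin + top_h
  ccx <- cx0 + center_in / 2
  ccy <- cy0 + center_in / 2

  grid::pushViewport(place(ccx, ccy, center_in, center_in))
  if (inherits(center_mat, "condition")) {
    draw_error_panel(conditionMessage(center_mat))
  } else {
    draw_joint_center(center_mat, spec)
  }
  grid::grid.rect(gp = grid::gpar(fill = NA, col = panel_frame_color, lwd = 0.5))
  grid::popViewport()

  draw_side <- function(side, cx, cy, angle, range) {
    if (is.null(sf[[side]])) return(invisible())
    plan <- plans[[side]]
    grid::pushViewport(place(cx, cy, center_in, plan$height, angle))
    draw_frame_region(sf[[side]], range, fetches[[side]], plan)
    grid::popViewport()
  }
  draw_side("top", ccx, margin + top_h / 2, 0, spec$range_h)
  draw_side("bottom", ccx, cy0 + center_in + bottom_h / 2, 0, spec$range_h)
  # left frame reads bottom-to-top along the vertical (row) axis
  draw_side("left", margin + left_w / 2, ccy, 90, spec$range_v)
  draw_side("right", cx0 + center_in + right_w / 2, ccy, -90, spec$range_v)

  ok <- TRUE
  on.exit()
  grDevices::dev.off()
  if (format == "svg") canonicalize_svg(out_path)
  invisible(out_path)
}

draw_joint_center <- function(mat, spec) {
  props <- spec$center$props
  clamp <- if (!is.null(props$min_value) && !is.null(props$max_value)) {
    c(props$min_value, props$max_value)
  } else NULL
  mpt <- matrix_panel_transform(mat, style = "square",
                                scale = props$scale %||% "log1p",
                                cmap = props$cmap %||% "reds",
                                clamp = clamp)
  rh <- spec$range_h; rv <- spec$range_v
  grid::pushViewport(grid::viewport(
    xscale = c(rh$start, rh$end + 1),
    yscale = c(rv$end + 1, rv$start),  # rows run top to bottom
    clip = "on"
  ))
  ax_r <- mat$row_axis; ax_c <- mat$col_axis
  for (i in seq_len(ax_r$n_bins)) {
    cols <- mpt$colors[i, ]
    ok <- !is.na(cols)
    if (!any(ok)) next
    yc <- (ax_r$starts[i] + ax_r$ends[i] + 1) / 2
    grid::grid.rect(x = grid::unit(ax_c$starts[ok], "native"),
                    y = grid::unit(rep(yc, sum(ok)), "native"),
                    width = grid::unit(ax_c$ends[ok] + 1 - ax_c$starts[ok], "native"),
                    height = grid::unit(rep(ax_r$ends[i] + 1 - ax_r$starts[i],
                                            sum(ok)), "native"),
                    just = c("left", "centre"),
                    gp = grid::gpar(fill = cols[ok], col = NA))
  }
  draw_colorbar_strip(mpt$colorbar)
  grid::popViewport()
}
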