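# Frame rendering: deterministic layout and drawing to PNG/JPEG/PDF/SVG.

#' Layout plan of a frame
#'
#' Computes the vertical panel layout before drawing: one panel per track,
#' y-extent proportional to `props$height` (in inches), panels tiling the
#' figure without overlap under a shared x transform.  Exposed so tests and
#' users can assert on geometry without decoding images.
#'
#' @param frame A [frame()].
#' @return List with `width`, `height` (inches) and a `panels` tibble
#'   (`track_id`, `track_type`, `height`, `y_top`, `y_bottom`, measured in
#'   inches from the top of the figure).
#' @export
layout_frame <- function(frame) {
  stopifnot(inherits(frame, "tk_frame"))
  if (!length(frame$tracks)) stop("cannot lay out an empty frame", call. = FALSE)
  heights <- vapply(frame$tracks, function(t) as.numeric(t$props$height), 1.0)
  margin <- 0.12
  y_top <- margin + cumsum(c(0, heights[-length(heights)]))
  panels <- tibble::tibble(
    track_id = vapply(frame$tracks, `[[`, "", "track_id"),
    track_type = vapply(frame$tracks, `[[`, "", "track_type"),
    height = heights,
    y_top = y_top,
    y_bottom = y_top + heights
  )
  list(width = frame$frame_props$width %||% 6,
       height = sum(heights) + 2 * margin,
       panels = panels)
}

supported_formats <- c("svg", "png", "jpeg", "pdf")

infer_format <- function(out_path, format) {
  if (!is.null(format)) {
    format <- match.arg(format, supported_formats)
    return(format)
  }
  ext <- tolower(tools::file_ext(out_path))
  if (ext == "jpg") ext <- "jpeg"
  if (!ext %in% supported_formats) {
    stop("cannot infer output format from '", out_path,
         "'; pass format = one of ", paste(supported_formats, collapse = "/"),
         call. = FALSE)
  }
  ext
}

open_device <- function(path, format, width, height, dpi) {
  switch(format,
    svg = grDevices::svg(path, width = width, height = height),
    png = grDevices::png(path, width = width, height = height,
                         units = "in", res = dpi, type = "cairo"),
    jpeg = grDevices::jpeg(path, width = width, height = height,
                           units = "in", res = dpi, quality = 95,
                           type = "cairo"),
    pdf = grDevices::pdf(path, width = width, height = height,
                         onefile = TRUE, useDingbats = FALSE)
  )
}

#' Canonicalize an SVG file
#'
#' Normalizes an SVG so identical drawing input gives byte-identical
#' output: strips comments, metadata and date elements, and rewrites the
#' file with LF line endings and a trailing newline.
#'
#' @param path SVG file, rewritten in place.
#' @return `path`, invisibly.
#' @export
canonicalize_svg <- function(path) {
  txt <- readLines(path, warn = FALSE)
  drop <- grepl("^\\s*<!--", txt) | grepl("dc:date|<metadata|</metadata", txt)
  txt <- txt[!drop]
  # embedded images carry process-global "source-N" ids; renumber them in
  # order of first appearance so identical drawings give identical bytes
  ids <- unlist(regmatches(txt, gregexpr("source-[0-9]+", txt)))
  ids <- unique(ids)
  if (length(ids)) {
    one <- paste(txt, collapse = "\n")
    for (k in seq_along(ids)) {
      one <- gsub(paste0(ids[k], "\\b"), sprintf("csource-%d", k), one)
    }
    one <- gsub("csource-", "source-", one, fixed = TRUE)
    txt <- strsplit(one, "\n", fixed = TRUE)[[1]]
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(txt, con, sep = "\n")
  invisible(path)
}

panel_frame_color <- "#d0d0d0"
undecorated_types <- c("XAxis", "Spacer")

draw_error_panel <- function(message) {
  grid::grid.rect(gp = grid::gpar(fill = "#f2f2f2", col = "#bbbbbb"))
  grid::grid.text(paste("fetch error:", substr(message, 1, 90)),
                  gp = grid::gpar(cex = 0.5, col = "#b2182b"))
}

# Draws a frame's panels inside the current viewport.  `results` must be
# the frame_fetch_all() output for `range`; rendering consumes only these
# payloads (the figure/data coupling contract).
draw_frame_region <- function(frame, range, results, plan) {
  total <- plan$height
  for (k in seq_len(nrow(plan$panels))) {
    track <- frame$tracks[[k]]
    p <- plan$panels[k, ]
    vp <- grid::viewport(
      x = grid::unit(0.5, "npc"),
      y = grid::unit(1 - (p$y_top + p$height / 2) / total, "npc"),
      width = grid::unit(1, "npc"),
      height = grid::unit(p$height / total, "npc")
    )
    grid::pushViewport(vp)
    # title + frame live in a margin column, the data panel to its right
    label_w <- 0.09
    if (nzchar(track$props$title %||% "")) {
      grid::pushViewport(grid::viewport(x = grid::unit(0, "npc"),
                                        width = grid::unit(label_w, "npc"),
                                        just = "left"))
      grid::grid.text(track$props$title, rot = 90,
                      gp = grid::gpar(cex = 0.55, col = "#333333"))
      grid::popViewport()
    }
    grid::pushViewport(grid::viewport(
      x = grid::unit(label_w, "npc"), just = "left",
      width = grid::unit(1 - label_w - 0.01, "npc")
    ))
    res <- results[[track$track_id]]
    if (inherits(res, "tk_fetch_error")) {
      draw_error_panel(res$message)
    } else {
      if (!track$track_type %in% undecorated_types) {
        grid::grid.rect(gp = grid::gpar(fill = NA, col = panel_frame_color,
                                        lwd = 0.5))
      }
      entry <- registry_entry(track$track_type)
      entry$draw(res$payload, track, range)
      for (cov in track$coverages) draw_coverage(cov, track, range)
    }
    grid::popViewport(2)
  }
  invisible()
}

#' Render a frame to a figure file
#'
#' Fetches every track's data for `range` and draws the panels top-to-bottom
#' in composition order under a shared x-axis.  Output is deterministic:
#' the same frame and range give byte-identical SVG (canonicalized via
#' [canonicalize_svg()]) and pixel-identical raster output.  A track whose
#' fetch fails renders as an error placeholder panel unless
#' `strict = TRUE`, in which case no file is produced and the error is
#' raised.
#'
#' @param frame A [frame()] (a single track is promoted automatically).
#' @param range Region to draw ([genome_range()] or string); defaults to
#'   the frame's current range.
#' @param out_path Output file; extension picks the format unless `format`
#'   is given.
#' @param format `"svg"`, `"png"`, `"jpeg"` or `"pdf"`.
#' @param dpi Raster resolution (png/jpeg).
#' @param strict Raise fetch errors instead of drawing placeholders.
#' @return `out_path`, invisibly.
#' @export
render_frame <- function(frame, range = NULL, out_path, format = NULL,
                         dpi = 96, strict = FALSE) {
  if (inherits(frame, "tk_track")) frame <- frame(list(frame))
  stopifnot(inherits(frame, "tk_frame"))
  range <- range %||% frame$current_range
  if (is.null(range)) {
    stop("no region set: pass `range` or navigate the frame first", call. = FALSE)
  }
  range <- parse_region(range)
  format <- infer_format(out_path, format)
  results <- frame_fetch_all(frame, range)
  errs <- purrr::keep(results, inherits, "tk_fetch_error")
  if (strict && length(errs)) {
    stop("fetch failed for track(s) ",
         paste(vapply(errs, `[[`, "", "track_id"), collapse = ", "), ": ",
         errs[[1]]$message, call. = FALSE)
  }
  plan <- layout_frame(frame)
  open_device(out_path, format, plan$width, plan$height, dpi)
  ok <- FALSE
  on.exit({
    grDevices::dev.off()
    if (!ok && file.exists(out_path)) unlink(out_path)
  })
  grid::grid.newpage()
  draw_frame_region(frame, range, results, plan)
  ok <- TRUE
  on.exit()
  grDevices::dev.off()
  if (format == "svg") canonicalize_svg(out_path)
  invisible(out_path)
}
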