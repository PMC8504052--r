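#' Browser-style navigation over a frame
#'
#' A browser state couples a [frame()] with a current range, chromosome
#' sizes and a navigation history.  Navigation is pure: each operation
#' returns a new state, and rendering a state is exactly a fresh
#' [render_frame()] of its frame at its current range — byte-identical
#' output, no hidden state.
#'
#' @param frame A [frame()].
#' @param region Initial region ([genome_range()] or string).
#' @param chromsizes Named vector of chromosome lengths (see
#'   [read_chrom_sizes()]); used to clamp navigation and expand bare
#'   chromosome names.
#' @return An object of class `tk_browser`.
#' @export
browser_state <- function(frame, region, chromsizes = NULL) {
  stopifnot(inherits(frame, "tk_frame"))
  range <- parse_region(region, chromsizes)
  structure(
    list(frame = frame, range = range, chromsizes = chromsizes,
         history = list(range)),
    class = "tk_browser"
  )
}

#' @export
print.tk_browser <- function(x, ...) {
  cat("<browser> @ ", format(x$range), " (", length(x$history),
      " step(s) of history)\n", sep = "")
  print(x$frame)
  invisible(x)
}

navigate <- function(state, range) {
  state$range <- range
  state$history <- c(state$history, list(range))
  state
}

#' Jump to a region
#'
#' @param state A [browser_state()].
#' @param region Target region (string or [genome_range()]).
#' @return A new `tk_browser` with the range updated and history appended.
#'   A parse/validation error is raised before any state is produced, so
#'   the caller's state is unchanged.
#' @export
browser_goto <- function(state, region) {
  stopifnot(inherits(state, "tk_browser"))
  navigate(state, parse_region(region, state$chromsizes))
}

#' Zoom about the current center
#'
#' @param state A [browser_state()].
#' @param fold Positive zoom factor (`> 1` zooms in); see [zoom_range()].
#' @return A new `tk_browser`.
#' @export
browser_zoom <- function(state, fold) {
  stopifnot(inherits(state, "tk_browser"))
  navigate(state, zoom_range(state$range, fold, state$chromsizes))
}

#' Slide along the chromosome
#'
#' @param state A [browser_state()].
#' @param frac Shift as a fraction of the current span (negative = left);
#'   see [shift_range()].
#' @return A new `tk_browser`.
#' @export
browser_shift <- function(state, frac) {
  stopifnot(inherits(state, "tk_browser"))
  navigate(state, shift_range(state$range, frac, state$chromsizes))
}

#' Render the current view of a browser state
#'
#' Equivalent to `render_frame(state$frame, state$range, ...)`.
#'
#' @param state A [browser_state()].
#' @param out_path,format,dpi,strict See [render_frame()].
#' @return The output path, invisibly.
#' @export
render_browser <- function(state, out_path, format = NULL, dpi = 96,
                           strict = FALSE) {
  stopifnot(inherits(state, "tk_browser"))
  render_frame(state$frame, state$range, out_path, format = format,
               dpi = dpi, strict = strict)
}
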