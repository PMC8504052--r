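#' Figure composition with `+`
#'
#' Tracks, frames, features and coverages combine with the `+` operator
#' (or the functional spelling [compose()]) into figures, ggplot2-style:
#'
#' * `track + track` makes a two-track [frame()];
#' * `frame + track` appends; `frame + frame` concatenates;
#' * `x + feature(...)` patches style properties — by default of the
#'   preceding track, or of every track with `scope = "all"`;
#' * `x + coverage(...)` overlays an extra layer on the preceding track.
#'
#' Composition never mutates its operands: every combination returns a new
#' value, so a track reused in two frames keeps independent styling.
#'
#' @param left,right Tracks, frames, features or coverages.
#' @return A `tk_track` or `tk_frame`.
#' @examples
#' \dontrun{
#' frame <- make_track("XAxis") +
#'   make_track("BedGraph", "signal.bg", color = "#ff0000") +
#'   make_track("GTF", "genes.gtf")
#' }
#' @name composition
NULL

#' Create an empty frame
#'
#' A frame is an ordered vertical stack of tracks sharing one genomic
#' x-axis.  Usually built by composing tracks with `+` rather than called
#' directly.
#'
#' @param tracks List of [make_track()] tracks (order = panel order).
#' @param range Optional current [genome_range()] (set by [browser_goto()]
#'   or the `goto` CLI verb).
#' @param width Figure width in inches.
#' @return An object of class `tk_frame`.
#' @export
frame <- function(tracks = list(), range = NULL, width = 6) {
  tracks <- unname(tracks)
  fr <- structure(
    list(tracks = list(), current_range = range,
         frame_props = list(width = width)),
    class = c("tk_frame", "tk_element")
  )
  for (t in tracks) fr <- frame_append(fr, t)
  fr
}

frame_append <- function(fr, track) {
  stopifnot(inherits(track, "tk_track"))
  ids <- vapply(fr$tracks, `[[`, "", "track_id")
  if (track$track_id %in% ids) {
    # the same track object may appear twice; panels need distinct ids
    k <- 2L
    while (paste0(track$track_id, ".", k) %in% ids) k <- k + 1L
    track$track_id <- paste0(track$track_id, ".", k)
  }
  fr$tracks <- c(fr$tracks, list(track))
  fr
}

#' @export
print.tk_frame <- function(x, ...) {
  cat("<frame> ", length(x$tracks), " track(s)",
      if (!is.null(x$current_range)) paste0(" @ ", format(x$current_range)),
      "\n", sep = "")
  for (t in x$tracks) cat("  - ", t$track_id, " (", t$track_type, ")\n", sep = "")
  invisible(x)
}

#' Style property patch
#'
#' A feature is a key/value style patch applied through composition.  With
#' the default `scope = "previous"` it styles the preceding track (the last
#' track of a frame); `scope = "all"` styles every track of a frame.
#'
#' @param ... Named style properties, e.g. `color = "#0000ff"`,
#'   `min_value = 0`.
#' @param scope `"previous"` (default) or `"all"`.
#' @return An object of class `tk_feature`.
#' @export
feature <- function(..., scope = c("previous", "all")) {
  scope <- match.arg(scope)
  props <- list(...)
  if (!length(props) || is.null(names(props)) || any(names(props) == "")) {
    stop("feature() needs named style properties", call. = FALSE)
  }
  structure(list(props = props, scope = scope),
            class = c("tk_feature", "tk_element"))
}

#' Overlay layer bound to a track
#'
#' A coverage paints an extra layer inside its target track's panel:
#' a highlighted region, vertical guide lines, an arcs overlay, or a custom
#' grid-drawing function.  Bind one with `track + coverage(...)` (or
#' `frame + coverage(...)`, which binds to the frame's last track).
#'
#' @param painter_type One of `"highlight_region"`, `"vlines"`,
#'   `"arcs_overlay"`, `"custom"`.
#' @param ... Painter parameters: `region =` (highlight), `positions =`
#'   (vlines), `path =` (arcs overlay), `fun =` (custom, a
#'   `function(track, range)` drawing in the panel viewport), plus optional
#'   `color =`, `alpha =`.
#' @return An object of class `tk_coverage`.
#' @export
coverage <- function(painter_type = c("highlight_region", "vlines",
                                      "arcs_overlay", "custom"), ...) {
  painter_type <- match.arg(painter_type)
  params <- list(...)
  needed <- switch(painter_type, highlight_region = "region",
                   vlines = "positions", arcs_overlay = "path", custom = "fun")
  if (!needed %in% names(params)) {
    stop("coverage('", painter_type, "') requires a `", needed, "` parameter",
         call. = FALSE)
  }
  structure(list(painter_type = painter_type, params = params),
            class = c("tk_coverage", "tk_element"))
}

element_kind <- function(x) {
  if (inherits(x, "tk_track")) "track"
  else if (inherits(x, "tk_frame")) "frame"
  else if (inherits(x, "tk_feature")) "feature"
  else if (inherits(x, "tk_coverage")) "coverage"
  else class(x)[1]
}

#' Combine two composition elements
#'
#' The functional form of the `+` operator; see [composition] for the
#' combination rules.
#'
#' @param left,right Tracks, frames, features or coverages.
#' @return A `tk_track` or `tk_frame`.
#' @export
compose <- function(left, right) {
  lk <- element_kind(left); rk <- element_kind(right)
  if (lk == "track" && rk == "track") {
    return(frame(list(left, right)))
  }
  if (lk == "track" && rk == "frame") {
    out <- frame(list(left))
    for (t in right$tracks) out <- frame_append(out, t)
    out["current_range"] <- list(right$current_range)
    return(out)
  }
  if (lk == "frame" && rk == "track") {
    return(frame_append(left, right))
  }
  if (lk == "frame" && rk == "frame") {
    out <- left
    for (t in right$tracks) out <- frame_append(out, t)
    return(out)
  }
  if (rk == "feature") {
    if (lk == "track") {
      return(apply_props(left, right$props))
    }
    if (lk == "frame") {
      if (!length(left$tracks)) {
        stop("cannot apply a feature to an empty frame", call. = FALSE)
      }
      idx <- if (right$scope == "all") seq_along(left$tracks) else length(left$tracks)
      for (i in idx) {
        left$tracks[[i]] <- apply_props(left$tracks[[i]], right$props)
      }
      return(left)
    }
  }
  if (rk == "coverage") {
    if (lk == "track") {
      left$coverages <- c(left$coverages, list(right))
      return(left)
    }
    if (lk == "frame") {
      if (!length(left$tracks)) {
        stop("cannot bind a coverage to an empty frame", call. = FALSE)
      }
      n <- length(left$tracks)
      left$tracks[[n]]$coverages <- c(left$tracks[[n]]$coverages, list(right))
      return(left)
    }
  }
  stop("undefined composition: cannot combine a ", lk, " with a ", rk,
       call. = FALSE)
}

#' @export
`+.tk_element` <- function(e1, e2) compose(e1, e2)

#' Fetch the data of every track in a frame
#'
#' One [fetch_track_data()] result per track, keyed by `track_id` — the
#' same payloads the next render of `range` will draw.  Per-track errors
#' are collected, not short-circuited: a failing track contributes a
#' `tk_fetch_error` entry carrying its `track_id` and message.
#'
#' @param frame A [frame()].
#' @param range Query [genome_range()] or region string.
#' @return Named list of `tk_fetch_result` / `tk_fetch_error` entries.
#' @export
frame_fetch_all <- function(frame, range) {
  stopifnot(inherits(frame, "tk_frame"))
  range <- parse_region(range)
  out <- purrr::map(frame$tracks, function(t) {
    tryCatch(fetch_track_data(t, range),
             error = function(e) {
               structure(list(track_id = t$track_id,
                              message = conditionMessage(e)),
                         class = "tk_fetch_error")
             })
  })
  stats::setNames(out, vapply(frame$tracks, `[[`, "", "track_id"))
}
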