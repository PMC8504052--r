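# Track registry and the two-method fetch/draw contract.
#
# A track type is an entry in a package-level registry: a fetch function
# (range -> payload), a draw function (payload -> grid output), per-type
# style defaults and, for types registered with `base = `, an optional
# post-fetch hook so a custom track needs to supply only its novel
# computation — everything else is inherited.

.tk_registry <- new.env(parent = emptyenv())
.tk_cache <- new.env(parent = emptyenv())
.tk_counter <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Register a track type
#'
#' Built-in types are registered at load time; users extend the toolkit by
#' registering a custom type, typically against a built-in `base` so that
#' data fetching and drawing are reused and only the novel post-processing
#' needs to be written.  A type registered with `base` and only a
#' `post_fetch` hook inherits the base's fetch and draw; the hook receives
#' the base payload and returns the (augmented) payload to render.
#'
#' @param type_tag Unique type name (e.g. `"CustomLoops"`).
#' @param fetch `function(track, range)` returning the payload; may be
#'   omitted when `base` is given.
#' @param draw `function(payload, track, range)` drawing into the current
#'   grid viewport; may be omitted when `base` is given.
#' @param base Existing type tag to inherit fetch/draw/defaults from.
#' @param post_fetch Optional `function(payload, track, range)` applied
#'   after the (inherited) fetch.
#' @param defaults Named list of style defaults, merged over the base's.
#' @param overwrite Allow re-registering an existing tag.
#' @return The type tag, invisibly (the registration handle).
#' @examples
#' \dontrun{
#' register_track_type("MaxSignal", base = "BedGraph",
#'   post_fetch = function(payload, track, range) {
#'     payload$value <- cummax(payload$value); payload
#'   })
#' }
#' @export
register_track_type <- function(type_tag, fetch = NULL, draw = NULL,
                                base = NULL, post_fetch = NULL,
                                defaults = list(), overwrite = FALSE) {
  stopifnot(is.character(type_tag), length(type_tag) == 1L, nzchar(type_tag))
  if (!overwrite && exists(type_tag, envir = .tk_registry, inherits = FALSE)) {
    stop("track type '", type_tag, "' is already registered", call. = FALSE)
  }
  base_entry <- NULL
  if (!is.null(base)) {
    base_entry <- registry_entry(base)
    fetch <- fetch %||% base_entry$fetch
    draw <- draw %||% base_entry$draw
    defaults <- utils::modifyList(base_entry$defaults, defaults)
  }
  if (is.null(fetch) || is.null(draw)) {
    stop("track type '", type_tag,
         "' needs both a fetch and a draw function (directly or via `base`)",
         call. = FALSE)
  }
  assign(type_tag,
         list(type = type_tag, fetch = fetch, draw = draw,
              post_fetch = post_fetch, defaults = defaults, base = base),
         envir = .tk_registry)
  invisible(type_tag)
}

registry_entry <- function(type_tag) {
  if (!exists(type_tag, envir = .tk_registry, inherits = FALSE)) {
    stop("unregistered track type '", type_tag, "'; known types: ",
         paste(sort(registered_track_types()), collapse = ", "), call. = FALSE)
  }
  get(type_tag, envir = .tk_registry, inherits = FALSE)
}

#' List registered track types
#' @return Character vector of type tags.
#' @export
registered_track_types <- function() ls(.tk_registry)

#' Per-type default style properties
#'
#' The documented defaults a [make_track()] call starts from; part of the
#' package interface (frozen in a fixture test so they cannot drift
#' silently).
#'
#' @param type_tag Registered type tag.
#' @return Named list of default properties.
#' @export
track_defaults <- function(type_tag) registry_entry(type_tag)$defaults

# ---- style property validation ------------------------------------------

known_style_keys <- c("color", "height", "alpha", "style", "min_value",
                      "max_value", "title")

valid_color <- function(x) {
  is.character(x) && length(x) == 1L &&
    (grepl("^#[0-9a-fA-F]{6}([0-9a-fA-F]{2})?$", x) || x %in% grDevices::colors())
}

validate_prop <- function(key, value, style_levels = NULL) {
  bad <- function(why) {
    stop("invalid value for style property '", key, "': ", why, call. = FALSE)
  }
  switch(key,
    color = if (!valid_color(value)) bad("not a hex string or named color"),
    height = if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
                 value <= 0) bad("must be a positive number"),
    alpha = if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
                value < 0 || value > 1) bad("must be in [0, 1]"),
    style = if (!is.null(style_levels) && !value %in% style_levels)
              bad(paste0("must be one of ", paste(style_levels, collapse = ", "))),
    min_value = ,
    max_value = if (!is.numeric(value) || length(value) != 1L || is.na(value))
                  bad("must be a single number"),
    title = if (!is.character(value) || length(value) != 1L) bad("must be a string"),
    NULL  # open extra keys: preserved, never dropped
  )
  invisible(value)
}

style_levels_for <- function(type_tag) {
  switch(type_tag,
    HiCMat = , HiCDiff = c("triangular", "square"),
    BED = , GTF = c("gene", "tile"),
    NULL
  )
}

apply_props <- function(track, new_props) {
  for (key in names(new_props)) {
    validate_prop(key, new_props[[key]], style_levels_for(track$track_type))
  }
  track$props <- utils::modifyList(track$props, new_props)
  track
}

# ---- track construction --------------------------------------------------

next_track_id <- function(type_tag) {
  n <- (.tk_counter[[type_tag]] %||% 0L) + 1L
  .tk_counter[[type_tag]] <- n
  paste0(type_tag, ".", n)
}

sourceless_types <- c("XAxis", "Spacer")

#' Create a track
#'
#' The low-level plot element: a registered type tag, a data source and a
#' set of style properties (unknown keys are preserved for track-specific
#' options).  Tracks are composed into frames with `+`; see
#' [compose()].
#'
#' @param track_type Registered type tag (`"XAxis"`, `"Spacer"`,
#'   `"BedGraph"`, `"BigWig"`, `"BED"`, `"GTF"`, `"Arcs"`, `"HiCMat"`,
#'   `"Virtual4C"`, `"DiScore"`, `"InsuScore"`, `"HiCDiff"`, `"SNP"`, or a
#'   custom tag).
#' @param source Data source path(s); analytic tracks take a contact-matrix
#'   source, `HiCDiff` a list/vector of two.  `NULL` for `XAxis`/`Spacer`.
#' @param ... Style properties (`color =`, `height =`, `title =`, ...), plus
#'   track-specific options (e.g. `anchor =` for `Virtual4C`, `window =`
#'   for `DiScore`/`InsuScore`).
#' @param track_id Optional explicit id; defaults to `"<type>.<n>"`.
#' @return An object of class `tk_track`.
#' @examples
#' \dontrun{
#' make_track("BedGraph", "signal.bg", color = "#ff0000", height = 2)
#' }
#' @export
make_track <- function(track_type, source = NULL, ..., track_id = NULL) {
  entry <- registry_entry(track_type)
  check_source_readable(track_type, source)
  track <- structure(
    list(track_id = track_id %||% next_track_id(track_type),
         track_type = track_type,
         source = source,
         props = entry$defaults,
         coverages = list()),
    class = c("tk_track", "tk_element")
  )
  apply_props(track, list(...))
}

check_source_readable <- function(track_type, source) {
  if (is.null(source)) {
    if (!track_type %in% sourceless_types) {
      stop("track type '", track_type, "' requires a data source", call. = FALSE)
    }
    return(invisible())
  }
  paths <- unlist(source, use.names = FALSE)
  # matrix sources may be "matrix,bins" composites
  paths <- unlist(strsplit(paths, ",", fixed = TRUE))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("track source not readable: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible()
}

#' @export
print.tk_track <- function(x, ...) {
  src <- if (is.null(x$source)) "" else paste0(" <- ", paste(unlist(x$source), collapse = " + "))
  cat("<track ", x$track_id, "> ", x$track_type, src, "\n", sep = "")
  if (length(x$coverages)) cat("  coverages: ", length(x$coverages), "\n", sep = "")
  invisible(x)
}

# ---- fetch ---------------------------------------------------------------

source_mtimes <- function(source) {
  if (is.null(source)) return(numeric())
  paths <- unlist(strsplit(unlist(source, use.names = FALSE), ",", fixed = TRUE))
  paths <- paths[file.exists(paths)]
  as.numeric(file.mtime(paths))
}

fetch_cache_key <- function(track, range) {
  paste(track$track_id, format(range),
        paste(deparse(track$props), collapse = ""),
        paste(unlist(track$source), collapse = ","), sep = "|")
}

#' Fetch the exact data a track will draw for a range
#'
#' Delegates to the reader/analytic operation matching the track type and
#' wraps the payload with its provenance, so figures and the data behind
#' them stay coupled: the renderer consumes exactly this payload.  Results
#' are cached keyed on (track, range, parameters) until a source file's
#' modification time changes.
#'
#' @param track A [make_track()] track.
#' @param range Query [genome_range()] or region string.
#' @return A `tk_fetch_result`: list with `track_id`, `range`, `payload`
#'   and `provenance` (source paths + parameters).
#' @export
fetch_track_data <- function(track, range) {
  stopifnot(inherits(track, "tk_track"))
  range <- parse_region(range)
  key <- fetch_cache_key(track, range)
  mt <- source_mtimes(track$source)
  hit <- .tk_cache[[key]]
  if (!is.null(hit) && identical(hit$mtimes, mt)) {
    return(hit$result)
  }
  entry <- registry_entry(track$track_type)
  payload <- tryCatch(
    entry$fetch(track, range),
    error = function(e) {
      stop("track '", track$track_id, "' (", track$track_type, "): ",
           conditionMessage(e), call. = FALSE)
    }
  )
  if (!is.null(entry$post_fetch)) {
    payload <- entry$post_fetch(payload, track, range)
  }
  result <- structure(
    list(track_id = track$track_id, range = range, payload = payload,
         provenance = list(source = track$source, track_type = track$track_type,
                           props = track$props)),
    class = "tk_fetch_result"
  )
  .tk_cache[[key]] <- list(result = result, mtimes = mt)
  result
}

#' @export
print.tk_fetch_result <- function(x, ...) {
  cat("<fetch_result> ", x$track_id, " @ ", format(x$range), "\n", sep = "")
  if (inherits(x$payload, "tbl_df")) {
    print(x$payload, n = 5)
  } else if (!is.null(x$payload)) {
    print(x$payload)
  } else {
    cat("  (no payload)\n")
  }
  invisible(x)
}

clear_fetch_cache <- function() {
  rm(list = ls(.tk_cache), envir = .tk_cache)
}
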