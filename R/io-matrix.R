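#' Contact matrices
#'
#' A `contact_matrix` holds a dense, binned window of a Hi-C contact map:
#' a numeric matrix whose rows and columns are annotated with
#' [range_to_bins()] axes.  On-diagonal windows (identical row and column
#' axes) are symmetric; absent contacts are 0 and masked entries are `NaN`.
#'
#' @param values Numeric matrix, `row_axis$n_bins` x `col_axis$n_bins`.
#' @param row_axis,col_axis `bin_axis` objects annotating rows and columns.
#' @return An object of class `contact_matrix` with fields `values`,
#'   `row_axis`, `col_axis`, `resolution`.
#' @export
contact_matrix <- function(values, row_axis, col_axis = row_axis) {
  stopifnot(is.matrix(values), inherits(row_axis, "bin_axis"),
            inherits(col_axis, "bin_axis"))
  if (nrow(values) != row_axis$n_bins || ncol(values) != col_axis$n_bins) {
    stop("matrix is ", nrow(values), "x", ncol(values),
         " but axes have ", row_axis$n_bins, "/", col_axis$n_bins, " bins",
         call. = FALSE)
  }
  if (row_axis$resolution != col_axis$resolution) {
    stop("row and column axes have different resolutions", call. = FALSE)
  }
  fin <- values[is.finite(values)]
  if (length(fin) && any(fin < 0)) {
    # differential/z-scored matrices are built internally and bypass this
    stop("contact counts must be non-negative", call. = FALSE)
  }
  new_contact_matrix(values, row_axis, col_axis)
}

# internal constructor without the non-negativity check (z-scores, diffs)
new_contact_matrix <- function(values, row_axis, col_axis = row_axis) {
  structure(
    list(values = values, row_axis = row_axis, col_axis = col_axis,
         resolution = row_axis$resolution),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("<contact_matrix> ", nrow(x$values), "x", ncol(x$values),
      " bins @ ", format(x$resolution, scientific = FALSE), " bp\n",
      "  rows: ", format(x$row_axis$range), "\n",
      "  cols: ", format(x$col_axis$range), "\n", sep = "")
  invisible(x)
}

#' @export
dim.contact_matrix <- function(x) dim(x$values)

is_square_matrix <- function(m) axes_identical(m$row_axis, m$col_axis)

#' @export
#' @method as_tibble contact_matrix
as_tibble.contact_matrix <- function(x, ...) {
  n_r <- nrow(x$values); n_c <- ncol(x$values)
  tibble::tibble(
    row_bin = rep(seq_len(n_r), times = n_c),
    col_bin = rep(seq_len(n_c), each = n_r),
    row_start = rep(x$row_axis$starts, times = n_c),
    col_start = rep(x$col_axis$starts, each = n_r),
    value = as.vector(x$values)
  )
}

# Resolve a HiC-Pro source spec into matrix + bins paths.  Accepted forms:
# c(matrix=..., bins=...), c(matrix_path, bins_path), "matrix_path,bins_path",
# or a single ".matrix" path with a sibling "<prefix>_abs.bed".
resolve_matrix_source <- function(source) {
  if (is.list(source)) source <- unlist(source)
  if (length(source) == 1L && grepl(",", source, fixed = TRUE)) {
    source <- strsplit(source, ",", fixed = TRUE)[[1]]
  }
  if (length(source) == 2L) {
    if (!is.null(names(source)) && all(c("matrix", "bins") %in% names(source))) {
      return(list(matrix = unname(source[["matrix"]]), bins = unname(source[["bins"]])))
    }
    return(list(matrix = source[[1]], bins = source[[2]]))
  }
  if (length(source) != 1L) {
    stop("matrix source must be one or two paths", call. = FALSE)
  }
  if (grepl("\\.cool$|\\.mcool$", source)) {
    stop("cooler containers ('", source, "') are not supported by this build; ",
         "convert to the HiC-Pro sparse text format (bins BED + triplets)",
         call. = FALSE)
  }
  bins <- c(sub("\\.matrix$", "_abs.bed", source),
            sub("\\.matrix$", ".bed", source))
  bins <- bins[bins != source & file.exists(bins)]
  if (!length(bins)) {
    stop("cannot locate the bins BED for '", source,
         "'; pass source = c(matrix, bins)", call. = FALSE)
  }
  list(matrix = source, bins = bins[[1]])
}

read_hicpro_bins <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read bins table '", path, "'", call. = FALSE)
  }
  txt <- readr::read_lines(path, progress = FALSE)
  txt <- txt[!is_comment_line(txt) & nzchar(trimws(txt))]
  fields <- split_fields(txt)
  check_min_fields(fields, 4L, path, seq_along(txt))
  n <- length(fields)
  bins <- tibble::tibble(
    chrom = vapply(fields, `[[`, "", 1L),
    start = as.numeric(vapply(fields, `[[`, "", 2L)) + 1,  # 0-based half-open in
    end = as.numeric(vapply(fields, `[[`, "", 3L)),
    id = as.integer(vapply(fields, `[[`, "", 4L))
  )
  has_weight <- all(vapply(fields, length, 1L) >= 5L)
  bins$weight <- if (has_weight) {
    suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  } else NA_real_
  attr(bins, "has_weight") <- has_weight
  bins
}

#' Read a window of a HiC-Pro sparse contact matrix
#'
#' The source is a HiC-Pro style pair of text files: a bins BED
#' (`chrom start end bin_id [weight]`, 0-based half-open, 1-based bin ids)
#' plus upper-triangle triplets (`bin1 bin2 count`).  The dense window over
#' `range_row` x `range_col` is returned; requested ranges are expanded
#' outward to the file's bin grid, absent triplets become 0, and an
#' on-diagonal window (identical ranges) is symmetrized.  With
#' `balanced = TRUE` entry `(i, j)` is multiplied by `weight_i * weight_j`
#' (a weight column must exist); non-finite weights give `NaN` entries.
#'
#' @param source Matrix source: `.matrix` path with a sibling `_abs.bed`
#'   bins file, `c(matrix, bins)`, or `"matrix,bins"`.
#' @param range_row,range_col Row/column query ranges ([genome_range()] or
#'   region strings); `range_col` defaults to `range_row`.
#' @param resolution Expected bin size in bp; must equal the file's bin
#'   size.  `NULL` (default) accepts the file's bin size.
#' @param balanced Apply balancing weights from the bins table.
#' @return A [contact_matrix()].
#' @export
read_contact_matrix <- function(source, range_row, range_col = NULL,
                                resolution = NULL, balanced = FALSE) {
  src <- resolve_matrix_source(source)
  range_row <- parse_region(range_row)
  range_col <- if (is.null(range_col)) range_row else parse_region(range_col)
  bins <- read_hicpro_bins(src$bins)

  widths <- bins$end - bins$start + 1
  file_res <- max(widths)  # last bin of each chromosome may be partial
  if (!is.null(resolution) && resolution != file_res) {
    stop("requested resolution ", format(resolution, scientific = FALSE),
         " does not match the file bin size ",
         format(file_res, scientific = FALSE), " of '", src$bins, "'",
         call. = FALSE)
  }

  select_bins <- function(range) {
    sel <- bins[overlaps_range(bins$chrom, bins$start, bins$end, range), ]
    if (!nrow(sel)) {
      stop("no bins of '", src$bins, "' overlap ", format(range), call. = FALSE)
    }
    sel
  }
  row_bins <- select_bins(range_row)
  col_bins <- select_bins(range_col)
  axis_of <- function(sel) {
    range_to_bins(genome_range(sel$chrom[1], min(sel$start), max(sel$end)), file_res)
  }
  row_axis <- axis_of(row_bins)
  col_axis <- axis_of(col_bins)
  same <- identical(row_bins$id, col_bins$id)

  n_r <- nrow(row_bins); n_c <- nrow(col_bins)
  values <- matrix(0, n_r, n_c)
  row_pos <- stats::setNames(seq_len(n_r), row_bins$id)
  col_pos <- stats::setNames(seq_len(n_c), col_bins$id)

  if (!file.exists(src$matrix)) {
    stop("cannot read triplet matrix '", src$matrix, "'", call. = FALSE)
  }
  trip <- readr::read_tsv(src$matrix,
                          col_names = c("bin1", "bin2", "count"),
                          col_types = "iid", progress = FALSE)
  if (any(is.na(trip$bin1)) || any(is.na(trip$bin2)) || any(!is.finite(trip$count))) {
    stop("format error in '", src$matrix, "': malformed triplet", call. = FALSE)
  }
  max_id <- max(bins$id)
  if (nrow(trip) && (max(trip$bin1, trip$bin2) > max_id || min(trip$bin1, trip$bin2) < 1)) {
    stop("format error in '", src$matrix, "': bin id outside the bins table (1..",
         max_id, ")", call. = FALSE)
  }

  fill <- function(b1, b2, count) {
    i <- row_pos[as.character(b1)]
    j <- col_pos[as.character(b2)]
    ok <- !is.na(i) & !is.na(j)
    values[cbind(i[ok], j[ok])] <<- count[ok]
  }
  fill(trip$bin1, trip$bin2, trip$count)
  fill(trip$bin2, trip$bin1, trip$count)  # mirror (upper-triangle storage)

  if (balanced) {
    if (!isTRUE(attr(bins, "has_weight"))) {
      stop("balanced = TRUE but '", src$bins, "' has no weight column",
           call. = FALSE)
    }
    w <- outer(row_bins$weight, col_bins$weight)
    values <- values * w
    values[!is.finite(w)] <- NaN
  }
  if (same) values[lower.tri(values)] <- t(values)[lower.tri(values)]
  out <- new_contact_matrix(values, row_axis, if (same) row_axis else col_axis)
  out
}

#' Aggregate scored intervals onto a bin axis
#'
#' Per display bin, combines the values of the intervals overlapping it:
#' `mean` is the coverage-weighted mean over covered bases, `max`/`min` the
#' extreme value among overlapping intervals, `sum` the base-weighted total
#' (value times covered bases).  Bins covered by no interval yield
#' `empty_value` (0 by default, so histograms have no gaps).
#'
#' @param intervals Tibble as returned by [read_scored_intervals()].
#' @param axis A [range_to_bins()] axis.
#' @param stat Aggregation statistic.
#' @param empty_value Value for bins with zero coverage.
#' @return Numeric vector of length `axis$n_bins`.
#' @export
bin_signal <- function(intervals, axis, stat = c("mean", "max", "min", "sum"),
                       empty_value = 0) {
  stat <- match.arg(stat)
  stopifnot(inherits(axis, "bin_axis"))
  n <- axis$n_bins
  wsum <- numeric(n); cov <- numeric(n)
  vmax <- rep(-Inf, n); vmin <- rep(Inf, n)
  rng <- axis$range
  res <- axis$resolution
  for (k in seq_len(nrow(intervals))) {
    if (!identical(intervals$chrom[k], rng$chrom)) next
    s <- max(intervals$start[k], rng$start)
    e <- min(intervals$end[k], rng$end)
    if (s > e) next
    v <- intervals$value[k]
    b0 <- floor((s - rng$start) / res) + 1
    b1 <- floor((e - rng$start) / res) + 1
    for (b in b0:b1) {
      os <- max(s, axis$starts[b]); oe <- min(e, axis$ends[b])
      len <- oe - os + 1
      wsum[b] <- wsum[b] + v * len
      cov[b] <- cov[b] + len
      vmax[b] <- max(vmax[b], v)
      vmin[b] <- min(vmin[b], v)
    }
  }
  out <- switch(stat,
    mean = ifelse(cov > 0, wsum / cov, empty_value),
    sum = ifelse(cov > 0, wsum, empty_value),
    max = ifelse(cov > 0, vmax, empty_value),
    min = ifelse(cov > 0, vmin, empty_value)
  )
  as.numeric(out)
}
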