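#' Genomic ranges, binning and browser-style navigation
#'
#' A `genome_range` is the universal query key of the package: a 1-based,
#' fully inclusive interval on a named chromosome. All on-disk half-open
#' formats (BED, bedGraph, BEDPE) are converted to this convention at the
#' reader boundary, so a range of length 1 is `start == end`.
#'
#' @param chrom Chromosome name (single string, no whitespace).
#' @param start,end 1-based inclusive base positions, `1 <= start <= end`.
#' @return An object of class `genome_range` with fields `chrom`, `start`,
#'   `end`.
#' @examples
#' genome_range("chr1", 1000, 2000)
#' parse_region("chr1:1,000-2,000")
#' @export
genome_range <- function(chrom, start, end) {
  if (!is.character(chrom) || length(chrom) != 1L || is.na(chrom) ||
      chrom == "" || grepl("\\s", chrom)) {
    stop("`chrom` must be a single non-empty string without whitespace", call. = FALSE)
  }
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(start) != 1L || length(end) != 1L || is.na(start) || is.na(end)) {
    stop("`start` and `end` must be single non-missing numbers", call. = FALSE)
  }
  if (start < 1) {
    stop("invalid range: start must be >= 1 (got ", start, ")", call. = FALSE)
  }
  if (end < start) {
    stop("invalid range: end (", end, ") < start (", start, ")", call. = FALSE)
  }
  structure(
    list(chrom = chrom, start = as.double(round(start)), end = as.double(round(end))),
    class = "genome_range"
  )
}

#' @export
format.genome_range <- function(x, ...) {
  sprintf("%s:%s-%s", x$chrom,
          format(x$start, scientific = FALSE, trim = TRUE),
          format(x$end, scientific = FALSE, trim = TRUE))
}

#' @export
print.genome_range <- function(x, ...) {
  cat("<genome_range> ", format(x), "  (", format(range_length(x), big.mark = ","),
      " bp)\n", sep = "")
  invisible(x)
}

#' @export
as.character.genome_range <- function(x, ...) format(x)

#' @export
`==.genome_range` <- function(e1, e2) {
  identical(e1$chrom, e2$chrom) && e1$start == e2$start && e1$end == e2$end
}

#' Length of a genomic range in base pairs
#'
#' @param range A [genome_range()].
#' @return Integer-valued length `end - start + 1` (always positive).
#' @export
range_length <- function(range) {
  stopifnot(inherits(range, "genome_range"))
  range$end - range$start + 1
}

is_genome_range <- function(x) inherits(x, "genome_range")

#' Parse a region string
#'
#' Accepts the genome-browser grammar `chrom` or `chrom:start-end`; commas
#' used as thousands separators are ignored. A bare chromosome name expands
#' to the full chromosome when `chromsizes` is supplied.
#'
#' @param text Region string such as `"chr9:4,000,000-6000000"` or `"chr1"`,
#'   or an existing [genome_range()] (returned unchanged).
#' @param chromsizes Optional named vector of chromosome lengths
#'   (see [read_chrom_sizes()]); required to expand a bare chromosome name
#'   and used to validate chromosome membership when present.
#' @return A [genome_range()].
#' @examples
#' parse_region("chr9:4000000-6000000")
#' parse_region("chr1", chromsizes = c(chr1 = 5000))
#' @export
parse_region <- function(text, chromsizes = NULL) {
  if (is_genome_range(text)) return(text)
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("region must be a single string", call. = FALSE)
  }
  text <- trimws(text)
  if (grepl(":", text, fixed = TRUE)) {
    m <- regmatches(text, regexec("^([^:[:space:]]+):([0-9,]+)-([0-9,]+)$", text))[[1]]
    if (length(m) != 4L) {
      stop("cannot parse region string '", text,
           "': expected 'chrom' or 'chrom:start-end'", call. = FALSE)
    }
    start <- as.numeric(gsub(",", "", m[3], fixed = TRUE))
    end <- as.numeric(gsub(",", "", m[4], fixed = TRUE))
    rng <- genome_range(m[2], start, end)
  } else {
    if (!grepl("^[^:[:space:]]+$", text)) {
      stop("cannot parse region string '", text, "'", call. = FALSE)
    }
    if (is.null(chromsizes)) {
      stop("bare chromosome '", text,
           "' requires `chromsizes` to expand to the full chromosome", call. = FALSE)
    }
    len <- chrom_length(chromsizes, text)
    rng <- genome_range(text, 1, len)
  }
  if (!is.null(chromsizes)) {
    len <- chrom_length(chromsizes, rng$chrom)
    if (rng$end > len) {
      stop("region ", format(rng), " extends past end of ", rng$chrom,
           " (length ", len, ")", call. = FALSE)
    }
  }
  rng
}

#' Read a chromosome-sizes table
#'
#' Two-column TSV (chromosome, length in bp), as produced by
#' `samtools faidx` / UCSC `fetchChromSizes`.
#'
#' @param path Path to the TSV file.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("chromosome-sizes file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  if (any(df$length <= 0 | is.na(df$length))) {
    stop("chromosome lengths must be positive integers: ", path, call. = FALSE)
  }
  stats::setNames(df$length, df$chrom)
}

chrom_length <- function(chromsizes, chrom) {
  if (!chrom %in% names(chromsizes)) {
    stop("chromosome '", chrom, "' not present in chromosome sizes", call. = FALSE)
  }
  as.numeric(chromsizes[[chrom]])
}

#' Clamp a range to chromosome bounds
#'
#' Slides/truncates `range` so that `1 <= start <= end <= length(chrom)`.
#' When the window is longer than the chromosome it becomes the full
#' chromosome; otherwise its length is preserved and it is slid flush
#' against the violated boundary.
#'
#' @param range A [genome_range()].
#' @param chromsizes Named vector of chromosome lengths.
#' @return A clamped [genome_range()].
#' @export
clamp_range <- function(range, chromsizes) {
  len <- chrom_length(chromsizes, range$chrom)
  w <- range_length(range)
  if (w >= len) return(genome_range(range$chrom, 1, len))
  start <- range$start
  end <- range$end
  if (start < 1) {
    end <- end + (1 - start)
    start <- 1
  }
  if (end > len) {
    start <- start - (end - len)
    end <- len
  }
  genome_range(range$chrom, max(1, start), min(len, end))
}

#' Do two ranges overlap?
#'
#' Any-overlap rule on 1-based inclusive coordinates; different chromosomes
#' never overlap.
#'
#' @param a,b [genome_range()] objects.
#' @return Logical scalar.
#' @export
ranges_overlap <- function(a, b) {
  identical(a$chrom, b$chrom) && a$start <= b$end && b$start <= a$end
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Zoom a range about its center
#'
#' `fold > 1` zooms in (shorter window), `fold < 1` zooms out. The center is
#' preserved up to 1 bp of rounding; the new length is the old length divided
#' by `fold`, with a minimum window of 2 bp. With `chromsizes` the result is
#' clamped to the chromosome.
#'
#' @param range A [genome_range()].
#' @param fold Positive zoom factor.
#' @param chromsizes Optional named vector of chromosome lengths.
#' @return A [genome_range()].
#' @examples
#' zoom_range(genome_range("chr1", 1000, 2000), 2)
#' @export
zoom_range <- function(range, fold, chromsizes = NULL) {
  if (!is.numeric(fold) || length(fold) != 1L || is.na(fold) || fold <= 0) {
    stop("`fold` must be a single positive number", call. = FALSE)
  }
  center <- (range$start + range$end) / 2
  new_half <- max(0.5, (range$end - range$start) / fold / 2)
  start <- round_half_away(center - new_half)
  end <- round_half_away(center + new_half)
  if (end - start < 1) end <- start + 1   # minimum window of 2 bp
  if (start < 1) {
    end <- end + (1 - start)
    start <- 1
  }
  out <- genome_range(range$chrom, start, end)
  if (!is.null(chromsizes)) out <- clamp_range(out, chromsizes)
  out
}

#' Slide a range along its chromosome
#'
#' Both ends move by `round(frac * (end - start))`; negative `frac` slides
#' left. Length is preserved, except near chromosome boundaries (with
#' `chromsizes`) where the window slides flush against the edge.
#'
#' @param range A [genome_range()].
#' @param frac Finite shift, as a fraction of the current span.
#' @param chromsizes Optional named vector of chromosome lengths.
#' @return A [genome_range()].
#' @examples
#' shift_range(genome_range("chr1", 1000, 2000), 0.5)
#' @export
shift_range <- function(range, frac, chromsizes = NULL) {
  if (!is.numeric(frac) || length(frac) != 1L || !is.finite(frac)) {
    stop("`frac` must be a single finite number", call. = FALSE)
  }
  offset <- round_half_away(frac * (range$end - range$start))
  start <- range$start + offset
  end <- range$end + offset
  if (start < 1) {
    end <- end + (1 - start)
    start <- 1
  }
  out <- genome_range(range$chrom, start, end)
  if (!is.null(chromsizes)) out <- clamp_range(out, chromsizes)
  out
}

#' Bin axis over a genomic range
#'
#' Tiles `range` with fixed-width bins anchored at the range start; the last
#' bin may be partial (clipped at the range end) but is always non-empty.
#' Bin `i` (0-based) covers `start + i*resolution` to
#' `min(start + (i+1)*resolution - 1, end)`.
#'
#' @param range A [genome_range()].
#' @param resolution Bin width in bp (positive integer).
#' @return A `bin_axis` object: list with `range`, `resolution`, `n_bins`,
#'   and per-bin `starts`/`ends` vectors.
#' @examples
#' range_to_bins(genome_range("chr1", 1, 250), 100)
#' @export
range_to_bins <- function(range, resolution) {
  stopifnot(inherits(range, "genome_range"))
  resolution <- as.numeric(resolution)
  if (length(resolution) != 1L || is.na(resolution) || resolution <= 0) {
    stop("`resolution` must be a single positive number", call. = FALSE)
  }
  n <- ceiling(range_length(range) / resolution)
  i <- seq_len(n) - 1
  starts <- range$start + i * resolution
  ends <- pmin(range$start + (i + 1) * resolution - 1, range$end)
  structure(
    list(range = range, resolution = resolution, n_bins = as.integer(n),
         starts = starts, ends = ends),
    class = "bin_axis"
  )
}

#' @export
print.bin_axis <- function(x, ...) {
  cat("<bin_axis> ", format(x$range), " @ ", format(x$resolution, scientific = FALSE),
      " bp = ", x$n_bins, " bins\n", sep = "")
  invisible(x)
}

#' @export
format.bin_axis <- function(x, ...) {
  paste0(format(x$range), "@", format(x$resolution, scientific = FALSE))
}

axes_identical <- function(a, b) {
  identical(format(a$range), format(b$range)) && a$resolution == b$resolution
}

#' Genomic extent of one bin
#'
#' @param axis A [range_to_bins()] axis.
#' @param i Bin index, 1-based.
#' @return A [genome_range()] covering bin `i`.
#' @export
bin_range <- function(axis, i) {
  stopifnot(inherits(axis, "bin_axis"), i >= 1, i <= axis$n_bins)
  genome_range(axis$range$chrom, axis$starts[i], axis$ends[i])
}

#' @export
#' @method as_tibble bin_axis
as_tibble.bin_axis <- function(x, ...) {
  tibble::tibble(bin = seq_len(x$n_bins), chrom = x$range$chrom,
                 start = x$starts, end = x$ends)
}
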