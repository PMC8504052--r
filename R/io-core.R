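# Shared machinery for region-indexed text readers.
#
# Every reader follows the same contract: return exactly the records
# overlapping the query range (any-overlap, after the half-open -> 1-based
# inclusive conversion), in file order.  When a tabix index (.tbi) sits next
# to a bgzipped file and Rsamtools is available the query goes through the
# index; otherwise the whole file is scanned and filtered.  The two paths
# must be bit-identical, which is why both feed raw lines into the same
# per-format line parsers.

is_comment_line <- function(x) {
  grepl("^#", x) | grepl("^(track|browser)([[:space:]]|$)", x)
}

has_tabix_index <- function(path) {
  grepl("\\.gz$", path) && file.exists(paste0(path, ".tbi")) &&
    requireNamespace("Rsamtools", quietly = TRUE)
}

# Returns list(text = character, line = integer or NA) of data lines to
# parse.  `line` carries original file line numbers on the linear path so
# format errors can name them; the indexed path cannot know them.
query_region_lines <- function(path, range) {
  if (!file.exists(path)) {
    stop("cannot read '", path, "': file does not exist", call. = FALSE)
  }
  if (has_tabix_index(path)) {
    tbx <- Rsamtools::TabixFile(path)
    res <- tryCatch(
      Rsamtools::scanTabix(
        tbx,
        param = GenomicRanges::GRanges(
          range$chrom,
          IRanges::IRanges(range$start, range$end)
        )
      ),
      error = function(e) list(character(0))  # chromosome absent from index
    )
    return(list(text = as.character(unlist(res, use.names = FALSE)),
                line = rep(NA_integer_, length(unlist(res))), indexed = TRUE))
  }
  txt <- readr::read_lines(path, progress = FALSE)
  keep <- !is_comment_line(txt) & nzchar(trimws(txt))
  list(text = txt[keep], line = which(keep), indexed = FALSE)
}

split_fields <- function(text) strsplit(text, "\t", fixed = TRUE)

line_label <- function(line) {
  ifelse(is.na(line), "(indexed record)", paste0("line ", line))
}

format_error <- function(path, line, why) {
  stop("format error in '", path, "' at ", line_label(line), ": ", why,
       call. = FALSE)
}

parse_num_field <- function(x, path, line, what) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v))
  if (length(bad)) {
    format_error(path, line[bad[1]], paste0("non-numeric ", what, " '", x[bad[1]], "'"))
  }
  v
}

check_min_fields <- function(fields, n, path, line) {
  bad <- which(vapply(fields, length, 1L) < n)
  if (length(bad)) {
    format_error(path, line[bad[1]],
                 paste0("expected at least ", n, " tab-separated fields"))
  }
}

# Coordinate-sortedness check (per chromosome, by start) used on the linear
# path, where the whole file is visible; indexed files were sorted when the
# index was built.
check_sorted <- function(chrom, start, path, line) {
  if (length(chrom) < 2) return(invisible())
  same <- chrom[-1] == chrom[-length(chrom)]
  dec <- same & start[-1] < start[-length(start)]
  if (any(dec)) {
    i <- which(dec)[1] + 1L
    format_error(path, line[i],
                 paste0("file is not coordinate-sorted (", chrom[i], ":",
                        format(start[i], scientific = FALSE),
                        " after ", format(start[i - 1L], scientific = FALSE), ")"))
  }
  invisible()
}

# any-overlap filter in 1-based inclusive coordinates
overlaps_range <- function(chrom, start, end, range) {
  chrom == range$chrom & start <= range$end & end >= range$start
}
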