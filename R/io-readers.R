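#' Read scored intervals (bedGraph) overlapping a region
#'
#' bedGraph records (`chrom start end value`, 0-based half-open) are
#' converted to 1-based inclusive coordinates at the reader boundary and
#' returned in file order.  Records are *not* clipped to the query range;
#' display clipping is the renderer's job.  A tabix index (`.tbi` next to a
#' bgzipped file) is used when present, with a bit-identical linear-scan
#' fallback otherwise.
#'
#' @param path bedGraph file (plain text or bgzip + tabix).
#' @param range Query [genome_range()] or region string.
#' @return Tibble with columns `chrom`, `start`, `end` (1-based inclusive)
#'   and `value`, containing exactly the records overlapping `range`.
#' @export
read_scored_intervals <- function(path, range) {
  range <- parse_region(range)
  q <- query_region_lines(path, range)
  if (!length(q$text)) {
    return(tibble::tibble(chrom = character(), start = double(),
                          end = double(), value = double()))
  }
  fields <- split_fields(q$text)
  check_min_fields(fields, 4L, path, q$line)
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- parse_num_field(vapply(fields, `[[`, "", 2L), path, q$line, "start")
  end0 <- parse_num_field(vapply(fields, `[[`, "", 3L), path, q$line, "end")
  value <- parse_num_field(vapply(fields, `[[`, "", 4L), path, q$line, "value")
  bad <- which(!is.finite(value))
  if (length(bad)) format_error(path, q$line[bad[1]], "non-finite value")
  if (!q$indexed) check_sorted(chrom, start0, path, q$line)
  start <- start0 + 1
  end <- end0
  keep <- overlaps_range(chrom, start, end, range)
  tibble::tibble(chrom = chrom[keep], start = start[keep],
                 end = end[keep], value = value[keep])
}

bed_strands <- c("+", "-", ".")

parse_bed_blocks <- function(start, end, n_blocks, sizes, starts, path, line) {
  sz <- as.numeric(strsplit(sub(",$", "", sizes), ",", fixed = TRUE)[[1]])
  st <- as.numeric(strsplit(sub(",$", "", starts), ",", fixed = TRUE)[[1]])
  if (any(is.na(sz)) || any(is.na(st)) ||
      length(sz) != n_blocks || length(st) != n_blocks) {
    format_error(path, line, "malformed block sizes/starts")
  }
  bs <- start + st            # 1-based block starts (st are 0-based offsets)
  be <- bs + sz - 1
  o <- order(bs)
  bs <- bs[o]; be <- be[o]
  if (any(bs < start) || any(be > end)) {
    format_error(path, line, "blocks extend outside the record interval")
  }
  if (length(bs) > 1 && any(bs[-1] <= be[-length(be)])) {
    format_error(path, line, "blocks overlap")
  }
  tibble::tibble(start = bs, end = be)
}

#' Read BED annotations overlapping a region
#'
#' Accepts BED3 up to BED12; missing optional fields default to `name = ""`,
#' `score = NA`, `strand = "."`.  Coordinates are converted from 0-based
#' half-open to 1-based inclusive; BED12 blocks are returned as a list
#' column of per-record tibbles in genomic coordinates.
#'
#' @inheritParams read_scored_intervals
#' @param path BED file (3, 6, 9 or 12 columns; plain text or bgzip+tabix).
#' @return Tibble with `chrom`, `start`, `end`, `name`, `score`, `strand`,
#'   `thick_start`, `thick_end` and list column `blocks`.
#' @export
read_bed <- function(path, range) {
  range <- parse_region(range)
  q <- query_region_lines(path, range)
  empty <- tibble::tibble(chrom = character(), start = double(), end = double(),
                          name = character(), score = double(), strand = character(),
                          thick_start = double(), thick_end = double(),
                          blocks = list())
  if (!length(q$text)) return(empty)
  fields <- split_fields(q$text)
  check_min_fields(fields, 3L, path, q$line)
  nf <- vapply(fields, length, 1L)
  get_col <- function(j, default = NA_character_) {
    ifelse(nf >= j, vapply(fields, function(f) if (length(f) >= j) f[[j]] else default, ""), default)
  }
  chrom <- get_col(1L)
  start <- parse_num_field(get_col(2L), path, q$line, "start") + 1
  end <- parse_num_field(get_col(3L), path, q$line, "end")
  if (any(end < start)) {
    format_error(path, q$line[which(end < start)[1]], "end < start")
  }
  name <- ifelse(is.na(get_col(4L)), "", get_col(4L))
  score_raw <- get_col(5L)
  score <- suppressWarnings(as.numeric(ifelse(score_raw %in% c(".", NA), NA, score_raw)))
  strand <- ifelse(is.na(get_col(6L)) | get_col(6L) == "", ".", get_col(6L))
  bad_strand <- which(!strand %in% bed_strands)
  if (length(bad_strand)) {
    format_error(path, q$line[bad_strand[1]],
                 paste0("invalid strand '", strand[bad_strand[1]], "'"))
  }
  thick_start <- suppressWarnings(as.numeric(get_col(7L))) + 1
  thick_end <- suppressWarnings(as.numeric(get_col(8L)))
  if (!q$indexed) check_sorted(chrom, start, path, q$line)

  blocks <- vector("list", length(chrom))
  for (k in seq_along(chrom)) {
    if (nf[k] >= 12L) {
      nb <- suppressWarnings(as.integer(fields[[k]][[10L]]))
      if (is.na(nb)) format_error(path, q$line[k], "malformed block count")
      blocks[[k]] <- parse_bed_blocks(start[k], end[k], nb,
                                      fields[[k]][[11L]], fields[[k]][[12L]],
                                      path, q$line[k])
    } else {
      blocks[k] <- list(NULL)
    }
  }
  keep <- overlaps_range(chrom, start, end, range)
  tibble::tibble(chrom = chrom, start = start, end = end, name = name,
                 score = score, strand = strand,
                 thick_start = thick_start, thick_end = thick_end,
                 blocks = blocks)[keep, ]
}

#' Read a SNP table overlapping a region
#'
#' Tab-separated file with a header naming (at least) chromosome, position
#' and p-value columns.  `neg_log10_p = -log10(pvalue)` is computed on read;
#' records with `p <= 0` or `p > 1` are dropped with a warning.
#'
#' @inheritParams read_scored_intervals
#' @param col_chrom,col_pos,col_p Header names of the chromosome, position
#'   (1-based bp) and p-value columns.
#' @return Tibble with `chrom`, `pos`, `pvalue`, `neg_log10_p`.
#' @export
read_snps <- function(path, range, col_chrom = "chrom", col_pos = "pos",
                      col_p = "pvalue") {
  range <- parse_region(range)
  if (!file.exists(path)) {
    stop("cannot read '", path, "': file does not exist", call. = FALSE)
  }
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(c(col_chrom, col_pos, col_p), names(df))
  if (length(miss)) {
    stop("SNP table '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    chrom = as.character(df[[col_chrom]]),
    pos = as.numeric(df[[col_pos]]),
    pvalue = as.numeric(df[[col_p]])
  )
  bad <- !is.finite(out$pvalue) | out$pvalue <= 0 | out$pvalue > 1
  if (any(bad)) {
    warning(sum(bad), " SNP record(s) with p-value outside (0, 1] dropped from '",
            path, "'", call. = FALSE)
    out <- out[!bad, ]
  }
  out <- dplyr::filter(out, .data$chrom == range$chrom,
                       .data$pos >= range$start, .data$pos <= range$end)
  dplyr::mutate(out, neg_log10_p = -log10(.data$pvalue))
}
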