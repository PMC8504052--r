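#' Read pairwise interactions (BEDPE or 4DN pairs) overlapping regions
#'
#' Two dialects are auto-detected: BEDPE
#' (`chrom1 start1 end1 chrom2 start2 end2 [name score ...]`, 0-based
#' half-open anchors) and 4DN pairs (`readID chrom1 pos1 chrom2 pos2 ...`,
#' 1-based point anchors).  Anchors are canonically ordered so that within
#' one chromosome `start1 <= start2`.  Selection rules:
#'
#' * `either`: at least one anchor overlaps `range_h` (arcs track),
#' * `both`: both anchors overlap `range_h`,
#' * `cross`: one anchor overlaps `range_v` and the other `range_h`
#'   (joint 2D view).
#'
#' Because a standard linear index covers only the first anchor, this reader
#' always performs a filtered linear scan.
#'
#' @inheritParams read_scored_intervals
#' @param path BEDPE or 4DN pairs file.
#' @param range_h Horizontal query [genome_range()] or region string.
#' @param range_v Optional vertical range (required for `rule = "cross"`).
#' @param rule Overlap rule, one of `"either"`, `"both"`, `"cross"`.
#' @param format `"auto"` (default), `"bedpe"` or `"pairs"` for ambiguous
#'   files.
#' @return Tibble with `chrom1`, `start1`, `end1`, `chrom2`, `start2`,
#'   `end2`, `name`, `score` (1-based inclusive anchors).
#' @export
read_pairs <- function(path, range_h, range_v = NULL,
                       rule = c("either", "both", "cross"),
                       format = c("auto", "bedpe", "pairs")) {
  rule <- match.arg(rule)
  format <- match.arg(format)
  range_h <- parse_region(range_h)
  if (!is.null(range_v)) range_v <- parse_region(range_v)
  if (rule == "cross" && is.null(range_v)) {
    stop("rule = 'cross' requires `range_v`", call. = FALSE)
  }
  if (!file.exists(path)) {
    stop("cannot read '", path, "': file does not exist", call. = FALSE)
  }
  txt <- readr::read_lines(path, progress = FALSE)
  header <- txt[grepl("^#", txt)]
  keep <- !is_comment_line(txt) & nzchar(trimws(txt))
  line <- which(keep)
  txt <- txt[keep]
  empty <- tibble::tibble(chrom1 = character(), start1 = double(), end1 = double(),
                          chrom2 = character(), start2 = double(), end2 = double(),
                          name = character(), score = double())
  if (!length(txt)) return(empty)
  fields <- split_fields(txt)
  nf <- vapply(fields, length, 1L)

  if (format == "auto") {
    if (any(grepl("pairs format", header, ignore.case = TRUE))) {
      format <- "pairs"
    } else {
      f1 <- fields[[1]]
      num <- function(j) !is.na(suppressWarnings(as.numeric(f1[j])))
      if (length(f1) >= 6 && num(2) && num(3) && num(5) && num(6) && !num(4)) {
        format <- "bedpe"
      } else if (length(f1) >= 5 && num(3) && num(5) && !num(2) && !num(4)) {
        format <- "pairs"
      } else {
        stop("cannot detect interaction-file dialect of '", path,
             "'; pass format = 'bedpe' or 'pairs'", call. = FALSE)
      }
    }
  }

  if (format == "bedpe") {
    check_min_fields(fields, 6L, path, line)
    col <- function(j) vapply(fields, `[[`, "", j)
    chrom1 <- col(1L)
    start1 <- parse_num_field(col(2L), path, line, "start1") + 1
    end1 <- parse_num_field(col(3L), path, line, "end1")
    chrom2 <- col(4L)
    start2 <- parse_num_field(col(5L), path, line, "start2") + 1
    end2 <- parse_num_field(col(6L), path, line, "end2")
    name <- if (all(nf >= 7L)) col(7L) else rep("", length(chrom1))
    score <- if (all(nf >= 8L)) {
      suppressWarnings(as.numeric(ifelse(col(8L) == ".", NA, col(8L))))
    } else rep(NA_real_, length(chrom1))
  } else {
    check_min_fields(fields, 5L, path, line)
    col <- function(j) vapply(fields, `[[`, "", j)
    chrom1 <- col(2L)
    start1 <- parse_num_field(col(3L), path, line, "pos1")
    end1 <- start1
    chrom2 <- col(4L)
    start2 <- parse_num_field(col(5L), path, line, "pos2")
    end2 <- start2
    name <- col(1L)
    score <- rep(NA_real_, length(chrom1))
  }

  # canonical anchor order within one chromosome
  swap <- chrom1 == chrom2 & start1 > start2
  if (any(swap)) {
    tmp <- list(chrom1[swap], start1[swap], end1[swap])
    chrom1[swap] <- chrom2[swap]; start1[swap] <- start2[swap]; end1[swap] <- end2[swap]
    chrom2[swap] <- tmp[[1]]; start2[swap] <- tmp[[2]]; end2[swap] <- tmp[[3]]
  }

  ov1_h <- overlaps_range(chrom1, start1, end1, range_h)
  ov2_h <- overlaps_range(chrom2, start2, end2, range_h)
  keep <- switch(rule,
    either = ov1_h | ov2_h,
    both = ov1_h & ov2_h,
    cross = {
      ov1_v <- overlaps_range(chrom1, start1, end1, range_v)
      ov2_v <- overlaps_range(chrom2, start2, end2, range_v)
      (ov1_v & ov2_h) | (ov2_v & ov1_h)
    }
  )
  tibble::tibble(chrom1 = chrom1, start1 = start1, end1 = end1,
                 chrom2 = chrom2, start2 = start2, end2 = end2,
                 name = name, score = score)[keep, ]
}
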