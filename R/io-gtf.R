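#' Read gene models from a GTF file
#'
#' Exon features are grouped into gene models keyed by the `gene_name`
#' attribute (falling back to `gene_id`); a gene's span is the min/max over
#' its exons and overlapping exons (e.g. from multiple transcripts) are
#' merged.  GTF coordinates are already 1-based inclusive and pass through
#' unchanged.  A gene is returned whenever its *span* overlaps the query
#' range, even if some exons lie outside it.  Exon records carrying neither
#' `gene_name` nor `gene_id` are skipped with a warning.
#'
#' @inheritParams read_scored_intervals
#' @param path GTF file (GTF2.2 attribute syntax; plain text or bgzip+tabix).
#' @return Tibble with one row per gene: `gene_name`, `chrom`, `start`,
#'   `end`, `strand`, `transcript_id` (NA when a gene has several) and list
#'   column `exons` of tibbles with merged `start`/`end`.
#' @export
read_gtf_genes <- function(path, range) {
  range <- parse_region(range)
  if (!file.exists(path)) {
    stop("cannot read '", path, "': file does not exist", call. = FALSE)
  }
  # Gene spans can exceed any exon returned by an indexed exon-level query,
  # so grouping is done over the whole chromosome and filtered by span.
  chrom_range <- genome_range(range$chrom, 1, 2147483646)
  q <- query_region_lines(path, chrom_range)
  empty <- tibble::tibble(gene_name = character(), chrom = character(),
                          start = double(), end = double(), strand = character(),
                          transcript_id = character(), exons = list())
  if (!length(q$text)) return(empty)
  fields <- split_fields(q$text)
  check_min_fields(fields, 9L, path, q$line)
  feature <- vapply(fields, `[[`, "", 3L)
  is_exon <- feature == "exon"
  if (!any(is_exon)) return(empty)
  fields <- fields[is_exon]
  line <- q$line[is_exon]
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- parse_num_field(vapply(fields, `[[`, "", 4L), path, line, "start")
  end <- parse_num_field(vapply(fields, `[[`, "", 5L), path, line, "end")
  strand <- vapply(fields, `[[`, "", 7L)
  attrs <- vapply(fields, `[[`, "", 9L)

  gtf_attr <- function(attr, key) {
    m <- regmatches(attr, regexec(paste0('(^|; ?)', key, ' "([^"]*)"'), attr))
    vapply(m, function(x) if (length(x) == 3L) x[[3L]] else NA_character_, "")
  }
  gene_name <- gtf_attr(attrs, "gene_name")
  gene_id <- gtf_attr(attrs, "gene_id")
  tx_id <- gtf_attr(attrs, "transcript_id")
  key <- ifelse(is.na(gene_name), gene_id, gene_name)
  if (anyNA(key)) {
    warning(sum(is.na(key)), " GTF exon record(s) without gene_name or gene_id ",
            "skipped in '", path, "'", call. = FALSE)
    keep <- !is.na(key)
    chrom <- chrom[keep]; start <- start[keep]; end <- end[keep]
    strand <- strand[keep]; tx_id <- tx_id[keep]; key <- key[keep]
  }
  if (!length(key)) return(empty)

  df <- tibble::tibble(key = key, chrom = chrom, start = start, end = end,
                       strand = strand, tx_id = tx_id)
  merge_exons <- function(s, e) {
    o <- order(s, e)
    s <- s[o]; e <- e[o]
    ms <- s[1]; me <- e[1]
    out_s <- double(); out_e <- double()
    for (k in seq_along(s)[-1]) {
      if (s[k] <= me + 1) {
        me <- max(me, e[k])
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- s[k]; me <- e[k]
      }
    }
    tibble::tibble(start = c(out_s, ms), end = c(out_e, me))
  }
  genes <- df |>
    dplyr::group_by(.data$key, .data$chrom) |>
    dplyr::summarise(
      exons = list(merge_exons(.data$start, .data$end)),
      start = min(.data$start),
      end = max(.data$end),
      strand = .data$strand[1],
      transcript_id = if (dplyr::n_distinct(.data$tx_id) == 1L) .data$tx_id[1] else NA_character_,
      .groups = "drop"
    ) |>
    dplyr::select("key", "chrom", "start", "end", "strand", "transcript_id", "exons") |>
    dplyr::rename(gene_name = "key") |>
    dplyr::arrange(.data$chrom, .data$start)
  keep <- overlaps_range(genes$chrom, genes$start, genes$end, range)
  genes[keep, ]
}
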