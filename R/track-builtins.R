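# Built-in track types: fetch functions and style defaults.
# Registered in .onLoad(); see register_track_type() for the contract.

fetch_none <- function(track, range) NULL

fetch_bedgraph <- function(track, range) read_scored_intervals(track$source, range)

fetch_bigwig <- function(track, range) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("BigWig reading requires the rtracklayer package", call. = FALSE)
  }
  gr <- rtracklayer::import(
    rtracklayer::BigWigFile(track$source),
    selection = rtracklayer::BigWigSelection(
      GenomicRanges::GRanges(range$chrom,
                             IRanges::IRanges(range$start, range$end))
    )
  )
  tibble::tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr),
                 end = GenomicRanges::end(gr),
                 value = as.numeric(gr$score))
}

fetch_bed <- function(track, range) read_bed(track$source, range)

fetch_gtf <- function(track, range) read_gtf_genes(track$source, range)

fetch_arcs <- function(track, range) {
  read_pairs(track$source, range, rule = track$props$rule %||% "either",
             format = track$props$format %||% "auto")
}

fetch_snp <- function(track, range) {
  read_snps(track$source, range,
            col_chrom = track$props$col_chrom %||% "chrom",
            col_pos = track$props$col_pos %||% "pos",
            col_p = track$props$col_p %||% "pvalue")
}

fetch_matrix_for <- function(source, props, range) {
  read_contact_matrix(source, range, range,
                      resolution = props$resolution %||% NULL,
                      balanced = isTRUE(props$balanced))
}

fetch_hicmat <- function(track, range) {
  fetch_matrix_for(track$source, track$props, range)
}

fetch_virtual4c <- function(track, range) {
  anchor <- track$props$anchor
  if (is.null(anchor)) {
    stop("Virtual4C tracks need an `anchor` property (region string)", call. = FALSE)
  }
  virtual_4c(fetch_matrix_for(track$source, track$props, range), anchor)
}

fetch_discore <- function(track, range) {
  directionality_index(fetch_matrix_for(track$source, track$props, range),
                       window = as.integer(track$props$window %||% 5L))
}

fetch_insuscore <- function(track, range) {
  insulation_score(fetch_matrix_for(track$source, track$props, range),
                   window = as.integer(track$props$window %||% 5L))
}

# two-matrix source: list/vector of two matrix sources
split_diff_sources <- function(source) {
  if (is.list(source) && length(source) == 2L) return(source)
  src <- unlist(source, use.names = FALSE)
  if (length(src) == 2L) return(as.list(src))
  stop("HiCDiff tracks need exactly two matrix sources", call. = FALSE)
}

fetch_hicdiff <- function(track, range) {
  src <- split_diff_sources(track$source)
  a <- fetch_matrix_for(src[[1]], track$props, range)
  b <- fetch_matrix_for(src[[2]], track$props, range)
  diff_matrix(a, b, method = track$props$method %||% "distance")
}

register_builtin_tracks <- function() {
  reg <- function(...) register_track_type(..., overwrite = TRUE)
  reg("XAxis", fetch_none, draw_xaxis,
      defaults = list(height = 0.45, color = "#333333", title = ""))
  reg("Spacer", fetch_none, draw_spacer,
      defaults = list(height = 0.3, title = ""))
  reg("BedGraph", fetch_bedgraph, draw_signal_bars,
      defaults = list(height = 0.9, color = "#2c7fb8", alpha = 1, title = ""))
  reg("BigWig", fetch_bigwig, draw_signal_bars,
      defaults = list(height = 0.9, color = "#2c7fb8", alpha = 1, title = ""))
  reg("BED", fetch_bed, draw_bed,
      defaults = list(height = 0.9, color = "#1b9e77", alpha = 1,
                      style = "tile", title = ""))
  reg("GTF", fetch_gtf, draw_gtf,
      defaults = list(height = 1.0, color = "#2166ac", alpha = 1,
                      style = "gene", title = ""))
  reg("Arcs", fetch_arcs, draw_arcs,
      defaults = list(height = 0.9, color = "#7570b3", alpha = 0.8, title = ""))
  reg("HiCMat", fetch_hicmat, draw_hicmat,
      defaults = list(height = 2.2, style = "triangular", cmap = "reds",
                      scale = "log1p", depth = 0.5, title = ""))
  reg("Virtual4C", fetch_virtual4c, draw_profile_line,
      defaults = list(height = 0.9, color = "#d95f02", alpha = 1, title = ""))
  reg("DiScore", fetch_discore, draw_profile_bars,
      defaults = list(height = 0.9, window = 5, title = ""))
  reg("InsuScore", fetch_insuscore, draw_profile_line,
      defaults = list(height = 0.9, color = "#1f78b4", alpha = 1,
                      window = 5, title = ""))
  reg("HiCDiff", fetch_hicdiff, draw_hicdiff,
      defaults = list(height = 2.2, style = "triangular", cmap = "bwr",
                      scale = "linear", depth = 0.5, title = ""))
  reg("SNP", fetch_snp, draw_snp,
      defaults = list(height = 0.9, color = "#636363", alpha = 0.9, title = ""))
  invisible()
}
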