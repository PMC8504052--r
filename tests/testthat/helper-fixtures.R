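# Shared synthetic dataset, generated once per test run.

fixture_env <- new.env()

fixture_dir <- function() {
  if (is.null(fixture_env$dir)) {
    dir <- file.path(tempdir(), "trackkit-fixtures")
    fixture_env$manifest <- generate_dataset(dir, seed = 42)
    fixture_env$dir <- dir
  }
  fixture_env$dir
}

fixture_manifest <- function() {
  fixture_dir()
  fixture_env$manifest
}

fixture_path <- function(key) {
  as.character(fixture_manifest()$paths[[key]])
}

fixture_chromsizes <- function() {
  unlist(fixture_manifest()$chromsizes)
}

write_tmp_lines <- function(lines, ext = "txt") {
  path <- tempfile(fileext = paste0(".", ext))
  con <- file(path, open = "wb")
  writeLines(lines, con, sep = "\n")
  close(con)
  path
}

# a small standalone HiC-Pro matrix fixture written from explicit triplets
write_hicpro <- function(triplets, n_bins, resolution = 100, chrom = "chr1",
                         weights = NULL) {
  bins <- paste(chrom, (seq_len(n_bins) - 1) * resolution,
                seq_len(n_bins) * resolution, seq_len(n_bins),
                if (!is.null(weights)) weights, sep = "\t")
  list(
    matrix = write_tmp_lines(
      vapply(triplets, function(t) paste(t, collapse = "\t"), ""), "matrix"),
    bins = write_tmp_lines(bins, "bed")
  )
}

# contact matrix straight from a plain R matrix
cm_of <- function(values, resolution = 100, chrom = "chr1") {
  values <- as.matrix(values)
  ax <- range_to_bins(
    genome_range(chrom, 1, nrow(values) * resolution), resolution)
  contact_matrix(values, ax)
}

file_bytes <- function(path) readBin(path, "raw", file.size(path))
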