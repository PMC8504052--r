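# Region-indexed readers: conversion, overlap semantics, dialects, and
# equality with brute-force linear-scan oracles.

test_that("bedGraph reader converts half-open input and uses any-overlap", {
  path <- write_tmp_lines(c("chr1\t0\t100\t1", "chr1\t100\t200\t2"))
  one <- read_scored_intervals(path, "chr1:1-100")
  expect_equal(nrow(one), 1)
  expect_equal(one$value, 1)
  expect_equal(c(one$start, one$end), c(1, 100))

  # position 100 is record 1's last base, 101 is record 2's first
  both <- read_scored_intervals(path, "chr1:100-101")
  expect_equal(both$value, c(1, 2))

  expect_equal(nrow(read_scored_intervals(path, "chrZ:1-100")), 0)
})

test_that("bedGraph reader rejects malformed and unsorted files by line", {
  bad <- write_tmp_lines(c("chr1\t0\t100\t1", "chr1\t100\tx\t2"))
  expect_error(read_scored_intervals(bad, "chr1:1-500"), "line 2")
  unsorted <- write_tmp_lines(c("chr1\t500\t600\t1", "chr1\t100\t200\t2"))
  expect_error(read_scored_intervals(unsorted, "chr1:1-1000"),
               "not coordinate-sorted")
  expect_error(read_scored_intervals(tempfile(), "chr1:1-2"), "does not exist")
})

test_that("BED reader handles 3 to 12 columns, defaults and blocks", {
  b3 <- read_bed(write_tmp_lines("chr1\t10\t50"), "chr1:1-100")
  expect_equal(b3$name, "")
  expect_equal(b3$strand, ".")
  expect_true(is.na(b3$score))
  expect_equal(c(b3$start, b3$end), c(11, 50))

  row12 <- paste("chr1", 100, 400, "tx1", 5, "-", 100, 400, "0",
                 2, "50,100,", "0,200,", sep = "\t")
  b12 <- read_bed(write_tmp_lines(row12), "chr1:1-1000")
  blocks <- b12$blocks[[1]]
  expect_equal(nrow(blocks), 2)
  expect_equal(blocks$start, c(101, 301))
  expect_equal(blocks$end, c(150, 400))

  bad <- paste("chr1", 100, 400, "tx1", 5, "-", 100, 400, "0",
               2, "50,400,", "0,200,", sep = "\t")
  expect_error(read_bed(write_tmp_lines(bad), "chr1:1-1000"), "blocks")
})

test_that("GTF exons group into gene models with merged exons", {
  attr1 <- 'gene_id "g1"; gene_name "Abca13"; transcript_id "t1";'
  attr2 <- 'gene_id "g1"; gene_name "Abca13"; transcript_id "t2";'
  lines <- c(
    paste("chr1", "src", "exon", 100, 200, ".", "-", ".", attr1, sep = "\t"),
    paste("chr1", "src", "exon", 300, 400, ".", "-", ".", attr1, sep = "\t"),
    paste("chr1", "src", "exon", 350, 500, ".", "-", ".", attr2, sep = "\t"),
    paste("chr1", "src", "CDS", 100, 200, ".", "-", ".", attr1, sep = "\t")
  )
  g <- read_gtf_genes(write_tmp_lines(lines), "chr1:1-1000")
  expect_equal(nrow(g), 1)
  expect_equal(g$gene_name, "Abca13")
  expect_equal(g$strand, "-")
  expect_equal(c(g$start, g$end), c(100, 500))
  expect_true(is.na(g$transcript_id))  # two transcripts
  ex <- g$exons[[1]]
  expect_equal(ex$start, c(100, 300))   # 300-400 and 350-500 merged
  expect_equal(ex$end, c(200, 500))

  # gene partially outside the query window is returned whole
  part <- read_gtf_genes(write_tmp_lines(lines), "chr1:450-460")
  expect_equal(c(part$start, part$end), c(100, 500))

  # gene_id fallback + skip-with-warning for anonymous exons
  lines2 <- c(lines,
              paste("chr1", "src", "exon", 600, 700, ".", "+", ".",
                    'gene_id "orphan";', sep = "\t"),
              paste("chr1", "src", "exon", 800, 900, ".", "+", ".",
                    'nothing "here";', sep = "\t"))
  expect_warning(g2 <- read_gtf_genes(write_tmp_lines(lines2), "chr1:1-1000"),
                 "without gene_name or gene_id")
  expect_setequal(g2$gene_name, c("Abca13", "orphan"))
})

test_that("pairs reader applies either/both/cross rules and both dialects", {
  bedpe <- write_tmp_lines(paste("chr1", 99, 200, "chr1", 4999, 6000,
                                 "int1", 7, "+", "-", sep = "\t"))
  either <- read_pairs(bedpe, "chr1:1-300", rule = "either")
  expect_equal(nrow(either), 1)
  expect_equal(either$start1, 100)   # half-open converted
  expect_equal(either$score, 7)
  expect_equal(nrow(read_pairs(bedpe, "chr1:1-300", rule = "both")), 0)
  expect_equal(nrow(read_pairs(bedpe, "chr1:1-300", range_v = "chr1:4900-6100",
                               rule = "cross")), 1)

  pairs4dn <- write_tmp_lines(c("## pairs format v1.0",
                                "#columns: readID chr1 pos1 chr2 pos2",
                                "r1\tchr1\t150\tchr1\t5500"))
  p <- read_pairs(pairs4dn, "chr1:1-300", rule = "either")
  expect_equal(nrow(p), 1)
  expect_equal(c(p$start1, p$end1), c(150, 150))  # point anchors, 1-based

  # anchors are canonically ordered within a chromosome
  swapped <- write_tmp_lines(paste("chr1", 4999, 6000, "chr1", 99, 200,
                                   "i", ".", "+", "-", sep = "\t"))
  s <- read_pairs(swapped, "chr1:1-300", rule = "either")
  expect_lte(s$start1, s$start2)

  expect_error(read_pairs(write_tmp_lines("just\tnot\tpairs"), "chr1:1-10"),
               "dialect")
})

test_that("SNP reader computes -log10 p and rejects invalid p-values", {
  path <- write_tmp_lines(c("chrom\tpos\tpvalue",
                            "chr1\t100\t0.01",
                            "chr1\t200\t1",
                            "chr1\t300\t0",
                            "chr1\t400\t1.5"))
  expect_warning(snp <- read_snps(path, "chr1:1-1000"), "dropped")
  expect_equal(nrow(snp), 2)
  expect_equal(snp$neg_log10_p, c(2, 0))
  expect_lt(max(abs(snp$neg_log10_p + log10(snp$pvalue))), 1e-9)
})

test_that("HiC-Pro windows mirror triplets, zero-fill and symmetrize", {
  src <- write_hicpro(list(c(1, 1, 4), c(1, 2, 2), c(2, 2, 4)), n_bins = 8)
  m <- read_contact_matrix(c(src$matrix, src$bins), "chr1:1-200")
  expect_equal(m$values, matrix(c(4, 2, 2, 4), 2, 2))
  expect_identical(m$values, t(m$values))  # exactly symmetric

  off <- read_contact_matrix(c(src$matrix, src$bins),
                             "chr1:1-200", "chr1:401-600")
  expect_equal(off$values, matrix(0, 2, 2))
  expect_equal(off$col_axis$starts, c(401, 501))

  expect_error(read_contact_matrix(c(src$matrix, src$bins), "chr1:1-200",
                                   resolution = 999),
               "file bin size 100")
  badtrip <- write_tmp_lines("1\t99\t5")
  expect_error(read_contact_matrix(c(badtrip, src$bins), "chr1:1-200"),
               "bins table")
  expect_error(read_contact_matrix("nope.cool", "chr1:1-200"),
               "not supported")
})

test_that("balancing weights multiply entries and require a weight column", {
  w <- c(0.5, 2)
  src <- write_hicpro(list(c(1, 1, 4), c(1, 2, 2), c(2, 2, 4)), n_bins = 2,
                      weights = c("0.5", "2.0"))
  m <- read_contact_matrix(c(src$matrix, src$bins), "chr1:1-200",
                           balanced = TRUE)
  expect_equal(m$values, matrix(c(4, 2, 2, 4), 2, 2) * outer(w, w))

  noW <- write_hicpro(list(c(1, 1, 4)), n_bins = 2)
  expect_error(read_contact_matrix(c(noW$matrix, noW$bins), "chr1:1-200",
                                   balanced = TRUE), "no weight column")

  naW <- write_hicpro(list(c(1, 1, 4), c(2, 2, 4)), n_bins = 2,
                      weights = c("NA", "1.0"))
  mn <- read_contact_matrix(c(naW$matrix, naW$bins), "chr1:1-200",
                            balanced = TRUE)
  expect_true(all(is.nan(mn$values[1, ])))
  expect_equal(mn$values[2, 2], 4)
})

test_that("random matrix windows equal the dict-lookup oracle", {
  set.seed(23)
  n <- 30
  trips <- list()
  for (k in 1:120) {
    i <- sample.int(n, 1); j <- sample.int(n, 1)
    trips[[k]] <- c(min(i, j), max(i, j), sample.int(50, 1))
  }
  # deduplicate (i, j) keys the way a real file would be written
  keys <- vapply(trips, function(t) paste(t[1], t[2]), "")
  trips <- trips[!duplicated(keys)]
  src <- write_hicpro(trips, n_bins = n)
  for (rep in 1:10) {
    b1 <- sort(sample.int(n, 2)); b2 <- sort(sample.int(n, 2))
    r_row <- genome_range("chr1", (b1[1] - 1) * 100 + 1, b1[2] * 100)
    r_col <- genome_range("chr1", (b2[1] - 1) * 100 + 1, b2[2] * 100)
    got <- read_contact_matrix(c(src$matrix, src$bins), r_row, r_col)
    want <- oracle_matrix_window(src$matrix, src$bins,
                                 b1[1]:b1[2], b2[1]:b2[2])
    expect_equal(got$values, want)
  }
})

test_that("bin_signal aggregates with coverage weighting", {
  iv <- tibble::tibble(chrom = "chr1", start = c(1, 11), end = c(10, 20),
                       value = c(2, 4))
  ax1 <- range_to_bins(genome_range("chr1", 1, 20), 20)
  expect_equal(bin_signal(iv, ax1, "mean"), 3.0)   # (10*2 + 10*4)/20
  expect_equal(bin_signal(iv, ax1, "max"), 4.0)
  expect_equal(bin_signal(iv, ax1, "min"), 2.0)
  expect_equal(bin_signal(iv, ax1, "sum"), 60)

  ax2 <- range_to_bins(genome_range("chr1", 1, 40), 10)
  expect_equal(bin_signal(iv, ax2, "mean"), c(2, 4, 0, 0))  # empty bins -> 0

  # partial overlap weighting: bin 6-15 covers 5 bases of each interval
  ax3 <- range_to_bins(genome_range("chr1", 6, 15), 10)
  expect_equal(bin_signal(iv, ax3, "mean"), 3.0)
})

test_that("every reader matches its linear-scan oracle on seeded queries", {
  cs <- fixture_chromsizes()
  set.seed(31)
  for (k in 1:40) {
    r <- random_test_range(cs)
    got_bg <- read_scored_intervals(fixture_path("bedgraph"), r)
    want_bg <- oracle_bedgraph(fixture_path("bedgraph"), r)
    expect_equal(as.data.frame(got_bg), want_bg, ignore_attr = TRUE)

    got_bed <- read_bed(fixture_path("bed6"), r)
    want_bed <- oracle_bed_spans(fixture_path("bed6"), r)
    expect_equal(got_bed$start, want_bed$start)
    expect_equal(got_bed$name, want_bed$name)

    got_g <- sort(read_gtf_genes(fixture_path("gtf"), r)$gene_name)
    expect_equal(got_g, oracle_gtf_genes(fixture_path("gtf"), r))

    got_snp <- read_snps(fixture_path("snp"), r)
    want_snp <- oracle_snp(fixture_path("snp"), r)
    expect_equal(got_snp$pos, want_snp$pos)
    expect_equal(got_snp$pvalue, want_snp$pvalue)
  }
})

test_that("adjacent disjoint queries union to the spanning query", {
  path <- fixture_path("bedgraph")
  r1 <- genome_range("chr1", 1, 50000)
  r2 <- genome_range("chr1", 50001, 120000)
  ru <- genome_range("chr1", 1, 120000)
  a <- read_scored_intervals(path, r1)
  b <- read_scored_intervals(path, r2)
  u <- read_scored_intervals(path, ru)
  merged <- dplyr::distinct(dplyr::bind_rows(a, b))
  expect_equal(dplyr::arrange(merged, start), u)
  # duplicates between the two half-queries only for records spanning the cut
  dup <- dplyr::intersect(a, b)
  expect_true(all(dup$start <= 50000 & dup$end >= 50001))
})

test_that("tabix-indexed queries are bit-identical to the linear scan", {
  path <- fixture_path("bedgraph")
  bgz <- paste0(tempfile(fileext = ".bedgraph"), ".gz")
  Rsamtools::bgzip(path, dest = bgz)
  Rsamtools::indexTabix(bgz, seq = 1, start = 2, end = 3, zeroBased = TRUE)
  expect_true(file.exists(paste0(bgz, ".tbi")))
  cs <- fixture_chromsizes()
  set.seed(37)
  for (k in 1:25) {
    r <- random_test_range(cs)
    expect_identical(read_scored_intervals(bgz, r),
                     read_scored_intervals(path, r))
  }
  # chromosome absent from the index
  expect_equal(nrow(read_scored_intervals(bgz, "chrZ:1-100")), 0)
})
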