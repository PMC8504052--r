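# Track registry, style validation, fetch delegation and the extension
# contract.

test_that("make_track validates types, sources and style properties", {
  sp <- make_track("Spacer")
  expect_null(sp$source)
  bg <- make_track("BedGraph", fixture_path("bedgraph"), color = "#ff0000")
  expect_equal(bg$props$color, "#ff0000")
  expect_error(make_track("NotAType", "x"), "unregistered track type")
  expect_error(make_track("BedGraph", "no/such/file.bg"), "not readable")
  expect_error(make_track("BedGraph"), "requires a data source")
  expect_error(make_track("BedGraph", fixture_path("bedgraph"), color = "#zz"),
               "'color'")
  expect_error(make_track("BedGraph", fixture_path("bedgraph"), height = -1),
               "'height'")
  expect_error(make_track("BedGraph", fixture_path("bedgraph"), alpha = 2),
               "'alpha'")
  expect_error(make_track("HiCMat", fixture_path("matrix_a"), style = "round"),
               "'style'")
  # unknown keys are preserved, never dropped
  tk <- make_track("BedGraph", fixture_path("bedgraph"), my_option = "kept")
  expect_equal(tk$props$my_option, "kept")
})

test_that("HiCDiff tracks hold two matrix sources", {
  t2 <- make_track("HiCDiff", c(fixture_path("matrix_b"),
                                fixture_path("matrix_a")))
  expect_length(t2$source, 2)
  res <- fetch_track_data(t2, "chr1:1-300000")
  expect_s3_class(res$payload, "contact_matrix")
  direct <- diff_matrix(
    read_contact_matrix(fixture_path("matrix_b"), "chr1:1-300000"),
    read_contact_matrix(fixture_path("matrix_a"), "chr1:1-300000")
  )
  expect_equal(res$payload$values, direct$values)
})

test_that("per-type default style table is frozen", {
  expect_setequal(
    registered_track_types(),
    c("XAxis", "Spacer", "BedGraph", "BigWig", "BED", "GTF", "Arcs",
      "HiCMat", "Virtual4C", "DiScore", "InsuScore", "HiCDiff", "SNP")
  )
  expect_equal(track_defaults("BedGraph"),
               list(height = 0.9, color = "#2c7fb8", alpha = 1, title = ""))
  expect_equal(track_defaults("HiCMat"),
               list(height = 2.2, style = "triangular", cmap = "reds",
                    scale = "log1p", depth = 0.5, title = ""))
  expect_equal(track_defaults("XAxis"),
               list(height = 0.45, color = "#333333", title = ""))
  expect_equal(track_defaults("Spacer"), list(height = 0.3, title = ""))
  expect_equal(track_defaults("GTF"),
               list(height = 1.0, color = "#2166ac", alpha = 1,
                    style = "gene", title = ""))
  expect_equal(track_defaults("HiCDiff"),
               list(height = 2.2, style = "triangular", cmap = "bwr",
                    scale = "linear", depth = 0.5, title = ""))
})

test_that("fetch delegates to the matching reader/analytic per type", {
  r <- genome_range("chr1", 1, 250000)
  src <- fixture_path("matrix_a")

  expect_equal(fetch_track_data(make_track("BedGraph", fixture_path("bedgraph")), r)$payload,
               read_scored_intervals(fixture_path("bedgraph"), r))
  expect_equal(fetch_track_data(make_track("BED", fixture_path("bed6")), r)$payload,
               read_bed(fixture_path("bed6"), r))
  expect_equal(fetch_track_data(make_track("GTF", fixture_path("gtf")), r)$payload,
               read_gtf_genes(fixture_path("gtf"), r))
  expect_equal(fetch_track_data(make_track("Arcs", fixture_path("bedpe")), r)$payload,
               read_pairs(fixture_path("bedpe"), r, rule = "either"))
  expect_equal(fetch_track_data(make_track("SNP", fixture_path("snp")), r)$payload,
               read_snps(fixture_path("snp"), r))
  expect_equal(fetch_track_data(make_track("HiCMat", src), r)$payload$values,
               read_contact_matrix(src, r)$values)
  expect_equal(fetch_track_data(make_track("InsuScore", src, window = 4), r)$payload$values,
               insulation_score(read_contact_matrix(src, r), 4)$values)
  expect_equal(fetch_track_data(make_track("DiScore", src, window = 4), r)$payload$values,
               directionality_index(read_contact_matrix(src, r), 4)$values)
  expect_equal(fetch_track_data(make_track("Virtual4C", src,
                                           anchor = "chr1:100001-110000"), r)$payload$values,
               virtual_4c(read_contact_matrix(src, r), "chr1:100001-110000")$values)
  expect_null(fetch_track_data(make_track("XAxis"), r)$payload)
})

test_that("bigWig tracks delegate to the established binary reader", {
  r <- genome_range("chr1", 1, 150000)
  iv <- read_scored_intervals(fixture_path("bedgraph"), "chr1:1-500000")
  gr <- GenomicRanges::GRanges(iv$chrom, IRanges::IRanges(iv$start, iv$end),
                               score = iv$value)
  GenomeInfoDb::seqlengths(gr) <- c(chr1 = 500000)
  bw <- tempfile(fileext = ".bw")
  rtracklayer::export.bw(gr, bw)
  got <- fetch_track_data(make_track("BigWig", bw), r)$payload
  want <- iv[iv$start <= r$end & iv$end >= r$start, ]
  expect_equal(got$start, want$start)
  expect_equal(got$value, want$value, tolerance = 1e-6)
})

test_that("fetch results are cached until the source file changes", {
  path <- write_tmp_lines(c("chr1\t0\t100\t1", "chr1\t100\t200\t2"))
  tk <- make_track("BedGraph", path)
  r <- genome_range("chr1", 1, 500)
  first <- fetch_track_data(tk, r)
  second <- fetch_track_data(tk, r)
  expect_identical(first, second)
  # rewrite the source with a bumped mtime: the cache must invalidate
  Sys.sleep(1.1)
  con <- file(path, "wb")
  writeLines(c("chr1\t0\t100\t9"), con, sep = "\n")
  close(con)
  third <- fetch_track_data(tk, r)
  expect_equal(third$payload$value, 9)
})

test_that("fetch errors are annotated with the failing track id", {
  path <- write_tmp_lines("chr1\t0\t100\t1")
  tk <- make_track("BedGraph", path, track_id = "mytrack")
  unlink(path)
  expect_error(fetch_track_data(tk, "chr1:1-50"), "mytrack")
})

test_that("custom types inherit fetch/draw and add only post-processing", {
  on.exit(rm(list = "CustomLoops", envir = trackkit:::.tk_registry), add = TRUE)
  # toy peak caller: cells more than 3 population SDs above their diagonal
  register_track_type(
    "CustomLoops", base = "HiCMat",
    post_fetch = function(payload, track, range) {
      z <- zscore_by_distance(payload)$values
      idx <- which(z > 3 & upper.tri(z), arr.ind = TRUE)
      list(matrix = payload,
           peaks = tibble::tibble(row = idx[, 1], col = idx[, 2]))
    }
  )
  expect_error(register_track_type("CustomLoops", base = "HiCMat"),
               "already registered")

  src <- fixture_path("matrix_a")
  r <- "chr1:1-500000"
  tk <- make_track("CustomLoops", src)
  res <- fetch_track_data(tk, r)
  # inherited fetch equals the base type's fetch on the same source/range
  base_res <- fetch_track_data(make_track("HiCMat", src), r)
  expect_equal(res$payload$matrix$values, base_res$payload$values)
  # the novel computation found the planted loops
  man <- fixture_manifest()
  planted <- vapply(man$planted_loops, function(l) paste(l$bin_i, l$bin_j), "")
  found <- paste(res$payload$peaks$row, res$payload$peaks$col)
  expect_true(all(planted %in% found))
  # defaults are inherited from the base
  expect_equal(track_defaults("CustomLoops")$style, "triangular")
  expect_error(register_track_type("NoFns"), "fetch and a draw")
})
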