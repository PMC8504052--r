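# Layout geometry, drawing determinism and the joint 2D view.  Numerical
# assertions live on geometry specs and fetch payloads; images are checked
# for existence and byte determinism only.

demo_frame <- function() {
  make_track("XAxis") +
    make_track("BedGraph", fixture_path("bedgraph"), title = "signal") +
    make_track("Spacer") +
    make_track("GTF", fixture_path("gtf")) +
    make_track("Arcs", fixture_path("bedpe")) +
    make_track("HiCMat", fixture_path("matrix_a")) +
    make_track("InsuScore", fixture_path("matrix_a")) +
    make_track("DiScore", fixture_path("matrix_a")) +
    make_track("SNP", fixture_path("snp"))
}

test_that("gene rows pack greedily without same-row overlap", {
  g <- tibble::tibble(start = c(1, 5, 20), end = c(10, 15, 30))
  expect_equal(layout_gene_rows(g, 0), c(0, 1, 0))
  expect_equal(layout_gene_rows(tibble::tibble(start = c(1, 20, 40),
                                               end = c(10, 30, 50))),
               c(0, 0, 0))
  # k mutually overlapping records need k distinct rows
  k <- 6
  overl <- tibble::tibble(start = seq_len(k), end = rep(100, k))
  expect_equal(sort(layout_gene_rows(overl)), 0:(k - 1))
  # min_gap forces separation
  close_by <- tibble::tibble(start = c(1, 12), end = c(10, 20))
  expect_equal(layout_gene_rows(close_by, min_gap = 0), c(0, 0))
  expect_equal(layout_gene_rows(close_by, min_gap = 5), c(0, 1))
})

test_that("arc geometry places apexes and scales heights and widths", {
  pairs <- tibble::tibble(chrom1 = "chr1", start1 = c(90, 100), end1 = c(110, 100),
                          chrom2 = "chr1", start2 = c(290, 500), end2 = c(310, 500),
                          name = "", score = c(NA, NA))
  geom <- arc_geometry(pairs)
  expect_equal(geom$apex_x[1], 200)      # midpoints 100 and 300
  expect_equal(geom$span, c(200, 400))
  expect_equal(geom$height, c(0.5, 1))   # ratio 1:2, tallest normalized to 1
  expect_true(all(geom$lwd == geom$lwd[1]))  # no scores: equal widths

  pairs$score <- c(1, 3)
  geom2 <- arc_geometry(pairs)
  expect_gt(geom2$lwd[2], geom2$lwd[1])
})

test_that("matrix panel transform clamps, colormaps and annotates", {
  m <- cm_of(matrix(0, 4, 4))
  mpt <- matrix_panel_transform(m, "square", "log1p")
  expect_equal(length(unique(as.vector(mpt$colors))), 1)  # uniform min color

  vals <- matrix(c(0, 5, 5, 100), 2, 2)
  mc <- matrix_panel_transform(cm_of(vals), "square", "linear",
                               clamp = c(0, 10))
  expect_equal(mc$colorbar$hi, 10)  # colorbar labeled with the clamp
  ten <- matrix_panel_transform(cm_of(matrix(10, 2, 2)), "square", "linear",
                                clamp = c(0, 10))
  expect_equal(mc$colors[2, 2], ten$colors[1, 1])  # 100 renders as 10

  nan_m <- cm_of(matrix(c(1, NaN, NaN, 1), 2, 2))
  mn <- matrix_panel_transform(nan_m, "square")
  expect_true(is.na(mn$colors[1, 2]))

  wide <- trackkit:::new_contact_matrix(
    matrix(1, 3, 5),
    range_to_bins(genome_range("chr1", 1, 300), 100),
    range_to_bins(genome_range("chr1", 401, 900), 100)
  )
  expect_equal(dim(matrix_panel_transform(wide, "square")$colors), c(3, 5))
})

test_that("panel layout tiles the figure proportional to track heights", {
  fr <- demo_frame()
  plan <- layout_frame(fr)
  heights <- vapply(fr$tracks, function(t) t$props$height, 1.0)
  expect_equal(plan$panels$height, heights)
  expect_equal(plan$panels$y_bottom[-nrow(plan$panels)],
               plan$panels$y_top[-1])  # no gaps, no overlap
  expect_equal(plan$panels$track_id[plan$panels$track_type == "Spacer"],
               fr$tracks[[3]]$track_id)  # spacer consumes height
  expect_equal(sum(plan$panels$height) + 0.24, plan$height)
  # heights are proportional to props within rounding
  expect_equal(plan$panels$height / sum(plan$panels$height),
               heights / sum(heights), tolerance = 1e-9)
})

test_that("rendering is deterministic and produces all four formats", {
  fr <- demo_frame()
  r <- "chr1:1-400000"
  outs <- vapply(c("svg", "png", "jpeg", "pdf"), function(fmt) {
    f <- tempfile(fileext = paste0(".", fmt))
    render_frame(fr, r, f)
    f
  }, "")
  expect_true(all(file.exists(outs)))
  expect_true(all(file.size(outs) > 1000))

  f1 <- tempfile(fileext = ".svg"); f2 <- tempfile(fileext = ".svg")
  render_frame(fr, r, f1)
  render_frame(fr, r, f2)
  expect_identical(file_bytes(f1), file_bytes(f2))

  p1 <- tempfile(fileext = ".png"); p2 <- tempfile(fileext = ".png")
  render_frame(fr, r, p1)
  render_frame(fr, r, p2)
  expect_identical(file_bytes(p1), file_bytes(p2))
})

test_that("square matrix style and coverages render deterministically", {
  fr <- make_track("HiCMat", fixture_path("matrix_a"), style = "square") +
    make_track("BedGraph", fixture_path("bedgraph")) +
    coverage("highlight_region", region = "chr1:100001-150000") +
    make_track("Arcs", fixture_path("pairs")) +
    coverage("vlines", positions = c(200000, 300000))
  f1 <- tempfile(fileext = ".svg"); f2 <- tempfile(fileext = ".svg")
  render_frame(fr, "chr1:1-400000", f1)
  render_frame(fr, "chr1:1-400000", f2)
  expect_identical(file_bytes(f1), file_bytes(f2))
})

test_that("missing sources draw placeholders unless strict", {
  gone <- write_tmp_lines("chr1\t0\t100\t1")
  fr <- make_track("BedGraph", fixture_path("bedgraph")) +
    make_track("BedGraph", gone)
  unlink(gone)
  f <- tempfile(fileext = ".svg")
  render_frame(fr, "chr1:1-10000", f)
  expect_true(file.exists(f))   # placeholder panel, figure still produced
  f2 <- tempfile(fileext = ".svg")
  expect_error(render_frame(fr, "chr1:1-10000", f2, strict = TRUE),
               "fetch failed")
  expect_false(file.exists(f2))
})

test_that("rendering without a region set is an error", {
  fr <- frame(list(make_track("XAxis")))
  expect_error(render_frame(fr, out_path = tempfile(fileext = ".svg")),
               "no region set")
})

test_that("browser navigation renders exactly like a fresh frame", {
  fr <- make_track("XAxis") +
    make_track("BedGraph", fixture_path("bedgraph")) +
    make_track("HiCMat", fixture_path("matrix_a"))
  st <- browser_state(fr, "chr1:1-100000", fixture_chromsizes())
  st <- browser_goto(st, "chr1:50001-250000")
  st <- browser_zoom(st, 2)
  st <- browser_shift(st, 0.25)
  nav <- tempfile(fileext = ".svg")
  render_browser(st, nav)
  fresh <- tempfile(fileext = ".svg")
  render_frame(fr, st$range, fresh)
  expect_identical(file_bytes(nav), file_bytes(fresh))
})

test_that("joint view payloads equal direct fetches; layout spans match", {
  center <- make_track("HiCMat", fixture_path("matrix_a"))
  top <- make_track("XAxis") + make_track("BedGraph", fixture_path("bedgraph"))
  left <- make_track("BedGraph", fixture_path("bedgraph"))
  spec <- joint_view(center, range_h = "chr1:200001-400000",
                     range_v = "chr1:1-200000", top = top, left = left)

  ctr <- joint_center_fetch(spec)
  direct <- read_contact_matrix(fixture_path("matrix_a"),
                                "chr1:1-200000", "chr1:200001-400000")
  expect_equal(ctr$values, direct$values)
  expect_equal(format(ctr$row_axis$range), "chr1:1-200000")
  expect_equal(format(ctr$col_axis$range), "chr1:200001-400000")

  # side-frame payloads equal frame_fetch_all at their own ranges
  top_fetch <- frame_fetch_all(spec$side_frames$top, spec$range_h)
  left_fetch <- frame_fetch_all(spec$side_frames$left, spec$range_v)
  expect_equal(top_fetch[[2]]$payload,
               read_scored_intervals(fixture_path("bedgraph"), spec$range_h))
  expect_equal(left_fetch[[1]]$payload,
               read_scored_intervals(fixture_path("bedgraph"), spec$range_v))

  f1 <- tempfile(fileext = ".svg"); f2 <- tempfile(fileext = ".svg")
  render_joint_view(spec, f1)
  render_joint_view(spec, f2)
  expect_identical(file_bytes(f1), file_bytes(f2))

  # on-diagonal case: center matrix is symmetric
  diag_spec <- joint_view(center, range_h = "chr1:1-300000")
  dm <- joint_center_fetch(diag_spec)
  expect_identical(dm$values, t(dm$values))
  f3 <- tempfile(fileext = ".png")
  render_joint_view(diag_spec, f3)
  expect_true(file.size(f3) > 1000)
})
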