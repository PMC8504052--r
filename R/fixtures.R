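# Seeded synthetic-data generator: every supported input format with
# machine-readable ground truth, so the full toolkit is testable with no
# downloads.

#' Synthetic contact matrix with planted TADs and loops
#'
#' Builds a symmetric matrix from a distance-decay base
#' `round(C * exp(-|i-j| / decay_length))`, an in-TAD bonus `B` added where
#' `i` and `j` fall in the same planted block, and loop strengths added at
#' planted `(i, j)` / `(j, i)` cells; optionally resampled with seeded
#' Poisson noise (the mean structure is the noise-free matrix).  The
#' defaults (`C = 100`, `B = 50`, `decay_length = 5` bins) keep the
#' analytic scores well away from degeneracy.
#'
#' @param n_bins Number of bins.
#' @param boundaries Integer bin indices strictly inside `(1, n_bins)`;
#'   boundary `b` starts a new TAD block at bin `b` (blocks are
#'   `1..b-1`, `b..`, ...).
#' @param loops List of `c(i, j, strength)` planted loops.
#' @param decay_length Exponential decay length in bins.
#' @param base_c Contact count at distance 0 before bonuses.
#' @param tad_bonus In-TAD additive bonus.
#' @param noise `"off"` (exact) or `"poisson"` (seeded resampling).
#' @param seed Seed for the Poisson noise.
#' @param chrom,start,resolution Genomic annotation of the bin axis.
#' @return A [contact_matrix()].
#' @export
planted_matrix <- function(n_bins, boundaries = integer(), loops = list(),
                           decay_length = 5, base_c = 100, tad_bonus = 50,
                           noise = c("off", "poisson"), seed = 1L,
                           chrom = "chr1", start = 1, resolution = 10000) {
  noise <- match.arg(noise)
  n_bins <- as.integer(n_bins)
  boundaries <- as.integer(boundaries)
  if (length(boundaries) && (any(boundaries <= 1L) || any(boundaries >= n_bins))) {
    stop("`boundaries` must lie strictly inside (1, n_bins)", call. = FALSE)
  }
  d <- abs(outer(seq_len(n_bins), seq_len(n_bins), "-"))
  vals <- round(base_c * exp(-d / decay_length))
  block <- findInterval(seq_len(n_bins), boundaries)
  same_block <- outer(block, block, "==")
  vals <- vals + tad_bonus * same_block
  for (lp in loops) {
    i <- lp[1]; j <- lp[2]; s <- lp[3]
    vals[i, j] <- vals[i, j] + s
    if (i != j) vals[j, i] <- vals[j, i] + s
  }
  if (noise == "poisson") {
    vals <- with_fixture_rng(seed, {
      up <- upper.tri(vals, diag = TRUE)
      noisy <- vals
      noisy[up] <- stats::rpois(sum(up), vals[up])
      noisy[lower.tri(noisy)] <- t(noisy)[lower.tri(noisy)]
      noisy
    })
  }
  axis <- range_to_bins(
    genome_range(chrom, start, start + n_bins * resolution - 1), resolution
  )
  contact_matrix(vals, axis)
}

# run `code` under a fixed, fully specified RNG and restore the caller's
# RNG state afterwards
with_fixture_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

fmt_int <- function(x) formatC(x, format = "d")
fmt_val <- function(x, digits = 4) formatC(x, format = "f", digits = digits)

write_fixture_lines <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  path
}

#' Generate a complete synthetic dataset
#'
#' Writes every input format the toolkit reads — chromosome sizes,
#' bedGraph signal, BED3/6/12, GTF gene models, BEDPE and 4DN pairs loops,
#' a SNP table, and two HiC-Pro sparse contact matrices (condition "a" and
#' a condition "b" with one extra planted loop) — plus a JSON manifest of
#' the planted ground truth.  Regeneration with the same seed reproduces
#' every file byte-identically.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed driving all randomness.
#' @param chromsizes Named vector of chromosome lengths.
#' @param resolution Contact-matrix bin size in bp.
#' @return The manifest, invisibly (also written to `manifest.json`):
#'   list with `seed`, `chromsizes`, `resolution`,
#'   `planted_tad_boundaries`, `planted_loops`, `extra_loop_b`,
#'   `signal_functions`, `files` and per-file record counts.
#' @export
generate_dataset <- function(outdir, seed = 1L,
                             chromsizes = c(chr1 = 500000, chr2 = 300000),
                             resolution = 10000) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  files <- list()
  counts <- list()

  n1 <- as.integer(chromsizes[[1]] / resolution)
  n2 <- as.integer(chromsizes[[2]] / resolution)
  boundaries <- as.integer(round(c(0.36, 0.68) * n1))
  loops <- list(c(as.integer(0.20 * n1), as.integer(0.52 * n1), 60),
                c(as.integer(0.44 * n1), as.integer(0.80 * n1), 60))
  extra_loop_b <- c(as.integer(0.60 * n1), as.integer(0.90 * n1), 80)

  with_fixture_rng(seed, {
    # chromosome sizes ----------------------------------------------------
    files$chromsizes <- p("genome.chrom.sizes")
    write_fixture_lines(
      paste(names(chromsizes), fmt_int(chromsizes), sep = "\t"),
      files$chromsizes
    )

    # bedGraph signal: deterministic sine + seeded jitter -----------------
    sig <- list(width = 2000, base = 6, amplitude = 5, period = 50000,
                jitter_sd = 0.5)
    bg_lines <- character()
    n_bg <- 0L
    for (chrom in names(chromsizes)) {
      starts0 <- seq(0, chromsizes[[chrom]] - sig$width, by = sig$width)
      mids <- starts0 + sig$width / 2
      vals <- pmax(0, sig$base + sig$amplitude * sin(2 * pi * mids / sig$period) +
                     stats::rnorm(length(mids), 0, sig$jitter_sd))
      bg_lines <- c(bg_lines, paste(chrom, fmt_int(starts0),
                                    fmt_int(starts0 + sig$width),
                                    fmt_val(vals), sep = "\t"))
      n_bg <- n_bg + length(starts0)
    }
    files$bedgraph <- p("signal.bedgraph")
    write_fixture_lines(bg_lines, files$bedgraph)
    counts$bedgraph_intervals <- n_bg

    # BED fixtures ---------------------------------------------------------
    random_intervals <- function(chrom, n, max_len, min_len = 100) {
      chrom_len <- chromsizes[[chrom]]
      s <- sort(sample.int(chrom_len - max_len, n))
      len <- sample.int(max_len - min_len, n) + min_len
      tibble::tibble(chrom = chrom, start0 = s, end0 = pmin(s + len, chrom_len))
    }
    bed6 <- dplyr::bind_rows(random_intervals("chr1", 24, 15000),
                             random_intervals("chr2", 12, 15000))
    bed6$name <- paste0("feat_", seq_len(nrow(bed6)))
    bed6$score <- sample.int(1000, nrow(bed6))
    bed6$strand <- sample(c("+", "-"), nrow(bed6), replace = TRUE)
    files$bed6 <- p("features.bed")
    write_fixture_lines(
      paste(bed6$chrom, fmt_int(bed6$start0), fmt_int(bed6$end0), bed6$name,
            fmt_int(bed6$score), bed6$strand, sep = "\t"),
      files$bed6
    )
    counts$bed6_records <- nrow(bed6)

    bed3 <- random_intervals("chr1", 15, 20000)
    files$bed3 <- p("regions.bed")
    write_fixture_lines(
      paste(bed3$chrom, fmt_int(bed3$start0), fmt_int(bed3$end0), sep = "\t"),
      files$bed3
    )
    counts$bed3_records <- nrow(bed3)

    # gene-like BED12 + matching GTF ---------------------------------------
    make_genes <- function(chrom, n, prefix) {
      g <- random_intervals(chrom, n, 40000, min_len = 8000)
      g$name <- paste0(prefix, seq_len(n))
      g$strand <- sample(c("+", "-"), n, replace = TRUE)
      g$exons <- lapply(seq_len(n), function(k) {
        len <- g$end0[k] - g$start0[k]
        n_ex <- sample(2:4, 1)
        cuts <- sort(sample.int(len - 200, n_ex * 2)) + g$start0[k]
        ex_s <- cuts[seq(1, by = 2, length.out = n_ex)]
        ex_e <- cuts[seq(2, by = 2, length.out = n_ex)]
        ex_s[1] <- g$start0[k]
        ex_e[n_ex] <- g$end0[k]
        tibble::tibble(start0 = ex_s, end0 = ex_e)
      })
      g
    }
    genes <- dplyr::bind_rows(make_genes("chr1", 6, "geneA"),
                              make_genes("chr2", 3, "geneB"))
    bed12_lines <- vapply(seq_len(nrow(genes)), function(k) {
      ex <- genes$exons[[k]]
      paste(genes$chrom[k], fmt_int(genes$start0[k]), fmt_int(genes$end0[k]),
            genes$name[k], "0", genes$strand[k],
            fmt_int(genes$start0[k]), fmt_int(genes$end0[k]), "0",
            fmt_int(nrow(ex)),
            paste0(paste(fmt_int(ex$end0 - ex$start0), collapse = ","), ","),
            paste0(paste(fmt_int(ex$start0 - genes$start0[k]), collapse = ","), ","),
            sep = "\t")
    }, "")
    files$bed12 <- p("genes.bed")
    write_fixture_lines(bed12_lines, files$bed12)
    counts$bed12_records <- nrow(genes)

    gtf_lines <- c("#!genome synthetic")
    for (k in seq_len(nrow(genes))) {
      ex <- genes$exons[[k]]
      attr_txt <- sprintf('gene_id "G%04d"; gene_name "%s"; transcript_id "%s.t1";',
                          k, genes$name[k], genes$name[k])
      gtf_lines <- c(
        gtf_lines,
        paste(genes$chrom[k], "synthetic", "transcript",
              fmt_int(genes$start0[k] + 1), fmt_int(genes$end0[k]),
              ".", genes$strand[k], ".", attr_txt, sep = "\t"),
        paste(genes$chrom[k], "synthetic", "exon",
              fmt_int(ex$start0 + 1), fmt_int(ex$end0),
              ".", genes$strand[k], ".", attr_txt, sep = "\t")
      )
    }
    # one gene carrying only gene_id, to exercise the naming fallback
    gtf_lines <- c(gtf_lines,
      paste("chr2", "synthetic", "exon", fmt_int(5001), fmt_int(8000), ".",
            "+", ".", 'gene_id "orphan1";', sep = "\t"))
    files$gtf <- p("annotation.gtf")
    write_fixture_lines(gtf_lines, files$gtf)
    counts$gtf_genes <- nrow(genes) + 1L

    # loops: BEDPE anchors = planted loop bins -----------------------------
    bin_span0 <- function(b) c((b - 1) * resolution, b * resolution)
    bedpe_lines <- vapply(seq_along(loops), function(k) {
      lp <- loops[[k]]
      a1 <- bin_span0(lp[1]); a2 <- bin_span0(lp[2])
      paste("chr1", fmt_int(a1[1]), fmt_int(a1[2]),
            "chr1", fmt_int(a2[1]), fmt_int(a2[2]),
            paste0("loop_", k), fmt_int(lp[3]), "+", "-", sep = "\t")
    }, "")
    files$bedpe <- p("loops.bedpe")
    write_fixture_lines(bedpe_lines, files$bedpe)
    counts$bedpe_records <- length(loops)

    pairs_lines <- c(
      "## pairs format v1.0",
      "#columns: readID chr1 pos1 chr2 pos2",
      vapply(seq_along(loops), function(k) {
        lp <- loops[[k]]
        paste(paste0("loop_", k), "chr1",
              fmt_int((lp[1] - 1) * resolution + resolution / 2),
              "chr1", fmt_int((lp[2] - 1) * resolution + resolution / 2),
              sep = "\t")
      }, "")
    )
    files$pairs <- p("loops.pairs")
    write_fixture_lines(pairs_lines, files$pairs)

    # SNP table ------------------------------------------------------------
    snp <- dplyr::bind_rows(
      tibble::tibble(chrom = "chr1",
                     pos = sort(sample.int(chromsizes[["chr1"]], 80))),
      tibble::tibble(chrom = "chr2",
                     pos = sort(sample.int(chromsizes[["chr2"]], 40)))
    )
    snp$pvalue <- signif(stats::runif(nrow(snp))^3, 4)
    files$snp <- p("snps.tsv")
    write_fixture_lines(
      c("chrom\tpos\tpvalue",
        paste(snp$chrom, fmt_int(snp$pos), formatC(snp$pvalue, format = "g"),
              sep = "\t")),
      files$snp
    )
    counts$snp_records <- nrow(snp)

    # HiC-Pro matrices ------------------------------------------------------
    mat_a1 <- planted_matrix(n1, boundaries, loops, resolution = resolution,
                             chrom = "chr1")
    mat_b1 <- planted_matrix(n1, boundaries, c(loops, list(extra_loop_b)),
                             resolution = resolution, chrom = "chr1")
    mat_2 <- planted_matrix(n2, resolution = resolution, chrom = "chr2")

    bins_lines <- c(
      paste("chr1", fmt_int((seq_len(n1) - 1) * resolution),
            fmt_int(seq_len(n1) * resolution), fmt_int(seq_len(n1)),
            fmt_val(stats::runif(n1, 0.8, 1.2)), sep = "\t"),
      paste("chr2", fmt_int((seq_len(n2) - 1) * resolution),
            fmt_int(seq_len(n2) * resolution), fmt_int(n1 + seq_len(n2)),
            fmt_val(stats::runif(n2, 0.8, 1.2)), sep = "\t")
    )

    triplet_lines <- function(m1, m2) {
      tri <- function(m, offset) {
        v <- m$values
        idx <- which(upper.tri(v, diag = TRUE) & v != 0, arr.ind = TRUE)
        idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
        paste(fmt_int(idx[, 1] + offset), fmt_int(idx[, 2] + offset),
              fmt_int(v[idx]), sep = "\t")
      }
      c(tri(m1, 0L), tri(m2, n1))
    }
    files$matrix_a <- p("hic_a.matrix")
    files$matrix_a_bins <- p("hic_a_abs.bed")
    files$matrix_b <- p("hic_b.matrix")
    files$matrix_b_bins <- p("hic_b_abs.bed")
    write_fixture_lines(bins_lines, files$matrix_a_bins)
    write_fixture_lines(bins_lines, files$matrix_b_bins)
    write_fixture_lines(triplet_lines(mat_a1, mat_2), files$matrix_a)
    write_fixture_lines(triplet_lines(mat_b1, mat_2), files$matrix_b)
    counts$matrix_bins <- n1 + n2

    manifest <- list(
      seed = seed,
      chromsizes = as.list(chromsizes),
      resolution = resolution,
      planted_tad_boundaries = boundaries,
      planted_loops = lapply(loops, function(lp) {
        list(bin_i = lp[1], bin_j = lp[2], strength = lp[3])
      }),
      extra_loop_b = list(bin_i = extra_loop_b[1], bin_j = extra_loop_b[2],
                          strength = extra_loop_b[3]),
      signal_functions = list(bedgraph = sig),
      files = lapply(files, basename),
      counts = counts
    )
    files$manifest <- p("manifest.json")
    jsonlite::write_json(manifest, files$manifest, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    manifest$paths <- files
    invisible(manifest)
  })
}
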