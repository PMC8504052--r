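# Independent brute-force oracles.  Deliberately minimal base-R code with
# no shared machinery with the package: whole-file linear scans with an
# any-overlap filter for the readers, and scalar (non-vectorized) reference
# implementations for the Hi-C statistics.

oracle_lines <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[!grepl("^(#|track\\b|browser\\b)", txt) & nzchar(trimws(txt))]
  strsplit(txt, "\t", fixed = TRUE)
}

oracle_overlap <- function(chrom, s, e, range) {
  chrom == range$chrom && s <= range$end && e >= range$start
}

oracle_bedgraph <- function(path, range) {
  rows <- list()
  for (f in oracle_lines(path)) {
    s <- as.numeric(f[2]) + 1; e <- as.numeric(f[3])
    if (oracle_overlap(f[1], s, e, range)) {
      rows[[length(rows) + 1]] <- data.frame(chrom = f[1], start = s, end = e,
                                             value = as.numeric(f[4]))
    }
  }
  if (!length(rows)) {
    data.frame(chrom = character(), start = double(), end = double(),
               value = double())
  } else do.call(rbind, rows)
}

oracle_bed_spans <- function(path, range) {
  rows <- list()
  for (f in oracle_lines(path)) {
    s <- as.numeric(f[2]) + 1; e <- as.numeric(f[3])
    if (oracle_overlap(f[1], s, e, range)) {
      rows[[length(rows) + 1]] <- data.frame(
        chrom = f[1], start = s, end = e,
        name = if (length(f) >= 4) f[4] else ""
      )
    }
  }
  if (!length(rows)) {
    data.frame(chrom = character(), start = double(), end = double(),
               name = character())
  } else do.call(rbind, rows)
}

oracle_gtf_genes <- function(path, range) {
  ex <- list()
  for (f in oracle_lines(path)) {
    if (f[3] != "exon" || f[1] != range$chrom) next
    gn <- regmatches(f[9], regexec('gene_name "([^"]*)"', f[9]))[[1]]
    gid <- regmatches(f[9], regexec('gene_id "([^"]*)"', f[9]))[[1]]
    key <- if (length(gn) == 2) gn[2] else if (length(gid) == 2) gid[2] else next
    ex[[length(ex) + 1]] <- data.frame(key = key, s = as.numeric(f[4]),
                                       e = as.numeric(f[5]))
  }
  if (!length(ex)) return(character())
  ex <- do.call(rbind, ex)
  keys <- unique(ex$key)
  hit <- character()
  for (k in keys) {
    span_s <- min(ex$s[ex$key == k]); span_e <- max(ex$e[ex$key == k])
    if (span_s <= range$end && span_e >= range$start) hit <- c(hit, k)
  }
  sort(hit)
}

oracle_pairs_either <- function(path, range) {
  keep <- list()
  for (f in oracle_lines(path)) {
    if (length(f) >= 6 && !is.na(suppressWarnings(as.numeric(f[3])))) {
      a <- c(f[1], as.numeric(f[2]) + 1, as.numeric(f[3]))
      b <- c(f[4], as.numeric(f[5]) + 1, as.numeric(f[6]))
    } else {
      a <- c(f[2], as.numeric(f[3]), as.numeric(f[3]))
      b <- c(f[4], as.numeric(f[5]), as.numeric(f[5]))
    }
    if (oracle_overlap(a[1], as.numeric(a[2]), as.numeric(a[3]), range) ||
        oracle_overlap(b[1], as.numeric(b[2]), as.numeric(b[3]), range)) {
      keep[[length(keep) + 1]] <- c(sort(c(as.numeric(a[2]), as.numeric(b[2]))))
    }
  }
  keep
}

oracle_snp <- function(path, range) {
  txt <- readLines(path, warn = FALSE)
  header <- strsplit(txt[1], "\t")[[1]]
  ci <- match(c("chrom", "pos", "pvalue"), header)
  rows <- list()
  for (line in txt[-1]) {
    f <- strsplit(line, "\t")[[1]]
    pos <- as.numeric(f[ci[2]])
    if (f[ci[1]] == range$chrom && pos >= range$start && pos <= range$end) {
      rows[[length(rows) + 1]] <- data.frame(chrom = f[ci[1]], pos = pos,
                                             pvalue = as.numeric(f[ci[3]]))
    }
  }
  if (!length(rows)) {
    data.frame(chrom = character(), pos = double(), pvalue = double())
  } else do.call(rbind, rows)
}

# dense window by dict lookup over the triplet file
oracle_matrix_window <- function(matrix_path, bins_path, row_ids, col_ids) {
  lut <- new.env()
  for (f in oracle_lines(matrix_path)) {
    assign(paste(f[1], f[2]), as.numeric(f[3]), envir = lut)
  }
  get0_ <- function(i, j) {
    v <- get0(paste(i, j), envir = lut)
    if (is.null(v)) v <- get0(paste(j, i), envir = lut)
    if (is.null(v)) 0 else v
  }
  out <- matrix(0, length(row_ids), length(col_ids))
  for (a in seq_along(row_ids)) {
    for (b in seq_along(col_ids)) {
      out[a, b] <- get0_(row_ids[a], col_ids[b])
    }
  }
  out
}

# ---- scalar reference implementations of the Hi-C statistics -------------

ref_virtual_4c <- function(m, rows) {
  out <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    acc <- 0
    for (i in rows) acc <- acc + m[i, j]
    out[j] <- acc / length(rows)
  }
  out
}

ref_di <- function(m, w) {
  n <- nrow(m)
  out <- rep(NaN, n)
  for (i in seq_len(n)) {
    if (i - w < 1 || i + w > n) next
    a <- 0; b <- 0
    for (k in 1:w) {
      a <- a + m[i, i - k]
      b <- b + m[i, i + k]
    }
    e <- (a + b) / 2
    out[i] <- if (a == b || e == 0) 0 else {
      ((b - a) / abs(b - a)) * ((a - e)^2 / e + (b - e)^2 / e)
    }
  }
  out
}

ref_insulation <- function(m, w) {
  n <- nrow(m)
  raw <- rep(NaN, n)
  for (i in seq_len(n)) {
    if (i - w < 1 || i + w - 1 > n) next
    acc <- 0; cnt <- 0
    for (r in (i - w):(i - 1)) {
      for (c in i:(i + w - 1)) {
        if (is.finite(m[r, c])) {
          acc <- acc + m[r, c]; cnt <- cnt + 1
        }
      }
    }
    raw[i] <- if (cnt > 0) acc / cnt else NaN
  }
  mu <- mean(raw[is.finite(raw)])
  log2(raw / mu)
}

ref_zscore_distance <- function(m) {
  n <- nrow(m)
  out <- matrix(NaN, n, n)
  for (d in 0:(n - 1)) {
    xs <- c()
    for (i in 1:(n - d)) if (is.finite(m[i, i + d])) xs <- c(xs, m[i, i + d])
    for (i in 1:(n - d)) {
      x <- m[i, i + d]
      if (!is.finite(x)) { out[i, i + d] <- x; out[i + d, i] <- x; next }
      if (length(xs) < 2) { out[i, i + d] <- 0; out[i + d, i] <- 0; next }
      mu <- sum(xs) / length(xs)
      sd_p <- sqrt(sum((xs - mu)^2) / length(xs))
      z <- if (sd_p == 0) 0 else (x - mu) / sd_p
      out[i, i + d] <- z
      out[i + d, i] <- z
    }
  }
  out
}

random_test_range <- function(chromsizes, max_len = 100000) {
  chrom <- sample(names(chromsizes), 1)
  len <- sample.int(max_len, 1)
  start <- sample.int(max(1, chromsizes[[chrom]] - len), 1)
  genome_range(chrom, start, min(start + len, chromsizes[[chrom]]))
}
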