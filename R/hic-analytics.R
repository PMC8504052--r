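#' Score profiles along a bin axis
#'
#' The common return type of the Hi-C analytic operations: one value per
#' bin of a [range_to_bins()] axis.  Edge bins that lack the context a
#' statistic needs are `NaN`; analytic code never silently converts `NaN`
#' to 0 — display layers decide.
#'
#' @param axis A `bin_axis`.
#' @param values Numeric vector of length `axis$n_bins`.
#' @param kind Profile kind tag (`"virtual4c"`, `"di"`, `"insulation"`).
#' @return An object of class `score_profile`.
#' @export
score_profile <- function(axis, values, kind) {
  stopifnot(inherits(axis, "bin_axis"), length(values) == axis$n_bins)
  structure(list(axis = axis, values = as.numeric(values), kind = kind),
            class = "score_profile")
}

#' @export
print.score_profile <- function(x, ...) {
  cat("<score_profile:", x$kind, "> ", format(x$axis), ", ",
      sum(is.finite(x$values)), "/", x$axis$n_bins, " finite values\n", sep = "")
  invisible(x)
}

#' @export
#' @method as_tibble score_profile
as_tibble.score_profile <- function(x, ...) {
  dplyr::mutate(as_tibble(x$axis), value = x$values, kind = x$kind)
}

check_square <- function(m, what) {
  stopifnot(inherits(m, "contact_matrix"))
  if (!is_square_matrix(m)) {
    stop(what, " requires an on-diagonal (square) contact matrix", call. = FALSE)
  }
}

#' Virtual 4C profile from a contact matrix
#'
#' Extracts a one-locus contact profile that mimics a 4C experiment: for
#' each bin `j` of the matrix axis, the mean contact between `j` and the
#' bins overlapped by the anchor.  A single-bin anchor is an exact row
#' extraction.  `NaN` entries propagate (no `NaN` removal), so an all-`NaN`
#' anchor row yields an all-`NaN` profile.
#'
#' @param matrix A square [contact_matrix()].
#' @param anchor Anchor region ([genome_range()] or string); must overlap
#'   the matrix range.
#' @return A [score_profile()] of kind `"virtual4c"`.
#' @export
virtual_4c <- function(matrix, anchor) {
  check_square(matrix, "virtual_4c")
  anchor <- parse_region(anchor)
  ax <- matrix$row_axis
  hit <- which(ax$range$chrom == anchor$chrom &
                 ax$starts <= anchor$end & ax$ends >= anchor$start)
  if (!length(hit)) {
    stop("anchor ", format(anchor), " does not overlap the matrix range ",
         format(ax$range), call. = FALSE)
  }
  vals <- colMeans(matrix$values[hit, , drop = FALSE])
  score_profile(ax, vals, "virtual4c")
}

#' Directionality index of a contact matrix
#'
#' The signed chi-square-like TAD statistic: for bin `i`, with upstream sum
#' `A = sum_k M[i, i-k]`, downstream sum `B = sum_k M[i, i+k]` over
#' `k = 1..window` and `E = (A+B)/2`,
#' `DI_i = sign(B - A) * ((A-E)^2/E + (B-E)^2/E)`; `DI_i = 0` when `A = B`
#' or `E = 0`.  Bins within `window` of either matrix edge are `NaN`.  Its
#' sign flips at TAD boundaries.
#'
#' @param matrix A square [contact_matrix()].
#' @param window Window size in bins (`1 <= window < n_bins`).
#' @return A [score_profile()] of kind `"di"`.
#' @export
directionality_index <- function(matrix, window = 5L) {
  check_square(matrix, "directionality_index")
  n <- nrow(matrix$values)
  window <- as.integer(window)
  if (window < 1L || window >= n) {
    stop("`window` must satisfy 1 <= window < n_bins (= ", n, ")", call. = FALSE)
  }
  m <- matrix$values
  vals <- rep(NaN, n)
  for (i in (window + 1L):(n - window)) {
    a <- sum(m[i, (i - window):(i - 1L)])
    b <- sum(m[i, (i + 1L):(i + window)])
    e <- (a + b) / 2
    vals[i] <- if (is.na(a) || is.na(b)) {
      NaN
    } else if (a == b || e == 0) {
      0
    } else {
      sign(b - a) * ((a - e)^2 / e + (b - e)^2 / e)
    }
  }
  score_profile(matrix$row_axis, vals, "di")
}

#' Insulation score of a contact matrix
#'
#' The diamond insulation statistic: `raw_i` is the `NaN`-aware mean of the
#' `window x window` block `M[(i-window)..(i-1), i..(i+window-1)]` — the
#' contacts crossing position `i` — and the reported score is
#' `log2(raw_i / mean(raw))` over all bins with a full diamond
#' (`normalize = "log2_mean"`, default) or the raw mean itself
#' (`normalize = "none"`).  Local minima of the score mark TAD boundaries.
#' Bins whose diamond does not fit are `NaN`.
#'
#' @param matrix A square [contact_matrix()].
#' @param window Diamond half-width in bins (`window <= (n_bins - 1)/2`).
#' @param normalize `"log2_mean"` or `"none"`.
#' @return A [score_profile()] of kind `"insulation"`.
#' @export
insulation_score <- function(matrix, window = 5L,
                             normalize = c("log2_mean", "none")) {
  check_square(matrix, "insulation_score")
  normalize <- match.arg(normalize)
  n <- nrow(matrix$values)
  window <- as.integer(window)
  if (window < 1L || window > (n - 1) / 2) {
    stop("`window` must satisfy 1 <= window <= (n_bins - 1)/2 (n_bins = ", n, ")",
         call. = FALSE)
  }
  m <- matrix$values
  raw <- rep(NaN, n)
  for (i in (window + 1L):(n - window + 1L)) {
    block <- m[(i - window):(i - 1L), i:(i + window - 1L), drop = FALSE]
    fin <- block[is.finite(block)]
    raw[i] <- if (length(fin)) mean(fin) else NaN
  }
  if (normalize == "none") {
    return(score_profile(matrix$row_axis, raw, "insulation"))
  }
  fin <- raw[is.finite(raw)]
  if (!length(fin) || mean(fin) <= 0) {
    stop("insulation score undefined: all diamond means are NaN or their mean is not positive",
         call. = FALSE)
  }
  score_profile(matrix$row_axis, log2(raw / mean(fin)), "insulation")
}

zscore_values_by_distance <- function(m) {
  n <- nrow(m)
  out <- matrix(NaN, n, n)
  for (d in 0:(n - 1L)) {
    i <- seq_len(n - d)
    idx <- cbind(i, i + d)
    x <- m[idx]
    fin <- is.finite(x)
    if (sum(fin) < 2L) {
      x[fin] <- 0
    } else {
      mu <- mean(x[fin])
      sd_p <- sqrt(mean((x[fin] - mu)^2))  # population SD
      x[fin] <- if (sd_p == 0) 0 else (x[fin] - mu) / sd_p
    }
    out[idx] <- x
    out[idx[, c(2, 1), drop = FALSE]] <- x
  }
  out
}

zscore_values_global <- function(m) {
  fin <- is.finite(m)
  x <- m[fin]
  out <- m
  if (length(x) < 2L || stats::sd(x) == 0) {
    out[fin] <- 0
    return(out)
  }
  mu <- mean(x)
  sd_p <- sqrt(mean((x - mu)^2))
  out[fin] <- (x - mu) / sd_p
  out
}

#' Z-score normalize a contact matrix
#'
#' With `method = "distance"` (default), every diagonal offset `d` is
#' z-scored independently — `(x - mu_d) / sigma_d` with population mean/SD
#' over the finite entries of that diagonal — which removes the distance
#' decay so that differences highlight local structure.  Diagonals with
#' fewer than 2 finite entries or zero SD become 0.  `method = "global"`
#' z-scores all finite entries together.  Non-finite entries stay `NaN` and
#' the output is re-symmetrized.
#'
#' @param matrix A square [contact_matrix()].
#' @param method `"distance"` (per-diagonal) or `"global"`.
#' @return A [contact_matrix()] of z-scores (may contain negatives).
#' @export
zscore_by_distance <- function(matrix, method = c("distance", "global")) {
  check_square(matrix, "zscore_by_distance")
  method <- match.arg(method)
  vals <- switch(method,
    distance = zscore_values_by_distance(matrix$values),
    global = zscore_values_global(matrix$values)
  )
  new_contact_matrix(vals, matrix$row_axis, matrix$col_axis)
}

#' Differential (z-score) contact matrix
#'
#' `zscore_by_distance(a) - zscore_by_distance(b)`, elementwise, over
#' identical axes: positive cells mark contacts enriched in `a`, negative
#' cells contacts enriched in `b`.  Cells that are `NaN` in either input
#' are `NaN` in the difference.
#'
#' @param a,b Square [contact_matrix()] objects on identical axes.
#' @param method Z-scoring method, see [zscore_by_distance()].
#' @return A [contact_matrix()] of z-score differences.
#' @export
diff_matrix <- function(a, b, method = c("distance", "global")) {
  method <- match.arg(method)
  check_square(a, "diff_matrix")
  check_square(b, "diff_matrix")
  if (!axes_identical(a$row_axis, b$row_axis) || a$resolution != b$resolution) {
    stop("diff_matrix requires identical axes; got ", format(a$row_axis),
         " vs ", format(b$row_axis), call. = FALSE)
  }
  za <- zscore_by_distance(a, method)
  zb <- zscore_by_distance(b, method)
  new_contact_matrix(za$values - zb$values, a$row_axis, a$col_axis)
}
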