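# Hi-C analytic statistics against hand-derived cases and independent
# scalar reference implementations.

test_that("virtual 4C extracts anchor rows and averages multi-bin anchors", {
  m <- cm_of(matrix(c(4, 2, 0,
                      2, 4, 2,
                      0, 2, 4), 3, 3, byrow = TRUE))
  # second bin (positions 101-200) is the single-bin anchor
  expect_equal(virtual_4c(m, "chr1:101-200")$values, c(2, 4, 2))
  # anchor over bins 1-2: column-wise mean of rows 1 and 2
  expect_equal(virtual_4c(m, "chr1:1-200")$values, c(3, 3, 1))
  # whole-range anchor = column means
  expect_equal(virtual_4c(m, "chr1:1-300")$values, colMeans(m$values))

  nan_m <- m
  nan_m$values[2, ] <- NaN
  nan_m$values[, 2] <- NaN
  expect_true(all(is.nan(virtual_4c(nan_m, "chr1:101-200")$values)))

  expect_error(virtual_4c(m, "chr2:1-100"), "does not overlap")
})

test_that("directionality index matches the signed chi-square form", {
  # w = 1; bin 3 sees A = 2 upstream, B = 8 downstream
  v <- matrix(0, 5, 5)
  v[3, 2] <- 2; v[2, 3] <- 2
  v[3, 4] <- 8; v[4, 3] <- 8
  di <- directionality_index(cm_of(v), 1)
  expect_equal(di$values[3], 3.6)   # E = 5: sign(6) * (9/5 + 9/5)

  # A = 8, B = 2: antisymmetric under swapping up/downstream
  v_sw <- matrix(0, 5, 5)
  v_sw[3, 2] <- 8; v_sw[2, 3] <- 8
  v_sw[3, 4] <- 2; v_sw[4, 3] <- 2
  expect_equal(directionality_index(cm_of(v_sw), 1)$values[3], -3.6)

  # symmetric environment (A = B) forces DI = 0
  const <- cm_of(matrix(7, 9, 9))
  di_c <- directionality_index(const, 3)$values
  expect_true(all(di_c[4:6] == 0))
  expect_true(all(is.nan(di_c[c(1:3, 7:9)])))  # edge bins

  expect_error(directionality_index(const, 9), "window")
})

test_that("insulation score is a log2 ratio over the diamond means", {
  const <- cm_of(matrix(3, 11, 11))
  ins <- insulation_score(const, 2)$values
  expect_true(all(ins[is.finite(ins)] == 0))
  expect_true(all(is.nan(ins[c(1, 2, 11)])))

  # w = 1 on 3 bins: the two valid diamonds are M[1,2] and M[2,3]
  v <- matrix(1, 3, 3)
  v[1, 2] <- 2; v[2, 1] <- 2
  v[2, 3] <- 8; v[3, 2] <- 8
  ins2 <- insulation_score(cm_of(v), 1)$values
  expect_equal(ins2[2:3], c(log2(2 / 5), log2(8 / 5)))

  expect_error(insulation_score(cm_of(matrix(0, 5, 5)), 2), "not positive")
})

test_that("insulation is scale-invariant; DI is not (and scales linearly)", {
  set.seed(41)
  v <- matrix(stats::rpois(400, 20), 20, 20)
  v <- v + t(v)
  m <- cm_of(v)
  m5 <- cm_of(v * 5)
  ins1 <- insulation_score(m, 3)$values
  ins5 <- insulation_score(m5, 3)$values
  expect_equal(ins1, ins5, tolerance = 1e-12)

  di1 <- directionality_index(m, 3)$values
  di5 <- directionality_index(m5, 3)$values
  fin <- is.finite(di1)
  expect_false(isTRUE(all.equal(di1[fin], di5[fin])))
  expect_equal(di5[fin], 5 * di1[fin], tolerance = 1e-9)
})

test_that("per-distance z-scoring centers each diagonal", {
  v <- matrix(c(5, 1, 0,
                1, 5, 3,
                0, 3, 5), 3, 3, byrow = TRUE)
  z <- zscore_by_distance(cm_of(v))$values
  # off-diagonal d=1 has values {1, 3}: mu 2, population sd 1
  expect_equal(z[1, 2], -1)
  expect_equal(z[2, 3], 1)
  expect_equal(z[1, 1], 0)  # constant main diagonal
  expect_identical(z, t(z))

  set.seed(43)
  v2 <- matrix(stats::runif(625, 1, 9), 25, 25)
  v2 <- (v2 + t(v2)) / 2
  z2 <- zscore_by_distance(cm_of(v2))$values
  for (d in 0:24) {
    i <- seq_len(25 - d)
    diagv <- z2[cbind(i, i + d)]
    if (length(i) >= 2 && stats::sd(v2[cbind(i, i + d)]) > 0) {
      expect_lt(abs(mean(diagv)), 1e-9)
    }
  }

  # global variant z-scores the whole matrix at once
  zg <- zscore_by_distance(cm_of(v2), method = "global")$values
  expect_lt(abs(mean(zg)), 1e-9)
})

test_that("differential matrices are antisymmetric in their arguments", {
  set.seed(47)
  v <- matrix(stats::rpois(100, 30), 10, 10); v <- v + t(v)
  w <- matrix(stats::rpois(100, 30), 10, 10); w <- w + t(w)
  a <- cm_of(v); b <- cm_of(w)
  expect_true(all(abs(diff_matrix(a, a)$values) == 0))
  expect_lt(max(abs(diff_matrix(a, b)$values + diff_matrix(b, a)$values)),
            1e-9)
  expect_error(diff_matrix(a, cm_of(w[1:9, 1:9])), "identical axes")

  base <- planted_matrix(30, decay_length = 4)
  enr <- planted_matrix(30, loops = list(c(8, 21, 70)), decay_length = 4)
  d <- diff_matrix(enr, base)$values
  idx <- which(abs(d) == max(abs(d)), arr.ind = TRUE)
  expect_setequal(as.vector(idx), c(8, 21))
  expect_gt(d[8, 21], 0)  # enrichment in the first argument is positive
})

test_that("analytics match scalar reference implementations on random matrices", {
  set.seed(53)
  for (k in 1:10) {
    n <- 40
    v <- matrix(stats::runif(n * n, 0, 40), n, n)
    v <- (v + t(v)) / 2
    m <- cm_of(v)
    w <- sample(2:6, 1)
    expect_equal(directionality_index(m, w)$values, ref_di(v, w),
                 tolerance = 1e-9)
    expect_equal(insulation_score(m, w)$values, ref_insulation(v, w),
                 tolerance = 1e-9)
    rows <- sort(sample.int(n, sample.int(3, 1)))
    anchor <- genome_range("chr1", (rows[1] - 1) * 100 + 1,
                           rows[length(rows)] * 100)
    expect_equal(virtual_4c(m, anchor)$values,
                 ref_virtual_4c(v, rows[1]:rows[length(rows)]),
                 tolerance = 1e-9)
    expect_equal(zscore_by_distance(m)$values, ref_zscore_distance(v),
                 tolerance = 1e-9)
  }
})
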