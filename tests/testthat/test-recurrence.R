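example_symbols <- function() symbolize_window(example_series, m = 3)

test_that("recurrence matrix marks exactly the equal-symbol pairs", {
  M <- recurrence_matrix(example_symbols())
  expect_identical(dim(M), c(5L, 5L))
  expect_true(all(!is.na(diag(M))))
  off <- which(!is.na(M) & row(M) != col(M), arr.ind = TRUE)
  expect_setequal(paste(off[, 1], off[, 2]), c("2 3", "3 2"))
  expect_identical(M[2, 3], symbol_index(c(2L, 1L, 0L)))

  # constant symbol sequence: fully recurrent
  Mc <- recurrence_matrix(symbolize_window(1:6, m = 3))
  expect_false(anyNA(Mc))
  # all-distinct symbols: only the main diagonal
  Md <- recurrence_matrix(c(0L, 3L, 5L, 1L), m = 3L)
  expect_identical(sum(!is.na(Md)), 4L)
  expect_error(recurrence_matrix(integer(0)), "at least one")
})

test_that("recurrence rates match the worked example and decompose exactly", {
  M <- recurrence_matrix(example_symbols())
  expect_equal(global_srr(M), 7 / 25)
  expect_equal(symbol_srr(M, c(2, 1, 0)), 4 / 25)
  expect_equal(symbol_srr(M, c(1, 2, 0)), 0)
  expect_equal(sum(symbol_srr_all(M)$srr), global_srr(M))
  expect_equal(global_srr(recurrence_matrix(rep(2L, 4L), 3L)), 1)
  expect_equal(global_srr(recurrence_matrix(3L, 3L)), 1) # n = 1
})

test_that("line distributions match hand-derived fixtures", {
  M <- recurrence_matrix(example_symbols())
  expect_identical(nrow(diagonal_lines(M)), 0L) # isolated off-diagonal points

  v <- vertical_lines(M, c(2, 1, 0))
  expect_equal(as.data.frame(v), data.frame(length = 2L, count = 2L),
               ignore_attr = TRUE)
  expect_identical(nrow(vertical_lines(M, c(0, 1, 2))), 0L)
  # non-monotone symbols can never build vertical lines for m = 3
  for (idx in 1:4) expect_identical(nrow(vertical_lines(M, idx)), 0L)

  Mc <- recurrence_matrix(rep(0L, 4L), 3L)
  dd <- diagonal_lines(Mc)
  expect_equal(as.data.frame(dd), data.frame(length = 2:3, count = c(2L, 2L)),
               ignore_attr = TRUE)
})

test_that("scalar measures follow their formulas on fixtures", {
  M <- recurrence_matrix(example_symbols())
  expect_equal(determinism(diagonal_lines(M), global_srr(M), 5), 0)

  Mc <- recurrence_matrix(rep(0L, 4L), 3L)
  expect_equal(determinism(diagonal_lines(Mc), 1, 4), 10 / 16)
  expect_error(determinism(diagonal_lines(Mc), 0, 4), "positive")

  expect_equal(trapping_time(vertical_lines(M, c(2, 1, 0))), 2)
  empty <- diagonal_lines(M)
  expect_equal(trapping_time(empty), 0)

  expect_equal(line_entropy(vertical_lines(M, c(2, 1, 0))), 0)
  two <- structure(tibble::tibble(length = 2:3, count = c(1L, 1L)),
                   class = class(empty))
  expect_equal(line_entropy(two), log(2))
  skewed <- structure(tibble::tibble(length = 2:3, count = c(3L, 1L)),
                      class = class(empty))
  expect_equal(line_entropy(skewed), -(0.75 * log(0.75) + 0.25 * log(0.25)))

  expect_equal(rline_vertical(vertical_lines(M, c(2, 1, 0)),
                              symbol_srr(M, c(2, 1, 0)), 5), 1)
  expect_equal(rline_vertical(empty, 0.3, 5), 0)
  expect_equal(rline_vertical(vertical_lines(M, c(2, 1, 0)), 0, 5), 0)
})

test_that("srqa_measures composes the pieces", {
  out <- srqa_measures(example_symbols())
  expect_equal(out$srr, 0.28)
  expect_equal(out$srr_210, 0.16)
  expect_equal(out$det_d, 0)
  expect_equal(out$ent_d, 0)
  expect_equal(out$vbar_dec, 2)
  expect_equal(out$rline_v_dec, 1)
  expect_equal(out$ent_v_dec, 0)
  expect_equal(out$srr_012 + out$srr_021 + out$srr_102 + out$srr_120 +
                 out$srr_201 + out$srr_210, out$srr)
  expect_error(srqa_measures(0L, m = 3L), "at least 2")

  # strictly monotone window: all mass on the increasing symbol,
  # single full-height vertical run per column
  mono <- srqa_measures(symbolize_window(1:8, m = 3))
  expect_equal(mono$srr, 1)
  expect_equal(mono$srr_012, 1)
  expect_equal(mono$vbar_inc, 6)
  expect_equal(mono$rline_v_inc, 1)
})

test_that("random-sequence identities hold and lines match the oracle", {
  set.seed(7)
  for (rep in 1:60) {
    n <- sample(2:12, 1)
    sym <- sample(0:5, n, replace = TRUE)
    M <- recurrence_matrix(sym, 3L)
    expect_identical(M, t(M), ignore_attr = TRUE)
    # cell-wise decomposition of SR into the SR(pi)
    expect_identical(!is.na(M),
                     Reduce(`|`, lapply(0:5, function(i) !is.na(M) & M == i)))
    expect_equal(sum(symbol_srr_all(M)$srr), global_srr(M))
    expect_identical(dist_to_lengths(diagonal_lines(M)), oracle_diag_lines(M))
    for (i in 0:5) {
      expect_identical(dist_to_lengths(vertical_lines(M, i)),
                       oracle_vert_lines(M, i))
    }
    # diagonal mass is bounded by off-diagonal recurrence mass
    mass <- sum(diagonal_lines(M)$length * diagonal_lines(M)$count)
    expect_lte(mass, n^2 * global_srr(M) - n)
    D <- determinism(diagonal_lines(M), global_srr(M), n)
    expect_gte(D, 0); expect_lt(D, 1)
  }
})

test_that("symbol relabeling permutes per-symbol measures, fixes global ones", {
  set.seed(8)
  sym <- sample(0:5, 40, replace = TRUE)
  relab <- sample(0:5)
  M1 <- recurrence_matrix(sym, 3L)
  M2 <- recurrence_matrix(relab[sym + 1L], 3L)
  expect_equal(global_srr(M1), global_srr(M2))
  expect_equal(determinism(diagonal_lines(M1), global_srr(M1), 40),
               determinism(diagonal_lines(M2), global_srr(M2), 40))
  expect_equal(line_entropy(diagonal_lines(M1)), line_entropy(diagonal_lines(M2)))
  for (i in 0:5) {
    expect_equal(symbol_srr(M1, i), symbol_srr(M2, relab[i + 1L]))
    expect_equal(trapping_time(vertical_lines(M1, i)),
                 trapping_time(vertical_lines(M2, relab[i + 1L])))
  }
})

test_that("long i.i.d. windows have recurrence rate near the uniform value", {
  set.seed(9)
  s <- symbolize_window(runif(3000), m = 3)
  expect_equal(global_srr(recurrence_matrix(s)), 1 / 6, tolerance = 0.02)
})

test_that("srp point sets are symmetric and complete", {
  M <- recurrence_matrix(example_symbols())
  pts <- srp_points(M)
  expect_identical(nrow(pts), 7L) # 5 diagonal + 2 off
  expect_setequal(paste(pts$t, pts$s), paste(pts$s, pts$t))
  Md <- recurrence_matrix(c(0L, 3L, 5L, 1L), 3L)
  expect_identical(nrow(srp_points(Md)), 4L)
  p <- plot_srp(M)
  expect_s3_class(p, "ggplot")
})
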