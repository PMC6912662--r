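#' Symbolic recurrence matrix
#'
#' Two histories \eqn{\bar{x}_t} and \eqn{\bar{x}_s} are symbolic
#' recurrent when they share the same ordinal pattern. The matrix stores,
#' for each pair `(t, s)`, the shared 0-based symbol index, or `NA` when
#' the two histories differ. The global indicator SR is recovered as
#' `!is.na(M)` and the per-symbol indicator SR(pi) as `M == pi`; by
#' construction the per-symbol matrices partition SR. The matrix is
#' symmetric and its main diagonal is never `NA` (every state recurs with
#' itself).
#'
#' @param symbols a `symbol_seq` from [symbolize_window()], or an integer
#'   vector of symbol indices.
#' @param m embedding dimension, taken from `symbols` when available.
#' @return an `n x n` integer matrix of class `srqa_matrix` with
#'   attribute `m`.
#' @examples
#' recurrence_matrix(symbolize_window(c(3, 9, 7, 6, 5, 10, 4)))
#' @export
recurrence_matrix <- function(symbols, m = attr(symbols, "m") %||% 3L) {
  sym <- as.integer(symbols)
  n <- length(sym)
  if (n < 1) stop("`symbols` must contain at least one symbol", call. = FALSE)
  M <- matrix(NA_integer_, n, n)
  eq <- outer(sym, sym, "==")
  M[eq] <- matrix(sym, n, n)[eq] # column symbol; equal to row symbol where recurrent
  structure(M, m = as.integer(m), class = c("srqa_matrix", class(M)))
}

#' @export
print.srqa_matrix <- function(x, ...) {
  cat("<srqa_matrix>", nrow(x), "x", ncol(x), " m =", attr(x, "m"),
      " recurrence rate =", signif(global_srr(x), 4), "\n")
  invisible(x)
}

symbols_of <- function(M) as.integer(diag(M))

#' Global symbolic recurrence rate
#'
#' The fraction of matrix cells that are recurrent,
#' \eqn{SRR = n^{-2} \sum_{t,s} SR_{ts}}, main diagonal included (the sum
#' runs over all pairs). Hence `SRR >= 1/n` always.
#'
#' @param M an `srqa_matrix`.
#' @return a fraction in `[1/n, 1]`.
#' @export
global_srr <- function(M) {
  n <- nrow(M)
  sum(!is.na(M)) / n^2
}

#' Per-symbol symbolic recurrence rate
#'
#' \eqn{SRR(\pi) = n^{-2} \sum_{t,s} SR_{ts}(\pi)}. Summed over all
#' `factorial(m)` symbols this recovers [global_srr()] exactly.
#'
#' @param M an `srqa_matrix`.
#' @param symbol a 0-based symbol index or a permutation vector.
#' @return a fraction in `[0, 1]`.
#' @export
symbol_srr <- function(M, symbol) {
  idx <- if (length(symbol) > 1L) symbol_index(symbol) else as.integer(symbol)
  n <- nrow(M)
  sum(M == idx, na.rm = TRUE) / n^2
}

#' Recurrence rates for every symbol
#'
#' @param M an `srqa_matrix`.
#' @return a tibble with one row per symbol: `symbol`, `pattern`, `srr`.
#' @export
symbol_srr_all <- function(M) {
  m <- attr(M, "m")
  ids <- 0:(factorial(m) - 1L)
  tibble::tibble(
    symbol = ids,
    pattern = vapply(ids, symbol_label, character(1), m = m),
    srr = vapply(ids, function(i) symbol_srr(M, i), numeric(1))
  )
}

line_dist <- function(lengths, counts, kind, symbol = NA_integer_) {
  out <- tibble::tibble(length = as.integer(lengths), count = as.integer(counts))
  out <- dplyr::arrange(out, .data$length)
  structure(out, kind = kind, symbol = symbol,
            class = c("line_dist", class(out)))
}

run_lengths <- function(flags, min_len) {
  if (!length(flags)) return(integer())
  r <- rle(flags)
  r$lengths[r$values & r$lengths >= min_len]
}

#' Diagonal line length distribution
#'
#' Counts maximal runs of recurrent cells along every diagonal of the
#' matrix except the main one (which is trivially all-recurrent), over
#' both triangles, keeping runs of length at least `min_len`. Symbols may
#' vary along a run: a diagonal line of length `d` marks two equal
#' stretches of `d` consecutive symbols starting at different times,
#' evidence of repeated (quasi-periodic) dynamics.
#'
#' @param M an `srqa_matrix`.
#' @param min_len minimum line length retained (default 2).
#' @return a `line_dist` tibble with columns `length` and `count`.
#' @export
diagonal_lines <- function(M, min_len = 2L) {
  sym <- symbols_of(M)
  n <- length(sym)
  lens <- integer()
  if (n >= 2) {
    for (k in seq_len(n - 1L)) {
      hits <- sym[seq_len(n - k)] == sym[(1L + k):n]
      lens <- c(lens, run_lengths(hits, min_len))
    }
  }
  if (!length(lens)) return(line_dist(integer(), integer(), "diagonal"))
  tab <- table(lens)
  # each off-main diagonal appears in both triangles
  line_dist(as.integer(names(tab)), 2L * as.integer(tab), "diagonal")
}

#' Vertical line length distribution for one symbol
#'
#' Vertical lines in SR(\eqn{\delta}) are runs of consecutive histories
#' that all display the pattern \eqn{\delta}; they measure how long the
#' dynamics stays trapped in one cell of the symbolic partition. For
#' `m = 3` only the monotone patterns `(0,1,2)` and `(2,1,0)` can repeat
#' consecutively, so all other symbols always give an empty distribution.
#' Main-diagonal cells take part in runs. Every non-empty column of
#' SR(\eqn{\delta}) reproduces the same runs (those of \eqn{\delta} in the
#' symbol sequence), so each run is counted once per \eqn{\delta}-column.
#'
#' @param M an `srqa_matrix`.
#' @param symbol a 0-based symbol index or permutation vector.
#' @param min_len minimum line length retained (default 2).
#' @return a `line_dist` tibble with columns `length` and `count`.
#' @export
vertical_lines <- function(M, symbol, min_len = 2L) {
  idx <- if (length(symbol) > 1L) symbol_index(symbol) else as.integer(symbol)
  sym <- symbols_of(M)
  n_cols <- sum(sym == idx)
  lens <- run_lengths(sym == idx, min_len)
  if (!length(lens) || n_cols == 0L) {
    return(line_dist(integer(), integer(), "vertical", idx))
  }
  tab <- table(lens)
  line_dist(as.integer(names(tab)), n_cols * as.integer(tab), "vertical", idx)
}

dist_mass <- function(dist) sum(dist$length * dist$count)

#' Determinism of a symbolic recurrence matrix
#'
#' The fraction of recurrence mass lying on diagonal lines of length at
#' least 2 (main diagonal excluded):
#' \eqn{D = \sum_d d\,n(d) / (n^2 \, SRR)}.
#'
#' @param diag a diagonal `line_dist` from [diagonal_lines()].
#' @param srr the global recurrence rate of the same matrix.
#' @param n matrix side length.
#' @return a fraction in `[0, 1)`.
#' @export
determinism <- function(diag, srr, n) {
  if (srr <= 0) stop("`srr` must be positive", call. = FALSE)
  dist_mass(diag) / (n^2 * srr)
}

#' Trapping time (mean vertical line length)
#'
#' Average length of the vertical lines: \eqn{\bar{v} = \sum_v v\,n(v) /
#' \sum_v n(v)}; 0 for an empty distribution so that feature vectors stay
#' complete.
#'
#' @param vert a vertical `line_dist`.
#' @return 0 or a value `>= 2`.
#' @export
trapping_time <- function(vert) {
  total <- sum(vert$count)
  if (total == 0) return(0)
  dist_mass(vert) / total
}

#' Shannon entropy of a line length distribution
#'
#' \eqn{-\sum_\ell p(\ell)\log p(\ell)} in nats, with
#' \eqn{p(\ell) = n(\ell)/\sum n(\ell)}. Empty and single-length
#' distributions have entropy 0.
#'
#' @param dist a `line_dist`.
#' @return a non-negative real (nats).
#' @export
line_entropy <- function(dist) {
  total <- sum(dist$count)
  if (total == 0) return(0)
  p <- dist$count / total
  -sum(p * log(p))
}

#' Fraction of per-symbol recurrence mass on vertical lines
#'
#' A laminarity-style ratio mirroring the determinism formula:
#' \eqn{\sum_v v\,n(v) / (n^2 \, SRR(\delta))}, with the convention 0 when
#' \eqn{SRR(\delta) = 0}.
#'
#' @param vert a vertical `line_dist` for symbol \eqn{\delta}.
#' @param srr_symbol the recurrence rate of that symbol.
#' @param n matrix side length.
#' @return a fraction in `[0, 1]`.
#' @export
rline_vertical <- function(vert, srr_symbol, n) {
  if (srr_symbol <= 0) return(0)
  dist_mass(vert) / (n^2 * srr_symbol)
}

#' All SRQA measures for one symbolized window
#'
#' Composes the recurrence operations into the quantification set used as
#' classifier covariates: global and per-symbol recurrence rates,
#' determinism and diagonal-line entropy, and the vertical-line measures
#' (trapping time, vertical mass fraction, vertical entropy) for the two
#' monotone patterns — the only ones that can persist for `m = 3`
#' (`inc` = (0,1,2), `dec` = (2,1,0)).
#'
#' @param symbols a `symbol_seq` (length `n >= 2`) or integer symbol vector.
#' @param m embedding dimension, taken from `symbols` when available.
#' @return a one-row tibble with columns `srr`, `srr_<pattern>` for each
#'   of the `factorial(m)` patterns, `det_d`, `ent_d`, `vbar_inc`,
#'   `vbar_dec`, `rline_v_inc`, `rline_v_dec`, `ent_v_inc`, `ent_v_dec`.
#' @examples
#' srqa_measures(symbolize_window(c(3, 9, 7, 6, 5, 10, 4)))
#' @export
srqa_measures <- function(symbols, m = attr(symbols, "m") %||% 3L) {
  sym <- as.integer(symbols)
  if (length(sym) < 2) stop("need at least 2 symbols", call. = FALSE)
  m <- as.integer(m)
  M <- recurrence_matrix(sym, m)
  n <- length(sym)
  per_symbol <- symbol_srr_all(M)
  srr <- sum(per_symbol$srr)
  dd <- diagonal_lines(M)
  inc <- 0L
  dec <- factorial(m) - 1L
  v_inc <- vertical_lines(M, inc)
  v_dec <- vertical_lines(M, dec)
  out <- tibble::tibble(
    srr = srr,
    det_d = determinism(dd, srr, n),
    ent_d = line_entropy(dd),
    vbar_inc = trapping_time(v_inc),
    vbar_dec = trapping_time(v_dec),
    rline_v_inc = rline_vertical(v_inc, per_symbol$srr[per_symbol$symbol == inc], n),
    rline_v_dec = rline_vertical(v_dec, per_symbol$srr[per_symbol$symbol == dec], n),
    ent_v_inc = line_entropy(v_inc),
    ent_v_dec = line_entropy(v_dec)
  )
  srr_cols <- stats::setNames(as.list(per_symbol$srr), paste0("srr_", per_symbol$pattern))
  dplyr::bind_cols(tibble::as_tibble(srr_cols), out)
}

#' Point set of a symbolic recurrence plot
#'
#' Long-format view of the non-empty cells of a recurrence matrix, one
#' row per recurrent pair `(t, s)` with its shared symbol; the input to
#' [plot_srp()]. The set is symmetric under swapping `t` and `s` and
#' always contains the `n` main-diagonal points.
#'
#' @param M an `srqa_matrix`.
#' @return a tibble with columns `t`, `s` (1-based), `symbol`, `pattern`.
#' @export
srp_points <- function(M) {
  m <- attr(M, "m")
  hit <- which(!is.na(M), arr.ind = TRUE)
  sym <- M[hit]
  tibble::tibble(
    t = as.integer(hit[, 1]),
    s = as.integer(hit[, 2]),
    symbol = as.integer(sym),
    pattern = vapply(as.integer(sym), symbol_label, character(1), m = m)
  )
}
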