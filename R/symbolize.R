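#' Ordinal-pattern symbolization of RR-interval histories
#'
#' An *m*-history is a vector of `m` consecutive time-series values
#' \eqn{(x_t, \ldots, x_{t+m-1})}. Its symbol is the unique permutation
#' \eqn{\pi = (i_1, \ldots, i_m)} of the offsets \eqn{\{0, \ldots, m-1\}}
#' such that \eqn{x_{t+i_1} \le x_{t+i_2} \le \cdots \le x_{t+i_m}}, with
#' ties resolved by ascending offset (so equal values keep their temporal
#' order). The symbol is therefore invariant under any strictly increasing
#' transform of the values.
#'
#' @param values numeric vector of length `m >= 2`; one m-history.
#' @return integer vector of 0-based offsets: the ordinal pattern of
#'   `values`. For example `c(6, 5, 10)` maps to `c(1, 0, 2)` (the middle
#'   value is smallest, the first is next, the last is largest).
#' @examples
#' symbolize_history(c(6, 5, 10))
#' symbolize_history(c(5, 5, 5)) # ties -> identity pattern
#' @seealso [symbolize_window()], [symbol_index()]
#' @export
symbolize_history <- function(values) {
  if (!is.numeric(values) || length(values) < 2) {
    stop("`values` must be a numeric vector of length >= 2", call. = FALSE)
  }
  if (anyNA(values)) stop("`values` must not contain missing values", call. = FALSE)
  # order() is stable: ties keep ascending offset, realizing the
  # uniqueness condition of the symbolization map exactly.
  as.integer(order(values) - 1L)
}

#' Lexicographic index of an ordinal pattern
#'
#' Patterns of length `m` are totally ordered lexicographically over their
#' offset tuples, so for `m = 3`: `(0,1,2) = 0`, `(0,2,1) = 1`,
#' `(1,0,2) = 2`, `(1,2,0) = 3`, `(2,0,1) = 4`, `(2,1,0) = 5`.
#'
#' @param perm integer vector: a permutation of `0:(m-1)`.
#' @return 0-based integer rank in `0:(factorial(m) - 1)`.
#' @examples
#' symbol_index(c(1, 0, 2)) # 2
#' @export
symbol_index <- function(perm) {
  m <- length(perm)
  if (m < 1 || !setequal(perm, 0:(m - 1))) {
    stop("`perm` must be a permutation of 0:(m-1)", call. = FALSE)
  }
  idx <- 0
  for (j in seq_len(m - 1)) {
    idx <- idx + sum(perm[(j + 1):m] < perm[j]) * factorial(m - j)
  }
  as.integer(idx)
}

#' Ordinal pattern for a lexicographic index
#'
#' Inverse of [symbol_index()].
#'
#' @param index 0-based integer rank in `0:(factorial(m) - 1)`.
#' @param m pattern length (embedding dimension).
#' @return integer vector: permutation of `0:(m-1)`.
#' @export
symbol_from_index <- function(index, m) {
  if (index < 0 || index >= factorial(m)) {
    stop("`index` must lie in 0:(factorial(m) - 1)", call. = FALSE)
  }
  pool <- 0:(m - 1)
  out <- integer(m)
  rest <- as.integer(index)
  for (j in seq_len(m)) {
    f <- factorial(m - j)
    take <- rest %/% f + 1L
    out[j] <- pool[take]
    pool <- pool[-take]
    rest <- rest %% f
  }
  out
}

#' Compact label for a symbol
#'
#' @param x either a permutation vector or a 0-based index (with `m` given).
#' @param m embedding dimension, needed when `x` is an index.
#' @return character such as `"102"` for the pattern `(1,0,2)`.
#' @export
symbol_label <- function(x, m = 3L) {
  if (length(x) == 1L) x <- symbol_from_index(x, m)
  paste(x, collapse = "")
}

#' Symbolize a window of RR intervals
#'
#' Slides an embedding window of dimension `m` (lag 1) over the `T` values
#' and maps each of the `n = T - m + 1` m-histories to its ordinal-pattern
#' symbol. The result is a `symbol_seq`: an integer vector of 0-based
#' lexicographic symbol indices with the embedding dimension attached.
#'
#' @param window numeric vector of length `T >= m`.
#' @param m embedding dimension (default 3, the value used throughout the
#'   AF pipeline; 3! = 6 symbols).
#' @return integer vector of class `symbol_seq` with length `T - m + 1`
#'   and attribute `m`.
#' @examples
#' symbolize_window(c(3, 9, 7, 6, 5, 10, 4), m = 3)
#' @export
symbolize_window <- function(window, m = 3L) {
  m <- as.integer(m)
  if (m < 2) stop("`m` must be at least 2", call. = FALSE)
  if (!is.numeric(window) || length(window) < m) {
    stop("`window` must be numeric with length >= m", call. = FALSE)
  }
  if (anyNA(window)) stop("`window` must not contain missing values", call. = FALSE)
  n <- length(window) - m + 1L
  E <- matrix(0, n, m)
  for (j in seq_len(m)) E[, j] <- window[j:(j + n - 1L)]
  # rank of each offset within its history, ties by ascending offset
  R <- matrix(0L, n, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (j == i) next
      if (j < i) R[, i] <- R[, i] + (E[, j] <= E[, i])
      else       R[, i] <- R[, i] + (E[, j] <  E[, i])
    }
  }
  # permutation: offset (i-1) occupies sorted position R[,i]
  P <- matrix(0L, n, m)
  for (i in seq_len(m)) P[cbind(seq_len(n), R[, i] + 1L)] <- i - 1L
  idx <- integer(n)
  for (j in seq_len(m - 1L)) {
    smaller_later <- integer(n)
    for (l in (j + 1L):m) smaller_later <- smaller_later + (P[, l] < P[, j])
    idx <- idx + smaller_later * as.integer(factorial(m - j))
  }
  new_symbol_seq(idx, m)
}

new_symbol_seq <- function(idx, m) {
  structure(as.integer(idx), m = as.integer(m), class = "symbol_seq")
}

#' @export
print.symbol_seq <- function(x, ...) {
  m <- attr(x, "m")
  cat("<symbol_seq> n =", length(x), " m =", m, "\n")
  labs <- vapply(unclass(x), symbol_label, character(1), m = m)
  cat(" ", paste0("(", labs, ")", collapse = " "), "\n")
  invisible(x)
}

#' @export
as.integer.symbol_seq <- function(x, ...) as.integer(unclass(x))

#' Tidy view of a symbol sequence
#'
#' @param x a `symbol_seq` from [symbolize_window()].
#' @param ... unused.
#' @return a tibble with columns `t` (1-based history start), `symbol`
#'   (0-based lexicographic index) and `pattern` (label such as `"102"`).
#' @export
tidy.symbol_seq <- function(x, ...) {
  m <- attr(x, "m")
  tibble::tibble(
    t = seq_along(x),
    symbol = as.integer(unclass(x)),
    pattern = vapply(unclass(x), symbol_label, character(1), m = m)
  )
}

#' Largest admissible embedding dimension for a window size
#'
#' Symbols must remain statistically distinguishable: under independence
#' each of the `m!` ordinal patterns should have expected frequency at
#' least 5 in a window of `w` histories, i.e. `5 * factorial(m) <= w`.
#' A window of 30 beats therefore admits at most `m = 3`.
#'
#' @param w window length in beats (`w >= 2`).
#' @return the largest `m` with `5 * factorial(m) <= w`; `1` when even
#'   `m = 2` is inadmissible (`w < 10`), meaning no valid embedding exists.
#' @examples
#' max_embedding_dimension(30)  # 3
#' max_embedding_dimension(120) # 4
#' @export
max_embedding_dimension <- function(w) {
  if (!is.numeric(w) || length(w) != 1 || w < 2) {
    stop("`w` must be a single number >= 2", call. = FALSE)
  }
  m <- 1L
  while (5 * factorial(m + 1L) <= w) m <- m + 1L
  m
}
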