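# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: symbols by exhaustive search over permutations, line
# structures by cell-by-cell matrix scans.

all_perms <- function(m) {
  if (m == 1L) return(list(0L))
  out <- list()
  for (p in all_perms(m - 1L)) {
    for (pos in 0:(m - 1L)) {
      out[[length(out) + 1L]] <- append(p, m - 1L, after = pos)
    }
  }
  out
}

# the unique permutation satisfying the ordering condition with ties
# broken by ascending offset, found by trying every candidate
oracle_symbolize <- function(values) {
  m <- length(values)
  for (p in all_perms(m)) {
    v <- values[p + 1L]
    if (any(diff(v) < 0)) next
    ok <- TRUE
    for (i in seq_len(m - 1L)) {
      if (v[i] == v[i + 1L] && p[i] > p[i + 1L]) { ok <- FALSE; break }
    }
    if (ok) return(as.integer(p))
  }
  stop("no admissible permutation found")
}

# scan every off-main diagonal cell by cell, both triangles
oracle_diag_lines <- function(M, min_len = 2L) {
  n <- nrow(M)
  lens <- integer()
  for (k in setdiff(-(n - 1):(n - 1), 0L)) {
    run <- 0L
    for (t in seq_len(n)) {
      s <- t + k
      rec <- s >= 1 && s <= n && !is.na(M[t, s])
      if (rec) run <- run + 1L
      if ((!rec || t == n) && run >= min_len) lens <- c(lens, run)
      if (!rec) run <- 0L
    }
  }
  sort(lens)
}

# scan every column cell by cell for runs of cells equal to `idx`
oracle_vert_lines <- function(M, idx, min_len = 2L) {
  n <- nrow(M)
  lens <- integer()
  for (s in seq_len(n)) {
    run <- 0L
    for (t in seq_len(n)) {
      rec <- !is.na(M[t, s]) && M[t, s] == idx
      if (rec) run <- run + 1L
      if ((!rec || t == n) && run >= min_len) lens <- c(lens, run)
      if (!rec) run <- 0L
    }
  }
  sort(lens)
}

dist_to_lengths <- function(dist) {
  sort(rep(dist$length, dist$count))
}

oracle_confusion <- function(probs, labels, tau) {
  y <- labels == "AF"
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(probs)) {
    pred <- probs[i] > tau
    if (pred && y[i]) tp <- tp + 1L
    if (pred && !y[i]) fp <- fp + 1L
    if (!pred && y[i]) fn <- fn + 1L
    if (!pred && !y[i]) tn <- tn + 1L
  }
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

# the printed seven-value series used in the worked examples
example_series <- c(3, 9, 7, 6, 5, 10, 4)
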