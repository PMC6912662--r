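#' Construct a beat-annotated RR record
#'
#' The pipeline's raw input: a sequence of inter-beat (RR) intervals in
#' milliseconds, each carrying the rhythm in force at that beat. `AF`
#' marks atrial fibrillation; `N` normal sinus rhythm; `OTHER` any other
#' annotated rhythm (atrial flutter, AV junctional, ...). For window
#' labelling both `N` and `OTHER` count as non-AF.
#'
#' @param rr_ms numeric vector of positive RR intervals (milliseconds).
#' @param rhythm character vector of per-beat labels in
#'   `c("AF", "N", "OTHER")`, recycled if length 1.
#' @param record_id identifier carried into feature provenance.
#' @return a tibble of class `rr_record` with columns `beat` (1-based),
#'   `rr_ms`, `rhythm`, and attribute `record_id`.
#' @export
rr_record <- function(rr_ms, rhythm = "N", record_id = "record") {
  if (!is.numeric(rr_ms) || length(rr_ms) < 1) {
    stop("`rr_ms` must be a non-empty numeric vector", call. = FALSE)
  }
  if (anyNA(rr_ms) || any(rr_ms <= 0)) {
    stop("all RR intervals must be positive and non-missing", call. = FALSE)
  }
  if (length(rhythm) == 1L) rhythm <- rep(rhythm, length(rr_ms))
  if (length(rhythm) != length(rr_ms)) {
    stop("`rhythm` must have length 1 or length(rr_ms)", call. = FALSE)
  }
  bad <- !rhythm %in% c("AF", "N", "OTHER")
  if (any(bad)) {
    stop("unknown rhythm label(s): ", paste(unique(rhythm[bad]), collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(
    beat = seq_along(rr_ms),
    rr_ms = as.numeric(rr_ms),
    rhythm = as.character(rhythm)
  )
  structure(out, record_id = as.character(record_id),
            class = c("rr_record", class(out)))
}

record_id_of <- function(record) attr(record, "record_id") %||% "record"

#' Cut an RR record into labelled beat windows
#'
#' Splits the record into consecutive, non-overlapping windows of exactly
#' `w` beats (trailing remainder dropped). A window is labelled `AF` when
#' strictly more than half of its beats are annotated AF, and `nonAF`
#' otherwise — so a 30-beat window needs at least 16 AF beats, and
#' `OTHER` rhythms count toward `nonAF`.
#'
#' @param record an [rr_record()] (or data frame with `rr_ms`, `rhythm`).
#' @param w beats per window; the study sizes are 30, 60, 120 and 200.
#' @return a tibble with one row per window: `record_id`, `window_idx`,
#'   `n_af` (AF beats in the window), `label` (`"AF"`/`"nonAF"`) and
#'   `rr` (list-column of the window's RR intervals). Zero rows, with a
#'   warning, when the record is shorter than `w`.
#' @export
make_windows <- function(record, w) {
  w <- as.integer(w)
  if (w < 2) stop("`w` must be at least 2", call. = FALSE)
  n <- nrow(record)
  k <- n %/% w
  if (k == 0L) {
    warning("record '", record_id_of(record), "' has ", n,
            " beats, shorter than one window of ", w, "; no windows produced")
    return(tibble::tibble(record_id = character(), window_idx = integer(),
                          n_af = integer(), label = character(), rr = list()))
  }
  idx <- rep(seq_len(k), each = w)
  used <- seq_len(k * w)
  rr_split <- split(record$rr_ms[used], idx)
  n_af <- vapply(split(record$rhythm[used] == "AF", idx), sum, integer(1))
  tibble::tibble(
    record_id = record_id_of(record),
    window_idx = seq_len(k),
    n_af = as.integer(n_af),
    label = ifelse(n_af / w > 0.5, "AF", "nonAF"),
    rr = unname(rr_split)
  )
}

#' Central-tendency and dispersion statistics of an RR window
#'
#' Besides the mean and median (milliseconds), two dimensionless
#' homogeneity measures: the Pearson coefficient of variation
#' `cv = sd(rr) / mean(rr)` (sample standard deviation, n-1 denominator)
#' and the coefficient of variation of the median
#' \eqn{VMe = \sum_i |RR_i - Me(RR)| / \sum_i RR_i}.
#' Both are invariant under rescaling of the intervals.
#'
#' @param rr numeric vector of at least 2 positive RR intervals.
#' @return a one-row tibble: `rr_mean`, `rr_median`, `cv`, `vme`.
#' @examples
#' rr_statistics(c(600, 800, 1000)) # vme = 1/6
#' @export
rr_statistics <- function(rr) {
  if (!is.numeric(rr) || length(rr) < 2) {
    stop("`rr` must be numeric with length >= 2", call. = FALSE)
  }
  if (anyNA(rr) || any(rr <= 0)) {
    stop("all RR intervals must be positive and non-missing", call. = FALSE)
  }
  med <- stats::median(rr)
  tibble::tibble(
    rr_mean = mean(rr),
    rr_median = med,
    cv = stats::sd(rr) / mean(rr),
    vme = sum(abs(rr - med)) / sum(rr)
  )
}

#' Canonical covariate names of the AF feature vector
#'
#' The 18 per-window covariates fed to the logistic model (for the
#' default `m = 3`), in canonical column order: the `factorial(m)`
#' per-symbol recurrence rates, determinism and diagonal entropy, the
#' vertical-line measures for the increasing and decreasing patterns,
#' and the four RR distribution statistics.
#'
#' @param m embedding dimension (default 3).
#' @return character vector of column names.
#' @export
af_covariates <- function(m = 3L) {
  patterns <- vapply(0:(factorial(m) - 1L), symbol_label, character(1), m = m)
  c(paste0("srr_", patterns),
    "det_d", "ent_d",
    "rline_v_inc", "rline_v_dec", "ent_v_inc", "ent_v_dec",
    "vbar_inc", "vbar_dec",
    "rr_mean", "rr_median", "cv", "vme")
}

#' Extract the covariate vector of one RR window
#'
#' Composes [symbolize_window()], [srqa_measures()] and
#' [rr_statistics()]. Degenerate recurrence structures (no lines) yield
#' zeros, never missing values, so every window produces a complete row.
#'
#' @param rr numeric vector of RR intervals, length at least `m + 1`.
#' @param m embedding dimension (default 3).
#' @return a one-row tibble with the [af_covariates()] columns.
#' @export
extract_features <- function(rr, m = 3L) {
  if (length(rr) < m + 1) {
    stop("window must contain at least m + 1 beats", call. = FALSE)
  }
  meas <- srqa_measures(symbolize_window(rr, m))
  dplyr::bind_cols(meas, rr_statistics(rr))[, af_covariates(m)]
}

#' Build the per-window feature table for a set of records
#'
#' Windows every record with [make_windows()], extracts the covariates of
#' each window, and stacks them in stable order (records in input order,
#' then window index). This is the samples-by-variables table consumed by
#' [fit_af_model()] and [kfold_cv()].
#'
#' @param records an [rr_record()] or a list of them.
#' @param w beats per window.
#' @param m embedding dimension (default 3).
#' @param allow_inadmissible_m keep going when `w < 5 * factorial(m)`,
#'   i.e. when `w` cannot support statistically distinguishable symbol
#'   frequencies for this `m`. Default `FALSE` (error).
#' @return a tibble with the [af_covariates()] columns plus `label`,
#'   `record_id`, `window_idx`.
#' @export
build_dataset <- function(records, w, m = 3L, allow_inadmissible_m = FALSE) {
  if (inherits(records, "rr_record") || is.data.frame(records)) {
    records <- list(records)
  }
  if (!length(records)) stop("`records` must contain at least one record", call. = FALSE)
  if (w < 5 * factorial(m) && !allow_inadmissible_m) {
    stop("window size ", w, " cannot support embedding dimension ", m,
         ": symbol frequencies are statistically distinguishable only when ",
         "5 * factorial(m) <= w (here 5 * ", factorial(m), " = ",
         5 * factorial(m), " > ", w, "). Use `allow_inadmissible_m = TRUE` ",
         "to override.", call. = FALSE)
  }
  windows <- purrr::map(records, make_windows, w = w) |> purrr::list_rbind()
  if (nrow(windows) == 0L) {
    stop("no windows could be produced from the given records", call. = FALSE)
  }
  feats <- purrr::map(windows$rr, extract_features, m = m) |> purrr::list_rbind()
  dplyr::bind_cols(
    feats,
    windows[, c("label", "record_id", "window_idx")]
  )
}
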