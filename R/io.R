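#' Read an RR record file
#'
#' The canonical on-disk form of an [rr_record()]: tab-separated text,
#' one row per beat with columns `beat_index` (1-based, consecutive),
#' `rr_ms` (positive, milliseconds) and `rhythm` (`AF`, `N` or `OTHER`).
#' A header line is required; lines starting with `#` are comments; LF
#' and CRLF endings are both accepted. Malformed content is reported with
#' its line number.
#'
#' @param path file to read.
#' @param record_id identifier attached to the record; defaults to the
#'   file name without extension.
#' @return an [rr_record()].
#' @export
read_rr_record <- function(path, record_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- sub("\r$", "", readLines(path, warn = FALSE))
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lineno <- which(keep)
  rows <- raw[keep]
  if (!length(rows)) stop("file ", path, " has no header line", call. = FALSE)
  fields <- strsplit(rows, "[\t ]+")
  header <- fields[[1]]
  if (!identical(header, c("beat_index", "rr_ms", "rhythm"))) {
    stop("line ", lineno[1], ": expected header 'beat_index\trr_ms\trhythm'",
         call. = FALSE)
  }
  fields <- fields[-1]
  lineno <- lineno[-1]
  if (!length(fields)) stop("file ", path, " contains no beats", call. = FALSE)
  bad_n <- which(lengths(fields) != 3L)
  if (length(bad_n)) {
    stop("line ", lineno[bad_n[1]], ": expected 3 fields, found ",
         lengths(fields)[bad_n[1]], call. = FALSE)
  }
  tab <- do.call(rbind, fields)
  idx <- suppressWarnings(as.integer(tab[, 1]))
  rr <- suppressWarnings(as.numeric(tab[, 2]))
  rhythm <- tab[, 3]
  if (anyNA(idx) || any(idx != seq_along(idx))) {
    bad <- which(is.na(idx) | idx != seq_along(idx))[1]
    stop("line ", lineno[bad], ": beat_index must increase consecutively from 1",
         call. = FALSE)
  }
  if (anyNA(rr) || any(rr <= 0)) {
    bad <- which(is.na(rr) | rr <= 0)[1]
    stop("line ", lineno[bad], ": rr_ms must be a positive number", call. = FALSE)
  }
  bad <- which(!rhythm %in% c("AF", "N", "OTHER"))
  if (length(bad)) {
    stop("line ", lineno[bad[1]], ": rhythm must be AF, N or OTHER (found '",
         rhythm[bad[1]], "')", call. = FALSE)
  }
  if (is.null(record_id)) record_id <- sub("\\.[^.]*$", "", basename(path))
  rr_record(rr, rhythm, record_id)
}

#' Write an RR record file
#'
#' Counterpart of [read_rr_record()]; values are printed with enough
#' digits that a read-back round-trips bit-identically.
#'
#' @param record an [rr_record()].
#' @param path output file.
#' @export
write_rr_record <- function(record, path) {
  lines <- c(
    paste0("# RR record '", record_id_of(record), "' (", nrow(record), " beats)"),
    "beat_index\trr_ms\trhythm",
    sprintf("%d\t%.17g\t%s", record$beat, record$rr_ms, record$rhythm)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a feature table to CSV
#'
#' One row per window, header with the canonical covariate names (see
#' [af_covariates()]) followed by `label`, `record_id`, `window_idx`;
#' UTF-8, `.` decimal separator. Doubles are printed with round-trip
#' precision so [read_features()] restores them bit-identically.
#'
#' @param features a feature table from [build_dataset()].
#' @param path output file.
#' @export
write_features <- function(features, path) {
  fmt <- function(x) {
    # 17 significant digits round-trip any IEEE double exactly; keep a
    # decimal point on whole numbers so readers restore a double column
    s <- sprintf("%.17g", x)
    whole <- !grepl("[.eE]", s)
    s[whole] <- paste0(s[whole], ".0")
    s
  }
  out <- dplyr::mutate(features, dplyr::across(dplyr::where(is.double), fmt))
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a feature table written by [write_features()]
#'
#' @param path CSV file.
#' @return a tibble.
#' @export
read_features <- function(path) {
  # base read.csv parses doubles with correctly-rounded strtod, so the
  # %.17g representation written by write_features() restores exactly
  out <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  if ("window_idx" %in% names(out)) {
    out$window_idx <- as.integer(out$window_idx)
  }
  out
}

#' Import a PhysioNet-style annotated record as an RR record
#'
#' Adapter for beat + rhythm annotations of long-term ECG records such as
#' the MIT-BIH Atrial Fibrillation Database. It consumes the plain-text
#' export of PhysioNet's `rdann` (whitespace-separated columns: elapsed
#' time, sample number, annotation type, sub, chan, num and optionally an
#' aux string), which carries both the QRS annotations and the `+`
#' rhythm-change annotations with aux strings like `(AFIB` or `(N`.
#'
#' RR intervals are successive differences of beat annotation samples
#' converted to milliseconds with the record's sampling frequency. Each
#' RR interval (attributed to its terminating beat) is labelled with the
#' rhythm regime in force at that beat: aux `(AFIB` maps to `AF`, `(N`
#' to `N`, anything else to `OTHER`; beats preceding the first rhythm
#' annotation are `OTHER` (conservatively non-AF).
#'
#' The download itself is external and optional: the rest of the package
#' never requires PhysioNet data.
#'
#' @param path `rdann`-style text annotation file.
#' @param fs sampling frequency in Hz (250 for the MIT-BIH AF database).
#' @param record_id identifier; defaults to the file name.
#' @return an [rr_record()].
#' @export
import_physionet_afdb <- function(path, fs = 250, record_id = NULL) {
  if (!file.exists(path)) {
    stop("no such annotation file: ", path,
         "\nPhysioNet input is optional and external; export annotations as ",
         "text with e.g. `rdann -r <record> -a atr -v` and pass that file.",
         call. = FALSE)
  }
  raw <- sub("\r$", "", readLines(path, warn = FALSE))
  raw <- raw[nzchar(trimws(raw)) & !grepl("^\\s*#", raw)]
  # drop a header line if present (rdann -v prints column names)
  if (length(raw) && grepl("Sample|Time", raw[1], ignore.case = TRUE)) raw <- raw[-1]
  if (!length(raw)) stop("annotation file ", path, " is empty", call. = FALSE)
  fields <- strsplit(trimws(raw), "\\s+")
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop("annotation line ", short[1], ": expected at least 3 columns",
         call. = FALSE)
  }
  sample <- vapply(fields, function(f) suppressWarnings(as.numeric(f[2])), numeric(1))
  type <- vapply(fields, function(f) f[3], character(1))
  aux <- vapply(fields, function(f) if (length(f) >= 7) f[7] else NA_character_,
                character(1))
  if (anyNA(sample)) {
    stop("annotation line ", which(is.na(sample))[1],
         ": sample column is not numeric", call. = FALSE)
  }
  is_rhythm <- type == "+"
  beats <- sample[!is_rhythm]
  if (length(beats) < 2) stop("need at least 2 beat annotations", call. = FALSE)
  rhythm_at <- sample[is_rhythm]
  rhythm_lab <- dplyr::case_when(
    aux[is_rhythm] == "(AFIB" ~ "AF",
    aux[is_rhythm] == "(N" ~ "N",
    TRUE ~ "OTHER"
  )
  rr <- diff(beats) / fs * 1000
  end_beat <- beats[-1]
  regime <- findInterval(end_beat, rhythm_at)
  labels <- ifelse(regime == 0, "OTHER", rhythm_lab[pmax(regime, 1)])
  if (is.null(record_id)) record_id <- sub("\\.[^.]*$", "", basename(path))
  rr_record(rr, labels, record_id)
}
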