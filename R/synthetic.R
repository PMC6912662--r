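#' Configuration of the synthetic RR generator
#'
#' Defines the two rhythm surrogates the test surface is built on.
#' Sinus-like (NS) records are a slow quasi-periodic modulation around a
#' resting mean with small beat-to-beat noise: the 4-beat sinusoid
#' coarsely mimics respiratory sinus arrhythmia and guarantees that
#' non-monotone ordinal patterns occur, so every per-symbol covariate is
#' exercised. AF-like records are near-random high-variability intervals:
#' i.i.d. uniform draws by default, optionally with mild first-order
#' serial correlation through a Gaussian copula (the uniform marginal is
#' preserved).
#'
#' @param ns_mean_ms sinus mean RR (default 800 ms, i.e. 75 bpm).
#' @param ns_mod_amp_ms amplitude of the sinus modulation (default 40 ms).
#' @param ns_mod_period_beats modulation period in beats (default 4).
#' @param ns_noise_sd_ms sd of additive Gaussian beat noise (default 10 ms).
#' @param af_min_ms,af_max_ms range of the AF uniform draw (defaults
#'   400 and 1100 ms).
#' @param af_corr first-order serial correlation of the AF surrogate in
#'   `[0, 0.3]` (default 0 = i.i.d.).
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(ns_mean_ms = 800, ns_mod_amp_ms = 40,
                             ns_mod_period_beats = 4, ns_noise_sd_ms = 10,
                             af_min_ms = 400, af_max_ms = 1100,
                             af_corr = 0) {
  cfg <- list(ns_mean_ms = ns_mean_ms, ns_mod_amp_ms = ns_mod_amp_ms,
              ns_mod_period_beats = ns_mod_period_beats,
              ns_noise_sd_ms = ns_noise_sd_ms,
              af_min_ms = af_min_ms, af_max_ms = af_max_ms,
              af_corr = af_corr)
  ms <- c("ns_mean_ms", "ns_mod_amp_ms", "ns_mod_period_beats",
          "af_min_ms", "af_max_ms")
  if (any(vapply(cfg[ms], function(x) !is.numeric(x) || x <= 0, logical(1)))) {
    stop("all millisecond/period parameters must be positive", call. = FALSE)
  }
  if (ns_noise_sd_ms < 0) stop("`ns_noise_sd_ms` must be >= 0", call. = FALSE)
  if (af_min_ms >= af_max_ms) stop("`af_min_ms` must be below `af_max_ms`", call. = FALSE)
  if (af_corr < 0 || af_corr > 0.3) {
    stop("`af_corr` must lie in [0, 0.3]", call. = FALSE)
  }
  structure(cfg, class = "generator_config")
}

#' Generate a sinus-like RR record
#'
#' `RR_t = ns_mean + ns_mod_amp * sin(2 pi t / ns_mod_period) +
#' N(0, ns_noise_sd)`, every beat labelled `N`. Reproducible under
#' `seed`; the caller's RNG state is left untouched.
#'
#' @param n_beats number of beats.
#' @param seed integer seed (optional).
#' @param config a [generator_config()].
#' @param record_id identifier (default `"ns"`).
#' @return an [rr_record()].
#' @export
gen_ns_record <- function(n_beats, seed = NULL, config = generator_config(),
                          record_id = "ns") {
  stopifnot(inherits(config, "generator_config"), n_beats >= 1)
  t <- seq_len(n_beats)
  rr <- with_preserved_seed(seed, {
    config$ns_mean_ms +
      config$ns_mod_amp_ms * sin(2 * pi * t / config$ns_mod_period_beats) +
      stats::rnorm(n_beats, 0, config$ns_noise_sd_ms)
  })
  rr_record(rr, "N", record_id)
}

#' Generate an AF-like RR record
#'
#' Intervals are uniform on `[af_min_ms, af_max_ms]`, i.i.d. when
#' `af_corr = 0` or serially correlated through a latent Gaussian AR(1)
#' mapped back to the uniform marginal (Gaussian copula) otherwise.
#' Every beat is labelled `AF`.
#'
#' @inheritParams gen_ns_record
#' @param record_id identifier (default `"af"`).
#' @return an [rr_record()].
#' @export
gen_af_record <- function(n_beats, seed = NULL, config = generator_config(),
                          record_id = "af") {
  stopifnot(inherits(config, "generator_config"), n_beats >= 1)
  rr <- with_preserved_seed(seed, {
    if (config$af_corr == 0) {
      stats::runif(n_beats, config$af_min_ms, config$af_max_ms)
    } else {
      rho <- config$af_corr
      z <- stats::rnorm(n_beats)
      for (i in seq_len(n_beats)[-1]) {
        z[i] <- rho * z[i - 1] + sqrt(1 - rho^2) * z[i]
      }
      config$af_min_ms +
        (config$af_max_ms - config$af_min_ms) * stats::pnorm(z)
    }
  })
  rr_record(rr, "AF", record_id)
}

#' Generate a mixed-rhythm (paroxysmal) RR record
#'
#' Concatenates per-segment generators with per-beat labels, emulating
#' intermittent AF episodes inside sinus rhythm; useful for exercising
#' the beat-majority window labelling rule across rhythm transitions.
#'
#' @param segments a data frame (or list of pairs) with columns `rhythm`
#'   (`"N"` or `"AF"`) and `n_beats`.
#' @param seed integer seed (optional).
#' @param config a [generator_config()].
#' @param record_id identifier (default `"mixed"`).
#' @return an [rr_record()] of length `sum(n_beats)`.
#' @export
gen_mixed_record <- function(segments, seed = NULL, config = generator_config(),
                             record_id = "mixed") {
  if (!is.data.frame(segments)) {
    segments <- purrr::map(segments, \(s) tibble::tibble(rhythm = s[[1]],
                                                         n_beats = as.integer(s[[2]]))) |>
      purrr::list_rbind()
  }
  stopifnot(nrow(segments) >= 1,
            all(segments$rhythm %in% c("N", "AF")),
            all(segments$n_beats >= 1))
  parts <- with_preserved_seed(seed, {
    purrr::pmap(segments, function(rhythm, n_beats) {
      if (rhythm == "AF") gen_af_record(n_beats, seed = NULL, config = config)
      else gen_ns_record(n_beats, seed = NULL, config = config)
    })
  })
  rr <- unlist(purrr::map(parts, "rr_ms"))
  rhythm <- unlist(purrr::map(parts, "rhythm"))
  rr_record(rr, rhythm, record_id)
}

#' Simulate a balanced set of labelled RR records
#'
#' Convenience wrapper producing `n_records` records of `n_beats` beats,
#' alternating sinus-like and AF-like, with per-record derived seeds.
#'
#' @param n_records number of records (half NS, half AF).
#' @param n_beats beats per record.
#' @param seed integer seed.
#' @param config a [generator_config()].
#' @return a list of [rr_record()]s.
#' @export
simulate_records <- function(n_records, n_beats, seed = 1L,
                             config = generator_config()) {
  stopifnot(n_records >= 1)
  purrr::map(seq_len(n_records), function(i) {
    s <- (as.integer(seed) * 1009L + i) %% .Machine$integer.max
    if (i %% 2L == 1L) {
      gen_ns_record(n_beats, seed = s, config = config,
                    record_id = sprintf("ns_%02d", i))
    } else {
      gen_af_record(n_beats, seed = s, config = config,
                    record_id = sprintf("af_%02d", i))
    }
  })
}
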