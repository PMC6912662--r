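#' Fit the logistic AF classifier
#'
#' Maximum-likelihood logistic regression of the window label (AF vs
#' non-AF) on the SRQA and RR-distribution covariates, fitted by
#' iteratively reweighted least squares (Fisher scoring) with convergence
#' tolerance `1e-8` and at most 100 iterations; Wald standard errors and
#' p-values come from the information matrix at the optimum. Covariates
#' with zero variance in the supplied data are dropped with a warning.
#' Perfectly separated data are flagged (`separation = TRUE`, model
#' marked non-converged) and the coefficients of the last iterate are
#' kept: predictions remain usable, the Wald inference does not.
#'
#' @param features a feature table from [build_dataset()]: the
#'   [af_covariates()] columns plus a `label` column in
#'   `c("AF", "nonAF")`.
#' @param covariates covariate columns to use (default all 18).
#' @return an object of class `af_model` wrapping the `glm` fit, with
#'   elements `fit`, `covariates`, `dropped`, `converged`, `separation`,
#'   `n_obs`.
#' @seealso [predict_af()], [roc_threshold()], [kfold_cv()]
#' @export
fit_af_model <- function(features, covariates = af_covariates()) {
  stopifnot(is.data.frame(features), "label" %in% names(features))
  missing_cols <- setdiff(covariates, names(features))
  if (length(missing_cols)) {
    stop("feature table lacks covariate(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  y <- features$label == "AF"
  if (length(unique(y)) < 2) {
    stop("both classes (AF and nonAF) must be present to fit the model",
         call. = FALSE)
  }
  if (sum(y) < 2 || sum(!y) < 2) {
    stop("need at least 2 windows per class", call. = FALSE)
  }
  keep <- covariates[vapply(features[covariates],
                            function(x) stats::var(x) > 0, logical(1))]
  dropped <- setdiff(covariates, keep)
  if (length(dropped)) {
    warning("dropping zero-variance covariate(s): ",
            paste(dropped, collapse = ", "))
  }
  dat <- features[, keep, drop = FALSE]
  dat$.af <- y
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.af ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (separation) {
    warning("(quasi-)separated data: coefficients taken at the last IRLS ",
            "iterate; Wald inference is unreliable")
  }
  structure(
    list(fit = fit, covariates = keep, dropped = dropped,
         converged = fit$converged && !separation,
         separation = separation, n_obs = length(y)),
    class = "af_model"
  )
}

#' @export
print.af_model <- function(x, ...) {
  cat("<af_model> logistic AF classifier\n")
  cat("  n =", x$n_obs, " covariates =", length(x$covariates),
      if (length(x$dropped)) paste0(" (dropped: ", paste(x$dropped, collapse = ", "), ")"),
      "\n")
  cat("  converged:", x$converged,
      if (x$separation) " [separation detected]", "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Coefficient table of a fitted AF model
#'
#' @param x an `af_model`.
#' @param ... unused.
#' @return a tibble with `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value` and `signif` (`"**"` below 1%, `"*"` below 5%, `""`
#'   otherwise).
#' @export
tidy.af_model <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(co),
    estimate = co[, 1],
    std_error = co[, 2],
    statistic = co[, 3],
    p_value = co[, 4],
    signif = dplyr::case_when(co[, 4] < 0.01 ~ "**",
                              co[, 4] < 0.05 ~ "*",
                              TRUE ~ "")
  )
}

#' One-row model summary
#'
#' @param x an `af_model`.
#' @param ... unused.
#' @return a tibble with `n_obs`, `n_covariates`, `converged`,
#'   `separation`, `null_deviance`, `deviance`, `aic`.
#' @export
glance.af_model <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs,
    n_covariates = length(x$covariates),
    converged = x$converged,
    separation = x$separation,
    null_deviance = x$fit$null.deviance,
    deviance = x$fit$deviance,
    aic = x$fit$aic
  )
}

#' Predicted AF probabilities
#'
#' \eqn{p = 1 / (1 + e^{-(\beta_0 + \sum_i \beta_i x_i)})}. A window is
#' classified AF when its probability strictly exceeds the chosen
#' threshold.
#'
#' @param model an `af_model`.
#' @param features a data frame containing the model's covariate columns.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict_af <- function(model, features) {
  missing_cols <- setdiff(model$covariates, names(features))
  if (length(missing_cols)) {
    stop("feature table lacks covariate(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  as.numeric(stats::predict(model$fit,
                            newdata = features[, model$covariates, drop = FALSE],
                            type = "response"))
}

as_af_logical <- function(labels) {
  if (is.logical(labels)) return(labels)
  labels == "AF"
}

#' ROC-based classification threshold
#'
#' Sweeps the threshold over the fixed grid 0, 0.001, ..., 1.000,
#' computing the false positive rate and sensitivity of the rule
#' "AF when p > tau" at each point, and picks the threshold closest to
#' the ideal corner (FPR, Se) = (0, 1):
#' \eqn{\tau = \arg\min_\tau \{FPR_\tau^2 + (1 - Se_\tau)^2\}},
#' taking the smallest grid value on ties.
#'
#' @param probs predicted AF probabilities.
#' @param labels window labels (`"AF"`/`"nonAF"` or logical AF flags).
#' @return an object of class `af_roc`: list with `grid` (tibble `tau`,
#'   `fpr`, `se`), `tau` (chosen threshold) and `distance` (corner
#'   distance attained, squared-root scale).
#' @export
roc_threshold <- function(probs, labels) {
  y <- as_af_logical(labels)
  stopifnot(length(probs) == length(y))
  if (!any(y) || all(y)) {
    stop("both classes must be present to build a ROC curve", call. = FALSE)
  }
  taus <- (0:1000) / 1000
  pos <- sort(probs[y])
  neg <- sort(probs[!y])
  # count of values strictly above tau via a single pass over sorted probs
  se <- (length(pos) - findInterval(taus, pos)) / length(pos)
  fpr <- (length(neg) - findInterval(taus, neg)) / length(neg)
  d2 <- fpr^2 + (1 - se)^2
  i <- which.min(d2) # first index: smallest tau on ties
  structure(
    list(grid = tibble::tibble(tau = taus, fpr = fpr, se = se),
         tau = taus[i], distance = sqrt(d2[i])),
    class = "af_roc"
  )
}

#' @export
print.af_roc <- function(x, ...) {
  at <- x$grid[x$grid$tau == x$tau, ]
  cat("<af_roc> 1001-point threshold grid\n")
  cat(sprintf("  chosen tau = %.3f (Se = %.3f, FPR = %.3f, corner distance = %.4f)\n",
              x$tau, at$se, at$fpr, x$distance))
  invisible(x)
}

#' Confusion-matrix evaluation at a threshold
#'
#' Applies the rule "AF when p > tau" and reports the confusion counts
#' with sensitivity `Se = TP / (TP + FN)`, specificity
#' `Sp = 1 - FP / (TN + FP)` and accuracy
#' `ACC = (TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param probs predicted AF probabilities.
#' @param labels window labels (`"AF"`/`"nonAF"` or logical AF flags).
#' @param tau classification threshold.
#' @return a one-row tibble: `tau`, `tp`, `tn`, `fp`, `fn`, `se`, `sp`,
#'   `acc`.
#' @export
evaluate_threshold <- function(probs, labels, tau) {
  y <- as_af_logical(labels)
  stopifnot(length(probs) == length(y), length(tau) == 1)
  pred <- probs > tau
  tp <- sum(pred & y); fn <- sum(!pred & y)
  fp <- sum(pred & !y); tn <- sum(!pred & !y)
  tibble::tibble(
    tau = tau, tp = tp, tn = tn, fp = fp, fn = fn,
    se = tp / (tp + fn),
    sp = 1 - fp / (tn + fp),
    acc = (tp + tn) / length(y)
  )
}

#' Stratified K-fold cross-validation of the AF pipeline
#'
#' Randomly partitions the windows into `k` folds, stratified by label so
#' every fold keeps the overall class balance (or grouped by record when
#' `by_record = TRUE`, so no record contributes to both sides). For each
#' fold the model is fitted on the remaining folds, the threshold is
#' selected on the *training* folds' ROC (selecting on the test fold
#' would leak), and the held-out fold is scored.
#'
#' @param features a feature table from [build_dataset()].
#' @param k number of folds (default 10).
#' @param seed integer seed making the partition reproducible.
#' @param covariates covariate columns (default all 18).
#' @param by_record assign whole records to folds instead of stratifying
#'   by label (default `FALSE`).
#' @return an object of class `af_cv`: list with `k`, `per_fold` (one
#'   [evaluate_threshold()] row per fold plus `fold`) and `summary`
#'   (25th/50th/75th percentiles of `tau`, `se`, `sp`, `acc`; linear
#'   interpolation between order statistics).
#' @export
kfold_cv <- function(features, k = 10L, seed = NULL,
                     covariates = af_covariates(), by_record = FALSE) {
  k <- as.integer(k)
  stopifnot(is.data.frame(features), "label" %in% names(features), k >= 2)
  y <- features$label == "AF"
  if (min(sum(y), sum(!y)) < k) {
    stop("each class needs at least k = ", k, " windows for ", k,
         "-fold cross-validation", call. = FALSE)
  }
  fold <- integer(nrow(features))
  with_preserved_seed(seed, {
    if (by_record) {
      ids <- unique(features$record_id)
      if (length(ids) < k) stop("fewer records than folds", call. = FALSE)
      fmap <- stats::setNames(sample(rep_len(seq_len(k), length(ids))), ids)
      fold <- unname(fmap[features$record_id])
    } else {
      for (cls in c(TRUE, FALSE)) {
        rows <- which(y == cls)
        fold[rows] <- sample(rep_len(seq_len(k), length(rows)))
      }
    }
  })
  per_fold <- purrr::map(seq_len(k), function(f) {
    train <- features[fold != f, , drop = FALSE]
    test <- features[fold == f, , drop = FALSE]
    model <- suppressWarnings(fit_af_model(train, covariates))
    roc <- roc_threshold(predict_af(model, train), train$label)
    dplyr::bind_cols(
      tibble::tibble(fold = f),
      evaluate_threshold(predict_af(model, test), test$label, roc$tau)
    )
  }) |> purrr::list_rbind()
  qs <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  summary <- purrr::map(c("tau", "se", "sp", "acc"), function(metric) {
    q <- qs(per_fold[[metric]])
    tibble::tibble(metric = metric, p25 = q[1], median = q[2], p75 = q[3])
  }) |> purrr::list_rbind()
  structure(list(k = k, per_fold = per_fold, summary = summary),
            class = "af_cv")
}

#' @export
print.af_cv <- function(x, ...) {
  cat("<af_cv>", x$k, "fold cross-validation\n")
  print(x$summary)
  invisible(x)
}

#' Per-fold cross-validation results
#'
#' @param x an `af_cv`.
#' @param ... unused.
#' @return the per-fold tibble (one row per held-out fold).
#' @export
tidy.af_cv <- function(x, ...) x$per_fold

#' Quartile summary of a cross-validation run
#'
#' @param x an `af_cv`.
#' @param ... unused.
#' @return tibble with `metric`, `p25`, `median`, `p75`.
#' @export
glance.af_cv <- function(x, ...) x$summary

#' Serialize a fitted model to JSON
#'
#' Writes covariate names, coefficients, standard errors, Wald p-values,
#' the chosen threshold and the window/embedding configuration.
#'
#' @param model an `af_model`.
#' @param path output file.
#' @param tau chosen classification threshold (optional).
#' @param w,m window size and embedding dimension used to build the
#'   features (optional, stored for provenance).
#' @export
write_model_json <- function(model, path, tau = NA_real_, w = NA_integer_, m = 3L) {
  td <- tidy(model)
  doc <- list(
    package = "srqafib",
    version = as.character(utils::packageVersion("srqafib")),
    w = w, m = m, tau = tau,
    converged = model$converged,
    separation = model$separation,
    n_obs = model$n_obs,
    terms = td$term,
    coefficients = td$estimate,
    std_errors = td$std_error,
    p_values = td$p_value
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a serialized model
#'
#' Rebuilds a prediction-capable object from [write_model_json()] output.
#' Only the linear predictor is restored (enough for [predict_af()] via
#' the returned closure), not the full `glm` fit.
#'
#' @param path JSON file written by [write_model_json()].
#' @return a list with `coefficients` (named), `tau`, `w`, `m` and
#'   `predict(features)`.
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- stats::setNames(doc$coefficients, doc$terms)
  covs <- setdiff(doc$terms, "(Intercept)")
  list(
    coefficients = beta,
    tau = doc$tau, w = doc$w, m = doc$m,
    predict = function(features) {
      X <- as.matrix(features[, covs, drop = FALSE])
      eta <- drop(X %*% beta[covs]) + beta[["(Intercept)"]]
      1 / (1 + exp(-eta))
    }
  )
}
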