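# small labelled feature-like table drawn from a known logistic law
sim_logistic <- function(n, beta0, beta, seed) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * length(beta)), n,
                dimnames = list(NULL, paste0("x", seq_along(beta))))
    p <- 1 / (1 + exp(-(beta0 + drop(X %*% beta))))
    tibble::as_tibble(X) |>
      dplyr::mutate(label = ifelse(runif(n) < p, "AF", "nonAF"))
  })
}

test_that("fitting recovers known coefficients within 3 standard errors", {
  beta0 <- -0.4; beta <- c(x1 = 0.9, x2 = -1.4)
  d <- sim_logistic(2500, beta0, beta, seed = 101)
  m <- fit_af_model(d, covariates = names(beta))
  expect_true(m$converged)
  td <- tidy(m)
  truth <- c("(Intercept)" = beta0, beta)
  for (term in names(truth)) {
    row <- td[td$term == term, ]
    expect_lt(abs(row$estimate - truth[[term]]), 3 * row$std_error, label = term)
  }
})

test_that("fit matches glm and is invariant to row duplication", {
  d <- sim_logistic(300, 0.2, c(x1 = 1), seed = 7)
  m1 <- fit_af_model(d, covariates = "x1")
  m2 <- fit_af_model(d[rep(seq_len(nrow(d)), 2), ], covariates = "x1")
  expect_equal(coef(m1$fit), coef(m2$fit), tolerance = 1e-6)
})

test_that("degenerate fitting inputs are rejected or flagged", {
  d <- sim_logistic(200, 0, c(x1 = 1), seed = 3)
  expect_error(fit_af_model(dplyr::filter(d, label == "AF"), covariates = "x1"),
               "both classes")
  d$flat <- 1
  expect_warning(m <- fit_af_model(d, covariates = c("x1", "flat")),
                 "zero-variance")
  expect_identical(m$covariates, "x1")
  expect_identical(m$dropped, "flat")

  # perfectly separable data: flagged, last-iterate coefficients kept
  sep <- tibble::tibble(x1 = c(rnorm(30, -4), rnorm(30, 4)),
                        label = rep(c("nonAF", "AF"), each = 30))
  expect_warning(ms <- fit_af_model(sep, covariates = "x1"), "separat")
  expect_true(ms$separation)
  expect_false(ms$converged)
  expect_true(all(is.finite(coef(ms$fit))))
  expect_error(fit_af_model(sep[c(1, 2, 31), ], covariates = "x1"),
               "at least 2")
})

test_that("predicted probabilities equal the logistic transform", {
  d <- sim_logistic(400, -0.3, c(x1 = 1.1, x2 = 0.5), seed = 11)
  m <- fit_af_model(d, covariates = c("x1", "x2"))
  p <- predict_af(m, d)
  expect_true(all(p >= 0 & p <= 1))
  beta <- coef(m$fit)
  for (i in c(3, 57, 311)) {
    eta <- unname(beta[1] + beta[2] * d$x1[i] + beta[3] * d$x2[i])
    expect_equal(p[i], 1 / (1 + exp(-eta)))
  }
  # monotone in a positive-coefficient covariate
  stopifnot(beta[["x1"]] > 0)
  shifted <- dplyr::mutate(d, x1 = x1 + 1)
  expect_true(all(predict_af(m, shifted) > p))
  expect_error(predict_af(m, d["x1"]), "lacks covariate")
})

test_that("wald type-I error is near nominal on null data", {
  reps <- 60
  hits <- 0L; total <- 0L
  for (r in seq_len(reps)) {
    d <- sim_logistic(300, 0, c(x1 = 0, x2 = 0, x3 = 0), seed = 2000 + r)
    td <- tidy(fit_af_model(d, covariates = c("x1", "x2", "x3")))
    pv <- td$p_value[td$term != "(Intercept)"]
    hits <- hits + sum(pv < 0.05)
    total <- total + length(pv)
  }
  expect_equal(hits / total, 0.05, tolerance = 0.5) # 2.5%..7.5% band
})

test_that("the threshold grid is exhaustive, monotone and corner-seeking", {
  probs <- c(rep(0.9, 20), rep(0.1, 20))
  labels <- rep(c("AF", "nonAF"), each = 20)
  roc <- roc_threshold(probs, labels)
  expect_identical(nrow(roc$grid), 1001L)
  expect_equal(roc$distance, 0)
  at <- roc$grid[roc$grid$tau == roc$tau, ]
  expect_equal(at$se, 1); expect_equal(at$fpr, 0)
  # first grid point attaining the minimum is returned
  zero <- roc$grid$tau[roc$grid$fpr^2 + (1 - roc$grid$se)^2 == 0]
  expect_equal(roc$tau, min(zero))
  expect_true(all(diff(roc$grid$se) <= 0))
  expect_true(all(diff(roc$grid$fpr) <= 0))
  expect_equal(roc$grid$se[roc$grid$tau == 0], 1) # everything flagged at tau = 0
  expect_error(roc_threshold(probs, rep("AF", 40)), "both classes")
})

test_that("uninformative probabilities give a chance-level operating point", {
  set.seed(21)
  probs <- runif(4000)
  labels <- ifelse(runif(4000) < 0.5, "AF", "nonAF")
  roc <- roc_threshold(probs, labels)
  at <- roc$grid[roc$grid$tau == roc$tau, ]
  expect_equal(at$se, 0.5, tolerance = 0.1)
  expect_equal(1 - at$fpr, 0.5, tolerance = 0.1)
})

test_that("threshold evaluation reproduces the confusion arithmetic", {
  probs <- c(rep(0.8, 96), rep(0.2, 4), rep(0.1, 95), rep(0.9, 5))
  labels <- rep(c("AF", "nonAF"), c(100, 100))
  ev <- evaluate_threshold(probs, labels, 0.5)
  expect_identical(unname(unlist(ev[c("tp", "fn", "tn", "fp")])),
                   c(96L, 4L, 95L, 5L))
  expect_equal(ev$se, 0.96)
  expect_equal(ev$sp, 0.95)
  expect_equal(ev$acc, 0.955)

  all_right <- evaluate_threshold(c(0.9, 0.9, 0.1), c("AF", "AF", "nonAF"), 0.5)
  expect_equal(unname(unlist(all_right[c("se", "sp", "acc")])), c(1, 1, 1))

  set.seed(31)
  for (r in 1:20) {
    p <- runif(50); lab <- ifelse(runif(50) < 0.4, "AF", "nonAF")
    if (length(unique(lab)) < 2) next
    tau <- runif(1)
    ev <- evaluate_threshold(p, lab, tau)
    expect_identical(unname(unlist(ev[c("tp", "tn", "fp", "fn")])),
                     unname(oracle_confusion(p, lab, tau)))
    # accuracy decomposes over class sizes
    P <- sum(lab == "AF"); N <- sum(lab != "AF")
    expect_equal(ev$acc, (ev$se * P + ev$sp * N) / (P + N))
  }
})

test_that("roc points agree with pROC on random data", {
  set.seed(17)
  probs <- runif(300)
  labels <- ifelse(runif(300) < 0.5 + 0.3 * (probs - 0.5), "AF", "nonAF")
  roc <- roc_threshold(probs, labels)
  ref <- pROC::roc(labels == "AF", probs, quiet = TRUE, direction = "<")
  for (tau in c(0.2, 0.5, 0.77)) {
    # pROC thresholds are midpoints; evaluate our strict rule at the same cut
    co <- pROC::coords(ref, x = tau + 1e-9, input = "threshold",
                       ret = c("sensitivity", "specificity"))
    at <- roc$grid[which.min(abs(roc$grid$tau - tau)), ]
    expect_equal(at$se, co$sensitivity, tolerance = 1e-6)
    expect_equal(1 - at$fpr, co$specificity, tolerance = 1e-6)
  }
})

test_that("cross-validation partitions correctly and is reproducible", {
  d <- sim_logistic(400, 0, c(x1 = 2), seed = 55)
  cv1 <- kfold_cv(d, k = 10, seed = 9, covariates = "x1")
  cv2 <- kfold_cv(d, k = 10, seed = 9, covariates = "x1")
  expect_identical(cv1$per_fold, cv2$per_fold)
  expect_identical(nrow(cv1$per_fold), 10L)
  expect_identical(sum(cv1$per_fold$tp + cv1$per_fold$tn +
                         cv1$per_fold$fp + cv1$per_fold$fn), 400L)
  s <- cv1$summary
  expect_true(all(s$p25 <= s$median & s$median <= s$p75))
  expect_identical(s$metric, c("tau", "se", "sp", "acc"))

  cv3 <- kfold_cv(d, k = 10, seed = 10, covariates = "x1")
  expect_false(identical(cv1$per_fold, cv3$per_fold))

  tiny <- d[c(1:5, which(d$label == "AF")[1:5]), ]
  expect_error(kfold_cv(tiny, k = 10, covariates = "x1"), "at least k")
})

test_that("record-grouped cross-validation keeps records intact", {
  d <- build_dataset(simulate_records(12, 310, seed = 6), w = 30)
  cv <- kfold_cv(d, k = 3, seed = 4, by_record = TRUE)
  expect_identical(nrow(cv$per_fold), 3L)
  expect_identical(sum(cv$per_fold$tp + cv$per_fold$tn +
                         cv$per_fold$fp + cv$per_fold$fn), nrow(d))
})

test_that("models serialize to JSON and predict identically after reload", {
  d <- sim_logistic(300, -0.2, c(x1 = 0.8, x2 = -0.6), seed = 77)
  m <- fit_af_model(d, covariates = c("x1", "x2"))
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path, tau = 0.42, w = 60L)
  back <- read_model_json(path)
  expect_equal(back$tau, 0.42)
  expect_equal(back$w, 60)
  expect_equal(unname(back$coefficients), unname(coef(m$fit)))
  expect_equal(back$predict(d), predict_af(m, d), tolerance = 1e-12)
})
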