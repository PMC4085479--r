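test_that("AUC matches exhaustive pair counting", {
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc(c(1, 2, 3, 10, 20), c(0, 0, 0, 1, 1)), 1)
  expect_equal(auc(rep(0.3, 6), c(1, 0, 1, 0, 0, 1)), 0.5)
  brute <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(pos) * length(neg))
  }
  set.seed(91)
  for (i in 1:60) {
    n <- sample(3:8, 1)
    y <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    s <- sample(seq(0, 1, 0.25), n, replace = TRUE)  # many ties
    expect_identical(auc(s, y), brute(s, y))
  }
  expect_error(auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("AUC direction reversal is exact for tie-free scores", {
  set.seed(92)
  for (i in 1:20) {
    s <- rnorm(30)
    y <- sample(c(rep(1, 10), rep(0, 20)))
    expect_equal(auc(s, y) + auc(-s, y), 1)
  }
})

test_that("ROC curves start at (0,0), end at (1,1) and integrate to the AUC", {
  set.seed(93)
  for (i in 1:50) {
    n <- sample(10:60, 1)
    y <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    s <- if (i %% 2) rnorm(n) else sample(1:5, n, replace = TRUE)
    rc <- roc_curve(s, y)
    expect_equal(c(rc$fpr[1], rc$tpr[1]), c(0, 0))
    expect_equal(c(rc$fpr[length(rc$fpr)], rc$tpr[length(rc$tpr)]), c(1, 1))
    expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
    expect_equal(rc$auc, auc(s, y), tolerance = 1e-12)
    rcr <- roc_curve(-s, y)
    expect_equal(rcr$auc, 1 - rc$auc, tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(94)
  s <- rnorm(80); y <- sample(c(rep(1, 30), rep(0, 50)))
  expect_equal(auc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))))
})

test_that("leave-one-subject-out emits one calibrated probability per subject", {
  set.seed(95)
  fc <- feature_cohort(n = 60, n_pos = 20, k_noise = 4, effect = 4)
  for (kind in c("logistic", "lda")) {
    run <- loo_posteriors(fc$x, fc$y, c("informative", "noise_01"), kind)
    expect_length(run$prob, 60)
    expect_true(all(run$prob >= 0 & run$prob <= 1))
    expect_gt(auc(run$prob, run$labels), 0.95)
    # subject order invariance
    perm <- sample(60)
    run_p <- loo_posteriors(fc$x[perm, ], fc$y[perm],
                            c("informative", "noise_01"), kind)
    expect_lt(max(abs(run_p$prob - run$prob[perm])), 1e-10)
  }
  wide <- feature_cohort(n = 30, n_pos = 10, k_noise = 8)
  expect_error(loo_posteriors(wide$x, wide$y, names(wide$x)), "at most 6")
  expect_error(loo_posteriors(fc$x[1:8, ], fc$y[1:8], "noise_01"), "n >= 10")
})

test_that("LDA posterior agrees with the reference implementation", {
  set.seed(96)
  fc <- feature_cohort(n = 40, n_pos = 15, k_noise = 3, effect = 1.5)
  x <- as.matrix(fc$x[, c("noise_01", "informative")])
  xtr <- x[-1, , drop = FALSE]; ytr <- fc$y[-1]
  xte <- x[1, , drop = FALSE]
  ours <- kinestroke:::lda_posterior(xtr, ytr, xte)
  ref <- MASS::lda(xtr, grouping = factor(ytr))
  ref_p <- predict(ref, xte)$posterior[, "TRUE"]
  expect_false(ours$ridged)
  expect_equal(unname(ours$prob), unname(ref_p), tolerance = 1e-8)
})

test_that("a posterior preserves its AUC under monotone transforms", {
  set.seed(97)
  fc <- feature_cohort(n = 40, n_pos = 15, k_noise = 3, effect = 2)
  run <- loo_posteriors(fc$x, fc$y, "informative", "lda")
  a <- auc(run$prob, run$labels)
  expect_equal(auc(qlogis(pmin(pmax(run$prob, 1e-12), 1 - 1e-12)), run$labels), a)
  expect_equal(auc(run$prob^3, run$labels), a)
})

test_that("semi-exhaustive subset selection finds planted signal deterministically", {
  set.seed(98)
  fc <- feature_cohort(n = 60, n_pos = 20, k_noise = 19, effect = 2)
  ss <- select_feature_subset(fc$x, fc$y, kind = "lda",
                              top_pool = 8, exhaustive_k = 2, beam_width = 5)
  expect_lte(length(ss), 6)
  expect_true("informative" %in% ss)
  ss2 <- select_feature_subset(fc$x, fc$y, kind = "lda",
                               top_pool = 8, exhaustive_k = 2, beam_width = 5)
  expect_identical(ss, ss2)
})

test_that("bootstrap CIs are reproducible and detect separable runs", {
  set.seed(99)
  fc <- feature_cohort(n = 50, n_pos = 20, k_noise = 2, effect = 3)
  run <- loo_posteriors(fc$x, fc$y, "informative", "logistic")
  ci1 <- bootstrap_auc_ci(run, B = 500, seed = 7)
  ci2 <- bootstrap_auc_ci(run, B = 500, seed = 7)
  expect_identical(ci1, ci2)
  expect_gt(ci1[["low"]], 0.5)
  expect_lte(ci1[["low"]], ci1[["high"]])
})

test_that("bootstrap CI coverage is near nominal", {
  # scores ~ N(delta, 1) for positives: true AUC = pnorm(delta / sqrt(2))
  set.seed(101)
  delta <- 1
  true_auc <- pnorm(delta / sqrt(2))
  covered <- vapply(1:200, function(i) {
    y <- c(rep(TRUE, 20), rep(FALSE, 20))
    s <- rnorm(40) + delta * y
    run <- structure(list(prob = s, labels = y, subset = "s",
                          kind = "logistic", meta = list()),
                     class = "classification_run")
    ci <- bootstrap_auc_ci(run, B = 300, seed = 1000 + i)
    ci[["low"]] <= true_auc && true_auc <= ci[["high"]]
  }, TRUE)
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 1.00)
})

test_that("the AUC matrix separates planted from null risk factors", {
  set.seed(103)
  n <- 60
  labels_df <- data.frame(subject_id = sprintf("S%03d", 1:n),
                          DM = c(rep(TRUE, 12), rep(FALSE, n - 12)),
                          CS = sample(c(rep(TRUE, 10), rep(FALSE, n - 10))))
  tables <- lapply(setNames(nm = c("2", "3")), function(task) {
    x <- as.data.frame(matrix(rnorm(n * 6), n))
    names(x) <- paste0("f", 1:6)
    x$f1 <- x$f1 + 2.5 * labels_df$DM        # DM signal, CS null
    cbind(data.frame(subject_id = labels_df$subject_id,
                     task_id = task, stringsAsFactors = FALSE), x)
  })
  m <- build_auc_matrix(tables, labels_df, kind = "lda",
                        selection = "pooled",
                        top_pool = 4, exhaustive_k = 2, beam_width = 3)
  expect_equal(dim(unclass(m)), c(2L, 2L))
  expect_true(all(m >= 0 & m <= 1, na.rm = TRUE))
  s <- summarize_auc_matrix(m)
  expect_gt(s$row_medians[["DM"]], s$row_medians[["CS"]])
  expect_gt(m["DM", "2"], 0.8)
})
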