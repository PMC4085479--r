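#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' The probability of ranking a randomly chosen affected subject above a
#' randomly chosen unaffected one: the fraction of (positive, negative)
#' pairs in which the positive scores higher, ties counted 1/2.
#' Computed via average ranks.
#'
#' @param scores numeric scores, higher meaning more likely positive.
#' @param labels binary labels (logical or 0/1).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels)) stopf("scores and labels must not contain NA")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stopf("undefined AUC: both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve
#'
#' Operating points over all distinct score thresholds, from (0, 0) to
#' (1, 1); the trapezoidal area under the curve equals the Mann-Whitney
#' [auc()] exactly (ties form diagonal segments).
#'
#' @inheritParams auc
#' @return list of class `roc_curve` with `thresholds`, `fpr`, `tpr`,
#'   `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stopf("undefined ROC: both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  grp_end <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(y)[grp_end]
  fp <- cumsum(!y)[grp_end]
  curve <- list(thresholds = c(Inf, s[grp_end]),
                fpr = c(0, fp / n0),
                tpr = c(0, tp / n1))
  curve$auc <- trapz_int(curve$fpr, curve$tpr)
  structure(curve, class = "roc_curve")
}

# Pooled-covariance Gaussian (LDA) posterior with the training-fold
# prevalence as prior; falls back to a ridge-regularized covariance when
# the pooled covariance is singular.
lda_posterior <- function(xtr, ytr, xte, ridge_eps = 1e-6) {
  mu1 <- colMeans(xtr[ytr, , drop = FALSE])
  mu0 <- colMeans(xtr[!ytr, , drop = FALSE])
  n1 <- sum(ytr); n0 <- sum(!ytr)
  c1 <- stats::cov(xtr[ytr, , drop = FALSE])
  c0 <- stats::cov(xtr[!ytr, , drop = FALSE])
  S <- ((n1 - 1) * c1 + (n0 - 1) * c0) / (n1 + n0 - 2)
  w <- tryCatch(solve(S, mu1 - mu0), error = function(e) NULL)
  ridged <- FALSE
  if (is.null(w) || !all(is.finite(w))) {
    S <- S + diag(ridge_eps * (1 + diag(S)), nrow(S))
    w <- solve(S, mu1 - mu0)
    ridged <- TRUE
  }
  b <- -0.5 * sum((mu1 + mu0) * w) + log(n1 / n0)
  z <- drop(xte %*% w) + b
  list(prob = 1 / (1 + exp(-z)), ridged = ridged)
}

logistic_posterior <- function(xtr, ytr, xte) {
  fit <- suppressWarnings(
    glm.fit(cbind(1, xtr), as.numeric(ytr), family = binomial()))
  eta <- drop(cbind(1, xte) %*% fit$coefficients)
  eta[!is.finite(eta)] <- sign(eta[!is.finite(eta)]) * 30
  1 / (1 + exp(-pmin(30, pmax(-30, eta))))
}

#' Leave-one-subject-out cross-validated class probabilities
#'
#' For every subject in turn, the chosen classifier is trained on the
#' remaining subjects and the held-out subject's probability of carrying
#' the risk factor is recorded, giving exactly one unbiased out-of-fold
#' probability per subject.  Features are standardized with
#' training-fold statistics only.  `logistic` is a maximum-likelihood
#' binary logistic model; `lda` is the pooled-covariance Gaussian
#' classifier with Bayes posterior under the training-fold prevalence
#' prior (singular covariances get a fixed-epsilon ridge retry, flagged
#' in the run metadata).
#'
#' @param table feature `data.frame` (rows = subjects) or matrix.
#' @param labels binary labels, one per subject.
#' @param subset character vector of feature names to use (at most 6).
#' @param kind `"logistic"` or `"lda"`.
#' @return list of class `classification_run` with `prob` (per-subject
#'   out-of-fold probabilities), `labels`, `subset`, `kind`, `meta`.
#' @export
loo_posteriors <- function(table, labels, subset = NULL,
                           kind = c("logistic", "lda")) {
  kind <- match.arg(kind)
  labels <- as.logical(labels)
  if (is.null(subset)) subset <- colnames(table)
  if (length(subset) > 6L) stopf("at most 6 features may be used (got %d)",
                                 length(subset))
  if (!all(subset %in% colnames(table)))
    stopf("unknown feature(s): %s", paste(setdiff(subset, colnames(table)),
                                          collapse = ", "))
  x <- as.matrix(table[, subset, drop = FALSE])
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (n != length(labels)) stopf("table rows and labels length differ")
  if (n < 10L || sum(labels) < 2L || sum(!labels) < 2L)
    stopf("need n >= 10 subjects with both classes represented")
  if (anyNA(x)) stopf("missing feature values; exclude incomplete subjects first")
  prob <- numeric(n)
  ridged <- FALSE
  for (i in seq_len(n)) {
    xtr <- x[-i, , drop = FALSE]; ytr <- labels[-i]
    mu <- colMeans(xtr); sdv <- apply(xtr, 2, sd)
    sdv[sdv < 1e-12] <- 1
    xtr <- sweep(sweep(xtr, 2, mu), 2, sdv, "/")
    xte <- (x[i, ] - mu) / sdv
    xte <- matrix(xte, nrow = 1)
    if (kind == "logistic") {
      prob[i] <- logistic_posterior(xtr, ytr, xte)
    } else {
      r <- lda_posterior(xtr, ytr, xte)
      prob[i] <- r$prob
      ridged <- ridged || r$ridged
    }
  }
  structure(list(prob = prob, labels = labels, subset = subset, kind = kind,
                 meta = list(n = n, ridge_used = ridged)),
            class = "classification_run")
}

#' Semi-exhaustive selection of the best feature subset
#'
#' Features are ranked by direction-free univariate AUC; all subsets of
#' size up to `exhaustive_k` drawn from the top `top_pool` features are
#' evaluated exhaustively by leave-one-out AUC of the chosen classifier;
#' the best `beam_width` subsets are then beam-extended one feature at a
#' time up to `max_k`.  Ties are broken deterministically by smaller
#' subset size, then lexicographic feature names, so the same inputs
#' always return the same subset.
#'
#' @inheritParams loo_posteriors
#' @param max_k maximum subset size (default 6).
#' @param top_pool number of top-ranked candidate features.
#' @param exhaustive_k exhaustive search covers subsets up to this size.
#' @param beam_width number of subsets kept per beam level.
#' @return character vector of selected feature names (length <= `max_k`).
#' @export
select_feature_subset <- function(table, labels, max_k = 6L,
                                  kind = c("logistic", "lda"),
                                  top_pool = 12L, exhaustive_k = 3L,
                                  beam_width = 10L) {
  kind <- match.arg(kind)
  labels <- as.logical(labels)
  feats <- colnames(table)
  feats <- feats[vapply(feats, function(f) {
    x <- table[[f]]
    is.numeric(x) && !anyNA(x) && sd(x) > 0
  }, TRUE)]
  if (!length(feats)) stopf("no candidate features available")
  uni <- vapply(feats, function(f) {
    a <- auc(table[[f]], labels); max(a, 1 - a)
  }, 0)
  pool <- feats[order(-uni, feats)][seq_len(min(top_pool, length(feats)))]
  score_subset <- function(ss) {
    run <- loo_posteriors(table, labels, ss, kind)
    auc(run$prob, run$labels)
  }
  cand <- list()
  for (k in seq_len(min(exhaustive_k, max_k, length(pool)))) {
    cmb <- utils::combn(pool, k, simplify = FALSE)
    for (ss in cmb) cand[[length(cand) + 1L]] <- sort(ss)
  }
  scored <- lapply(cand, function(ss) list(ss = ss, score = score_subset(ss)))
  order_key <- function(sc) {
    nm <- vapply(sc, function(e) paste(e$ss, collapse = "|"), "")
    order(-vapply(sc, `[[`, 0, "score"),
          vapply(sc, function(e) length(e$ss), 0L), nm)
  }
  scored <- scored[order_key(scored)]
  best <- scored[[1]]
  beam <- scored[seq_len(min(beam_width, length(scored)))]
  k <- max(vapply(beam, function(e) length(e$ss), 0L))
  while (k < min(max_k, length(pool))) {
    ext <- list()
    seen <- character(0)
    for (e in beam) {
      for (f in setdiff(pool, e$ss)) {
        ss <- sort(c(e$ss, f))
        key <- paste(ss, collapse = "|")
        if (key %in% seen) next
        seen <- c(seen, key)
        ext[[length(ext) + 1L]] <- list(ss = ss, score = score_subset(ss))
      }
    }
    if (!length(ext)) break
    ext <- ext[order_key(ext)]
    if (ext[[1]]$score > best$score) best <- ext[[1]]
    beam <- ext[seq_len(min(beam_width, length(ext)))]
    k <- k + 1L
  }
  best$ss
}

#' Bootstrap percentile confidence interval for a run's AUC
#'
#' Subjects are resampled with replacement, stratified by class (so both
#' classes are always present), and the percentile interval of the
#' resampled AUCs is returned.
#'
#' @param run a [loo_posteriors()] result.
#' @param B number of bootstrap resamples.
#' @param level confidence level.
#' @param seed RNG seed for reproducibility.
#' @return named numeric vector `c(low, high)`.
#' @export
bootstrap_auc_ci <- function(run, B = 2000L, level = 0.95, seed = 1L) {
  stopifnot(inherits(run, "classification_run"))
  pos <- which(run$labels); neg <- which(!run$labels)
  set.seed(seed)
  stats <- vapply(seq_len(B), function(b) {
    idx <- c(sample(pos, length(pos), replace = TRUE),
             sample(neg, length(neg), replace = TRUE))
    auc(run$prob[idx], run$labels[idx])
  }, 0)
  a <- (1 - level) / 2
  setNames(quantile(stats, c(a, 1 - a), names = FALSE, type = 7),
           c("low", "high"))
}

#' Risk-factor x task AUC matrix
#'
#' For every (risk factor, task) pair: optionally select the best
#' feature subset, run leave-one-subject-out cross-validation, and
#' compute the out-of-fold AUC, mirroring the layout of the published
#' summary table (risk-factor rows, task columns).  Selection modes:
#' `"nested"` re-runs the subset search inside every LOO fold (unbiased
#' but expensive), `"pooled"` selects once on all subjects and then
#' cross-validates only the classifier coefficients, `"none"` uses
#' `fixed_subset` as is.  Subjects with missing feature cells are
#' excluded listwise per cell.
#'
#' @param tables named list (task id -> feature table with `subject_id`).
#' @param labels_df `data.frame` with `subject_id` and one logical/0-1
#'   column per risk factor.
#' @param factors risk-factor column names (rows of the matrix).
#' @param kind classifier kind.
#' @param selection `"pooled"`, `"nested"` or `"none"`.
#' @param fixed_subset features used when `selection = "none"`.
#' @param ... selection tuning passed to [select_feature_subset()].
#' @return object of class `auc_matrix`: numeric matrix (factors x
#'   tasks) with the per-cell runs in `attr(, "runs")`.
#' @export
build_auc_matrix <- function(tables, labels_df,
                             factors = setdiff(names(labels_df), "subject_id"),
                             kind = c("logistic", "lda"),
                             selection = c("pooled", "nested", "none"),
                             fixed_subset = NULL, ...) {
  kind <- match.arg(kind)
  selection <- match.arg(selection)
  tasks <- names(tables)
  m <- matrix(NA_real_, nrow = length(factors), ncol = length(tasks),
              dimnames = list(factors, tasks))
  runs <- list()
  for (task in tasks) {
    tab <- tables[[task]]
    if (is.null(tab)) next
    feat_cols <- setdiff(names(tab), c("subject_id", "task_id", "n_valid_trials"))
    for (f in factors) {
      lab <- labels_df[[f]][match(tab$subject_id, labels_df$subject_id)]
      keep <- stats::complete.cases(tab[, feat_cols, drop = FALSE]) & !is.na(lab)
      x <- tab[keep, feat_cols, drop = FALSE]
      y <- as.logical(lab[keep])
      cell <- tryCatch({
        run <- switch(selection,
          none = loo_posteriors(x, y, fixed_subset, kind),
          pooled = {
            ss <- select_feature_subset(x, y, kind = kind, ...)
            loo_posteriors(x, y, ss, kind)
          },
          nested = nested_loo(x, y, kind, ...))
        runs[[paste(f, task, sep = ":")]] <- run
        auc(run$prob, run$labels)
      }, error = function(e) NA_real_)
      m[f, task] <- cell
    }
  }
  structure(m, class = c("auc_matrix", "matrix"), runs = runs, kind = kind,
            selection = selection)
}

# Fully nested LOO: the feature subset is re-selected inside each fold.
nested_loo <- function(x, y, kind, ...) {
  n <- nrow(x)
  prob <- numeric(n)
  subsets <- vector("list", n)
  for (i in seq_len(n)) {
    xtr_df <- x[-i, , drop = FALSE]; ytr <- y[-i]
    ss <- select_feature_subset(xtr_df, ytr, kind = kind, ...)
    xtr <- as.matrix(xtr_df[, ss, drop = FALSE])
    xte <- matrix(as.numeric(x[i, ss, drop = FALSE]), nrow = 1)
    mu <- colMeans(xtr); sdv <- apply(xtr, 2, sd); sdv[sdv < 1e-12] <- 1
    xtr <- sweep(sweep(xtr, 2, mu), 2, sdv, "/")
    xte <- sweep(sweep(xte, 2, mu), 2, sdv, "/")
    prob[i] <- if (kind == "logistic") logistic_posterior(xtr, ytr, xte)
               else lda_posterior(xtr, ytr, xte)$prob
    subsets[[i]] <- ss
  }
  structure(list(prob = prob, labels = y, subset = subsets, kind = kind,
                 meta = list(n = n, nested = TRUE)),
            class = "classification_run")
}
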