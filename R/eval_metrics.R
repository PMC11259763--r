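# Discrimination metrics for rare binary outcomes: AUROC (midrank
# Mann-Whitney), AUPRC (average precision), the DeLong test for correlated
# ROC areas, and stratified-bootstrap model evaluation.

#' Area under the ROC curve (midrank Mann-Whitney estimator)
#'
#' Ties between a positive and a negative score receive 0.5 credit.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present",
                               call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Average-precision form: scores are ranked in descending order (ties
#' broken by stable index order) and precision is averaged at the rank of
#' each positive. Under random scores this concentrates near the outcome
#' prevalence, which is what makes it informative at 0.2-0.4% mortality.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels; at least one positive required.
#' @return AUPRC in [0, 1].
#' @export
auprc <- function(scores, labels) {
  if (sum(labels == 1) == 0) stop("at least one positive required",
                                  call. = FALSE)
  ord <- order(-scores, seq_along(scores))
  y <- labels[ord]
  prec <- cumsum(y) / seq_along(y)
  mean(prec[y == 1])
}

# Midranks within a vector (helper for DeLong structural components).
midranks <- function(x) rank(x, ties.method = "average")

#' DeLong test for two correlated AUROCs
#'
#' Nonparametric comparison of the AUROCs of two score vectors evaluated
#' on the same labels, using the structural components (V10 for positives,
#' V01 for negatives) of the Mann-Whitney statistic. When the variance of
#' the AUC difference is zero and the difference itself is zero (e.g.
#' identical scores) the p-value is 1.
#'
#' @param scores_a,scores_b paired score vectors.
#' @param labels shared 0/1 labels, both classes present.
#' @return list with `auc_a`, `auc_b`, `z`, `p_value`, `var_diff`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  pos <- labels == 1
  m <- sum(pos); n <- sum(!pos)
  if (m == 0 || n == 0) stop("both classes must be present", call. = FALSE)

  comps <- function(s) {
    x <- s[pos]; y <- s[!pos]
    tz <- midranks(c(x, y))
    tx <- midranks(x); ty <- midranks(y)
    v10 <- (tz[seq_len(m)] - tx) / n
    v01 <- 1 - (tz[m + seq_len(n)] - ty) / m
    auc <- (sum(tz[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
    list(v10 = v10, v01 = v01, auc = auc)
  }
  a <- comps(scores_a); b <- comps(scores_b)
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- a$auc - b$auc
  if (var_diff <= 0) {
    z <- if (abs(d) < 1e-15) 0 else sign(d) * Inf
  } else {
    z <- d / sqrt(var_diff)
  }
  p <- if (is.infinite(z)) 0 else 2 * stats::pnorm(-abs(z))
  list(auc_a = a$auc, auc_b = b$auc, z = z, p_value = p,
       var_diff = var_diff)
}

#' Bootstrap-averaged model evaluation
#'
#' Repeats B times: resample the training data with replacement, refit
#' with `trainer`, and score every fixed test set; reports per-test-set
#' mean AUROC/AUPRC with percentile 95% CIs. By default resampling is
#' stratified by outcome (cases and controls resampled separately, so
#' every replicate keeps the original case count) -- at a 0.2% outcome
#' prevalence a naive resample has a non-trivial chance of containing no
#' events at all; `stratified = FALSE` restores naive resampling.
#'
#' @param trainer function(X, y, replicate_seed) returning a
#'   `model_weights` (or a list with element `weights`).
#' @param train_set list with `X`, `y`.
#' @param test_sets named list of lists with `X`, `y`.
#' @param B number of bootstrap replicates (>= 1).
#' @param seed integer seed.
#' @param stratified stratify the resampling by outcome.
#' @return `bootstrap_result`: list with `results` (data.frame replicate x
#'   test set metrics), `ci` (data.frame test_set, metric, mean, lo, hi),
#'   `B`, `seed`.
#' @export
bootstrap_evaluate <- function(trainer, train_set, test_sets, B = 100,
                               seed = 1L, stratified = TRUE) {
  stopifnot(B >= 1)
  n <- nrow(train_set$X)
  case_idx <- which(train_set$y == 1)
  ctrl_idx <- which(train_set$y == 0)
  rows <- list()
  for (b in seq_len(B)) {
    rs <- derive_seed(seed, paste0("boot-", b))
    idx <- with_seed(rs, {
      if (stratified) {
        c(sample(case_idx, length(case_idx), replace = TRUE),
          sample(ctrl_idx, length(ctrl_idx), replace = TRUE))
      } else {
        sample.int(n, n, replace = TRUE)
      }
    })
    fit <- tryCatch(
      trainer(train_set$X[idx, , drop = FALSE], train_set$y[idx], rs),
      error = function(e) {
        stop(sprintf("trainer failed at replicate %d: %s", b,
                     conditionMessage(e)), call. = FALSE)
      })
    wts <- if (inherits(fit, "model_weights")) fit else fit$weights
    for (ts in names(test_sets)) {
      p <- predict_proba(wts, test_sets[[ts]]$X)
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = b, test_set = ts,
        auroc = auroc(p, test_sets[[ts]]$y),
        auprc = auprc(p, test_sets[[ts]]$y))
    }
  }
  results <- do.call(rbind, rows)
  ci <- do.call(rbind, lapply(names(test_sets), function(ts) {
    sub <- results[results$test_set == ts, ]
    do.call(rbind, lapply(c("auroc", "auprc"), function(metric) {
      v <- sub[[metric]]
      data.frame(test_set = ts, metric = metric, mean = mean(v),
                 lo = unname(stats::quantile(v, 0.025)),
                 hi = unname(stats::quantile(v, 0.975)))
    }))
  }))
  structure(list(results = results, ci = ci, B = B, seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> B=%d\n", x$B))
  print(x$ci, row.names = FALSE)
  invisible(x)
}

#' Paired bootstrap percentile test for an AUPRC difference
#'
#' The DeLong machinery is defined for ROC areas only; differences in
#' AUPRC are compared by resampling the test set with replacement and
#' reading the two-sided percentile p-value of the paired difference.
#'
#' @param scores_a,scores_b paired score vectors.
#' @param labels shared 0/1 labels.
#' @param B resamples.
#' @param seed integer seed.
#' @return list with `auprc_a`, `auprc_b`, `p_value`.
#' @export
auprc_boot_test <- function(scores_a, scores_b, labels, B = 1000,
                            seed = 1L) {
  n <- length(labels)
  d0 <- auprc(scores_a, labels) - auprc(scores_b, labels)
  ds <- with_seed(seed, vapply(seq_len(B), function(b) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (sum(labels[idx] == 1) > 0) break
    }
    auprc(scores_a[idx], labels[idx]) - auprc(scores_b[idx], labels[idx])
  }, 0))
  p <- 2 * min(mean(ds <= 0), mean(ds >= 0))
  list(auprc_a = auprc(scores_a, labels), auprc_b = auprc(scores_b, labels),
       delta = d0, p_value = min(1, p))
}
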