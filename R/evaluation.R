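#' Confusion-matrix performance metrics
#'
#' Accuracy, sensitivity, specificity, positive/negative predictive value
#' and the Matthews correlation coefficient from the four confusion counts:
#' `Ac = (TP+TN)/(TP+FP+TN+FN)`, `Sn = TP/(TP+FN)`, `Sp = TN/(TN+FP)`,
#' `PPV = TP/(TP+FP)`, `NPV = TN/(TN+FN)`,
#' `MCC = (TP*TN - FN*FP) / sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN))`.
#' A metric whose denominator is zero is reported as `NA` (flagged, never
#' silently zero).
#'
#' @param tp,fp,tn,fn Non-negative confusion counts.
#' @return A one-row tibble with columns `ac`, `sn`, `sp`, `ppv`, `npv`,
#'   `mcc`.
#' @export
#' @examples
#' confusion_metrics(tp = 8, fp = 10, tn = 90, fn = 2)
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) abort("confusion counts must be non-negative.")
  if (sum(counts) == 0) abort("all confusion counts are zero.")
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  mcc_den <- sqrt(prod(c(tp + fn, tn + fp, tp + fp, tn + fn)))
  tibble(
    ac = (tp + tn) / sum(counts),
    sn = rate(tp, tp + fn),
    sp = rate(tn, tn + fp),
    ppv = rate(tp, tp + fp),
    npv = rate(tn, tn + fn),
    mcc = if (mcc_den > 0) (tp * tn - fn * fp) / mcc_den else NA_real_
  )
}

#' ROC curve and AUC
#'
#' The AUC is the Mann-Whitney probability that a random positive outscores
#' a random negative, ties counting one half. The ROC points are the
#' `(1 - Sp, Sn)` pairs swept over the distinct score thresholds (one point
#' per distinct threshold, plus the origin); the trapezoid area under these
#' points equals the Mann-Whitney AUC.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (1 = positive); both classes must be
#'   present.
#' @return An object of class `pbs_roc`: a list with `auc` and
#'   `roc_points` (tibble of `threshold`, `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) {
    abort("`scores` and `labels` must have equal length.")
  }
  auc <- auc_mw(scores, labels)  # errors on single-class input
  np <- sum(labels == 1L)
  nn <- sum(labels == 0L)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # index of the last occurrence of each distinct threshold
  keep <- which(!duplicated(s, fromLast = TRUE))
  pts <- tibble(
    threshold = c(Inf, s[keep]),
    fpr = c(0, cumsum(y == 0L)[keep] / nn),
    tpr = c(0, cumsum(y == 1L)[keep] / np)
  )
  structure(list(auc = auc, roc_points = pts), class = "pbs_roc")
}

#' @export
print.pbs_roc <- function(x, ...) {
  cat(sprintf("<pbs_roc> AUC %.4f over %d thresholds\n", x$auc,
              nrow(x$roc_points) - 1L))
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.pbs_roc <- function(object, ...) {
  ggplot(object$roc_points, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    geom_line() +
    coord_equal() +
    labs(x = "1 - Specificity", y = "Sensitivity") +
    theme_minimal()
}

subset_benchmark <- function(benchmark, idx) {
  at <- benchmark_attrs(benchmark)
  new_pbs_benchmark(as_tibble(benchmark)[idx, , drop = FALSE],
                    node = at$node, m = at$m, n = at$n,
                    center_classes = at$center_classes)
}

resolve_scheme <- function(scheme, n_pos) {
  if (identical(scheme, "auto")) {
    if (n_pos >= 30) 10L else "loo"
  } else if (identical(scheme, "loo") || identical(scheme, "LOO")) {
    "loo"
  } else {
    k <- as.integer(scheme)
    if (!k %in% c(4L, 6L, 8L, 10L)) {
      abort("`scheme` must be 'auto', 'loo', or one of 4, 6, 8, 10 folds.")
    }
    if (k > n_pos) abort("more folds than positive items.")
    k
  }
}

#' Cross-validate the full prediction pipeline
#'
#' Runs position-weight optimization, pair-similarity encoding and
#' classifier training entirely inside each training fold, scores the
#' held-out items, and pools the held-out scores into a single ROC/AUC.
#' Folds are stratified by label and drawn once from `seed`. Following the
#' benchmark-size rule for validation schemes, `scheme = "auto"` selects
#' 10-fold for benchmarks with at least 30 positives and leave-one-out
#' (LOO) otherwise; 4-, 6- and 8-fold are available explicitly. In LOO
#' fast mode the position weights are optimized once on the full benchmark
#' (per-round re-optimization via `exact_loo = TRUE`), while encoding and
#' classifier training still exclude the held-out item.
#'
#' @param benchmark A `pbs_benchmark`.
#' @param scheme `"auto"`, `"loo"`, or 4, 6, 8, 10.
#' @param seed Integer seed for folds and fold-derived model seeds.
#' @param matrix Substitution matrix.
#' @param pwd A [pwd_control()] for the per-fold weight optimization.
#' @param dnn A [dnn_config()] template; each fold trains with a seed
#'   derived from it.
#' @param exact_loo Re-optimize weights in every LOO round.
#' @return An object of class `pbs_evaluation`: scheme, pooled `auc`,
#'   `roc_points`, threshold-0.5 `metrics`, and the per-item held-out
#'   scores.
#' @export
cross_validate <- function(benchmark, scheme = "auto", seed = 1L,
                           matrix = blosum62_21(), pwd = pwd_control(),
                           dnn = dnn_config(), exact_loo = FALSE) {
  check_substitution_matrix(matrix)
  y <- benchmark_labels(benchmark)
  n_pos <- sum(y == 1L)
  if (n_pos < 2L || sum(y == 0L) < 2L) {
    abort("benchmark must hold at least two items of each class.")
  }
  scheme <- resolve_scheme(scheme, n_pos)
  n <- nrow(benchmark)
  scores <- rep(NA_real_, n)
  fold_of <- rep(NA_integer_, n)

  if (!identical(scheme, "loo")) {
    k <- scheme
    folds <- stratified_folds(y, k, seed)
    for (f in seq_len(k)) {
      tr <- which(folds != f)
      te <- which(folds == f)
      bm_tr <- subset_benchmark(benchmark, tr)
      fit <- optimize_weights(bm_tr, matrix, seed = seed + f, control = pwd)
      pos_tr <- benchmark_positives(bm_tr)
      cfg <- dnn
      cfg$seed <- dnn$seed + f
      enc_tr <- pvt_encode(bm_tr$peptide, pos_tr, fit$weights, matrix)
      model <- train_dnn(enc_tr, benchmark_labels(bm_tr), cfg)
      enc_te <- pvt_encode(benchmark$peptide[te], pos_tr, fit$weights,
                           matrix)
      scores[te] <- predict_proba(model, enc_te)
      fold_of[te] <- f
    }
    scheme_label <- paste0(k, "-fold")
  } else {
    fit_full <- if (exact_loo) NULL else
      optimize_weights(benchmark, matrix, seed = seed, control = pwd)
    for (i in seq_len(n)) {
      tr <- setdiff(seq_len(n), i)
      bm_tr <- subset_benchmark(benchmark, tr)
      w <- if (exact_loo) {
        optimize_weights(bm_tr, matrix, seed = seed + i,
                         control = pwd)$weights
      } else {
        fit_full$weights
      }
      pos_tr <- benchmark_positives(bm_tr)
      cfg <- dnn
      cfg$seed <- dnn$seed + i
      enc_tr <- pvt_encode(bm_tr$peptide, pos_tr, w, matrix)
      model <- train_dnn(enc_tr, benchmark_labels(bm_tr), cfg)
      enc_i <- pvt_encode(benchmark$peptide[i], pos_tr, w, matrix)
      scores[i] <- predict_proba(model, enc_i)
      fold_of[i] <- i
    }
    scheme_label <- "LOO"
  }

  roc <- roc_auc(scores, y)
  metrics <- confusion_metrics(
    tp = sum(scores >= 0.5 & y == 1L), fp = sum(scores >= 0.5 & y == 0L),
    tn = sum(scores < 0.5 & y == 0L), fn = sum(scores < 0.5 & y == 1L))
  structure(
    list(scheme = scheme_label, auc = roc$auc,
         roc_points = roc$roc_points, metrics = metrics,
         scores = tibble(item = seq_len(n), label = y, score = scores,
                         fold = fold_of),
         n_pos = n_pos, n_neg = sum(y == 0L), seed = seed),
    class = "pbs_evaluation")
}

#' @export
print.pbs_evaluation <- function(x, ...) {
  cat(sprintf(
    "<pbs_evaluation> %s; %d positives / %d negatives; pooled AUC %.4f\n",
    x$scheme, x$n_pos, x$n_neg, x$auc))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pbs_evaluation <- function(x, ...) x$scores

#' @exportS3Method generics::glance
glance.pbs_evaluation <- function(x, ...) {
  dplyr::bind_cols(
    tibble(scheme = x$scheme, auc = x$auc, n_pos = x$n_pos,
           n_neg = x$n_neg),
    x$metrics)
}

#' @exportS3Method ggplot2::autoplot
autoplot.pbs_evaluation <- function(object, ...) {
  ggplot(object$roc_points, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    geom_line() +
    coord_equal() +
    labs(x = "1 - Specificity", y = "Sensitivity",
         title = sprintf("%s cross-validation, AUC = %.3f",
                         object$scheme, object$auc)) +
    theme_minimal()
}
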