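#' Fit a complete predictor for one hierarchy node
#'
#' Bundles the full training pipeline for a node of the domain hierarchy:
#' position-weight optimization on the benchmark, pair-similarity encoding
#' of every item, and classifier training (optionally fine-tuned from a
#' parent node's predictor instead of trained from scratch). The returned
#' predictor carries everything needed to score new peptides: the positive
#' peptide set, the optimized weights, the trained network, and (after
#' [calibrate_thresholds()]) the FPR-calibrated score cutoffs.
#'
#' A cluster-level node must own at least 3 positive sites to be
#' admissible for training.
#'
#' @param benchmark A `pbs_benchmark`.
#' @param matrix Substitution matrix.
#' @param pwd A [pwd_control()].
#' @param dnn A [dnn_config()].
#' @param parent Optional parent `pbs_predictor` to fine-tune from.
#' @param fine_tune_epochs Epochs when fine-tuning from `parent`.
#' @param seed Seed for weight optimization.
#' @return An object of class `pbs_predictor`.
#' @export
pbs_predictor <- function(benchmark, matrix = blosum62_21(),
                          pwd = pwd_control(), dnn = dnn_config(),
                          parent = NULL, fine_tune_epochs = 50,
                          seed = 1L) {
  check_substitution_matrix(matrix)
  at <- benchmark_attrs(benchmark)
  node <- at$node
  n_pos <- sum(benchmark$label == "positive")
  if (!is.null(node) && node$level == "cluster" && n_pos < 3L) {
    abort("a single-domain cluster needs at least 3 positive sites.")
  }
  if (!is.null(parent) && !is.null(node) && !is.null(node$parent)) {
    pc <- parent$node
    if (!is.null(pc) &&
        !setequal(pc$center_classes, node$center_classes)) {
      abort("parent predictor reads a different phosphoresidue group.")
    }
  }
  fit <- optimize_weights(benchmark, matrix, seed = seed, control = pwd)
  positives <- benchmark_positives(benchmark)
  enc <- pvt_encode(benchmark$peptide, positives, fit$weights, matrix)
  y <- benchmark_labels(benchmark)
  model <- if (is.null(parent)) {
    train_dnn(enc, y, dnn)
  } else {
    fine_tune(parent$model, enc, y, epochs = fine_tune_epochs,
              seed = dnn$seed)
  }
  structure(
    list(node = node, m = at$m, n = at$n,
         center_classes = at$center_classes,
         positives = positives, pwd = fit, model = model,
         matrix = matrix, thresholds = NULL, seed = seed),
    class = "pbs_predictor")
}

#' @export
print.pbs_predictor <- function(x, ...) {
  nm <- if (!is.null(x$node)) x$node$name else "unnamed"
  cat(sprintf(
    "<pbs_predictor> node %s; PBP(%d, %d); centers %s; %d positives%s\n",
    nm, x$m, x$n, paste(x$center_classes, collapse = "/"),
    length(x$positives),
    if (is.null(x$thresholds)) "; uncalibrated" else "; calibrated"))
  invisible(x)
}

#' Score peptide windows with a fitted predictor
#'
#' @param predictor A `pbs_predictor`.
#' @param peptides Character vector of windows of the predictor's length.
#' @return Numeric probabilities in (0, 1).
#' @export
predict_pbs <- function(predictor, peptides) {
  stopifnot(inherits(predictor, "pbs_predictor"))
  enc <- pvt_encode(peptides, predictor$positives,
                    predictor$pwd$weights, predictor$matrix)
  predict_proba(predictor$model, enc)
}

#' Scan proteins for predicted binding phosphosites
#'
#' Every S/T/Y residue matching a predictor's central classes is windowed
#' with that predictor's (m, n), encoded against its positive set and
#' weights, scored by its classifier, and thresholded at the requested
#' stringency. One record is emitted per (site, predictor) pair that
#' passes; `level = "all"` emits every candidate with its score. Output is
#' sorted by protein, position, then predictor for deterministic diffs.
#'
#' @param proteins Named character vector, `AAStringSet`, or FASTA path.
#' @param predictors A single `pbs_predictor` or a (optionally named) list
#'   of them.
#' @param level `"high"`, `"medium"`, `"low"` or `"all"`. Thresholded
#'   levels require calibrated predictors.
#' @return A tibble with columns `protein_id`, `position`, `residue`,
#'   `peptide`, `predictor`, `score`, `passed_level`.
#' @export
scan_fasta <- function(proteins, predictors, level = "medium") {
  proteins <- as_protein_set(proteins)
  if (inherits(predictors, "pbs_predictor")) {
    predictors <- list(predictors)
  }
  names(predictors) <- names(predictors) %||%
    vapply(predictors, function(p) {
      if (!is.null(p$node)) p$node$name else "predictor"
    }, character(1))
  level <- tolower(level)
  out <- purrr::imap_dfr(predictors, function(p, nm) {
    wins <- purrr::imap_dfr(proteins, function(seq_i, pid) {
      pbp_windows(seq_i, m = p$m, n = p$n,
                  center_classes = p$center_classes, protein_id = pid)
    })
    if (nrow(wins) == 0L) return(tibble())
    wins$predictor <- nm
    wins$score <- predict_pbs(p, wins$peptide)
    wins$passed_level <- score_level(wins$score, p$thresholds)
    if (level != "all") {
      if (is.null(p$thresholds)) {
        abort(sprintf(
          "predictor '%s' is uncalibrated; calibrate it or use level = 'all'.",
          nm))
      }
      wins <- wins[apply_threshold(wins$score, p$thresholds, level), ,
                   drop = FALSE]
    }
    wins
  })
  if (nrow(out) == 0L) {
    return(tibble(protein_id = character(), position = integer(),
                  residue = character(), peptide = character(),
                  predictor = character(), score = double(),
                  passed_level = character()))
  }
  arrange(out, .data$protein_id, .data$position, .data$predictor)
}

#' @rdname scan_fasta
#' @param record A single named sequence (length-1 named character vector).
#' @export
scan_protein <- function(record, predictors, level = "medium") {
  scan_fasta(record, predictors, level = level)
}

# Most stringent threshold level each score passes.
score_level <- function(scores, thresholds) {
  if (is.null(thresholds)) return(rep(NA_character_, length(scores)))
  out <- rep("none", length(scores))
  for (lv in c("low", "medium", "high")) {
    cut <- thresholds$cutoff[thresholds$level == lv]
    out[scores >= cut] <- lv
  }
  out
}
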