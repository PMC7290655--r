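#' Compare fine-tuning against from-scratch training on a small benchmark
#'
#' The controlled experiment behind the transfer-learning design: both
#' arms see the identical stratified `k`-fold split of the child
#' benchmark, the identical encoding (child training-fold positives with
#' the parent's optimized position weights), and the identical classifier
#' architecture; they differ only in initialization — one arm fine-tunes
#' the parent predictor's network, the other trains from random
#' initialization. Held-out scores are pooled into one AUC per arm.
#'
#' @param parent A trained `pbs_predictor` for the parent (group or
#'   family) node.
#' @param child_benchmark A `pbs_benchmark` for the child node (typically
#'   small; transfer matters most at a handful of positives).
#' @param k Folds (default 4, suiting very small positive sets).
#' @param seed Fold and training seed.
#' @param fine_tune_epochs Epochs of fine-tuning per fold (default 30).
#' @param scratch_config Optional [dnn_config()] for the scratch arm;
#'   defaults to the parent's configuration with fresh seeds and no
#'   early-stopping split (the folds are already small).
#' @return A one-row tibble: `auc_fine_tuned`, `auc_scratch`, `n_pos`,
#'   `k`, `seed`.
#' @export
compare_transfer <- function(parent, child_benchmark, k = 4, seed = 1L,
                             fine_tune_epochs = 30,
                             scratch_config = NULL) {
  stopifnot(inherits(parent, "pbs_predictor"))
  y <- benchmark_labels(child_benchmark)
  if (sum(y == 1L) < k) abort("more folds than positive items.")
  folds <- stratified_folds(y, k, seed)
  peptides <- child_benchmark$peptide
  w <- parent$pwd$weights
  cfg <- scratch_config %||% {
    c0 <- parent$model$config
    c0$validation_fraction <- 0
    do.call(dnn_config, unclass(c0))
  }
  scores_ft <- rep(NA_real_, length(y))
  scores_sc <- rep(NA_real_, length(y))
  for (f in seq_len(k)) {
    tr <- which(folds != f)
    te <- which(folds == f)
    pos_tr <- peptides[tr][y[tr] == 1L]
    enc_tr <- pvt_encode(peptides[tr], pos_tr, w, parent$matrix)
    enc_te <- pvt_encode(peptides[te], pos_tr, w, parent$matrix)
    ft <- fine_tune(parent$model, enc_tr, y[tr],
                    epochs = fine_tune_epochs, seed = seed + f,
                    validation_fraction = 0)
    cfg_f <- cfg
    cfg_f$seed <- seed + f
    sc <- train_dnn(enc_tr, y[tr], cfg_f)
    scores_ft[te] <- predict_proba(ft, enc_te)
    scores_sc[te] <- predict_proba(sc, enc_te)
  }
  tibble(auc_fine_tuned = auc_mw(scores_ft, y),
         auc_scratch = auc_mw(scores_sc, y),
         n_pos = sum(y == 1L), k = as.integer(k),
         seed = as.integer(seed))
}
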