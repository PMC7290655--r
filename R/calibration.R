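default_fpr_targets <- function(group) {
  if (identical(group, "pY")) {
    c(high = 0.04, medium = 0.09, low = 0.15)
  } else {
    c(high = 0.02, medium = 0.06, low = 0.10)
  }
}

#' Candidate background windows of a proteome
#'
#' Enumerates every residue of the requested central classes in a protein
#' set and extracts its PBP(m, n) window; the pool that random background
#' draws are taken from during threshold calibration.
#'
#' @param proteins Named character vector, `AAStringSet`, or FASTA path.
#' @param center_classes Central residues to window (e.g. `c("S","T")`).
#' @param m,n Window flanks.
#' @return A tibble of candidate windows (`protein_id`, `position`,
#'   `residue`, `peptide`).
#' @export
background_windows <- function(proteins, center_classes = c("S", "T"),
                               m = 10, n = 10) {
  proteins <- as_protein_set(proteins)
  purrr::imap_dfr(proteins, function(seq_i, pid) {
    pbp_windows(seq_i, m = m, n = n, center_classes = center_classes,
                protein_id = pid)
  })
}

# Conservative empirical cutoff: the smallest observed score c such that
# the fraction of background scores >= c is at most the target FPR; when
# even the maximum score exceeds the target (target < 1/n), a cutoff just
# above the maximum is returned so that nothing passes.
cutoff_at_fpr <- function(scores, target) {
  n <- length(scores)
  u <- sort(unique(scores))
  srt <- sort(scores)
  # number of scores >= each distinct value
  ge <- n - findInterval(u, srt, left.open = TRUE)
  ok <- u[ge / n <= target]
  if (length(ok)) min(ok) else max(scores) + 1e-8
}

#' Calibrate FPR-based decision thresholds against random background
#'
#' Implements the random-background calibration: `repeats` times (default
#' 20), `background_size` (default 10,000) candidate windows of the
#' predictor's central classes are drawn at random from the background
#' pool and scored; the cutoff achieving each target false-positive rate
#' is located as an empirical quantile of the draw, and per-level cutoffs
#' are averaged across the repeats. Default targets are 2/6/10 percent
#' (high/medium/low) for pS/pT-group predictors and 4/9/15 percent for
#' pY-group predictors.
#'
#' @param predictor A `pbs_predictor`.
#' @param background A protein set (named character vector, `AAStringSet`,
#'   FASTA path), a tibble of candidate windows from
#'   [background_windows()], or a bare character vector of peptide
#'   windows.
#' @param seed Integer seed driving the repeated draws.
#' @param background_size Windows per draw (default 10,000).
#' @param repeats Number of draws averaged (default 20).
#' @param targets Optional named numeric vector of target FPRs
#'   (`high`/`medium`/`low`), overriding the group defaults.
#' @return A `threshold_table`: a tibble with columns `level`,
#'   `target_fpr`, `cutoff` (ordered high, medium, low) and attributes
#'   recording the calibration conditions.
#' @export
calibrate_thresholds <- function(predictor, background, seed = 1L,
                                 background_size = 10000, repeats = 20,
                                 targets = NULL) {
  stopifnot(inherits(predictor, "pbs_predictor"))
  if (is.data.frame(background)) {
    pool <- background$peptide
  } else if (is.character(background) && is.null(names(background)) &&
             all(nchar(background) == predictor$m + 1L + predictor$n)) {
    pool <- background
  } else {
    pool <- background_windows(background, predictor$center_classes,
                               predictor$m, predictor$n)$peptide
  }
  if (length(pool) < background_size) {
    abort(sprintf(
      "background supplies %d candidate windows; %d are required.",
      length(pool), background_size))
  }
  group <- if (identical(predictor$center_classes, "Y")) "pY" else "pS/pT"
  targets <- targets %||% default_fpr_targets(group)
  targets <- targets[order(targets)]  # high (smallest FPR) first
  cuts <- matrix(NA_real_, nrow = repeats, ncol = length(targets),
                 dimnames = list(NULL, names(targets)))
  withr::with_seed(seed, {
    for (r in seq_len(repeats)) {
      idx <- sample.int(length(pool), background_size)
      sc <- predict_pbs(predictor, pool[idx])
      for (lv in names(targets)) {
        cuts[r, lv] <- cutoff_at_fpr(sc, targets[[lv]])
      }
    }
  })
  out <- tibble(
    level = names(targets),
    target_fpr = unname(targets),
    cutoff = unname(colMeans(cuts))
  )
  attr(out, "group") <- group
  attr(out, "background_size") <- as.integer(background_size)
  attr(out, "repeats") <- as.integer(repeats)
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("threshold_table", class(out))
  out
}

#' Attach calibrated thresholds to a predictor
#'
#' @inheritParams calibrate_thresholds
#' @return The predictor with its `thresholds` field set.
#' @export
calibrate_predictor <- function(predictor, background, seed = 1L,
                                background_size = 10000, repeats = 20,
                                targets = NULL) {
  predictor$thresholds <- calibrate_thresholds(
    predictor, background, seed = seed,
    background_size = background_size, repeats = repeats,
    targets = targets)
  predictor
}

#' Apply a stringency level to prediction scores
#'
#' `"high"`, `"medium"` and `"low"` keep scores at or above the calibrated
#' cutoff; `"all"` keeps every score (the score itself remains attached to
#' the prediction record). Predictions at stricter levels are always a
#' subset of looser ones.
#'
#' @param scores Numeric scores.
#' @param table A `threshold_table`.
#' @param level `"high"`, `"medium"`, `"low"` or `"all"` (case
#'   insensitive).
#' @return Logical vector, `TRUE` where the score passes.
#' @export
apply_threshold <- function(scores, table, level) {
  level <- tolower(level)
  if (identical(level, "all")) return(rep(TRUE, length(scores)))
  if (!level %in% table$level) {
    abort(sprintf("unknown threshold level '%s'.", level))
  }
  scores >= table$cutoff[table$level == level]
}

#' @export
print.threshold_table <- function(x, ...) {
  cat(sprintf("<threshold_table> %s group; %d x %d background draws\n",
              attr(x, "group"), attr(x, "repeats"),
              attr(x, "background_size")))
  NextMethod()
}
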